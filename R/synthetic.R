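#' Pain intensity classes
#'
#' The four-level pain coding used throughout the package: A = no pain,
#' B = slight pain, C = moderate pain, D = severe pain.
#'
#' @format Character vector of length 4.
#' @export
pain_classes <- c("A", "B", "C", "D")

#' Configuration for the synthetic facial-motion dataset generator
#'
#' Builds the parameter set for [generate_dataset()]. Each class is rendered
#' as a smoothed random base texture warped by a class-specific displacement
#' field: class A is static, B oscillates the lower half of the image
#' vertically (a mouth-region analogue), C expands radially about the image
#' center, and D combines the vertical and radial fields at the largest
#' amplitude. Gaussian pixel noise is added per frame.
#'
#' @param n_per_class Sequences generated per class (default 40, i.e. a
#'   balanced 4-class set of 160 sequences).
#' @param n_frames Frames per sequence, at least 2. The default of 2 makes
#'   each sequence yield exactly one motion image (one consecutive frame
#'   pair), matching a per-image document unit downstream.
#' @param image_size Side of the square frame in pixels (default 64).
#' @param motion_amplitudes Named numeric vector, mean per-frame displacement
#'   magnitude in pixels for classes A-D. Class A must be 0 (no pain means
#'   no motion beyond noise) and amplitudes must be strictly increasing.
#' @param motion_patterns Named character vector mapping each class to one of
#'   `"none"`, `"vertical"`, `"radial"`, `"combined"`.
#' @param noise_sigma Standard deviation of i.i.d. Gaussian pixel noise, in
#'   gray levels on the 0-255 scale.
#' @param texture_smoothness Gaussian blur sigma (pixels) applied to the
#'   uniform-noise base texture; keeps image gradients nonzero everywhere,
#'   which brightness-constancy flow estimation needs.
#' @param seed Master seed; per-sequence seeds are derived from it, so the
#'   same configuration always reproduces the identical dataset.
#'
#' @return An object of class `synth_config`.
#' @seealso [generate_sequence()], [generate_dataset()]
#' @export
synth_config <- function(n_per_class = 40L,
                         n_frames = 2L,
                         image_size = 64L,
                         motion_amplitudes = c(A = 0, B = 0.5, C = 1, D = 2),
                         motion_patterns = c(A = "none", B = "vertical",
                                             C = "radial", D = "combined"),
                         noise_sigma = 2,
                         texture_smoothness = 3,
                         seed = 1L) {
  stopifnot(n_per_class >= 1L, n_frames >= 2L, image_size >= 8L,
            noise_sigma >= 0, texture_smoothness >= 0)
  if (!setequal(names(motion_amplitudes), pain_classes)) {
    stop("`motion_amplitudes` must be named A, B, C, D", call. = FALSE)
  }
  if (!setequal(names(motion_patterns), pain_classes)) {
    stop("`motion_patterns` must be named A, B, C, D", call. = FALSE)
  }
  motion_amplitudes <- motion_amplitudes[pain_classes]
  motion_patterns <- motion_patterns[pain_classes]
  if (any(motion_amplitudes < 0)) {
    stop("motion amplitudes must be nonnegative", call. = FALSE)
  }
  if (motion_amplitudes[["A"]] != 0) {
    stop("class A is 'no pain': its motion amplitude must be 0", call. = FALSE)
  }
  if (any(diff(motion_amplitudes) <= 0)) {
    stop("motion amplitudes must be strictly increasing A < B < C < D",
         call. = FALSE)
  }
  bad <- setdiff(motion_patterns, c("none", "vertical", "radial", "combined"))
  if (length(bad)) {
    stop("unknown motion pattern: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_frames = as.integer(n_frames),
         image_size = as.integer(image_size),
         motion_amplitudes = motion_amplitudes,
         motion_patterns = motion_patterns,
         noise_sigma = noise_sigma,
         texture_smoothness = texture_smoothness,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Unit displacement field for a motion pattern: a list (dx, dy) of matrices
# whose mean per-pixel magnitude is 1 (except "none", which is zero).
pattern_field <- function(pattern, size) {
  zero <- matrix(0, size, size)
  if (pattern == "none") return(list(dx = zero, dy = zero))
  Y <- matrix(seq_len(size), size, size)
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  ctr <- (size + 1) / 2
  field <- switch(
    pattern,
    vertical = {
      # Gaussian bump over the lower half of the image, vertical motion only.
      bump <- exp(-((Y - 0.75 * size)^2) / (2 * (0.15 * size)^2))
      list(dx = zero, dy = bump)
    },
    radial = list(dx = X - ctr, dy = Y - ctr),
    combined = {
      bump <- exp(-((Y - 0.75 * size)^2) / (2 * (0.15 * size)^2))
      rx <- X - ctr
      ry <- Y - ctr
      rn <- mean(sqrt(rx^2 + ry^2))
      bn <- mean(bump)
      list(dx = rx / rn, dy = ry / rn + bump / bn)
    },
    stop("unknown motion pattern: ", pattern, call. = FALSE)
  )
  mag <- mean(sqrt(field$dx^2 + field$dy^2))
  list(dx = field$dx / mag, dy = field$dy / mag)
}

# Scalar motion phase at frame t (0-based). Oscillatory patterns follow a
# triangle wave of period 4 so every frame step has unit magnitude; monotone
# patterns grow linearly. Either way |phase(t+1) - phase(t)| = 1.
pattern_phase <- function(pattern, t) {
  if (pattern == "vertical") c(0, 1, 0, -1)[(t %% 4) + 1] else t
}

#' Generate one labeled synthetic facial-motion sequence
#'
#' Renders `n_frames` grayscale frames (gray levels 0-255) by warping a
#' Gaussian-smoothed uniform-noise base texture with the class's displacement
#' field, scaled so the mean per-pixel displacement between consecutive
#' frames equals the class amplitude, then adding Gaussian pixel noise.
#' Warping uses bilinear interpolation with edge clamping.
#'
#' @param config A [synth_config()].
#' @param class_label One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param seed Integer seed for this sequence (texture and noise).
#'
#' @return A `frame_sequence`: list with `frames` (image_size x image_size x
#'   n_frames array), `label`, `seed`, and `step_field`, the generating
#'   per-frame-step displacement field (list of `dx`, `dy` matrices) whose
#'   mean magnitude equals the class amplitude.
#' @export
generate_sequence <- function(config, class_label, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.character(class_label) || length(class_label) != 1L ||
      !(class_label %in% pain_classes)) {
    stop("`class_label` must be one of ", paste(pain_classes, collapse = ", "),
         call. = FALSE)
  }
  amp <- config$motion_amplitudes[[class_label]]
  if (amp < 0) stop("motion amplitude must be nonnegative", call. = FALSE)
  pat <- config$motion_patterns[[class_label]]
  size <- config$image_size
  unit <- pattern_field(pat, size)

  frames <- with_seed(seed, {
    base <- gaussian_blur(matrix(runif(size * size), size, size),
                          config$texture_smoothness)
    # Stretch back to the full 0-255 range: blurring shrinks contrast and
    # weak gradients starve the flow estimator downstream.
    base <- (base - min(base)) / max(max(base) - min(base), 1e-12) * 255
    arr <- array(0, dim = c(size, size, config$n_frames))
    for (t in seq_len(config$n_frames)) {
      ph <- pattern_phase(pat, t - 1L)
      frame <- if (amp == 0 || pat == "none") {
        base
      } else {
        warp_bilinear(base, amp * ph * unit$dx, amp * ph * unit$dy)
      }
      if (config$noise_sigma > 0) {
        frame <- frame + rnorm(size * size, sd = config$noise_sigma)
      }
      arr[, , t] <- pmin(pmax(frame, 0), 255)
    }
    arr
  })

  structure(
    list(frames = frames,
         label = class_label,
         seed = as.integer(seed),
         pattern = pat,
         amplitude = amp,
         step_field = list(dx = amp * unit$dx, dy = amp * unit$dy)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> class %s, %d frames of %dx%d px (seed %d)\n",
              x$label, d[3], d[1], d[2], x$seed))
  invisible(x)
}

#' Generate a balanced labeled synthetic dataset
#'
#' One call produces `n_per_class` sequences for each of the four pain
#' classes; per-sequence seeds are derived deterministically from
#' `config$seed`, so the same configuration reproduces the identical dataset.
#'
#' @param config A [synth_config()].
#' @return A `pain_dataset`: list of [generate_sequence()] results with the
#'   generating config attached as an attribute.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seqs <- vector("list", 4L * config$n_per_class)
  idx <- 0L
  for (cl in pain_classes) {
    for (i in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      seqs[[idx]] <- generate_sequence(
        config, cl, seed = child_seed(config$seed, idx, salt = match(cl, pain_classes)))
    }
  }
  structure(seqs, class = "pain_dataset", config = config)
}

#' @export
print.pain_dataset <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<pain_dataset> %d sequences (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' Summarize a dataset as a manifest tibble
#'
#' @param dataset A `pain_dataset`.
#' @return A tibble with one row per sequence: `sequence_id`, `class`,
#'   `n_frames`, `seed`.
#' @export
dataset_manifest <- function(dataset) {
  stopifnot(inherits(dataset, "pain_dataset"))
  tibble::tibble(
    sequence_id = sprintf("seq_%04d", seq_along(dataset)),
    class = vapply(dataset, `[[`, character(1), "label"),
    n_frames = vapply(dataset, function(s) dim(s$frames)[3], numeric(1)),
    seed = vapply(dataset, function(s) as.double(s$seed), numeric(1))
  )
}

#' Randomly permute the class labels of a dataset
#'
#' Utility for permutation-null controls: shuffles the sequence labels
#' (seeded) while leaving the pixel data untouched, so any classifier should
#' fall to chance accuracy.
#'
#' @param dataset A `pain_dataset`.
#' @param seed Integer seed for the shuffle.
#' @return The dataset with labels permuted.
#' @export
permute_dataset_labels <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "pain_dataset"))
  labs <- vapply(dataset, `[[`, character(1), "label")
  perm <- with_seed(seed, sample(labs))
  for (i in seq_along(dataset)) dataset[[i]]$label <- perm[[i]]
  dataset
}

#' Write a dataset to disk as per-frame PNG files
#'
#' Frames are written 8-bit grayscale under `class/sequence/frame_####.png`
#' with a `manifest.csv` (columns `sequence_id`, `class`, `path`, `n_frames`)
#' at the root.
#'
#' @param dataset A `pain_dataset`.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pain_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset_manifest(dataset)
  man$path <- file.path(man$class, man$sequence_id)
  for (i in seq_along(dataset)) {
    sdir <- file.path(dir, man$path[i])
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    fr <- dataset[[i]]$frames
    for (t in seq_len(dim(fr)[3])) {
      png::writePNG(fr[, , t] / 255,
                    file.path(sdir, sprintf("frame_%04d.png", t)))
    }
  }
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A `pain_dataset` (gray levels restored to the 0-255 scale; seeds
#'   and generating fields are not persisted).
#' @export
read_dataset <- function(dir) {
  man <- readr::read_csv(file.path(dir, "manifest.csv"),
                         show_col_types = FALSE)
  seqs <- lapply(seq_len(nrow(man)), function(i) {
    files <- sort(list.files(file.path(dir, man$path[i]),
                             pattern = "^frame_\\d+\\.png$", full.names = TRUE))
    mats <- lapply(files, function(f) png::readPNG(f) * 255)
    arr <- array(0, dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
    for (t in seq_along(mats)) arr[, , t] <- mats[[t]]
    structure(list(frames = arr, label = man$class[i], seed = NA_integer_,
                   pattern = NA_character_, amplitude = NA_real_,
                   step_field = NULL),
              class = "frame_sequence")
  })
  structure(seqs, class = "pain_dataset", config = NULL)
}
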