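#' Extract block-wise motion descriptors from flow channels
#'
#' Tiles the frame into non-overlapping `L x L` blocks (row-major over the
#' block grid) and concatenates, per block, the four blurred channels in
#' fixed channel-major, row-major-within-block order, giving descriptors of
#' length `4 * L^2`. With `mode = "raw2"` the signed components
#' `ux = ux+ - ux-` and `uy = uy+ - uy-` are used instead (length `2 * L^2`).
#'
#' @param channels A `flow_channels` object.
#' @param L Block side in pixels; must divide the image size exactly.
#' @param mode `"rectified4"` (default, the four nonnegative channels) or
#'   `"raw2"` (the two signed components).
#' @return Numeric matrix with one descriptor per row,
#'   `(image_size / L)^2` rows; attributes `block_row`/`block_col` give grid
#'   coordinates, `L` and `mode` record the geometry.
#' @export
extract_block_descriptors <- function(channels, L, mode = c("rectified4", "raw2")) {
  mode <- match.arg(mode)
  stopifnot(inherits(channels, "flow_channels"))
  n <- nrow(channels$ubx_pos)
  m <- ncol(channels$ubx_pos)
  if (n != m) stop("flow channels must be square", call. = FALSE)
  L <- as.integer(L)
  if (L < 1L || n %% L != 0L) {
    stop(sprintf("block size L = %d must divide the image size %d", L, n),
         call. = FALSE)
  }
  mats <- if (mode == "rectified4") {
    list(channels$ubx_pos, channels$ubx_neg, channels$uby_pos, channels$uby_neg)
  } else {
    list(channels$ubx_pos - channels$ubx_neg,
         channels$uby_pos - channels$uby_neg)
  }
  g <- n %/% L
  n_blocks <- g * g
  dim_desc <- length(mats) * L * L
  out <- matrix(0, n_blocks, dim_desc)
  block_row <- integer(n_blocks)
  block_col <- integer(n_blocks)
  b <- 0L
  for (br in seq_len(g)) {
    rows <- ((br - 1L) * L + 1L):(br * L)
    for (bc in seq_len(g)) {
      b <- b + 1L
      cols <- ((bc - 1L) * L + 1L):(bc * L)
      # row-major flatten within the block, channels concatenated
      out[b, ] <- unlist(lapply(mats, function(mm) as.vector(t(mm[rows, cols]))))
      block_row[b] <- br
      block_col[b] <- bc
    }
  }
  structure(out, block_row = block_row, block_col = block_col,
            L = L, mode = mode)
}

# k-means++ style seeding: first center uniform, then points with
# probability proportional to squared distance to the nearest chosen center.
# Zero-distance duplicates can never be re-picked, so centers are distinct
# whenever the data has >= M distinct rows.
kmeanspp_centers <- function(x, M) {
  n <- nrow(x)
  xs <- rowSums(x^2)
  dist2_to <- function(ctr) {
    # ||x - c||^2 expanded; clamp tiny negative round-off to zero
    pmax(xs - 2 * drop(x %*% ctr) + sum(ctr^2), 0)
  }
  centers <- matrix(0, M, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- dist2_to(centers[1L, ])
  for (k in seq_len(M - 1L)) {
    if (all(d2 <= 0)) stop("fewer distinct descriptors than M", call. = FALSE)
    idx <- sample.int(n, 1L, prob = d2)
    centers[k + 1L, ] <- x[idx, ]
    d2 <- pmin(d2, dist2_to(centers[k + 1L, ]))
  }
  centers
}

#' Build a visual-word codebook by k-means clustering
#'
#' Clusters a random subset of block descriptors into `M` visual words
#' (squared-Euclidean k-means, k-means++-style seeding, several restarts
#' keeping the lowest within-cluster sum of squares). Deterministic given
#' the seed.
#'
#' @param descriptors Numeric matrix of block descriptors (rows), e.g. rows
#'   bound from [extract_block_descriptors()] over many frames.
#' @param M Vocabulary size (number of cluster centers), at least 2.
#' @param seed Integer seed controlling subsampling and seeding.
#' @param subset_size Maximum number of descriptors used for clustering
#'   (default 10000); a random subset is drawn when more are supplied.
#' @param n_restarts Number of seeded k-means restarts (default 3; k-means++
#'   seeding makes additional restarts largely redundant).
#' @param iter_max Lloyd iteration cap per restart.
#' @param L,mode Block geometry recorded in the codebook; taken from the
#'   descriptor attributes when present.
#' @return A `flow_codebook`: list with `centroids` (M x descriptor-dim
#'   matrix), `M`, `L`, `mode`, `seed`, `inertia`.
#' @export
build_codebook <- function(descriptors, M, seed = 1L, subset_size = 10000L,
                           n_restarts = 3L, iter_max = 30L,
                           L = attr(descriptors, "L"),
                           mode = attr(descriptors, "mode") %||% "rectified4") {
  if (!is.matrix(descriptors)) descriptors <- as.matrix(descriptors)
  M <- as.integer(M)
  if (M < 2L) stop("vocabulary size M must be at least 2", call. = FALSE)
  x <- with_seed(child_seed(seed, 1L, salt = 11L), {
    if (nrow(descriptors) > subset_size) {
      descriptors[sample.int(nrow(descriptors), subset_size), , drop = FALSE]
    } else {
      descriptors
    }
  })
  n_distinct <- nrow(unique(x))
  if (n_distinct < M) {
    stop(sprintf("need at least M = %d distinct descriptors, got %d",
                 M, n_distinct), call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(child_seed(seed, r, salt = 13L), {
      init <- kmeanspp_centers(x, M)
      tryCatch(
        stats::kmeans(x, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd"),
        error = function(e) NULL,
        warning = function(w) {
          # Lloyd not converged within iter.max: keep the fit anyway.
          suppressWarnings(stats::kmeans(x, centers = init,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd"))
        })
    })
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("k-means failed on all restarts", call. = FALSE)
  if (!is.null(L)) L <- as.integer(L)
  structure(
    list(centroids = unname(best$centers), M = M, L = L, mode = mode,
         seed = as.integer(seed), inertia = best$tot.withinss),
    class = "flow_codebook"
  )
}

#' @export
print.flow_codebook <- function(x, ...) {
  cat(sprintf("<flow_codebook> M = %d words, descriptor dim %d (L = %s, %s)\n",
              x$M, ncol(x$centroids),
              if (is.null(x$L)) "?" else x$L, x$mode))
  invisible(x)
}

# Squared Euclidean distances between descriptor rows and centroids.
cross_dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * tcrossprod(x, centers)
}

#' Quantize descriptors to visual-word indices
#'
#' Assigns each descriptor to the Euclidean-nearest codebook centroid; exact
#' ties go to the smallest index.
#'
#' @param descriptors A numeric vector (single descriptor) or matrix (one
#'   per row).
#' @param codebook A `flow_codebook`.
#' @return Integer vector of word indices in `1..M`.
#' @export
quantize <- function(descriptors, codebook) {
  stopifnot(inherits(codebook, "flow_codebook"))
  if (is.null(dim(descriptors))) descriptors <- matrix(descriptors, nrow = 1L)
  if (ncol(descriptors) != ncol(codebook$centroids)) {
    stop(sprintf("descriptor dimension %d does not match codebook dimension %d",
                 ncol(descriptors), ncol(codebook$centroids)), call. = FALSE)
  }
  d2 <- cross_dist2(descriptors, codebook$centroids)
  max.col(-d2, ties.method = "first")
}

#' Bag-of-visual-words histogram of one frame's motion channels
#'
#' Counts, for each visual word, how many of the frame's blocks quantize to
#' it. The counts always sum to the number of blocks,
#' `(image_size / L)^2`.
#'
#' @param channels A `flow_channels` object.
#' @param codebook A `flow_codebook` (supplies `L` and descriptor mode).
#' @return Named integer vector of length `M` (`w1 ... wM`).
#' @export
bow_histogram <- function(channels, codebook) {
  stopifnot(inherits(codebook, "flow_codebook"))
  if (is.null(codebook$L)) {
    stop("codebook does not record a block size L", call. = FALSE)
  }
  desc <- extract_block_descriptors(channels, codebook$L, codebook$mode)
  idx <- quantize(desc, codebook)
  counts <- tabulate(idx, nbins = codebook$M)
  names(counts) <- paste0("w", seq_len(codebook$M))
  counts
}

#' Assemble a document-term matrix of bag-of-words histograms
#'
#' @param counts Nonnegative integer matrix, documents in rows, visual words
#'   in columns.
#' @param labels Optional per-document class labels (character or factor).
#' @param doc_ids Optional document identifiers.
#' @return A `flow_dtm`: list with `counts`, `labels` (factor or NULL),
#'   `doc_ids`, `doc_lengths`.
#' @export
flow_dtm <- function(counts, labels = NULL, doc_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be nonnegative integers", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(counts)) {
      stop("`labels` length must match the number of documents", call. = FALSE)
    }
    labels <- factor(labels)
  }
  doc_ids <- doc_ids %||% sprintf("doc_%04d", seq_len(nrow(counts)))
  structure(
    list(counts = unname(counts), labels = labels, doc_ids = doc_ids,
         doc_lengths = rowSums(counts)),
    class = "flow_dtm"
  )
}

#' @export
print.flow_dtm <- function(x, ...) {
  cat(sprintf("<flow_dtm> %d documents x %d words%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", nlevels(x$labels))))
  invisible(x)
}

#' @describeIn flow_dtm Long-format view: one row per nonzero
#'   (document, word) count.
#' @param x A `flow_dtm`.
#' @param ... Unused.
#' @export
tidy.flow_dtm <- function(x, ...) {
  nz <- which(x$counts > 0, arr.ind = TRUE)
  tibble::tibble(
    doc_id = x$doc_ids[nz[, 1]],
    label = if (is.null(x$labels)) NA_character_ else
      as.character(x$labels[nz[, 1]]),
    word = paste0("w", nz[, 2]),
    count = x$counts[nz]
  ) |> dplyr::arrange(.data$doc_id, .data$word)
}

#' Encode a list of flow-channel frames as a labeled document-term matrix
#'
#' Convenience wrapper applying [bow_histogram()] to every element.
#'
#' @param channels_list List of `flow_channels`.
#' @param codebook A `flow_codebook`.
#' @param labels Optional per-document labels.
#' @param doc_ids Optional document ids.
#' @return A `flow_dtm`.
#' @export
encode_documents <- function(channels_list, codebook, labels = NULL,
                             doc_ids = NULL) {
  counts <- t(vapply(channels_list, bow_histogram,
                     integer(codebook$M), codebook = codebook))
  flow_dtm(counts, labels = labels, doc_ids = doc_ids)
}

#' Persist a codebook as JSON + CSV centroids
#'
#' Writes `<path>.json` (geometry header) and `<path>.csv` (centroid
#' matrix), both plain text.
#'
#' @param codebook A `flow_codebook`.
#' @param path Output path prefix (without extension).
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "flow_codebook"))
  jsonlite::write_json(
    list(M = codebook$M, L = codebook$L, mode = codebook$mode,
         seed = codebook$seed, inertia = codebook$inertia),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(as.data.frame(codebook$centroids), paste0(path, ".csv"),
                   col_names = FALSE)
  invisible(path)
}

#' Read a codebook written by [write_codebook()]
#'
#' @param path Path prefix used when writing.
#' @return A `flow_codebook`.
#' @export
read_codebook <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cent <- as.matrix(readr::read_csv(paste0(path, ".csv"), col_names = FALSE,
                                    show_col_types = FALSE))
  structure(
    list(centroids = unname(cent), M = as.integer(hdr$M),
         L = if (is.null(hdr$L)) NULL else as.integer(hdr$L),
         mode = hdr$mode, seed = as.integer(hdr$seed),
         inertia = hdr$inertia),
    class = "flow_codebook"
  )
}
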