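#' Configuration for dense optical-flow estimation
#'
#' Parameters of the iterative Horn-Schunck-style estimator and of the
#' downstream channel post-processing (Gaussian blur and normalization).
#'
#' @param lambda_reg Smoothness regularization weight (dimensionless, > 0).
#'   Enters the update denominator as `lambda + Ix^2 + Iy^2`; larger values
#'   damp the data term and yield smoother, smaller flow.
#' @param n_iterations Maximum number of fixed-point iterations.
#' @param convergence_tol Stop when the mean absolute update of the two flow
#'   components falls below this threshold (pixels/frame).
#' @param blur_sigma Gaussian blur sigma (pixels) applied to the four
#'   rectified channels; 0 disables blurring.
#' @param normalization One of `"frame-max"` (each channel divided by the
#'   maximum over all four channels of that frame, zero-guarded),
#'   `"global-max"` (divide by the maximum over all frames of a sequence;
#'   only meaningful in [sequence_flow_channels()]), or `"none"`.
#'
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(lambda_reg = 100,
                        n_iterations = 100L,
                        convergence_tol = 1e-4,
                        blur_sigma = 1.5,
                        normalization = c("frame-max", "global-max", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(lambda_reg > 0, n_iterations >= 1L, convergence_tol > 0,
            blur_sigma >= 0)
  structure(
    list(lambda_reg = lambda_reg,
         n_iterations = as.integer(n_iterations),
         convergence_tol = convergence_tol,
         blur_sigma = blur_sigma,
         normalization = normalization),
    class = "flow_config"
  )
}

#' Spatiotemporal image derivatives for optical flow
#'
#' Classic Horn-Schunck derivative estimates from a consecutive frame pair:
#' each spatial derivative is the average of four forward differences over
#' the 2x2x2 cube spanning both frames; the temporal derivative is the
#' average of the four frame differences. Border values use edge clamping.
#'
#' @param frame_t,frame_t1 Same-shape numeric matrices (grayscale frames),
#'   at least 2x2.
#' @return List with matrices `Ix`, `Iy`, `It`.
#' @export
image_derivatives <- function(frame_t, frame_t1) {
  stop_if_not_matrix(frame_t, "frame_t")
  stop_if_not_matrix(frame_t1, "frame_t1")
  if (!identical(dim(frame_t), dim(frame_t1))) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  if (any(dim(frame_t) < 2L)) {
    stop("frames must be at least 2x2 pixels", call. = FALSE)
  }
  f1 <- frame_t
  f2 <- frame_t1
  # x = column direction, y = row direction.
  Ix <- 0.25 * ((shift_clamp(f1, 0, 1) - f1) +
                (shift_clamp(f1, 1, 1) - shift_clamp(f1, 1, 0)) +
                (shift_clamp(f2, 0, 1) - f2) +
                (shift_clamp(f2, 1, 1) - shift_clamp(f2, 1, 0)))
  Iy <- 0.25 * ((shift_clamp(f1, 1, 0) - f1) +
                (shift_clamp(f1, 1, 1) - shift_clamp(f1, 0, 1)) +
                (shift_clamp(f2, 1, 0) - f2) +
                (shift_clamp(f2, 1, 1) - shift_clamp(f2, 0, 1)))
  It <- 0.25 * ((f2 - f1) +
                (shift_clamp(f2, 1, 0) - shift_clamp(f1, 1, 0)) +
                (shift_clamp(f2, 0, 1) - shift_clamp(f1, 0, 1)) +
                (shift_clamp(f2, 1, 1) - shift_clamp(f1, 1, 1)))
  list(Ix = Ix, Iy = Iy, It = It)
}

# Horn-Schunck weighted neighborhood average: 1/6 for the 4-neighbors and
# 1/12 for the diagonals, edge-clamped borders.
hs_neighborhood_mean <- function(u) {
  (shift_clamp(u, -1, 0) + shift_clamp(u, 1, 0) +
     shift_clamp(u, 0, -1) + shift_clamp(u, 0, 1)) / 6 +
    (shift_clamp(u, -1, -1) + shift_clamp(u, -1, 1) +
       shift_clamp(u, 1, -1) + shift_clamp(u, 1, 1)) / 12
}

#' Estimate dense optical flow between two frames
#'
#' Iterative Horn-Schunck scheme: starting from a zero field, each iteration
#' replaces the flow by the neighborhood mean corrected along the image
#' gradient,
#' \deqn{u^{k+1} = \bar u^k - \nabla I \,
#'   \frac{I_x \bar u_x^k + I_y \bar u_y^k + I_t}{\lambda + I_x^2 + I_y^2},}
#' until the mean absolute update drops below `convergence_tol` or
#' `n_iterations` is reached. Identical frames return the exact zero field.
#'
#' @param frame_t,frame_t1 Same-shape numeric matrices.
#' @param config A [flow_config()].
#' @return A `flow_field`: list with matrices `ux`, `uy` (pixels/frame),
#'   iteration count `n_iter`, and `converged` flag.
#' @export
horn_schunck_flow <- function(frame_t, frame_t1, config = flow_config()) {
  stopifnot(inherits(config, "flow_config"))
  d <- image_derivatives(frame_t, frame_t1)
  den <- config$lambda_reg + d$Ix^2 + d$Iy^2
  ux <- matrix(0, nrow(frame_t), ncol(frame_t))
  uy <- ux
  n_iter <- 0L
  converged <- FALSE
  for (k in seq_len(config$n_iterations)) {
    ubx <- hs_neighborhood_mean(ux)
    uby <- hs_neighborhood_mean(uy)
    resid <- (d$Ix * ubx + d$Iy * uby + d$It) / den
    ux_new <- ubx - d$Ix * resid
    uy_new <- uby - d$Iy * resid
    delta <- (mean(abs(ux_new - ux)) + mean(abs(uy_new - uy))) / 2
    ux <- ux_new
    uy <- uy_new
    n_iter <- k
    if (delta < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(ux = ux, uy = uy, n_iter = n_iter, converged = converged),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %dx%d px, %d iterations%s; mean |u| = %.4g\n",
              nrow(x$ux), ncol(x$ux), x$n_iter,
              if (x$converged) " (converged)" else "",
              mean(sqrt(x$ux^2 + x$uy^2))))
  invisible(x)
}

#' Smoothness-plus-data objective of a flow field
#'
#' Evaluates the discrete functional the iterative scheme relaxes:
#' `lambda * (||grad ux||^2 + ||grad uy||^2)` (forward differences) plus the
#' squared brightness-constancy residual, summed over pixels. Useful for
#' checking that iterates do not increase the objective.
#'
#' @param flow A `flow_field`.
#' @param derivatives Output of [image_derivatives()] for the same frame pair.
#' @param lambda_reg Regularization weight.
#' @return Scalar objective value.
#' @export
flow_objective <- function(flow, derivatives, lambda_reg) {
  gx <- function(u) shift_clamp(u, 0, 1) - u
  gy <- function(u) shift_clamp(u, 1, 0) - u
  smooth <- sum(gx(flow$ux)^2 + gy(flow$ux)^2 + gx(flow$uy)^2 + gy(flow$uy)^2)
  resid <- derivatives$Ix * flow$ux + derivatives$Iy * flow$uy + derivatives$It
  lambda_reg * smooth + sum(resid^2)
}

#' Half-wave rectify a flow field into four nonnegative channels
#'
#' Splits each signed component into its positive and negative parts:
#' `u+ = max(u, 0)`, `u- = max(-u, 0)`, so `u+ - u-` reconstructs `u`
#' exactly at every pixel.
#'
#' @param flow A `flow_field` (or list with `ux`, `uy` matrices).
#' @return List with matrices `ux_pos`, `ux_neg`, `uy_pos`, `uy_neg`.
#' @export
rectify_channels <- function(flow) {
  stop_if_not_matrix(flow$ux, "ux")
  stop_if_not_matrix(flow$uy, "uy")
  list(ux_pos = pmax(flow$ux, 0), ux_neg = pmax(-flow$ux, 0),
       uy_pos = pmax(flow$uy, 0), uy_neg = pmax(-flow$uy, 0))
}

#' Blur and normalize rectified motion channels
#'
#' Convolves each nonnegative channel with an isotropic Gaussian (mirror
#' boundary, unit-mass kernel) and normalizes per the configured scheme.
#' Under `"frame-max"` every channel is divided by the maximum over all four
#' channels of the frame (zero-guarded), preserving the channels' relative
#' magnitudes while mapping into \[0, 1\].
#'
#' @param channels List of four nonnegative matrices as returned by
#'   [rectify_channels()].
#' @param config A [flow_config()] (`blur_sigma`, `normalization`).
#' @return A `flow_channels` object: list of matrices `ubx_pos`, `ubx_neg`,
#'   `uby_pos`, `uby_neg`.
#' @export
blur_and_normalize <- function(channels, config = flow_config()) {
  stopifnot(inherits(config, "flow_config"))
  ch <- channels[c("ux_pos", "ux_neg", "uy_pos", "uy_neg")]
  if (any(vapply(ch, is.null, logical(1)))) {
    stop("`channels` must contain ux_pos, ux_neg, uy_pos, uy_neg",
         call. = FALSE)
  }
  for (nm in names(ch)) {
    stop_if_not_matrix(ch[[nm]], nm)
    if (any(ch[[nm]] < 0)) {
      stop("rectified channels must be nonnegative", call. = FALSE)
    }
  }
  ch <- lapply(ch, gaussian_blur, sigma = config$blur_sigma)
  if (config$normalization == "frame-max") {
    mx <- max(vapply(ch, max, numeric(1)))
    if (mx > 0) ch <- lapply(ch, function(m) m / mx)
  }
  names(ch) <- c("ubx_pos", "ubx_neg", "uby_pos", "uby_neg")
  structure(ch, class = "flow_channels")
}

#' Motion channels for every consecutive frame pair of a sequence
#'
#' Runs [horn_schunck_flow()], [rectify_channels()] and
#' [blur_and_normalize()] for each of the `n_frames - 1` consecutive pairs.
#' Under `normalization = "global-max"` the division uses the maximum channel
#' value across the whole sequence instead of per frame.
#'
#' @param seq A `frame_sequence` (or a 3-D array of frames).
#' @param config A [flow_config()].
#' @return List of `flow_channels`, one per frame pair.
#' @export
sequence_flow_channels <- function(seq, config = flow_config()) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`seq` must be a frame_sequence or a 3-D array", call. = FALSE)
  }
  n_t <- dim(frames)[3]
  if (n_t < 2L) stop("sequence must have at least 2 frames", call. = FALSE)
  blur_cfg <- config
  if (config$normalization == "global-max") blur_cfg$normalization <- "none"
  out <- lapply(seq_len(n_t - 1L), function(t) {
    fl <- horn_schunck_flow(frames[, , t], frames[, , t + 1L], config)
    blur_and_normalize(rectify_channels(fl), blur_cfg)
  })
  if (config$normalization == "global-max") {
    mx <- max(vapply(out, function(ch) max(vapply(ch, max, numeric(1))),
                     numeric(1)))
    if (mx > 0) {
      out <- lapply(out, function(ch) {
        structure(lapply(ch, function(m) m / mx), class = "flow_channels")
      })
    }
  }
  out
}

#' @export
print.flow_channels <- function(x, ...) {
  cat(sprintf("<flow_channels> %dx%d px, mean energy %.4g\n",
              nrow(x$ubx_pos), ncol(x$ubx_pos),
              mean(x$ubx_pos + x$ubx_neg + x$uby_pos + x$uby_neg)))
  invisible(x)
}
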