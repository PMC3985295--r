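# Internal numeric helpers shared across modules: seeded RNG scoping,
# separable Gaussian convolution with reflective borders, clamped matrix
# shifts, and bilinear warping.

# Run `code` under a temporary RNG state; the caller's state is untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
child_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) + 100003 * as.double(salt) + as.double(index)) %%
               2147483646) + 1L
}

# Discrete Gaussian taps, truncated at 3 sigma, normalized to unit mass.
gaussian_kernel_1d <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Mirror (symmetric, edge repeated) index into 1..n.
mirror_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Separable convolution of a matrix with a 1-D kernel applied along both
# axes; borders are handled by mirror reflection so total mass is conserved
# for a unit-mass kernel.
convolve_separable <- function(x, kernel) {
  taps <- length(kernel)
  if (taps == 1L) return(x * kernel)
  r <- (taps - 1L) %/% 2L
  offs <- seq.int(-r, r)
  n <- nrow(x)
  m <- ncol(x)
  out <- matrix(0, n, m)
  for (t in seq_len(taps)) {
    out <- out + kernel[t] * x[mirror_index(seq_len(n) + offs[t], n), , drop = FALSE]
  }
  x <- out
  out <- matrix(0, n, m)
  for (t in seq_len(taps)) {
    out <- out + kernel[t] * x[, mirror_index(seq_len(m) + offs[t], m), drop = FALSE]
  }
  out
}

gaussian_blur <- function(x, sigma) {
  if (sigma == 0) return(x)
  convolve_separable(x, gaussian_kernel_1d(sigma))
}

# Shift a matrix by (dr, dc) with edge clamping: entry (i, j) of the result
# is x[clamp(i + dr), clamp(j + dc)].
shift_clamp <- function(x, dr, dc) {
  n <- nrow(x)
  m <- ncol(x)
  ri <- pmin(pmax(seq_len(n) + dr, 1L), n)
  ci <- pmin(pmax(seq_len(m) + dc, 1L), m)
  x[ri, ci, drop = FALSE]
}

# Backward bilinear warp: result(i, j) = img(i - dy(i,j), j - dx(i,j)),
# sampling positions clamped to the image domain.
warp_bilinear <- function(img, dx, dy) {
  n <- nrow(img)
  m <- ncol(img)
  Y <- matrix(seq_len(n), n, m)
  X <- matrix(seq_len(m), n, m, byrow = TRUE)
  xs <- pmin(pmax(X - dx, 1), m)
  ys <- pmin(pmax(Y - dy, 1), n)
  x0 <- pmin(floor(xs), m - 1L)
  y0 <- pmin(floor(ys), n - 1L)
  if (m == 1L) x0[] <- 1
  if (n == 1L) y0[] <- 1
  fx <- xs - x0
  fy <- ys - y0
  x1 <- pmin(x0 + 1, m)
  y1 <- pmin(y0 + 1, n)
  at <- function(yy, xx) matrix(img[cbind(as.vector(yy), as.vector(xx))], n, m)
  (1 - fy) * ((1 - fx) * at(y0, x0) + fx * at(y0, x1)) +
    fy * ((1 - fx) * at(y1, x0) + fx * at(y1, x1))
}

stop_if_not_matrix <- function(x, arg) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
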