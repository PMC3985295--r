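#' EM configuration for the supervised pLSA model
#'
#' @param max_iterations Iteration cap for training EM (default 500).
#' @param tol Relative log-likelihood change below which EM stops
#'   (default 1e-6).
#' @param smoothing_alpha Pseudo-count added to the label-informed
#'   initialization of the word-topic matrix; keeps words unseen in a class
#'   at strictly positive probability so unseen-word test documents remain
#'   well defined (default 1e-3).
#' @param seed Seed for the random (Dirichlet) initialization of the
#'   document-topic matrix.
#' @param max_iterations_fold_in Iteration cap for fold-in inference
#'   (default 100).
#' @param anchor `"none"` (plain EM, default) or `"hard"` (re-impose the
#'   one-hot label distribution on the document-topic rows after every M-step,
#'   guarding against topic-label drift).
#' @param fold_in_matrix `"refined"` (default: fold-in uses the EM-refined
#'   word-topic matrix) or `"init"` (use the raw label-informed count-ratio
#'   matrix instead).
#' @return An object of class `em_config`.
#' @export
em_config <- function(max_iterations = 500L,
                      tol = 1e-6,
                      smoothing_alpha = 1e-3,
                      seed = 1L,
                      max_iterations_fold_in = 100L,
                      anchor = c("none", "hard"),
                      fold_in_matrix = c("refined", "init")) {
  anchor <- match.arg(anchor)
  fold_in_matrix <- match.arg(fold_in_matrix)
  stopifnot(max_iterations >= 1L, tol > 0, smoothing_alpha >= 0,
            max_iterations_fold_in >= 1L)
  structure(
    list(max_iterations = as.integer(max_iterations), tol = tol,
         smoothing_alpha = smoothing_alpha, seed = as.integer(seed),
         max_iterations_fold_in = as.integer(max_iterations_fold_in),
         anchor = anchor, fold_in_matrix = fold_in_matrix),
    class = "em_config"
  )
}

# Numerical floor used in E-step denominators and log arguments.
.plsa_floor <- 1e-12

#' Label-informed initialization of the word-topic matrix
#'
#' For each class k, `p(w_j | z_k) = (n_jk + alpha) / (n_k + alpha * M)`,
#' where `n_jk` is the total count of word j over the class-k training
#' documents and `n_k` the total word count of class k. With `alpha = 0`
#' this is the exact per-class count ratio.
#'
#' @param dtm A labeled [flow_dtm()].
#' @param K Number of topics; must equal the number of label levels.
#' @param smoothing_alpha Pseudo-count (>= 0).
#' @return K x M row-stochastic matrix, rows named by class.
#' @export
supervised_init <- function(dtm, K = nlevels(dtm$labels),
                            smoothing_alpha = 0) {
  stopifnot(inherits(dtm, "flow_dtm"))
  if (is.null(dtm$labels)) {
    stop("supervised initialization needs a labeled dtm", call. = FALSE)
  }
  if (K != nlevels(dtm$labels)) {
    stop(sprintf("K = %d does not match the %d label levels",
                 K, nlevels(dtm$labels)), call. = FALSE)
  }
  if (any(tabulate(dtm$labels, nbins = K) == 0L)) {
    stop("every class must have at least one training document",
         call. = FALSE)
  }
  M <- ncol(dtm$counts)
  pw <- matrix(0, K, M, dimnames = list(levels(dtm$labels), NULL))
  for (k in seq_len(K)) {
    njk <- colSums(dtm$counts[dtm$labels == levels(dtm$labels)[k], ,
                              drop = FALSE])
    pw[k, ] <- (njk + smoothing_alpha) / (sum(njk) + smoothing_alpha * M)
  }
  pw
}

#' E-step posterior of the pLSA model
#'
#' Computes `p(z_k | d_i, w_j) = p(w_j | z_k) p(z_k | d_i) /
#' sum_l p(w_j | z_l) p(z_l | d_i)` for every document-word pair.
#' Denominators are floored at 1e-12, which smoothing renders inactive in
#' normal use.
#'
#' @param p_w_given_z K x M row-stochastic word-topic matrix.
#' @param p_z_given_d n x K row-stochastic document-topic matrix.
#' @return n x M x K array of posteriors, summing to 1 over the topic axis.
#' @export
em_e_step <- function(p_w_given_z, p_z_given_d) {
  K <- nrow(p_w_given_z)
  n <- nrow(p_z_given_d)
  M <- ncol(p_w_given_z)
  stopifnot(ncol(p_z_given_d) == K)
  denom <- pmax(p_z_given_d %*% p_w_given_z, .plsa_floor)   # n x M
  post <- array(0, dim = c(n, M, K))
  for (k in seq_len(K)) {
    post[, , k] <- outer(p_z_given_d[, k], p_w_given_z[k, ]) / denom
  }
  post
}

#' M-step updates of the pLSA model
#'
#' Re-estimates the word-topic and document-topic matrices from the E-step
#' posterior weighted by the observed counts:
#' `p(w_j | z_k)` proportional to `sum_i n(d_i, w_j) p(z_k | d_i, w_j)` and
#' `p(z_k | d_i) = sum_j n(d_i, w_j) p(z_k | d_i, w_j) / n(d_i)`.
#'
#' @param posterior n x M x K array from [em_e_step()].
#' @param dtm A [flow_dtm()] (documents must be non-empty).
#' @return List with `p_w_given_z` (K x M) and `p_z_given_d` (n x K), both
#'   row-stochastic.
#' @export
em_m_step <- function(posterior, dtm) {
  stopifnot(inherits(dtm, "flow_dtm"))
  if (any(dtm$doc_lengths == 0)) {
    stop("empty documents are not allowed", call. = FALSE)
  }
  n <- dim(posterior)[1]
  M <- dim(posterior)[2]
  K <- dim(posterior)[3]
  stopifnot(nrow(dtm$counts) == n, ncol(dtm$counts) == M)
  pw <- matrix(0, K, M)
  pz <- matrix(0, n, K)
  for (k in seq_len(K)) {
    wk <- dtm$counts * posterior[, , k]     # n x M weighted counts
    pw[k, ] <- colSums(wk)
    pz[, k] <- rowSums(wk)
  }
  pw <- pw / pmax(rowSums(pw), .plsa_floor)
  pz <- pz / dtm$doc_lengths
  list(p_w_given_z = pw, p_z_given_d = pz)
}

#' Corpus log-likelihood of a pLSA model
#'
#' `l = sum_i sum_j n(d_i, w_j) log p(w_j | d_i)` with the word-document
#' marginal `p(w_j | d_i) = sum_k p(z_k | d_i) p(w_j | z_k)`. Returns `-Inf`
#' if an observed pair has zero marginal probability.
#'
#' @param dtm A [flow_dtm()].
#' @param p_w_given_z K x M word-topic matrix.
#' @param p_z_given_d n x K document-topic matrix.
#' @return Scalar log-likelihood.
#' @export
plsa_log_likelihood <- function(dtm, p_w_given_z, p_z_given_d) {
  stopifnot(inherits(dtm, "flow_dtm"),
            nrow(dtm$counts) == nrow(p_z_given_d),
            ncol(dtm$counts) == ncol(p_w_given_z),
            ncol(p_z_given_d) == nrow(p_w_given_z))
  marg <- p_z_given_d %*% p_w_given_z
  obs <- dtm$counts > 0
  if (any(marg[obs] <= 0)) return(-Inf)
  sum(dtm$counts[obs] * log(marg[obs]))
}

# One fused EM sweep via multiplicative updates (algebraically identical to
# em_e_step + em_m_step, without materializing the n x M x K posterior).
plsa_em_sweep <- function(counts, doc_lengths, pw, pz) {
  denom <- pmax(pz %*% pw, .plsa_floor)
  R <- counts / denom                       # n x M
  pw_new <- pw * crossprod(pz, R)           # K x M
  pw_new <- pw_new / pmax(rowSums(pw_new), .plsa_floor)
  pz_new <- pz * tcrossprod(R, pw)          # n x K  (uses old pw, as in the
  pz_new <- pz_new / doc_lengths            #  simultaneous E/M update)
  list(pw = pw_new, pz = pz_new)
}

#' Train the supervised pLSA model
#'
#' Topics are identified with the pain classes: the word-topic matrix is
#' initialized from the labeled count ratios ([supervised_init()]), the
#' document-topic matrix from a seeded flat-Dirichlet draw per document, and
#' plain EM then alternates E- and M-steps until the relative log-likelihood
#' change drops below `tol` or `max_iterations` is reached. The
#' log-likelihood trace is recorded and is nondecreasing up to numerical
#' slack.
#'
#' @param dtm A labeled [flow_dtm()] with no empty documents.
#' @param config An [em_config()].
#' @return An `splsa` model: list with `p_w_given_z` (K x M, rows named by
#'   class), `p_z_given_d` (n x K), `p_w_given_z_init`, `class_names`,
#'   `log_likelihood_trace`, `n_iter`, `converged`, `config`.
#' @export
splsa_train <- function(dtm, config = em_config()) {
  stopifnot(inherits(dtm, "flow_dtm"), inherits(config, "em_config"))
  if (is.null(dtm$labels)) stop("training needs a labeled dtm", call. = FALSE)
  if (any(dtm$doc_lengths == 0)) {
    stop("training documents must be non-empty", call. = FALSE)
  }
  if (ncol(dtm$counts) < 2L) stop("vocabulary is degenerate", call. = FALSE)
  K <- nlevels(dtm$labels)
  n <- nrow(dtm$counts)
  class_names <- levels(dtm$labels)
  pw0 <- supervised_init(dtm, K, config$smoothing_alpha)
  pz <- with_seed(config$seed, {
    g <- matrix(rgamma(n * K, shape = 1), n, K)
    g / rowSums(g)
  })
  if (config$anchor == "hard") {
    pz <- one_hot(dtm$labels, K)
  }
  pw <- pw0
  ll <- plsa_log_likelihood(dtm, pw, pz)
  trace <- ll
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(config$max_iterations)) {
    upd <- plsa_em_sweep(dtm$counts, dtm$doc_lengths, pw, pz)
    pw <- upd$pw
    pz <- if (config$anchor == "hard") one_hot(dtm$labels, K) else upd$pz
    ll_new <- plsa_log_likelihood(dtm, pw, pz)
    trace <- c(trace, ll_new)
    n_iter <- it
    if (is.finite(ll) && abs(ll_new - ll) < config$tol * abs(ll)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  rownames(pw) <- class_names
  dimnames(pz) <- list(NULL, class_names)
  structure(
    list(p_w_given_z = pw, p_z_given_d = pz, p_w_given_z_init = pw0,
         K = K, class_names = class_names, log_likelihood_trace = trace,
         n_iter = n_iter, converged = converged, config = config),
    class = "splsa"
  )
}

one_hot <- function(labels, K) {
  z <- matrix(0, length(labels), K)
  z[cbind(seq_along(labels), as.integer(labels))] <- 1
  z
}

#' @export
print.splsa <- function(x, ...) {
  cat(sprintf(paste0("<splsa> K = %d topics (%s), M = %d words; ",
                     "%d EM iterations%s, log-lik %.4f\n"),
              x$K, paste(x$class_names, collapse = "/"),
              ncol(x$p_w_given_z), x$n_iter,
              if (x$converged) " (converged)" else "",
              x$log_likelihood_trace[length(x$log_likelihood_trace)]))
  invisible(x)
}

#' @describeIn splsa_train Word-topic distributions in long form: one row
#'   per (class, word) with its probability.
#' @param x An `splsa` model.
#' @param ... Unused.
#' @export
tidy.splsa <- function(x, ...) {
  tibble::tibble(
    class = rep(x$class_names, each = ncol(x$p_w_given_z)),
    word = rep(paste0("w", seq_len(ncol(x$p_w_given_z))), x$K),
    probability = as.vector(t(x$p_w_given_z))
  )
}

#' @describeIn splsa_train One-row model summary (topics, vocabulary,
#'   iterations, final log-likelihood, convergence flag).
#' @export
glance.splsa <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    M = ncol(x$p_w_given_z),
    n_documents = nrow(x$p_z_given_d),
    n_iter = x$n_iter,
    converged = x$converged,
    log_likelihood = x$log_likelihood_trace[length(x$log_likelihood_trace)]
  )
}

# Word-topic matrix used at inference time (EM-refined or raw init).
fold_in_pw <- function(model, config) {
  if (config$fold_in_matrix == "init") model$p_w_given_z_init else
    model$p_w_given_z
}

#' Fold-in inference of the topic posterior for a new document
#'
#' Holds the trained word-topic matrix fixed and iterates the E-step with
#' the partial M-step that re-estimates only the new document's topic
#' mixture, starting from the uniform distribution, until the document
#' log-likelihood change is below `tol` or `max_iterations_fold_in` sweeps.
#'
#' @param histogram Length-M nonnegative count vector (a bag-of-words
#'   histogram), not all zero.
#' @param model A trained `splsa` model.
#' @param config An [em_config()]; defaults to the model's own.
#' @return Named numeric vector on the K-simplex: `p(z_k | d_test)`.
#' @export
splsa_fold_in <- function(histogram, model, config = model$config) {
  stopifnot(inherits(model, "splsa"))
  h <- as.numeric(histogram)
  M <- ncol(model$p_w_given_z)
  if (length(h) != M) {
    stop(sprintf("histogram length %d does not match vocabulary size %d",
                 length(h), M), call. = FALSE)
  }
  if (any(h < 0)) stop("histogram counts must be nonnegative", call. = FALSE)
  n_d <- sum(h)
  if (n_d == 0) stop("cannot fold in an all-zero histogram", call. = FALSE)
  pw <- fold_in_pw(model, config)
  K <- model$K
  pz <- rep(1 / K, K)
  obs <- h > 0
  ll <- -Inf
  for (it in seq_len(config$max_iterations_fold_in)) {
    denom <- pmax(as.vector(crossprod(pw, pz)), .plsa_floor)  # length M
    # partial M-step: p(z_k|d) = sum_j h_j * pz_k pw_kj / denom_j / n_d
    pz_new <- pz * as.vector(pw[, obs, drop = FALSE] %*%
                               (h[obs] / denom[obs])) / n_d
    pz_new <- pz_new / sum(pz_new)
    pz <- pz_new
    ll_new <- sum(h[obs] * log(pmax(as.vector(crossprod(pw, pz))[obs],
                                    .plsa_floor)))
    if (is.finite(ll) && abs(ll_new - ll) < config$tol * abs(ll)) break
    ll <- ll_new
  }
  names(pz) <- model$class_names
  pz
}

#' Classify a bag-of-words histogram into a pain class
#'
#' Runs [splsa_fold_in()] and returns the class whose topic has maximal
#' posterior; exact ties go to the smallest class index.
#'
#' @inheritParams splsa_fold_in
#' @return Single class label (character).
#' @export
splsa_classify <- function(histogram, model, config = model$config) {
  pz <- splsa_fold_in(histogram, model, config)
  model$class_names[which.max(pz)]
}

#' Persist a fitted model as JSON + CSV matrices
#'
#' Writes `<path>.json` (header) plus `<path>_pw.csv`, `<path>_pw_init.csv`
#' and `<path>_pz.csv`.
#'
#' @param model An `splsa` model.
#' @param path Output path prefix.
#' @return `path`, invisibly.
#' @export
write_splsa <- function(model, path) {
  stopifnot(inherits(model, "splsa"))
  jsonlite::write_json(
    list(K = model$K, M = ncol(model$p_w_given_z),
         class_names = model$class_names,
         log_likelihood_trace = model$log_likelihood_trace,
         n_iter = model$n_iter, converged = model$converged,
         config = unclass(model$config)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(as.data.frame(model$p_w_given_z),
                   paste0(path, "_pw.csv"), col_names = FALSE)
  readr::write_csv(as.data.frame(model$p_w_given_z_init),
                   paste0(path, "_pw_init.csv"), col_names = FALSE)
  readr::write_csv(as.data.frame(model$p_z_given_d),
                   paste0(path, "_pz.csv"), col_names = FALSE)
  invisible(path)
}

#' Read a model written by [write_splsa()]
#'
#' @param path Path prefix used when writing.
#' @return An `splsa` model.
#' @export
read_splsa <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rd <- function(suffix) {
    unname(as.matrix(readr::read_csv(paste0(path, suffix), col_names = FALSE,
                                     show_col_types = FALSE)))
  }
  cfg <- hdr$config
  config <- em_config(max_iterations = cfg$max_iterations, tol = cfg$tol,
                      smoothing_alpha = cfg$smoothing_alpha, seed = cfg$seed,
                      max_iterations_fold_in = cfg$max_iterations_fold_in,
                      anchor = cfg$anchor, fold_in_matrix = cfg$fold_in_matrix)
  pw <- rd("_pw.csv")
  rownames(pw) <- hdr$class_names
  pz <- rd("_pz.csv")
  colnames(pz) <- hdr$class_names
  structure(
    list(p_w_given_z = pw, p_z_given_d = pz,
         p_w_given_z_init = rd("_pw_init.csv"),
         K = as.integer(hdr$K), class_names = hdr$class_names,
         log_likelihood_trace = hdr$log_likelihood_trace,
         n_iter = as.integer(hdr$n_iter), converged = hdr$converged,
         config = config),
    class = "splsa"
  )
}
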