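# Fixtures shared across test files. Everything is generated in code, at
# small sizes, under explicit seeds.

# Smoothed random texture on the 0-255 gray scale with nonzero gradients
# everywhere (what the flow estimator needs to observe motion).
make_texture <- function(size = 64, smoothness = 3, seed = 1) {
  set.seed(seed)
  g <- painflow:::gaussian_blur(matrix(runif(size * size), size, size),
                                smoothness)
  (g - min(g)) / (max(g) - min(g)) * 255
}

# Integer 1-px shift in +x (columns move right; leading column replicated),
# so the true displacement is exactly (ux, uy) = (1, 0) with no resampling.
shift_x1 <- function(img) img[, c(1, seq_len(ncol(img) - 1))]

# Planted pLSA model: each topic puts (1 - background) of its mass uniformly
# on its own quarter of the vocabulary and spreads `background` over all
# words, so rows share support but are far apart (pairwise TV = 1 - bg).
planted_pw <- function(K = 4, M = 60, background = 0.05) {
  pw <- matrix(background / M, K, M)
  for (k in seq_len(K)) {
    own <- ((k - 1) * (M / K) + 1):(k * (M / K))
    pw[k, own] <- pw[k, own] + (1 - background) / (M / K)
  }
  pw / rowSums(pw)
}

# Labeled corpus sampled from the planted model: each document draws
# `doc_len` words from its class's row.
planted_corpus <- function(seed, K = 4, M = 60, n_docs = 200, doc_len = 100,
                           background = 0.05) {
  pw <- planted_pw(K, M, background)
  set.seed(seed)
  lab <- rep(seq_len(K), each = n_docs / K)
  counts <- t(sapply(lab, function(k) rmultinom(1, doc_len, pw[k, ])))
  list(pw = pw,
       dtm = flow_dtm(counts, labels = factor(LETTERS[lab],
                                              levels = LETTERS[seq_len(K)])))
}

# Corpus in which each class uses a class-disjoint pair of words; the
# cleanest case for checking topic-class anchoring and fold-in.
disjoint_corpus <- function(docs_per_class = 2) {
  K <- 4
  counts <- matrix(0, K * docs_per_class, 2 * K)
  lab <- rep(seq_len(K), each = docs_per_class)
  for (i in seq_len(nrow(counts))) {
    k <- lab[i]
    counts[i, (2 * k - 1):(2 * k)] <- c(5, 7)
  }
  flow_dtm(counts, labels = factor(LETTERS[lab], levels = LETTERS[1:4]))
}

# Mean total-variation distance between fitted and planted word-topic rows
# under the bijective nearest-row matching.
matched_tv <- function(fitted, planted) {
  K <- nrow(planted)
  D <- outer(seq_len(K), seq_len(K), Vectorize(function(a, b) {
    0.5 * sum(abs(fitted[a, ] - planted[b, ]))
  }))
  perm <- apply(D, 1, which.min)
  stopifnot(length(unique(perm)) == K)  # matching must be bijective
  mean(D[cbind(seq_len(K), perm)])
}

# flow_channels object wrapping four given matrices (for bow tests that
# bypass the flow estimator).
as_flow_channels <- function(ubx_pos, ubx_neg, uby_pos, uby_neg) {
  structure(list(ubx_pos = ubx_pos, ubx_neg = ubx_neg,
                 uby_pos = uby_pos, uby_neg = uby_neg),
            class = "flow_channels")
}

# Small clean synthetic dataset reused by pipeline tests.
small_clean_config <- function(n_per_class = 8, seed = 5) {
  synth_config(n_per_class = n_per_class, noise_sigma = 0, seed = seed)
}
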