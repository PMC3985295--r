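test_that("label-informed initialization equals brute-force count ratios", {
  # hand case: class k with word counts (3, 7) over M = 2
  dtm <- flow_dtm(rbind(c(3, 7)), labels = "A")
  expect_equal(supervised_init(dtm, 1, 0), rbind(A = c(0.3, 0.7)))

  # random toy corpora against a nested-loop oracle, exact at alpha = 0
  for (seed in 1:3) {
    set.seed(seed)
    K <- 3
    M <- 7
    n <- 12
    lab <- factor(sample(LETTERS[1:K], n, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)))
    while (nlevels(droplevels(lab)) < K) {
      lab <- factor(sample(LETTERS[1:K], n, replace = TRUE))
    }
    counts <- matrix(rpois(n * M, 3) + 1, n, M)
    dtm <- flow_dtm(counts, labels = lab)
    oracle <- matrix(0, K, M)
    for (k in 1:K) {
      n_k <- 0
      for (i in 1:n) {
        if (as.integer(dtm$labels)[i] == k) {
          for (j in 1:M) {
            oracle[k, j] <- oracle[k, j] + counts[i, j]
            n_k <- n_k + counts[i, j]
          }
        }
      }
      oracle[k, ] <- oracle[k, ] / n_k
    }
    expect_equal(unname(supervised_init(dtm, K, 0)), oracle)
  }
})

test_that("initialization smoothing lifts class-absent words above zero", {
  counts <- rbind(c(5, 0, 3), c(0, 4, 4))
  dtm <- flow_dtm(counts, labels = c("A", "B"))
  raw <- supervised_init(dtm, 2, 0)
  expect_equal(unname(raw["A", 2]), 0)
  sm <- supervised_init(dtm, 2, 1e-3)
  expect_gt(sm["A", 2], 0)
  expect_equal(rowSums(sm), c(A = 1, B = 1))

  unif <- flow_dtm(rbind(c(2, 2, 2), c(3, 3, 3)), labels = c("A", "B"))
  expect_equal(unname(supervised_init(unif, 2, 0)),
               matrix(1 / 3, 2, 3))
  expect_error(supervised_init(flow_dtm(rbind(c(1, 1)), labels = "A"), 2),
               "label levels|K")
})

test_that("E-step posterior matches hand arithmetic and normalizes", {
  # K = 2, M = 2 hand case
  pw <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  pz <- rbind(c(0.5, 0.5))
  post <- em_e_step(pw, pz)
  expect_equal(post[1, 1, ], c(0.9 / 1.1, 0.2 / 1.1), tolerance = 1e-12)
  expect_equal(post[1, 2, ], c(0.1 / 0.9, 0.8 / 0.9), tolerance = 1e-12)
  expect_equal(apply(post, c(1, 2), sum), matrix(1, 1, 2))

  # K = 1 degenerates to certainty
  expect_equal(em_e_step(rbind(c(0.4, 0.6)), rbind(1, 1))[, , 1],
               matrix(1, 2, 2))

  # uniform word distributions make the word uninformative
  pw_u <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  pz2 <- rbind(c(0.3, 0.7), c(0.6, 0.4))
  post2 <- em_e_step(pw_u, pz2)
  for (j in 1:2) expect_equal(post2[, j, ], pz2)
})

test_that("M-step matches brute-force summation on a 2x2x2 toy", {
  counts <- rbind(c(4, 1), c(2, 3))
  dtm <- flow_dtm(counts, labels = c("A", "B"))
  post <- array(c(0.7, 0.4, 0.2, 0.9,    # k = 1, (i, j) column-major
                  0.3, 0.6, 0.8, 0.1),   # k = 2
                dim = c(2, 2, 2))
  upd <- em_m_step(post, dtm)
  pw_oracle <- matrix(0, 2, 2)
  pz_oracle <- matrix(0, 2, 2)
  for (k in 1:2) {
    for (j in 1:2) {
      for (i in 1:2) {
        pw_oracle[k, j] <- pw_oracle[k, j] + counts[i, j] * post[i, j, k]
      }
    }
    for (i in 1:2) {
      for (j in 1:2) {
        pz_oracle[i, k] <- pz_oracle[i, k] + counts[i, j] * post[i, j, k]
      }
    }
  }
  pw_oracle <- pw_oracle / rowSums(pw_oracle)
  pz_oracle <- pz_oracle / rowSums(counts)
  expect_equal(upd$p_w_given_z, pw_oracle, tolerance = 1e-12)
  expect_equal(upd$p_z_given_d, pz_oracle, tolerance = 1e-12)
  expect_equal(rowSums(upd$p_w_given_z), c(1, 1))
  expect_equal(rowSums(upd$p_z_given_d), c(1, 1))
})

test_that("M-step degenerate cases behave as the update formulas dictate", {
  counts <- rbind(c(2, 1), c(1, 2))
  dtm <- flow_dtm(counts, labels = c("A", "B"))
  post <- array(0, dim = c(2, 2, 2))
  post[, , 1] <- 1   # all mass on topic 1
  upd <- em_m_step(post, dtm)
  expect_equal(upd$p_z_given_d[, 1], c(1, 1))
  expect_equal(upd$p_w_given_z[1, ], colSums(counts) / sum(counts))

  empty <- flow_dtm(rbind(c(0, 0), c(1, 1)))
  expect_error(em_m_step(post, empty), "empty")
})

test_that("log-likelihood equals an independent evaluation", {
  expect_equal(plsa_log_likelihood(flow_dtm(rbind(1)),
                                   rbind(1), rbind(1)), 0)
  # uniform model: n words over M equally likely words
  M <- 5
  dtm_u <- flow_dtm(rbind(rep(2, M)))
  expect_equal(plsa_log_likelihood(dtm_u, rbind(rep(1 / M, M)), rbind(1)),
               10 * log(1 / M))
  # toy corpus, independent double-sum evaluation
  set.seed(20)
  counts <- matrix(rpois(6 * 4, 2), 6, 4)
  counts[rowSums(counts) == 0, 1] <- 1
  dtm <- flow_dtm(counts)
  pw <- matrix(rgamma(2 * 4, 1), 2, 4)
  pw <- pw / rowSums(pw)
  pz <- matrix(rgamma(6 * 2, 1), 6, 2)
  pz <- pz / rowSums(pz)
  direct <- 0
  for (i in 1:6) {
    for (j in 1:4) {
      if (counts[i, j] > 0) {
        direct <- direct + counts[i, j] *
          log(sum(pz[i, ] * pw[, j]))
      }
    }
  }
  expect_equal(plsa_log_likelihood(dtm, pw, pz), direct, tolerance = 1e-12)
})

test_that("the fused EM sweep equals the explicit E-step/M-step composition", {
  pc <- planted_corpus(31, n_docs = 24, doc_len = 30, M = 12)
  pw <- supervised_init(pc$dtm, 4, 1e-3)
  set.seed(31)
  pz <- matrix(rgamma(24 * 4, 1), 24, 4)
  pz <- pz / rowSums(pz)
  fused <- painflow:::plsa_em_sweep(pc$dtm$counts, pc$dtm$doc_lengths, pw, pz)
  explicit <- em_m_step(em_e_step(pw, pz), pc$dtm)
  expect_equal(unname(fused$pw), unname(explicit$p_w_given_z), tolerance = 1e-12)
  expect_equal(unname(fused$pz), unname(explicit$p_z_given_d), tolerance = 1e-12)
})

test_that("training keeps distributions stochastic and the likelihood rising", {
  pc <- planted_corpus(41, n_docs = 40, doc_len = 50)
  m <- splsa_train(pc$dtm, em_config(seed = 41))
  expect_equal(unname(rowSums(m$p_w_given_z)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(rowSums(m$p_z_given_d)), rep(1, 40), tolerance = 1e-9)
  tr <- m$log_likelihood_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-1])))

  # re-running EM from the converged state moves less than tol immediately
  dtm2 <- pc$dtm
  cfg <- em_config(seed = 41)
  upd <- painflow:::plsa_em_sweep(dtm2$counts, dtm2$doc_lengths,
                                  m$p_w_given_z, m$p_z_given_d)
  ll0 <- plsa_log_likelihood(dtm2, m$p_w_given_z, m$p_z_given_d)
  ll1 <- plsa_log_likelihood(dtm2, upd$pw, upd$pz)
  expect_lt(abs(ll1 - ll0), cfg$tol * abs(ll0) * 10)
})

test_that("disjoint-support classes keep their topics on their own words", {
  dtm <- disjoint_corpus()
  m <- splsa_train(dtm, em_config(seed = 1))
  for (k in 1:4) {
    expect_gte(sum(m$p_w_given_z[k, (2 * k - 1):(2 * k)]), 1 - 1e-3)
  }
  # fold-in of a class-D-support document
  h <- c(0, 0, 0, 0, 0, 0, 3, 4)
  pz <- splsa_fold_in(h, m)
  expect_gte(pz[["D"]], 0.99)
  expect_equal(splsa_classify(h, m), "D")
})

test_that("fold-in recovers a training document's topic mixture", {
  pc <- planted_corpus(7)
  m <- splsa_train(pc$dtm, em_config(seed = 7))
  for (i in c(5, 60, 150)) {
    pz <- splsa_fold_in(pc$dtm$counts[i, ], m)
    expect_lt(0.5 * sum(abs(pz - m$p_z_given_d[i, ])), 1e-3)
  }
})

test_that("fold-in handles degenerate inputs per contract", {
  pc <- planted_corpus(8, n_docs = 24, doc_len = 30, M = 12)
  m <- splsa_train(pc$dtm, em_config(seed = 8))
  expect_error(splsa_fold_in(rep(0, 12), m), "all-zero")
  expect_error(splsa_fold_in(rep(1, 5), m), "length")
  expect_error(splsa_fold_in(c(-1, rep(1, 11)), m), "nonnegative")

  # K = 1 returns certainty
  dtm1 <- flow_dtm(rbind(c(2, 3), c(1, 4)), labels = c("A", "A"))
  m1 <- splsa_train(dtm1, em_config(seed = 1))
  expect_equal(unname(splsa_fold_in(c(1, 1), m1)), 1)
})

test_that("classification breaks exact posterior ties by smallest index", {
  m <- structure(list(p_w_given_z = matrix(0.25, 4, 2), K = 4L,
                      class_names = pain_classes,
                      p_w_given_z_init = matrix(0.25, 4, 2),
                      p_z_given_d = NULL, log_likelihood_trace = 0,
                      n_iter = 0L, converged = TRUE,
                      config = em_config()),
                 class = "splsa")
  # identical topics: fold-in stays uniform, argmax falls to class A
  expect_equal(splsa_classify(c(3, 2), m), "A")
})

test_that("the raw-count fold-in matrix mode is honored", {
  dtm <- disjoint_corpus()
  m <- splsa_train(dtm, em_config(seed = 2))
  cfg_init <- em_config(seed = 2, fold_in_matrix = "init")
  h <- c(5, 7, 0, 0, 0, 0, 0, 0)
  expect_equal(splsa_classify(h, m, cfg_init), "A")
  pz <- splsa_fold_in(h, m, cfg_init)
  expect_gte(pz[["A"]], 0.99)
})

test_that("hard-anchor training pins document rows to their labels", {
  pc <- planted_corpus(9, n_docs = 24, doc_len = 30, M = 12)
  m <- splsa_train(pc$dtm, em_config(seed = 9, anchor = "hard"))
  expect_equal(unname(m$p_z_given_d),
               painflow:::one_hot(pc$dtm$labels, 4))
})

test_that("parameter recovery: planted word-topic rows are reproduced", {
  for (seed in c(101, 202, 303)) {
    pc <- planted_corpus(seed)
    m <- splsa_train(pc$dtm, em_config(seed = seed))
    expect_lt(matched_tv(m$p_w_given_z, pc$pw), 0.05)
  }
})

test_that("model persistence round-trips the fitted distributions", {
  pc <- planted_corpus(10, n_docs = 24, doc_len = 30, M = 12)
  m <- splsa_train(pc$dtm, em_config(seed = 10))
  path <- file.path(withr::local_tempdir(), "model")
  write_splsa(m, path)
  back <- read_splsa(path)
  expect_equal(back$p_w_given_z, m$p_w_given_z, tolerance = 1e-12)
  expect_equal(back$p_z_given_d, m$p_z_given_d, tolerance = 1e-12)
  expect_identical(back$class_names, m$class_names)
  h <- pc$dtm$counts[3, ]
  expect_equal(splsa_classify(h, back), splsa_classify(h, m))
})

test_that("tidy and glance expose the fitted model in tabular form", {
  pc <- planted_corpus(11, n_docs = 24, doc_len = 30, M = 12)
  m <- splsa_train(pc$dtm, em_config(seed = 11))
  td <- tidy(m)
  expect_equal(nrow(td), 4 * 12)
  sums <- tapply(td$probability, td$class, sum)
  expect_equal(unname(c(sums)), rep(1, 4), tolerance = 1e-9)
  g <- glance(m)
  expect_equal(g$K, 4)
  expect_equal(g$M, 12)
  expect_true(g$log_likelihood <= 0)
})
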