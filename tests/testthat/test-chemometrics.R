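test_that("spectrum summary gives per-channel mean and n-1 sd", {
  v <- rnorm(12)
  same <- toy_set(rbind(v, v, v))
  s <- summarize_spectra(same)
  expect_equal(s$mean, v)
  expect_equal(s$sd, rep(0, 12))
  # rows v and -v: mean 0, sd |v| * sqrt(2) (two-point sample sd)
  pm <- summarize_spectra(toy_set(rbind(v, -v)))
  expect_equal(pm$mean, rep(0, 12))
  expect_equal(pm$sd, abs(v) * sqrt(2))
  # permutation invariance
  m <- matrix(rnorm(5 * 12), nrow = 5)
  expect_equal(summarize_spectra(toy_set(m)),
               summarize_spectra(toy_set(m[5:1, ], ids = paste0("S", 5:1))),
               ignore_attr = TRUE)
  expect_error(summarize_spectra(toy_set(matrix(v, nrow = 1))), "insufficient")
})

test_that("PCA matches direct covariance eigendecomposition", {
  # 3 points in the plane, oracle = eigen() of the 2x2 covariance
  m <- rbind(c(0, 0), c(1, 2), c(3, 1))
  pca <- fit_pca(toy_set(m, grid = c(100, 200)))
  ev <- eigen(cov(m))$values
  total <- sum(ev)
  expect_equal(pca$variance_fraction, ev / total, tolerance = 1e-10)
  # larger random case
  set.seed(31)
  m2 <- matrix(rnorm(12 * 6), nrow = 12)
  pca2 <- fit_pca(toy_set(m2, grid = seq(100, 600, by = 100)))
  ev2 <- eigen(cov(m2))$values
  expect_equal(pca2$variance_fraction, ev2 / sum(ev2), tolerance = 1e-8)
  # loadings orthonormal; scores centered and uncorrelated
  expect_equal(crossprod(pca2$loadings), diag(ncol(pca2$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(pca2$scores))), 1e-9)
  cc <- crossprod(pca2$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("PCA reconstructs the centered data at full rank", {
  set.seed(5)
  m <- matrix(rnorm(8 * 5), nrow = 8)
  pca <- fit_pca(toy_set(m))
  recon <- pca$scores %*% t(pca$loadings)
  centered <- sweep(m, 2, colMeans(m))
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("PCA sign convention is deterministic and permutation/duplication stable", {
  set.seed(8)
  m <- matrix(rnorm(10 * 7), nrow = 10)
  pca <- fit_pca(toy_set(m))
  # largest-|.| channel of every loading is positive
  for (j in seq_len(ncol(pca$loadings))) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  # row permutation: identical loadings and variance fractions
  perm <- c(4, 1, 10, 6, 2, 9, 3, 8, 5, 7)
  pcap <- fit_pca(toy_set(m[perm, ], ids = paste0("S", perm)))
  expect_equal(pcap$loadings, pca$loadings, tolerance = 1e-9)
  expect_equal(pcap$variance_fraction, pca$variance_fraction, tolerance = 1e-9)
  # duplicating every row: identical loadings and variance fractions
  pcad <- fit_pca(toy_set(rbind(m, m), ids = c(paste0("S", 1:10),
                                               paste0("T", 1:10))))
  expect_equal(pcad$loadings, pca$loadings, tolerance = 1e-8)
  expect_equal(pcad$variance_fraction, pca$variance_fraction, tolerance = 1e-8)
  # rank-1 data: all variance on the first component
  v <- rnorm(6)
  r1 <- fit_pca(toy_set(outer(c(1, 2, 3, 5), v) + 10))
  expect_equal(r1$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("select_n_pcs matches a cumulative-sum oracle", {
  vf <- c(0.60, 0.30, 0.05, 0.04, 0.01)
  expect_identical(select_n_pcs(vf, 0.90), 2L)
  expect_identical(select_n_pcs(vf, 0.95), 3L)
  expect_identical(select_n_pcs(vf, 1.0), 5L)
  expect_error(select_n_pcs(c(0.5, 0.3), 0.9), "coverage error")
  # property over random variance vectors
  set.seed(99)
  for (i in 1:200) {
    v <- sort(rexp(sample(2:12, 1)), decreasing = TRUE)
    v <- v / sum(v)
    t <- runif(1, 0.05, 1)
    oracle <- which(cumsum(v) >= t - 1e-12)[1]
    expect_identical(select_n_pcs(v, t), oracle)
  }
})

test_that("loading attribution finds the channel that drives the variance", {
  # identity-like loadings: component j concentrated on one channel
  set.seed(12)
  m <- cbind(rnorm(20, sd = 3), rnorm(20, sd = 1), rnorm(20, sd = 0.1))
  pca <- fit_pca(toy_set(m, grid = c(700, 1000, 1300)))
  att <- loading_attribution(pca, 2)
  expect_equal(att$per_component$shift[att$per_component$component == 1][1], 700)
  expect_equal(att$combined$shift[1], 700)
  # combined ranking invariant to sign flips (uses absolute loadings)
  flipped <- pca
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  expect_equal(loading_attribution(flipped, 2)$combined,
               att$combined, tolerance = 1e-12)
  expect_error(loading_attribution(pca, 99), "exceeds")
})

test_that("a cohort varying only the urea band attributes variance near 1002 cm-1", {
  # fixed multi-band profile in which only the urea amplitude varies
  grid <- default_grid()
  lor <- function(c0, fw, a) a * (fw / 2)^2 / ((grid - c0)^2 + (fw / 2)^2)
  # narrow metabolite bands plus a broad fixed feature: the broad spectral
  # mass keeps the L2 norm from being dominated by the varied band itself
  fixed <- lor(680, 10, 40) + lor(981, 10, 25) + lor(870, 10, 15) +
    lor(1071, 10, 20) + lor(1117, 10, 15) + lor(1640, 300, 30)
  set.seed(21)
  urea_amp <- 100 * rlnorm(20, sdlog = 0.4)
  m <- do.call(rbind, lapply(urea_amp, function(a) {
    fixed + lor(1002, 10, a) + rnorm(length(grid), 0, 0.2)
  }))
  set <- vector_normalize(spectrum_set(grid, m, sprintf("u%02d", 1:20)))
  pca <- fit_pca(truncate_window(set, c(400, 1800)))
  top <- loading_attribution(pca, 1)$combined$shift[1]
  expect_lte(abs(top - 1002), 4)
})

test_that("DAPC recovers class means, priors, and degeneracies", {
  set.seed(44)
  n <- 50
  scores <- rbind(sweep(matrix(rnorm(n * 3), ncol = 3), 2, c(5, 0, 0), `+`),
                  sweep(matrix(rnorm(n * 3), ncol = 3), 2, c(5, 0, 0), `-`))
  # wrap the scores as a spectrum_set so fit_pca sees rank-3 data
  set <- toy_set(scores %*% matrix(rnorm(3 * 6), nrow = 3),
                 ids = sprintf("s%03d", 1:(2 * n)))
  labels <- rep(c("pos", "neg"), each = n)
  pca <- fit_pca(set)
  model <- fit_dapc(pca, labels, n_pcs = 3)
  expect_identical(model$classes, c("neg", "pos"))
  expect_equal(model$priors, c(0.5, 0.5))
  # class means in PC space match the sample means of the projected classes
  for (cl in model$classes) {
    expect_equal(model$class_means[cl, ],
                 colMeans(pca$scores[labels == cl, 1:3]), tolerance = 1e-10)
  }
  # duplicating all rows leaves class means unchanged
  set2 <- toy_set(rbind(set$intensities, set$intensities),
                  ids = c(sprintf("s%03d", 1:(2 * n)), sprintf("t%03d", 1:(2 * n))))
  model2 <- fit_dapc(fit_pca(set2), rep(labels, 2), n_pcs = 3)
  expect_equal(abs(model2$class_means), abs(model$class_means), tolerance = 1e-6)
  expect_error(fit_dapc(pca, rep("pos", 2 * n), 3), "class-size")
  expect_error(fit_dapc(pca, c("a", rep("b", 2 * n - 1)), 3), "class-size")
})

test_that("DAPC posteriors agree with MASS::lda and direct Bayes evaluation", {
  skip_if_not_installed("MASS")
  set.seed(7)
  n <- 40
  m <- rbind(matrix(rnorm(n * 5), ncol = 5) + 2,
             matrix(rnorm(n * 5), ncol = 5))
  labels <- rep(c("hi", "lo"), each = n)
  pca <- fit_pca(toy_set(m, ids = sprintf("x%02d", 1:(2 * n))))
  model <- fit_dapc(pca, labels, n_pcs = 4)
  newx <- matrix(rnorm(10 * 5), ncol = 5) + 1
  pred <- predict_dapc(model, newx)
  expect_equal(rowSums(pred$posterior), rep(1, 10), tolerance = 1e-9)

  ref <- MASS::lda(pca$scores[, 1:4], grouping = labels)
  ref_pred <- predict(ref, project_scores(pca, newx, 4))
  expect_equal(unname(pred$posterior), unname(ref_pred$posterior),
               tolerance = 1e-4)
  expect_identical(pred$label, as.character(ref_pred$class))
})

test_that("posterior mechanics: class-mean points, ties, and prior monotonicity", {
  set.seed(3)
  scores <- rbind(sweep(matrix(rnorm(30 * 2, sd = 1), ncol = 2), 2, c(4, 0), `+`),
                  sweep(matrix(rnorm(30 * 2, sd = 1), ncol = 2), 2, c(4, 0), `-`))
  set <- toy_set(cbind(scores, scores[, 1] * 0.5),
                 ids = sprintf("p%02d", 1:60))
  labels <- rep(c("a", "b"), each = 30)
  pca <- fit_pca(set)
  model <- fit_dapc(pca, labels, n_pcs = 2, priors = "uniform")
  # at a class mean the posterior favours that class (input given as scores)
  at_a <- predict_dapc(model, matrix(model$class_means["a", ], nrow = 1))
  expect_identical(at_a$label, "a")
  expect_gt(at_a$posterior[1, "a"], 0.5)
  # the midpoint of symmetric classes ties, broken toward the first class
  mid <- (model$class_means["a", ] + model$class_means["b", ]) / 2
  at_mid <- predict_dapc(model, matrix(mid, nrow = 1))
  expect_equal(as.numeric(at_mid$posterior), c(0.5, 0.5), tolerance = 1e-6)
  expect_identical(at_mid$label, "a")
  # doubling a prior strictly increases that class's posterior everywhere
  # (oracle = direct Bayes rule: posterior odds scale with prior odds)
  freq <- fit_dapc(pca, c(rep("a", 40), rep("b", 20)), n_pcs = 2,
                   priors = "frequency")
  unif <- fit_dapc(pca, c(rep("a", 40), rep("b", 20)), n_pcs = 2,
                   priors = "uniform")
  pts <- matrix(rnorm(20 * 2, sd = 3), ncol = 2)
  pf <- predict_dapc(freq, pts)$posterior[, "a"]
  pu <- predict_dapc(unif, pts)$posterior[, "a"]
  expect_true(all(pf > pu))
  odds_ratio <- (pf / (1 - pf)) / (pu / (1 - pu))
  expect_equal(odds_ratio, rep(2, 20), tolerance = 1e-9)
})

test_that("full-rank equal-prior DAPC is nearest-Mahalanobis-mean classification", {
  set.seed(15)
  m <- rbind(sweep(matrix(rnorm(25 * 4), ncol = 4), 2, c(3, 0, 0, 0), `+`),
             matrix(rnorm(25 * 4), ncol = 4),
             sweep(matrix(rnorm(25 * 4), ncol = 4), 2, c(0, 3, 0, 0), `-`))
  labels <- rep(c("a", "b", "c"), each = 25)
  pca <- fit_pca(toy_set(m, ids = sprintf("q%02d", 1:75)))
  k <- ncol(pca$scores)
  model <- fit_dapc(pca, labels, n_pcs = k, priors = "uniform")
  pts <- matrix(rnorm(20 * 4, sd = 2), ncol = 4)
  pred <- predict_dapc(model, pts)$label
  s <- project_scores(pca, pts, k)
  inv <- solve(model$pooled_covariance)
  brute <- apply(s, 1, function(x) {
    d2 <- apply(model$class_means, 1, function(mu) {
      t(x - mu) %*% inv %*% (x - mu)
    })
    names(which.min(d2))
  })
  expect_identical(pred, unname(brute))
})
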