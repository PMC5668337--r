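test_that("PCA recovers rank, conserves variance and matches the eigen oracle", {
  # rank-1 data: exactly one component carries variance
  set.seed(5)
  base <- runif(8)
  x1 <- outer(c(1, 2, 3, 5), base) + matrix(rep(runif(8), each = 4), nrow = 4)
  p1 <- fit_pca(x1, 3L)
  expect_gt(p1$variance[1], 1e-10)
  expect_lt(p1$variance[2] / p1$variance[1], 1e-20)

  # full-rank: component variances sum to total variance
  x <- matrix(rnorm(10 * 6), nrow = 10)
  pf <- fit_pca(x, 6L)
  expect_equal(sum(pf$variance), sum(apply(x, 2, var)), tolerance = 1e-10)

  # covariance eigendecomposition oracle (up to sign), 10 x 20
  x2 <- matrix(rnorm(10 * 20), nrow = 10)
  n_pc <- 5L
  p2 <- fit_pca(x2, n_pc)
  eg <- eigen(cov(x2), symmetric = TRUE)
  ora <- align_signs(eg$vectors[, seq_len(n_pc)], p2$loadings)
  expect_equal(p2$loadings, ora, tolerance = 1e-8)
  sc_ora <- sweep(x2, 2, colMeans(x2)) %*% ora
  expect_equal(p2$scores, sc_ora, tolerance = 1e-8)

  expect_error(fit_pca(x2, 12L), "n_pca")
})

test_that("LDA respects the class-1 axis cap and finds separating directions", {
  set.seed(8)
  labels5 <- rep(letters[1:5], each = 4)
  s5 <- matrix(rnorm(20 * 6), nrow = 20) +
    outer(as.integer(factor(labels5)), rep(1, 6))
  expect_error(fit_lda(s5, labels5, 5L), "n_lda")
  l4 <- fit_lda(s5, labels5, 4L)
  expect_identical(ncol(l4$axes), 4L)

  # two clouds split along coordinate 1: first axis parallel to it
  lab2 <- rep(c("a", "b"), each = 20)
  s2 <- cbind(c(rnorm(20, 0, 0.1), rnorm(20, 5, 0.1)), rnorm(40, 0, 1))
  l1 <- fit_lda(s2, lab2, 1L)
  expect_gt(abs(l1$axes[1, 1]) / sqrt(sum(l1$axes[, 1]^2)), 0.99)

  expect_error(fit_lda(s2, c("a", rep("b", 39)), 1L), "singleton")
})

test_that("LDA axes agree with the brute-force generalized eigenproblem", {
  set.seed(12)
  labels <- rep(c("a", "b", "c"), each = 6)
  scores <- matrix(rnorm(18 * 2), ncol = 2) +
    cbind(rep(c(0, 3, 0), each = 6), rep(c(0, 0, 3), each = 6))
  fit <- fit_lda(scores, labels, 2L)

  # oracle: eigen(solve(Sw_reg) %*% Sb) with the same ridge
  grand <- colMeans(scores)
  Sw <- matrix(0, 2, 2); Sb <- matrix(0, 2, 2)
  for (cl in unique(labels)) {
    rows <- scores[labels == cl, ]
    mu <- colMeans(rows)
    Sw <- Sw + crossprod(sweep(rows, 2, mu))
    Sb <- Sb + nrow(rows) * tcrossprod(mu - grand)
  }
  Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / 2, 2)
  eg <- eigen(solve(Sw) %*% Sb)
  for (j in 1:2) {
    a <- fit$axes[, j]
    o <- Re(eg$vectors[, j]); o <- o / sqrt(sum(o^2))
    expect_gt(abs(sum(a * o)), 1 - 1e-8)
  }
})

test_that("class statistics match their textbook definitions", {
  set.seed(3)
  z <- matrix(rnorm(24 * 3), ncol = 3)
  labels <- rep(c("p", "q", "r"), each = 8)
  st <- fit_class_stats(z, labels)
  expect_equal(st$centroids["q", ], colMeans(z[labels == "q", ]))
  expect_equal(st$dispersions["r", ], apply(z[labels == "r", ], 2, sd))

  # symmetric pair: centroid at the origin
  zz <- rbind(c(1, -2), c(-1, 2), c(5, 5), c(6, 6))
  st2 <- fit_class_stats(zz, c("s", "s", "t", "t"))
  expect_equal(unname(st2$centroids["s", ]), c(0, 0))

  # identical members: dispersion at the floor, distinct queries far away
  zd <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 2))
  st3 <- fit_class_stats(zd, c("u", "u", "v", "v"))
  expect_equal(unname(st3$dispersions["u", ]), c(1e-12, 1e-12))
  expect_error(fit_class_stats(zz, c("s", "s", "s", "t")), "singleton")
})

test_that("classification agrees with the brute-force oracle and handles outliers", {
  dat <- fp5()
  model <- fp5_model()

  # training centroids classify to their own class at distance ~ 0
  for (k in seq_along(model$classes)) {
    rows <- dat$labels == model$classes[k]
    cent <- colMeans(dat$x[rows, , drop = FALSE])
    res <- predict(model, cent)
    expect_identical(res$label, model$classes[k])
  }

  # 20 in-model queries plus far-off queries: oracle equivalence
  set.seed(44)
  queries <- rbind(dat$x[sample(nrow(dat$x), 20L), ],
                   matrix(runif(2 * 701) / 350, nrow = 2))
  res <- predict(model, queries)
  ora <- classify_oracle(model, queries)
  expect_identical(res$label, ora$label)
  expect_equal(res$distance, ora$distance, tolerance = 1e-10)

  # a query beyond 5 sigma for every class is an outlier
  far <- which(apply(res[, paste0("d_", model$classes)], 1, min) > 5)
  expect_true(all(res$label[far] == "outlier"))

  expect_error(predict(model, runif(5)), "bins")
})

test_that("distances are invariant to adding a constant vector to all data", {
  dat <- fp5()
  idx <- 1:40
  x <- dat$x[idx, ]
  shift <- matrix(rep(runif(ncol(x)), each = length(idx)), nrow = length(idx))
  m0 <- reims_pcalda(x, dat$labels[idx], n_pca = 10L, n_lda = 1L)
  m1 <- reims_pcalda(x + shift, dat$labels[idx], n_pca = 10L, n_lda = 1L)
  q <- dat$x[141:150, ]
  d0 <- predict(m0, q)
  d1 <- predict(m1, q + matrix(rep(shift[1, ], each = 10), nrow = 10))
  expect_equal(d0[paste0("d_", m0$classes)], d1[paste0("d_", m0$classes)],
               tolerance = 1e-6)
})

test_that("raising sigma_max never turns an assignment into an outlier", {
  dat <- fp5()
  x <- dat$x
  set.seed(71)
  queries <- rbind(x[sample(nrow(x), 10L), ],
                   matrix(runif(3 * 701) / 350, nrow = 3))
  prev <- NULL
  for (sig in c(1, 2, 5, 10, 50)) {
    m <- reims_pcalda(x, dat$labels, n_pca = 15L, n_lda = 4L, sigma_max = sig)
    lab <- predict(m, queries)$label
    if (!is.null(prev)) {
      became_outlier <- prev != "outlier" & lab == "outlier"
      expect_false(any(became_outlier))
    }
    prev <- lab
  }
})

test_that("cross-validation partitions each sample into exactly one fold", {
  dat <- fp5()
  idx <- c(which(dat$labels == "cod")[1:5], which(dat$labels == "pollock")[1:5])
  cv <- pcalda_cv(dat$x[idx, ], dat$labels[idx], n_pca = 5L, seed = 2L)
  expect_identical(sort(unique(cv$fold)), 1:5)
  expect_true(all(table(cv$fold) == 2L))
  expect_length(cv$predicted, 10L)

  cv5 <- pcalda_cv(dat$x, dat$labels, n_pca = 25L, seed = 2L)
  expect_identical(sort(unique(cv5$fold)), 1:5)
  for (cl in unique(dat$labels)) {
    expect_identical(sort(unique(cv5$fold[dat$labels == cl])), 1:5)
  }
  # clearly separated classes: perfect recovery
  expect_equal(cv5$rate, 100)
  expect_equal(sum(cv5$confusion), 150)

  expect_error(pcalda_cv(dat$x[1:33, ], c(rep("a", 30), rep("b", 3)),
                         n_pca = 5L), "'b'")
})

test_that("classification rates reproduce printed-percentage arithmetic", {
  expect_equal(classification_rate(475, 478), 99.37)
  expect_equal(classification_rate(98, 99), 98.99)
  expect_equal(classification_rate(95, 100), 95.00)
  expect_equal(classification_rate(13, 14), 92.86)
  expect_error(classification_rate(5, 0), "total")
  expect_error(classification_rate(6, 5), "correct")
})

test_that("external classification summarises per-class counts", {
  model <- fp5_model()
  dat <- fp5()
  ext <- classify_external(dat$x[1:8, ], model)
  expect_identical(ext$n, 8L)
  expect_equal(sum(ext$counts), 8)
  empty <- classify_external(dat$x[0, , drop = FALSE], model)
  expect_identical(empty$n, 0L)
})

test_that("JSON model serialization preserves predictions", {
  model <- fp5_model()
  dat <- fp5()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  a <- predict(model, dat$x[1:12, ])
  b <- predict(back, dat$x[1:12, ])
  expect_identical(a$label, b$label)
  expect_equal(a$distance, b$distance, tolerance = 1e-12)
  expect_error(read_model_json(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "model file")
})
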