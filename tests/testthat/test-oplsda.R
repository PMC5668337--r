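# Two-class fingerprint set reused across OPLS-DA tests: haddock catch
# methods (trawl vs line), 30 samples each.
catch_data <- function() {
  memo("catch_data", function() {
    p <- fish_profiles()
    design <- dataset_design(p[c("haddock_trawl", "haddock_line")],
                             c(haddock_trawl = 30L, haddock_line = 30L),
                             seed = 13L)
    simulate_fingerprints(design)
  })
}

test_that("Pareto scaling divides by the root standard deviation", {
  set.seed(19)
  x <- cbind(a = rnorm(12, sd = 2), b = rnorm(12, sd = 0.3),
             c = rep(4, 12), d = runif(12))
  x[, "a"] <- x[, "a"] * 4 / sd(x[, "a"])  # force sd exactly 4
  sc <- pareto_scale(x)
  expect_equal(unname(sc$scale["a"]), 2)
  expect_equal(sc$x[, "a"], (x[, "a"] - mean(x[, "a"])) / 2)
  # constant column dropped and recorded
  expect_identical(unname(sc$dropped), 3L)
  expect_identical(colnames(sc$x), c("a", "b", "d"))
  # round trip
  expect_equal(pareto_unscale(sc$x, sc), x[, c("a", "b", "d")],
               tolerance = 1e-10)
  expect_error(pareto_scale(x[1, , drop = FALSE]), ">= 2")
})

test_that("with zero orthogonal components the fit is plain PLS (SVD oracle)", {
  dat <- fp5()
  x <- dat$x[1:60, ]
  labels <- dat$labels[1:60]
  fit <- reims_oplsda(x, labels, n_predictive = 3L, n_orthogonal = 0L)

  sc <- pareto_scale(x)
  y <- vapply(sort(unique(labels)), function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  yc <- sweep(y, 2, colMeans(y))
  ora <- pls_svd_oracle(sc$x, yc, 3L)
  expect_equal(fit$weights, align_signs(ora$W, fit$weights), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$scores, align_signs(ora$T, fit$scores), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$loadings, align_signs(ora$P, fit$loadings), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a single separating bin dominates the predictive weight", {
  set.seed(27)
  n <- 30
  x <- matrix(rnorm(2 * n * 10, sd = 0.01), ncol = 10)
  x[, 4] <- rep(c(0, 1), each = n)  # noise-free separator
  colnames(x) <- sprintf("b%02d", 1:10)
  labels <- rep(c("g1", "g2"), each = n)
  fit <- reims_oplsda(x, labels, n_predictive = 1L)
  expect_gt(abs(fit$weights[4, 1])^2 / sum(fit$weights[, 1]^2), 0.99)
  expect_gt(fit$R2Y, 0.99)
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  dat <- catch_data()
  fit <- reims_oplsda(dat$x, dat$labels, n_predictive = 1L, n_orthogonal = 3L)
  cross <- crossprod(fit$scores, fit$scores_ortho)
  scale <- sqrt(sum(fit$scores^2) * sum(fit$scores_ortho^2))
  expect_lt(max(abs(cross)) / scale, 1e-8)
  # orthogonal scores mutually orthogonal as well
  gram <- crossprod(fit$scores_ortho)
  off <- gram - diag(diag(gram))
  expect_lt(max(abs(off)) / max(diag(gram)), 1e-8)
})

test_that("Q2 is high for informative labels, low under the null, and <= R2Y", {
  dat <- catch_data()
  q2 <- oplsda_q2(dat$x, dat$labels, n_predictive = 1L, n_orthogonal = 3L,
                  seed = 4L)
  expect_gt(q2, 0.7)
  expect_lte(q2, 1)
  fit <- reims_oplsda(dat$x, dat$labels, n_predictive = 1L, n_orthogonal = 3L)
  expect_lte(q2, fit$R2Y)

  # permuted labels: Q2 collapses in >= 95% of seeded repetitions (n = 60)
  set.seed(61)
  low <- vapply(1:20, function(i) {
    perm <- sample(dat$labels)
    oplsda_q2(dat$x, perm, n_predictive = 1L, n_orthogonal = 0L,
              seed = 100L + i)
  }, numeric(1))
  expect_gte(sum(low <= 0.2), 19L)
})

test_that("permutation testing is seeded and flags informative models", {
  dat <- catch_data()
  x <- dat$x[seq(1, 60, by = 2), ]  # 30 samples keeps 100 refits quick
  labels <- dat$labels[seq(1, 60, by = 2)]
  pt <- oplsda_permutation(x, labels, n_predictive = 1L, n_orthogonal = 0L,
                           n_perm = 100L, seed = 9L)
  expect_lte(pt$exceedance, 0.05)
  expect_length(pt$permuted, 100L)
  # the observed statistic equals a direct Q2 evaluation (identity labelling)
  expect_equal(pt$observed,
               oplsda_q2(x, labels, 1L, 0L, seed = 9L))
  pt2 <- oplsda_permutation(x, labels, n_predictive = 1L, n_orthogonal = 0L,
                            n_perm = 100L, seed = 9L)
  expect_identical(pt$permuted, pt2$permuted)
  expect_error(oplsda_permutation(x, labels, n_perm = 5L), "n_perm")
})

test_that("S-plot geometry: perfect separators, noise bins, bounds", {
  dat <- catch_data()
  set.seed(55)
  x <- cbind(dat$x, `999.9` = runif(nrow(dat$x)) * 1e-3)  # pure-noise bin
  fit <- oplsda_ovr(x, dat$labels, "haddock_trawl", n_predictive = 1L,
                    n_orthogonal = 0L)
  sp <- splot(fit)
  expect_true(all(abs(sp$p_corr) <= 1 + 1e-12))
  # trawl marker 764.5 in the positive extreme corner
  trawl <- sp[sp$bin == 764.5, ]
  expect_gt(trawl$p_corr, 0.5)
  expect_gt(trawl$p, 0.03)
  # line marker 819.5 in the opposite corner
  line <- sp[sp$bin == 819.5, ]
  expect_lt(line$p_corr, -0.5)
  expect_lt(line$p, -0.03)
  # the injected noise bin shows no class correlation
  noise <- sp[sp$bin == 999.9, ]
  expect_lt(abs(noise$p_corr), 0.25)

  multi <- reims_oplsda(fp5()$x, fp5()$labels, n_predictive = 4L)
  expect_error(splot(multi), "two-group")
})

test_that("a bin proportional to the score has correlation one", {
  set.seed(66)
  n <- 40
  sep <- rep(c(0, 1), each = n / 2) + rnorm(n, sd = 0.05)
  x <- cbind(s1 = sep, s2 = sep * 2 + 1, n1 = rnorm(n, sd = 1e-3))
  fit <- reims_oplsda(x, rep(c("a", "b"), each = n / 2), n_predictive = 1L)
  sp <- splot(fit, focal = "b")
  # both copies of the separator are (anti)parallel to the score
  expect_gt(abs(sp$p_corr[1]), 0.999)
  expect_gt(abs(sp$p_corr[2]), 0.999)
})

test_that("VIP satisfies its normalization identity and formula", {
  dat <- catch_data()
  fit <- reims_oplsda(dat$x, dat$labels, n_predictive = 1L, n_orthogonal = 2L)
  v <- vip(fit)
  expect_equal(sum(v^2), length(v), tolerance = 1e-10)

  # brute-force formula evaluation on a 5-bin toy fit
  set.seed(77)
  x <- matrix(rnorm(20 * 5), ncol = 5,
              dimnames = list(NULL, sprintf("t%d", 1:5)))
  x[, 2] <- x[, 2] + rep(c(0, 2), each = 10)
  x[, 5] <- x[, 5] + rep(c(0, 1), each = 10)
  toy <- reims_oplsda(x, rep(c("a", "b"), each = 10), n_predictive = 2L)
  v_toy <- vip(toy)
  J <- 5
  ssy <- sapply(1:2, function(a) {
    sum(toy$scores[, a]^2) * sum(toy$y_loadings[, a]^2)
  })
  brute <- sapply(1:J, function(j) {
    sqrt(J * sum(ssy * (toy$weights[j, ]^2 / colSums(toy$weights^2))) / sum(ssy))
  })
  expect_equal(unname(v_toy), brute, tolerance = 1e-10)
})

test_that("marker selection applies all three thresholds and ranks by |p_corr|", {
  dat <- fp5()
  fit <- oplsda_ovr(dat$x, dat$labels, "pollock", n_predictive = 1L,
                    n_orthogonal = 3L)
  sp <- splot(fit)
  v <- vip(fit)

  expect_identical(nrow(select_markers(sp, v, vip_min = Inf)), 0L)
  all_bins <- select_markers(sp, v, vip_min = 0, p_abs_min = 0,
                             p_corr_abs_min = 0)
  expect_identical(nrow(all_bins), nrow(sp))

  sel <- select_markers(sp, v)
  expect_true(all(c(629.5, 655.5, 667.5) %in% sel$bin))
  expect_lte(nrow(sel) - 3L, 2L)  # at most two false positives
  expect_true(all(diff(abs(sel$p_corr)) <= 1e-12))
  expect_true(all(sel$vip > 1 & abs(sel$p) > 0.03 & abs(sel$p_corr) > 0.5))
})

test_that("misclassification tables count every sample once", {
  dat <- catch_data()
  fit <- reims_oplsda(dat$x, dat$labels, n_predictive = 1L, n_orthogonal = 3L)
  mis <- misclassification_table(fit, dat$x, dat$labels)
  expect_equal(unname(rowSums(mis$table)), unname(as.numeric(table(dat$labels))))
  expect_equal(mis$rate, 100)
  expect_equal(classification_rate(95, 100), 95.00)
})
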