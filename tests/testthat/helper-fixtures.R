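# Shared fixtures (memoised: built once per test session) and independent
# oracles used across test files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

fish_profiles <- function() {
  memo("profiles", default_species_profiles)
}

five_species <- function() {
  p <- fish_profiles()
  p[c("cod", "coley", "haddock", "pollock", "whiting")]
}

# 5-class sample-level fingerprints, 30 per class.
fp5 <- function() {
  memo("fp5", function() {
    fish <- five_species()
    design <- dataset_design(fish, stats::setNames(rep(30L, 5), names(fish)),
                             seed = 11L)
    simulate_fingerprints(design)
  })
}

# PCA-LDA model on fp5.
fp5_model <- function() {
  memo("fp5_model", function() {
    dat <- fp5()
    reims_pcalda(dat$x, dat$labels, n_pca = 25L, n_lda = 4L)
  })
}

# Per-burn features of a small raw-stream dataset (5 runs per class) and the
# per-burn recognition model trained on them.
burn_data <- function() {
  memo("burn_data", function() {
    fish <- five_species()
    design <- dataset_design(fish, stats::setNames(rep(5L, 5), names(fish)),
                             seed = 21L)
    simulate_features(design, mode = "per_burn")
  })
}

burn_model <- function() {
  memo("burn_model", function() {
    dat <- burn_data()
    reims_pcalda(dat$x, dat$labels, n_pca = 20L, n_lda = 4L)
  })
}

# One raw cod run with default acquisition settings.
raw_run <- function() {
  memo("raw_run", function() {
    simulate_run(fish_profiles()$cod, run_id = "cod_fixture", seed = 42L)
  })
}

# Hand-built run with prescribed per-scan TICs (single grid point).
toy_run <- function(tics, period = 0.5) {
  scans <- matrix(tics, ncol = 1L)
  structure(
    list(mz = 700, scans = scans,
         clock = (seq_along(tics) - 1L) * period,
         meta = list(run_id = "toy", label = "toy", drift = 1,
                     scan_period = period,
                     burns = data.frame(start = integer(0), end = integer(0)))),
    class = "reims_run"
  )
}

# --- Independent oracles -------------------------------------------------

# PLS2 where each weight is the dominant left singular vector of E'F
# (deflation identical to NIPALS, extraction by direct SVD).
pls_svd_oracle <- function(x, y, ncomp) {
  e <- x
  f <- y
  W <- NULL; P <- NULL; Tm <- NULL; Q <- NULL
  for (a in seq_len(ncomp)) {
    w <- svd(crossprod(e, f), nu = 1L, nv = 0L)$u[, 1L]
    w <- w / sqrt(sum(w^2))
    tt <- e %*% w
    p <- crossprod(e, tt) / sum(tt^2)
    q <- crossprod(f, tt) / sum(tt^2)
    e <- e - tcrossprod(tt, p)
    f <- f - tcrossprod(tt, q)
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, tt); Q <- cbind(Q, q)
  }
  list(W = W, P = P, T = Tm, Q = Q)
}

# Align the sign of each column of `a` to the matching column of `b`.
align_signs <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * b[, j]) < 0) a[, j] <- -a[, j]
  }
  a
}

# Brute-force reclassification: recompute projection and standardized
# distances from the model's stored parameters with fresh, scalar code.
classify_oracle <- function(model, x) {
  out <- character(nrow(x))
  dist <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    xc <- x[i, ] - model$center
    s <- as.numeric(t(model$loadings) %*% xc)
    z <- as.numeric(t(model$axes) %*% s)
    d <- sapply(seq_along(model$classes), function(k) {
      sqrt(sum(((z - model$centroids[k, ]) / model$dispersions[k, ])^2) /
             model$n_lda)
    })
    k <- which.min(d)
    dist[i] <- d[k]
    out[i] <- if (d[k] <= model$sigma_max) model$classes[k] else "outlier"
  }
  list(label = out, distance = dist)
}
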