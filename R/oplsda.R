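# OPLS-DA: orthogonal projections to latent structures discriminant
# analysis, with R2/Q2 validation, permutation testing, S-plot and VIP
# marker mining.
#
# Fitting follows the two-block scheme: orthogonal components (systematic
# X-variation uncorrelated with class membership) are extracted and removed
# first, then predictive components are fitted by NIPALS PLS2 on the
# filtered matrix. Predictive scores are exactly orthogonal to the removed
# components by construction.

#' Mean-centre and Pareto-scale a feature matrix
#'
#' Each retained column is transformed to `(x - mean) / sqrt(sd)`. Pareto
#' scaling damps the dominance of high-abundance lipid bins without
#' inflating noise bins the way unit-variance scaling would.
#' Zero-variance columns carry no class information under any scaling and
#' are dropped (their identities are recorded).
#'
#' @param x Numeric matrix, rows = samples (>= 2).
#' @return List with `x` (scaled matrix, dropped columns removed),
#'   `center`, `scale` (the sqrt-sd divisors), `kept` (column indices
#'   retained) and `dropped` (indices removed).
#' @export
pareto_scale <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("need >= 2 samples to scale", call. = FALSE)
  center <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  kept <- which(sds > 0)
  dropped <- which(sds == 0)
  scl <- sqrt(sds[kept])
  xs <- sweep(x[, kept, drop = FALSE], 2L, center[kept])
  xs <- sweep(xs, 2L, scl, "/")
  list(x = xs, center = center[kept], scale = scl,
       kept = kept, dropped = dropped)
}

#' Invert [pareto_scale()]
#' @param xs Scaled matrix (columns = retained bins).
#' @param scaling The list returned by [pareto_scale()].
#' @return Matrix on the original scale (retained columns only).
#' @export
pareto_unscale <- function(xs, scaling) {
  sweep(sweep(xs, 2L, scaling$scale, "*"), 2L, scaling$center, "+")
}

# Class-membership dummy matrix (one column per class, 1/0).
.dummy_y <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  y <- vapply(classes, function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  if (length(labels) == 1L) y <- matrix(y, nrow = 1L)
  colnames(y) <- classes
  y
}

# First PLS weight: dominant left singular vector of X'Y.
.pls_weight <- function(x, y) {
  w <- svd(crossprod(x, y), nu = 1L, nv = 0L)$u[, 1L]
  w / sqrt(sum(w^2))
}

# NIPALS PLS2 with X and Y deflation. Returns weights W, X-loadings P,
# Y-loadings Q, scores T (columns = components).
.pls_nipals <- function(x, y, ncomp, tol = 1e-26, max_iter = 2000L) {
  n <- nrow(x); p <- ncol(x); k <- ncol(y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, k, ncomp); Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- y[, which.max(colSums(y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(x, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tt <- x %*% w
      q <- crossprod(y, tt) / sum(tt^2)
      u <- y %*% q / sum(q^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), tol) < tol) break
      t_old <- tt
    }
    pp <- crossprod(x, tt) / sum(tt^2)
    x <- x - tcrossprod(tt, pp)
    y <- y - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
  }
  list(W = W, P = P, Q = Q, T = Tm, x_resid = x, y_resid = y)
}

#' Fit an OPLS-DA model
#'
#' Class labels are encoded as a mean-centred dummy matrix (one column per
#' class). `n_orthogonal` components of X-variation uncorrelated with the
#' class structure are extracted and removed first; `n_predictive`
#' components are then fitted by NIPALS PLS2 on the filtered matrix.
#' Fingerprints are mean-centred and Pareto-scaled internally.
#'
#' @param x Feature matrix (rows = samples, columns = bins).
#' @param labels Class labels; at least two classes.
#' @param n_predictive Predictive (latent) components; for multi-class
#'   data at most `n_classes - 1`.
#' @param n_orthogonal Orthogonal components (>= 0).
#' @return An object of class `reims_oplsda` with scores, loadings and
#'   weights for both blocks, the scaling, and cumulative `R2X`, `R2Y`.
#' @seealso [oplsda_q2()], [splot()], [vip()], [oplsda_permutation()]
#' @export
reims_oplsda <- function(x, labels, n_predictive = 1L, n_orthogonal = 0L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels),
            n_predictive >= 1L, n_orthogonal >= 0L)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (length(classes) > 2L && n_predictive > length(classes) - 1L) {
    stop(sprintf("n_predictive must be <= %d for %d classes",
                 length(classes) - 1L, length(classes)), call. = FALSE)
  }
  scaling <- pareto_scale(x)
  xs <- scaling$x
  y <- .dummy_y(labels)
  y_center <- colMeans(y)
  yc <- sweep(y, 2L, y_center)
  ssx0 <- sum(xs^2)
  ssy0 <- sum(yc^2)

  e <- xs
  n_orth <- as.integer(n_orthogonal)
  Wo <- matrix(0, ncol(e), n_orth); Po <- matrix(0, ncol(e), n_orth)
  To <- matrix(0, nrow(e), n_orth)
  for (o in seq_len(n_orth)) {
    w <- .pls_weight(e, yc)
    tt <- e %*% w
    p <- crossprod(e, tt) / sum(tt^2)
    # joint Y-predictive subspace of the current matrix
    wy <- qr.Q(qr(crossprod(e, yc)))
    w_orth <- p - wy %*% crossprod(wy, p)
    nrm <- sqrt(sum(w_orth^2))
    if (nrm < 1e-12) {
      stop("no orthogonal variation left to extract (component ", o, ")",
           call. = FALSE)
    }
    w_orth <- w_orth / nrm
    t_orth <- e %*% w_orth
    p_orth <- crossprod(e, t_orth) / sum(t_orth^2)
    e <- e - tcrossprod(t_orth, p_orth)
    Wo[, o] <- w_orth; Po[, o] <- p_orth; To[, o] <- t_orth
  }

  pls <- .pls_nipals(e, yc, as.integer(n_predictive))
  # regression coefficients on the orthogonal-filtered matrix
  B <- pls$W %*% solve(crossprod(pls$P, pls$W)) %*% t(pls$Q)
  r2x <- 1 - sum(pls$x_resid^2) / ssx0
  r2y <- 1 - sum(pls$y_resid^2) / ssy0

  structure(
    list(center = scaling$center, scale = scaling$scale,
         kept = scaling$kept, dropped = scaling$dropped,
         bins = colnames(x)[scaling$kept],
         classes = classes, labels = labels, y_center = y_center,
         n_predictive = as.integer(n_predictive),
         n_orthogonal = n_orth,
         weights = pls$W, loadings = pls$P, y_loadings = pls$Q,
         scores = pls$T,
         weights_ortho = Wo, loadings_ortho = Po, scores_ortho = To,
         coef = B, R2X = r2x, R2Y = r2y,
         x_scaled = xs, x_filtered = e),
    class = "reims_oplsda"
  )
}

#' @export
print.reims_oplsda <- function(x, ...) {
  cat(sprintf("<reims_oplsda> %d classes (%s): %d predictive + %d orthogonal components\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$n_predictive, x$n_orthogonal))
  cat(sprintf("  R2X(cum) = %.3f, R2Y(cum) = %.3f, %d retained bins\n",
              x$R2X, x$R2Y, length(x$bins)))
  invisible(x)
}

#' @export
summary.reims_oplsda <- function(object, ...) {
  print(object)
  mis <- misclassification_table(object,
                                 pareto_unscale(object$x_scaled,
                                                list(center = object$center,
                                                     scale = object$scale)),
                                 object$labels, .retained = TRUE)
  cat(sprintf("Training misclassification rate: %.2f%% correct\n", mis$rate))
  print(mis$table)
  invisible(object)
}

# Scale new data with the model's scaling and remove orthogonal variation.
.oplsda_filter <- function(object, newdata, .retained = FALSE) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (!.retained) newdata <- newdata[, object$kept, drop = FALSE]
  xs <- sweep(newdata, 2L, object$center)
  xs <- sweep(xs, 2L, object$scale, "/")
  for (o in seq_len(object$n_orthogonal)) {
    t_orth <- xs %*% object$weights_ortho[, o]
    xs <- xs - tcrossprod(t_orth, object$loadings_ortho[, o])
  }
  xs
}

#' Predict class membership from an OPLS-DA model
#'
#' @param object A [reims_oplsda()] model.
#' @param newdata Feature matrix on the training bin grid.
#' @param type `"class"` for hard assignments (argmax of predicted
#'   membership), `"response"` for the predicted dummy-Y matrix,
#'   `"scores"` for predictive scores.
#' @param ... Unused.
#' @return Per `type`: character vector, numeric matrix, or score matrix.
#' @export
predict.reims_oplsda <- function(object, newdata,
                                 type = c("class", "response", "scores"), ...) {
  type <- match.arg(type)
  xf <- .oplsda_filter(object, newdata)
  if (type == "scores") {
    # successive NIPALS scores with X-deflation
    Tm <- matrix(0, nrow(xf), object$n_predictive)
    e <- xf
    for (a in seq_len(object$n_predictive)) {
      Tm[, a] <- e %*% object$weights[, a]
      e <- e - tcrossprod(Tm[, a], object$loadings[, a])
    }
    return(Tm)
  }
  yhat <- xf %*% object$coef
  yhat <- sweep(yhat, 2L, object$y_center, "+")
  colnames(yhat) <- object$classes
  if (type == "response") return(yhat)
  object$classes[apply(yhat, 1L, which.max)]
}

#' @export
fitted.reims_oplsda <- function(object, ...) {
  yhat <- object$x_filtered %*% object$coef
  sweep(yhat, 2L, object$y_center, "+")
}

#' @export
residuals.reims_oplsda <- function(object, ...) {
  .dummy_y(object$labels)[, object$classes, drop = FALSE] -
    fitted(object)
}

#' @export
plot.reims_oplsda <- function(x, ...) {
  if (x$n_predictive >= 2L) {
    s <- x$scores[, 1:2]
    ylab <- "t2 (predictive)"
  } else {
    s <- cbind(x$scores[, 1L],
               if (x$n_orthogonal >= 1L) x$scores_ortho[, 1L] else
                 seq_len(nrow(x$scores)))
    ylab <- if (x$n_orthogonal >= 1L) "to1 (orthogonal)" else "index"
  }
  cls <- factor(x$labels, levels = x$classes)
  graphics::plot(s, col = as.integer(cls), pch = 19,
                 xlab = "t1 (predictive)", ylab = ylab,
                 main = "OPLS-DA scores", ...)
  graphics::legend("topright", legend = levels(cls),
                   col = seq_along(levels(cls)), pch = 19, cex = 0.8)
  invisible(x)
}

#' Cross-validated predictive ability Q2(cum)
#'
#' Stratified k-fold cross-validation: per fold the whole model — scaling
#' included — is refitted on the training portion and the held-out dummy-Y
#' rows are predicted. `Q2 = 1 - PRESS / TSS` with TSS taken about the
#' full-data class means.
#'
#' @inheritParams reims_oplsda
#' @param n_folds Number of folds (>= 2; default 7).
#' @param seed Seed for the fold assignment.
#' @return Scalar Q2 (<= 1; can be negative for uninformative models).
#' @export
oplsda_q2 <- function(x, labels, n_predictive = 1L, n_orthogonal = 0L,
                      n_folds = 7L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (n_folds < 2L) stop("'n_folds' must be >= 2", call. = FALSE)
  labels <- as.character(labels)
  y <- .dummy_y(labels)
  # stratify where possible; tiny classes fall back to pooled assignment
  fold <- tryCatch(.stratified_folds(labels, n_folds, seed),
                   error = function(e) with_seed(seed, {
                     rep_len(seq_len(n_folds), length(labels))[sample.int(length(labels))]
                   }))
  press <- 0
  for (f in sort(unique(fold))) {
    train <- fold != f
    if (length(unique(labels[train])) < 2L) next
    fit <- reims_oplsda(x[train, , drop = FALSE], labels[train],
                        n_predictive = n_predictive,
                        n_orthogonal = n_orthogonal)
    yhat <- predict(fit, x[!train, , drop = FALSE], type = "response")
    ytest <- y[!train, fit$classes, drop = FALSE]
    press <- press + sum((ytest - yhat)^2)
  }
  tss <- sum(sweep(y, 2L, colMeans(y))^2)
  1 - press / tss
}

#' Permutation test of model validity
#'
#' Refits the full model (scaling included) under `n_perm` random
#' relabellings and records the cross-validated Q2 of each; an informative
#' model's observed Q2 should exceed essentially all permuted values. The
#' empirical exceedance proportion `#(permuted >= observed) / n_perm` is
#' the reported statistic.
#'
#' @inheritParams oplsda_q2
#' @param n_perm Number of label permutations (>= 10).
#' @return An object of class `reims_perm` with `observed`, `permuted`,
#'   `n_perm` and `exceedance`.
#' @export
oplsda_permutation <- function(x, labels, n_predictive = 1L,
                               n_orthogonal = 0L, n_perm = 100L,
                               n_folds = 7L, seed = 1L) {
  if (n_perm < 10L) stop("'n_perm' must be >= 10", call. = FALSE)
  labels <- as.character(labels)
  observed <- oplsda_q2(x, labels, n_predictive, n_orthogonal,
                        n_folds = n_folds, seed = seed)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(labels)
      oplsda_q2(x, perm, n_predictive, n_orthogonal,
                n_folds = n_folds, seed = child_seed(seed, i))
    }, numeric(1))
  })
  structure(
    list(observed = observed, permuted = permuted, n_perm = as.integer(n_perm),
         exceedance = mean(permuted >= observed)),
    class = "reims_perm"
  )
}

#' @export
print.reims_perm <- function(x, ...) {
  cat(sprintf("<reims_perm> observed Q2 = %.3f; %d permutations, max permuted Q2 = %.3f\n",
              x$observed, x$n_perm, max(x$permuted)))
  cat(sprintf("  exceedance proportion = %.3f\n", x$exceedance))
  invisible(x)
}

#' S-plot of a two-class OPLS-DA model
#'
#' For every retained bin, `p` is the covariance and `p_corr` the Pearson
#' correlation of the (scaled) bin with the first predictive score. The
#' score is oriented so positive values mean enrichment in the focal
#' class; candidate markers sit in the extreme corners.
#'
#' @param model A two-class [reims_oplsda()] model with >= 1 predictive
#'   component.
#' @param focal Class treated as the positive direction (default: first
#'   class alphabetically that is not `"rest"`, so one-vs-rest models fit
#'   with [oplsda_ovr()] point at the focal species).
#' @return Data frame with columns `bin` (centre, Da), `p`, `p_corr`.
#' @export
splot <- function(model, focal = NULL) {
  stopifnot(inherits(model, "reims_oplsda"))
  if (length(model$classes) != 2L) {
    stop("S-plot is defined for two-group (one-vs-rest) models; fit the focal class against the rest",
         call. = FALSE)
  }
  if (is.null(focal)) {
    focal <- setdiff(model$classes, "rest")[1]
  }
  stopifnot(focal %in% model$classes)
  t1 <- model$scores[, 1L]
  if (stats::sd(t1) == 0) stop("predictive score has zero variance", call. = FALSE)
  if (mean(t1[model$labels == focal]) < mean(t1[model$labels != focal])) {
    t1 <- -t1
  }
  xs <- model$x_scaled
  n <- nrow(xs)
  tc <- t1 - mean(t1)
  p <- as.numeric(crossprod(xs, tc)) / (n - 1)   # columns of xs are centred
  denom <- apply(xs, 2L, stats::sd) * stats::sd(t1)
  p_corr <- ifelse(denom > 0, p / denom, 0)
  bins <- suppressWarnings(as.numeric(model$bins))
  if (anyNA(bins)) bins <- model$bins  # non-numeric column names
  data.frame(bin = bins, p = p, p_corr = p_corr)
}

#' Fit a one-vs-rest OPLS-DA model for a focal class
#'
#' Relabels every non-focal sample as `"rest"` and fits a two-class model,
#' the construction behind per-species S-plots.
#'
#' @inheritParams reims_oplsda
#' @param focal The class of interest.
#' @return A two-class `reims_oplsda` model (classes `focal`, `"rest"`).
#' @export
oplsda_ovr <- function(x, labels, focal, n_predictive = 1L,
                       n_orthogonal = 0L) {
  labels <- as.character(labels)
  if (!focal %in% labels) stop("focal class not present", call. = FALSE)
  lab2 <- ifelse(labels == focal, focal, "rest")
  reims_oplsda(x, lab2, n_predictive = n_predictive,
               n_orthogonal = n_orthogonal)
}

#' Variable importance in projection
#'
#' Standard VIP over the predictive components:
#' \eqn{VIP_j = \sqrt{J \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with `J` the retained bin count and `SSY_a` the Y-variance explained by
#' component `a`. By construction the mean squared VIP equals 1.
#'
#' @param model A [reims_oplsda()] model.
#' @return Named numeric vector of VIP scores (names = bin centres).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "reims_oplsda"))
  J <- length(model$bins)
  A <- model$n_predictive
  ssy <- vapply(seq_len(A), function(a) {
    sum(model$scores[, a]^2) * sum(model$y_loadings[, a]^2)
  }, numeric(1))
  wnorm2 <- colSums(model$weights^2)
  contrib <- sweep(model$weights^2, 2L, wnorm2, "/")
  v <- sqrt(J * as.numeric(contrib %*% ssy) / sum(ssy))
  names(v) <- model$bins
  v
}

#' Select marker ions by joint VIP / S-plot thresholds
#'
#' Keeps the bins passing all three criteria — `VIP > vip_min`,
#' `|p| > p_abs_min`, `|p_corr| > p_corr_abs_min` (defaults 1, 0.03, 0.5)
#' — ranked by `|p_corr|` descending, ties by `|p|` descending.
#'
#' @param splot_rows Data frame from [splot()].
#' @param vip_scores Vector from [vip()] on the same model.
#' @param vip_min,p_abs_min,p_corr_abs_min Selection thresholds (>= 0).
#' @return Data frame of selected bins with their `p`, `p_corr` and `vip`
#'   values; zero rows when nothing passes.
#' @export
select_markers <- function(splot_rows, vip_scores, vip_min = 1,
                           p_abs_min = 0.03, p_corr_abs_min = 0.5) {
  stopifnot(nrow(splot_rows) == length(vip_scores),
            vip_min >= 0, p_abs_min >= 0, p_corr_abs_min >= 0)
  out <- cbind(splot_rows, vip = as.numeric(vip_scores))
  out <- out[out$vip > vip_min & abs(out$p) > p_abs_min &
               abs(out$p_corr) > p_corr_abs_min, , drop = FALSE]
  out <- out[order(-abs(out$p_corr), -abs(out$p)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Misclassification table of an OPLS-DA model
#'
#' Hard class predictions (argmax of predicted membership) tabulated
#' against truth, with the correct rate in percent.
#'
#' @param model A [reims_oplsda()] model.
#' @param x Feature matrix to classify.
#' @param labels True labels.
#' @param .retained Internal: `x` already restricted to retained bins.
#' @return List with `table` (truth x predicted) and `rate`.
#' @export
misclassification_table <- function(model, x, labels, .retained = FALSE) {
  stopifnot(inherits(model, "reims_oplsda"))
  xf <- .oplsda_filter(model, x, .retained = .retained)
  yhat <- sweep(xf %*% model$coef, 2L, model$y_center, "+")
  pred <- model$classes[apply(yhat, 1L, which.max)]
  labels <- as.character(labels)
  lev <- sort(unique(c(labels, model$classes)))
  tab <- table(truth = factor(labels, levels = lev),
               predicted = factor(pred, levels = lev))
  list(table = tab,
       rate = classification_rate(sum(pred == labels), length(labels)))
}
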