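# PCA-LDA speciation engine: principal-component reduction, discriminant
# projection, per-class standardized distances and the 5-sigma outlier rule.

#' Principal component basis of a feature matrix
#'
#' Mean-centred PCA via singular value decomposition; axes ordered by
#' decreasing explained variance.
#'
#' @param x Numeric matrix, rows = samples.
#' @param n_pca Number of components to retain
#'   (`<= min(nrow(x) - 1, ncol(x))`).
#' @return List with `center` (column means), `loadings`
#'   (`ncol(x) x n_pca`, orthonormal), `scores` (`nrow(x) x n_pca`) and
#'   `variance` (per-component score variance).
#' @export
fit_pca <- function(x, n_pca) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  max_pc <- min(nrow(x) - 1L, ncol(x))
  if (n_pca < 1L || n_pca > max_pc) {
    stop(sprintf("n_pca must be in [1, %d] for %d samples x %d features",
                 max_pc, nrow(x), ncol(x)), call. = FALSE)
  }
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc, nu = 0, nv = n_pca)
  loadings <- sv$v
  scores <- xc %*% loadings
  list(center = center, loadings = loadings, scores = scores,
       variance = sv$d[seq_len(n_pca)]^2 / (nrow(x) - 1L))
}

#' Linear discriminant axes on PCA scores
#'
#' Solves the generalized eigenproblem of between-class versus within-class
#' scatter. The pooled within-class scatter is ridge-regularized by
#' `eps * trace / dim` for numerical invertibility. At most
#' `n_classes - 1` axes exist.
#'
#' @param scores Numeric matrix of PCA scores.
#' @param labels Class labels (one per row).
#' @param n_lda Number of discriminant axes (`<= n_classes - 1`).
#' @param eps Ridge fraction for the within-class scatter.
#' @return List with `axes` (`ncol(scores) x n_lda`, unit columns) and
#'   `scores` (discriminant scores of the training rows).
#' @export
fit_lda <- function(scores, labels, n_lda, eps = 1e-6) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("singleton class(es): ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  if (n_lda < 1L || n_lda > length(classes) - 1L) {
    stop(sprintf("n_lda must be in [1, %d] for %d classes",
                 length(classes) - 1L, length(classes)), call. = FALSE)
  }
  p <- ncol(scores)
  grand <- colMeans(scores)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in classes) {
    rows <- scores[labels == cl, , drop = FALSE]
    mu <- colMeans(rows)
    dc <- sweep(rows, 2L, mu)
    Sw <- Sw + crossprod(dc)
    d <- mu - grand
    Sb <- Sb + nrow(rows) * tcrossprod(d)
  }
  Sw <- Sw + diag(eps * sum(diag(Sw)) / p, p)
  # whiten within-class scatter, then eigendecompose the between scatter
  R <- chol(Sw)
  Rinv <- backsolve(R, diag(p))
  M <- crossprod(Rinv, Sb %*% Rinv)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  axes <- Rinv %*% eg$vectors[, seq_len(n_lda), drop = FALSE]
  axes <- sweep(axes, 2L, sqrt(colSums(axes^2)), "/")
  list(axes = axes, scores = scores %*% axes)
}

#' Per-class centroids and dispersions in discriminant space
#'
#' The sigma of the 5-sigma rule: for each class, the centroid is the class
#' mean and the dispersion the per-axis sample standard deviation of its
#' members, floored at `1e-12` so degenerate classes still yield finite
#' standardized distances.
#'
#' @param lda_scores Matrix of discriminant scores.
#' @param labels Class labels.
#' @return List with `classes`, `centroids` (class x axis matrix) and
#'   `dispersions` (same shape).
#' @export
fit_class_stats <- function(lda_scores, labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("singleton class(es): ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  cent <- t(vapply(classes, function(cl) {
    colMeans(lda_scores[labels == cl, , drop = FALSE])
  }, numeric(ncol(lda_scores))))
  disp <- t(vapply(classes, function(cl) {
    apply(lda_scores[labels == cl, , drop = FALSE], 2L, stats::sd)
  }, numeric(ncol(lda_scores))))
  disp <- pmax(disp, 1e-12)
  if (ncol(lda_scores) == 1L) {  # vapply collapses to vectors
    cent <- matrix(cent, ncol = 1L, dimnames = list(classes, NULL))
    disp <- matrix(disp, ncol = 1L, dimnames = list(classes, NULL))
  }
  list(classes = classes, centroids = cent, dispersions = disp)
}

#' Fit a PCA-LDA species model with a 5-sigma outlier rule
#'
#' The speciation engine: mean-centred PCA reduces the fingerprint matrix,
#' LDA finds up to `n_classes - 1` discriminant axes, and each class gets a
#' centroid and per-axis dispersions in discriminant space. Queries are
#' assigned to the nearest class by standardized distance
#' \eqn{d_k = \sqrt{\sum_a ((z_a - c_{ka})/s_{ka})^2 / n_{lda}}} and marked
#' `"outlier"` when \eqn{\min_k d_k > \sigma_{max}} (default 5).
#'
#' @param x Feature matrix (rows = samples, columns = bins).
#' @param labels Class labels, one per row.
#' @param n_pca Retained principal components (default 25; the speciation
#'   preset in the source study used 80).
#' @param n_lda Discriminant axes (default `min(n_classes - 1, n_pca)`).
#' @param sigma_max Dispersion multiple for class assignment (default 5).
#' @return An object of class `reims_pcalda`.
#' @seealso [predict.reims_pcalda()], [pcalda_cv()]
#' @export
reims_pcalda <- function(x, labels, n_pca = 25L, n_lda = NULL, sigma_max = 5) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.character(labels)
  if (sigma_max <= 0) stop("'sigma_max' must be > 0", call. = FALSE)
  classes <- unique(labels)
  if (is.null(n_lda)) n_lda <- min(length(classes) - 1L, n_pca)
  pca <- fit_pca(x, n_pca)
  lda <- fit_lda(pca$scores, labels, n_lda)
  stats <- fit_class_stats(lda$scores, labels)
  structure(
    list(center = pca$center, loadings = pca$loadings,
         pca_variance = pca$variance, axes = lda$axes,
         classes = stats$classes, centroids = stats$centroids,
         dispersions = stats$dispersions,
         n_pca = as.integer(n_pca), n_lda = as.integer(n_lda),
         sigma_max = sigma_max, bins = colnames(x),
         n_train = nrow(x), class_sizes = table(labels),
         lda_scores = lda$scores, train_labels = labels),
    class = "reims_pcalda"
  )
}

#' @export
print.reims_pcalda <- function(x, ...) {
  cat(sprintf("<reims_pcalda> %d classes, %d PCA components, %d LDA axes, sigma_max = %g\n",
              length(x$classes), x$n_pca, x$n_lda, x$sigma_max))
  cat("  classes:", paste(sprintf("%s (n=%d)", names(x$class_sizes),
                                  as.integer(x$class_sizes)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.reims_pcalda <- function(object, ...) {
  cat(sprintf("PCA-LDA species model: %d training fingerprints, %d bins\n",
              object$n_train, length(object$bins)))
  cat(sprintf("  %d PCA components (%.1f%% of variance), %d LDA axes, outlier rule at %g sigma\n",
              object$n_pca,
              100 * sum(object$pca_variance) / max(sum(object$pca_variance), .Machine$double.eps),
              object$n_lda, object$sigma_max))
  cat("Per-class centroids (discriminant space):\n")
  print(round(object$centroids, 4))
  invisible(object)
}

# Project raw fingerprints into the model's discriminant space. Rows are
# projected one at a time so that batch and streaming classification of the
# same fingerprint are bit-identical (BLAS may otherwise take different
# code paths for matrix-matrix and matrix-vector products).
.project <- function(object, x) {
  z <- matrix(0, nrow(x), object$n_lda)
  for (i in seq_len(nrow(x))) {
    xc <- x[i, ] - object$center
    z[i, ] <- (xc %*% object$loadings) %*% object$axes
  }
  z
}

# Standardized per-class distances for a matrix of discriminant scores.
.class_distances <- function(object, z) {
  n_lda <- object$n_lda
  d <- vapply(seq_along(object$classes), function(k) {
    dz <- sweep(z, 2L, object$centroids[k, ], "-")
    dz <- sweep(dz, 2L, object$dispersions[k, ], "/")
    sqrt(rowSums(dz^2) / n_lda)
  }, numeric(nrow(z)))
  if (nrow(z) == 1L) d <- matrix(d, nrow = 1L)
  colnames(d) <- object$classes
  d
}

#' Classify fingerprints with a fitted PCA-LDA model
#'
#' Projects each query through mean-centring, the PCA basis and the LDA
#' axes, computes its standardized distance to every class and assigns the
#' closest class, or `"outlier"` when all distances exceed the model's
#' `sigma_max`. Distance ties are broken by class list order.
#'
#' @param object A [reims_pcalda()] model.
#' @param newdata Feature matrix (rows = queries) or a single feature
#'   vector on the model's bin grid.
#' @param ... Unused.
#' @return Data frame with one row per query: `id`, `label` (assigned
#'   class or `"outlier"`), `distance` (of the assigned/nearest class) and
#'   one `d_<class>` column per class.
#' @export
predict.reims_pcalda <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$bins)) {
    stop(sprintf("query has %d bins; model expects %d",
                 ncol(newdata), length(object$bins)), call. = FALSE)
  }
  if (nrow(newdata) == 0L) {
    return(data.frame(id = character(0), label = character(0),
                      distance = numeric(0)))
  }
  z <- .project(object, newdata)
  d <- .class_distances(object, z)
  nearest <- apply(d, 1L, which.min)
  dmin <- d[cbind(seq_len(nrow(d)), nearest)]
  label <- ifelse(dmin <= object$sigma_max, object$classes[nearest], "outlier")
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- sprintf("query_%03d", seq_len(nrow(newdata)))
  out <- data.frame(id = ids, label = label, distance = dmin)
  dd <- as.data.frame(d)
  names(dd) <- paste0("d_", object$classes)
  cbind(out, dd)
}

#' @export
plot.reims_pcalda <- function(x, axes = c(1L, 2L), ...) {
  if (x$n_lda < 2L) stop("need >= 2 LDA axes to plot", call. = FALSE)
  z <- x$lda_scores[, axes, drop = FALSE]
  cls <- factor(x$train_labels, levels = x$classes)
  graphics::plot(z, col = as.integer(cls), pch = 19,
                 xlab = sprintf("LD%d", axes[1]), ylab = sprintf("LD%d", axes[2]),
                 main = "Discriminant scores", ...)
  graphics::legend("topright", legend = levels(cls), col = seq_along(levels(cls)),
                   pch = 19, cex = 0.8)
  invisible(x)
}

#' Correct classification rate as a percentage
#'
#' @param correct Number of correctly classified samples.
#' @param total Total number of samples (>= 1).
#' @return `100 * correct / total`, rounded to 2 decimals.
#' @export
classification_rate <- function(correct, total) {
  stop_if_not_scalar_num(correct, "correct")
  stop_if_not_scalar_num(total, "total")
  if (total < 1) stop("'total' must be >= 1", call. = FALSE)
  if (correct < 0 || correct > total) {
    stop("'correct' must be in [0, total]", call. = FALSE)
  }
  round(100 * correct / total, 2L)
}

# Stratified fold assignment: within each class, shuffle then deal folds
# cyclically, so every class appears in every training split.
.stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds) {
        stop(sprintf("class '%s' has %d samples; need >= %d to stratify into %d folds",
                     cl, length(idx), n_folds, n_folds), call. = FALSE)
      }
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))]
    }
    fold
  })
}

#' Leave-20%-out cross-validation of the PCA-LDA model
#'
#' Stratified, seeded partition into `round(1 / fraction)` folds; each fold
#' is held out once, a model is fitted on the remainder and the held-out
#' samples are classified, so every sample is left out exactly once.
#'
#' @inheritParams reims_pcalda
#' @param fraction Held-out fraction per fold (0.2 gives 5 folds).
#' @param seed Seed for the fold assignment.
#' @return An object of class `reims_cv`: fold assignments, per-sample
#'   predicted vs true labels, a confusion table (including an outlier
#'   column) and the correct-classification rate in percent.
#' @export
pcalda_cv <- function(x, labels, n_pca = 25L, n_lda = NULL, sigma_max = 5,
                      fraction = 0.2, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels), fraction > 0, fraction < 1)
  labels <- as.character(labels)
  n_folds <- as.integer(round(1 / fraction))
  fold <- .stratified_folds(labels, n_folds, seed)
  predicted <- character(length(labels))
  for (f in seq_len(n_folds)) {
    train <- fold != f
    fit <- reims_pcalda(x[train, , drop = FALSE], labels[train],
                        n_pca = n_pca, n_lda = n_lda, sigma_max = sigma_max)
    predicted[!train] <- predict(fit, x[!train, , drop = FALSE])$label
  }
  lev <- c(sort(unique(labels)), "outlier")
  confusion <- table(truth = factor(labels, levels = lev),
                     predicted = factor(predicted, levels = lev))
  correct <- sum(predicted == labels)
  structure(
    list(fold = fold, truth = labels, predicted = predicted,
         confusion = confusion, correct = correct, total = length(labels),
         rate = classification_rate(correct, length(labels)),
         n_folds = n_folds, seed = seed),
    class = "reims_cv"
  )
}

#' @export
print.reims_cv <- function(x, ...) {
  cat(sprintf("<reims_cv> leave-%d%%-out: %d/%d correct (%.2f%%)\n",
              round(100 / x$n_folds), x$correct, x$total, x$rate))
  print(x$confusion)
  invisible(x)
}

#' Classify an external validation set
#'
#' Batch application of [predict.reims_pcalda()] with a per-class summary,
#' the workflow used to validate a trained speciation model on samples that
#' never entered model building.
#'
#' @param x_new Feature matrix of external samples (possibly zero rows).
#' @param model A fitted [reims_pcalda()] model.
#' @return An object of class `reims_external`: per-sample results plus
#'   per-class counts including outliers.
#' @export
classify_external <- function(x_new, model) {
  stopifnot(inherits(model, "reims_pcalda"))
  res <- predict(model, x_new)
  counts <- table(factor(res$label, levels = c(model$classes, "outlier")))
  structure(list(results = res, counts = counts,
                 n = nrow(res), n_outlier = sum(res$label == "outlier")),
            class = "reims_external")
}

#' @export
print.reims_external <- function(x, ...) {
  cat(sprintf("<reims_external> %d samples classified (%d outliers)\n",
              x$n, x$n_outlier))
  print(x$counts)
  invisible(x)
}

#' Serialize a PCA-LDA model to versioned JSON
#'
#' Stores means, loadings, discriminant axes, class statistics and
#' hyperparameters; [read_model_json()] reconstructs a model whose
#' predictions match the original to full double precision.
#'
#' @param model A [reims_pcalda()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "reims_pcalda"))
  doc <- list(
    format = "reimsid-pcalda", version = 1L,
    n_pca = model$n_pca, n_lda = model$n_lda, sigma_max = model$sigma_max,
    bins = model$bins, classes = model$classes,
    center = model$center, loadings = model$loadings, axes = model$axes,
    centroids = model$centroids, dispersions = model$dispersions,
    class_sizes = as.list(model$class_sizes), n_train = model$n_train
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "reimsid-pcalda")) {
    stop("not a reimsid PCA-LDA model file: ", path, call. = FALSE)
  }
  as_mat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  structure(
    list(center = doc$center, loadings = as_mat(doc$loadings),
         pca_variance = NULL, axes = as_mat(doc$axes),
         classes = doc$classes,
         centroids = matrix(as_mat(doc$centroids),
                            nrow = length(doc$classes),
                            dimnames = list(doc$classes, NULL)),
         dispersions = matrix(as_mat(doc$dispersions),
                              nrow = length(doc$classes),
                              dimnames = list(doc$classes, NULL)),
         n_pca = doc$n_pca, n_lda = doc$n_lda, sigma_max = doc$sigma_max,
         bins = doc$bins, n_train = doc$n_train,
         class_sizes = unlist(doc$class_sizes)),
    class = "reims_pcalda"
  )
}
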