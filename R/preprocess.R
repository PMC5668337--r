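# Preprocessing: raw scan streams -> binned, floored, TIC-normalised
# lipid fingerprints over the modelled m/z 600-950 window.

#' Preprocessing configuration
#'
#' Defaults encode the modelling choices used throughout: fingerprints over
#' m/z 600-950 at 0.5 Da (701 bins), a spectral intensity floor of 2e6
#' counts applied per bin, lockmass recalibration against leucine
#' enkephalin (m/z 554.2615, +/- 0.5 Da search window) and a burn gate of
#' 1e8 TIC counts separating cuts from background.
#'
#' @param model_mz_min,model_mz_max Modelled mass window (Da).
#' @param bin_width Bin width (Da).
#' @param intensity_floor Per-bin raw intensity floor (counts).
#' @param lockmass_mz Reference mass (Da).
#' @param lockmass_window Half-width (Da) of the lockmass search window.
#' @param burn_gate_tic Per-scan TIC above which a scan belongs to a burn.
#' @return An object of class `reims_ppcfg`.
#' @export
preprocess_config <- function(model_mz_min = 600, model_mz_max = 950,
                              bin_width = 0.5, intensity_floor = 2e6,
                              lockmass_mz = 554.2615, lockmass_window = 0.5,
                              burn_gate_tic = 1e8) {
  stopifnot(model_mz_min < model_mz_max, bin_width > 0, intensity_floor >= 0,
            lockmass_window > 0, burn_gate_tic > 0)
  structure(
    list(model_mz_min = model_mz_min, model_mz_max = model_mz_max,
         bin_width = bin_width, intensity_floor = intensity_floor,
         lockmass_mz = lockmass_mz, lockmass_window = lockmass_window,
         burn_gate_tic = burn_gate_tic),
    class = "reims_ppcfg"
  )
}

#' Bin centres of the fingerprint grid
#'
#' Centres are inclusive of both window endpoints: `600.0, 600.5, ..., 950.0`
#' gives 701 bins under the default configuration. A point with mass `m`
#' belongs to the bin whose centre `c` satisfies `c - w/2 <= m < c + w/2`
#' (half-open, so edge points are assigned deterministically).
#'
#' @param cfg A [preprocess_config()].
#' @return Numeric vector of bin centres (Da).
#' @export
bin_centers <- function(cfg = preprocess_config()) {
  seq(cfg$model_mz_min, cfg$model_mz_max, by = cfg$bin_width)
}

#' Construct a spectrum object
#'
#' A `reims_spectrum` is a paired (m/z, intensity) continuum or point list,
#' the unit that averaging, lockmass correction and binning operate on.
#'
#' @param mz,intensity Equal-length numeric vectors; intensities >= 0.
#' @param provenance Free-text origin tag (run id, segment, ...).
#' @return An object of class `reims_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, provenance = "") {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(mz = mz, intensity = intensity, provenance = provenance),
            class = "reims_spectrum")
}

#' @export
print.reims_spectrum <- function(x, ...) {
  cat(sprintf("<reims_spectrum> %d points, m/z %g-%g, TIC %.4g [%s]\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity),
              x$provenance))
  invisible(x)
}

#' Per-scan total ion count of a run
#' @param run A `reims_run`.
#' @return Numeric vector, one TIC per scan.
#' @export
scan_tic <- function(run) {
  rowSums(run$scans)
}

#' Segment a run into burns by the TIC gate
#'
#' Returns the maximal consecutive scan intervals whose per-scan TIC
#' strictly exceeds `cfg$burn_gate_tic` (1e8 by default), ordered by time.
#' This is the rule that lets the recognition software classify only cuts,
#' never background.
#'
#' @param run A `reims_run`.
#' @param cfg A [preprocess_config()].
#' @return Data frame with columns `start` (first scan index, 1-based),
#'   `end` (one past the last scan), `n_scans` and `duration` (seconds).
#'   Zero rows if no scan passes the gate.
#' @export
detect_burns <- function(run, cfg = preprocess_config()) {
  stopifnot(inherits(run, "reims_run"))
  if (nrow(run$scans) < 1L) stop("run has no scans", call. = FALSE)
  hot <- scan_tic(run) > cfg$burn_gate_tic
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  period <- if (length(run$clock) > 1L) run$clock[2] - run$clock[1] else
    run$meta$scan_period
  data.frame(start = starts[keep], end = ends[keep] + 1L,
             n_scans = r$lengths[keep],
             duration = r$lengths[keep] * period)
}

#' Average scans into one spectrum
#'
#' Pointwise arithmetic mean of scan intensities on a shared m/z grid —
#' the "one average spectrum per sample" reduction.
#'
#' @param scans Either a numeric matrix (rows = scans) with the grid in
#'   attribute `"mz"` or passed via `mz`, or a list of `reims_spectrum`
#'   objects on identical grids.
#' @param mz Grid override for the matrix form.
#' @param provenance Provenance tag for the result.
#' @return A `reims_spectrum`.
#' @export
average_scans <- function(scans, mz = NULL, provenance = "average") {
  if (is.list(scans) && !is.data.frame(scans) && !is.matrix(scans)) {
    if (length(scans) == 0L) stop("no scans to average", call. = FALSE)
    stopifnot(all(vapply(scans, inherits, TRUE, "reims_spectrum")))
    g <- scans[[1]]$mz
    for (s in scans[-1]) {
      if (!identical(s$mz, g)) stop("mismatched m/z grids", call. = FALSE)
    }
    m <- do.call(rbind, lapply(scans, `[[`, "intensity"))
    return(new_spectrum(g, colMeans(m), provenance))
  }
  if (!is.matrix(scans) || nrow(scans) < 1L) {
    stop("'scans' must be a non-empty matrix or list of spectra", call. = FALSE)
  }
  g <- if (is.null(mz)) attr(scans, "mz") else mz
  if (is.null(g) || length(g) != ncol(scans)) {
    stop("m/z grid missing or mismatched with scan columns", call. = FALSE)
  }
  new_spectrum(g, colMeans(scans), provenance)
}

#' Lockmass recalibration against the infused reference
#'
#' Locates the intensity-weighted centroid `c` of all points within
#' `lockmass_mz +/- lockmass_window` and multiplies the whole m/z axis by
#' `lockmass_mz / c`. Single-point multiplicative recalibration: with one
#' infused reference no higher-order correction is identifiable.
#'
#' @param spec A `reims_spectrum`.
#' @param cfg A [preprocess_config()].
#' @return List with `spectrum` (corrected) and `factor` (the applied
#'   scale; 1 means the axis was already calibrated).
#' @export
lockmass_correct <- function(spec, cfg = preprocess_config()) {
  stopifnot(inherits(spec, "reims_spectrum"))
  idx <- which(abs(spec$mz - cfg$lockmass_mz) <= cfg$lockmass_window)
  total <- sum(spec$intensity[idx])
  if (length(idx) == 0L || total <= 0) {
    stop("no lockmass signal within ", cfg$lockmass_mz, " +/- ",
         cfg$lockmass_window, " Da; spectrum cannot be recalibrated",
         call. = FALSE)
  }
  centroid <- sum(spec$mz[idx] * spec$intensity[idx]) / total
  factor <- cfg$lockmass_mz / centroid
  out <- new_spectrum(spec$mz * factor, spec$intensity, spec$provenance)
  list(spectrum = out, factor = factor)
}

#' Bin a spectrum onto the fingerprint grid and apply the intensity floor
#'
#' Each bin sums the continuum intensity of points with m/z in
#' `[centre - w/2, centre + w/2)`; bins whose summed raw intensity falls
#' below `intensity_floor` (2e6 counts by default) are zeroed. The result
#' is *not* yet normalised.
#'
#' @param spec A `reims_spectrum` (lockmass-corrected).
#' @param cfg A [preprocess_config()].
#' @return Named numeric feature vector (names = bin centres) with
#'   attribute `"mz"` holding the centres.
#' @export
bin_spectrum <- function(spec, cfg = preprocess_config()) {
  stopifnot(inherits(spec, "reims_spectrum"))
  centers <- bin_centers(cfg)
  w <- cfg$bin_width
  idx <- floor((spec$mz - (cfg$model_mz_min - w / 2)) / w) + 1
  ok <- idx >= 1 & idx <= length(centers)
  v <- numeric(length(centers))
  if (any(ok)) {
    agg <- rowsum(spec$intensity[ok], group = idx[ok])
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  v[v < cfg$intensity_floor] <- 0
  names(v) <- sprintf("%.1f", centers)
  attr(v, "mz") <- centers
  v
}

#' Normalise a feature vector to total ion count
#'
#' Divides each entry by the vector sum so entries sum to one. An all-zero
#' vector (no bin survived the floor) is an error: the sample yields no
#' usable signal.
#'
#' @param v Numeric feature vector from [bin_spectrum()].
#' @return The normalised vector (attributes preserved).
#' @export
tic_normalize <- function(v) {
  s <- sum(v)
  if (!is.finite(s) || s <= 0) {
    stop("cannot TIC-normalise: no usable signal (all bins zero)",
         call. = FALSE)
  }
  out <- v / s
  attributes(out) <- attributes(v)
  out
}

# average -> lockmass -> bin -> floor -> normalise, for a block of scan rows.
# Lockmass failure degrades to an uncorrected fingerprint with a warning.
.scans_to_feature <- function(scan_rows, mz, cfg, provenance) {
  avg <- average_scans(scan_rows, mz = mz, provenance = provenance)
  corrected <- TRUE
  factor <- NA_real_
  lm <- tryCatch(lockmass_correct(avg, cfg), error = function(e) NULL)
  if (is.null(lm)) {
    warning(sprintf("lockmass correction failed for %s; proceeding uncorrected",
                    provenance), call. = FALSE)
    corrected <- FALSE
  } else {
    avg <- lm$spectrum
    factor <- lm$factor
  }
  v <- tic_normalize(bin_spectrum(avg, cfg))
  attr(v, "lockmass_factor") <- factor
  attr(v, "lockmass_corrected") <- corrected
  v
}

#' Reduce a run to fingerprint vector(s)
#'
#' The full preprocessing chain in fixed order: gate burns (1e8 TIC),
#' average the gated scans, lockmass-correct, bin to 0.5 Da over m/z
#' 600-950, apply the 2e6 floor, TIC-normalise. `per_sample` pools the
#' scans of *all* burns into one average spectrum (baseline scans are
#' excluded by the gate); `per_burn` runs the chain once per burn segment.
#'
#' @param run A `reims_run`.
#' @param cfg A [preprocess_config()].
#' @param mode `"per_sample"` or `"per_burn"`.
#' @return `per_sample`: one named feature vector. `per_burn`: a matrix
#'   with one row per burn.
#' @export
run_to_features <- function(run, cfg = preprocess_config(),
                            mode = c("per_sample", "per_burn")) {
  mode <- match.arg(mode)
  burns <- detect_burns(run, cfg)
  if (nrow(burns) == 0L) {
    stop("no burns detected in run ", run$meta$run_id,
         " (no scan TIC exceeds the gate)", call. = FALSE)
  }
  if (mode == "per_sample") {
    rows <- unlist(lapply(seq_len(nrow(burns)), function(b) {
      seq.int(burns$start[b], burns$end[b] - 1L)
    }))
    return(.scans_to_feature(run$scans[rows, , drop = FALSE], run$mz, cfg,
                             paste0(run$meta$run_id, "/whole-run")))
  }
  vs <- lapply(seq_len(nrow(burns)), function(b) {
    rows <- seq.int(burns$start[b], burns$end[b] - 1L)
    .scans_to_feature(run$scans[rows, , drop = FALSE], run$mz, cfg,
                      sprintf("%s/burn%02d", run$meta$run_id, b))
  })
  out <- do.call(rbind, vs)
  rownames(out) <- sprintf("burn%02d", seq_len(nrow(burns)))
  attr(out, "mz") <- bin_centers(cfg)
  attr(out, "lockmass_corrected") <-
    vapply(vs, function(v) attr(v, "lockmass_corrected"), TRUE)
  out
}

#' Preprocess a list of runs into a labelled feature matrix
#'
#' @param runs List of `reims_run` objects.
#' @param cfg A [preprocess_config()].
#' @return List with `x` (matrix, one row per run) and `labels`.
#' @export
features_from_runs <- function(runs, cfg = preprocess_config()) {
  vs <- lapply(runs, run_to_features, cfg = cfg, mode = "per_sample")
  x <- do.call(rbind, vs)
  rownames(x) <- vapply(runs, function(r) r$meta$run_id, "")
  list(x = x, labels = vapply(runs, function(r) r$meta$label, ""))
}

#' Write / read a feature matrix as CSV
#'
#' Rows are samples; the first column is the sample id, the second the
#' class label, and the remaining columns are headed by their bin centre.
#' Values are written with 17 significant digits so the round trip is
#' bit-exact.
#'
#' @param x Feature matrix (rows = samples, columns = bins).
#' @param labels Character vector of class labels.
#' @param path Output file.
#' @param ids Sample identifiers (default: rownames of `x`).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, labels, path, ids = rownames(x)) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_len(nrow(x)))
  header <- paste(c("id", "label", colnames(x)), collapse = ",")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(ids[i], labels[i], sprintf("%.17g", x[i, ])), collapse = ",")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return `read_feature_matrix()`: list with `x`, `labels`, `ids`.
#' @export
read_feature_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  tab$id <- as.character(tab$id)
  tab$label <- as.character(tab$label)
  x <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(x) <- tab$id
  attr(x, "mz") <- as.numeric(colnames(x))
  list(x = x, labels = tab$label, ids = tab$id)
}
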