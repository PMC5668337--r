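# Synthetic REIMS scan-stream generation.
#
# A "run" is the acquisition for one physical sample: alternating blocks of
# low-TIC baseline scans (lockmass + chemical noise) and high-TIC burn scans
# (lipid ion peaks + lockmass + noise). Scans are continuum vectors on a
# fixed m/z grid; peaks are Gaussians whose grid sum equals the ion's total
# intensity, so downstream binning conserves intensity exactly.

# Add Gaussian peaks (total intensity per peak = `intensity`) to `v` in place.
.deposit_peaks <- function(v, grid, mz, intensity, sigma, step) {
  half <- ceiling(6 * sigma / step)
  n <- length(grid)
  g0 <- grid[1]
  for (i in seq_along(mz)) {
    centre <- round((mz[i] - g0) / step) + 1
    lo <- max(1L, centre - half)
    hi <- min(n, centre + half)
    if (lo > hi) next
    x <- grid[lo:hi]
    g <- exp(-((x - mz[i])^2) / (2 * sigma^2))
    v[lo:hi] <- v[lo:hi] + intensity[i] * g / sum(g)
  }
  v
}

# One scan's worth of sparse additive chemical noise (counts).
.noise_scan <- function(v, acq) {
  if (acq$noise_tic <= 0) return(v)
  idx <- sample.int(length(v), acq$noise_points)
  v[idx] <- v[idx] + stats::rexp(acq$noise_points,
                                 rate = acq$noise_points / acq$noise_tic)
  v
}

#' Simulate the scans of a single electrosurgical burn
#'
#' Builds `n_scans` continuum scans: the profile's ions (mass axis scaled by
#' the run's drift factor) with a lognormal per-burn intensity jitter, plus
#' the lockmass peak, plus low-level chemical noise per scan. Ion weights
#' are rescaled so the expected per-scan TIC equals `burn_tic_scale`.
#'
#' @param profile A [species_profile()].
#' @param acq An [acquisition_config()].
#' @param n_scans Number of scans (>= 1).
#' @param drift Multiplicative mass-axis scale factor for this run
#'   (1 = no drift).
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return Numeric matrix (`n_scans` rows, one column per grid point) with
#'   attribute `"mz"` holding the grid.
#' @export
simulate_burn <- function(profile, acq, n_scans, drift = 1, seed = NULL) {
  stopifnot(inherits(profile, "reims_profile"), inherits(acq, "reims_acq"))
  if (!is.numeric(n_scans) || length(n_scans) != 1L || n_scans < 1) {
    stop("'n_scans' must be >= 1", call. = FALSE)
  }
  n_scans <- as.integer(n_scans)
  with_seed(seed, {
    grid <- mz_grid(acq)
    ions <- rbind(profile$base_ions, profile$marker_ions)
    w <- ions$intensity
    if (profile$intensity_cv > 0) {
      sdlog <- sqrt(log(1 + profile$intensity_cv^2))
      w <- w * stats::rlnorm(length(w), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    ion_budget <- acq$burn_tic_scale - acq$lockmass_intensity - acq$noise_tic
    w <- w * ion_budget / sum(ions$intensity)
    template <- numeric(length(grid))
    template <- .deposit_peaks(template, grid, ions$mz * drift, w,
                               acq$peak_width_sigma, acq$grid_step)
    template <- .deposit_peaks(template, grid, acq$lockmass_mz * drift,
                               acq$lockmass_intensity,
                               acq$peak_width_sigma, acq$grid_step)
    scans <- matrix(template, nrow = n_scans, ncol = length(grid), byrow = TRUE)
    if (acq$noise_tic > 0) {
      for (s in seq_len(n_scans)) scans[s, ] <- .noise_scan(scans[s, ], acq)
    }
    attr(scans, "mz") <- grid
    scans
  })
}

# Baseline (inter-burn) scans: lockmass plus noise, TIC ~ baseline_tic.
.simulate_baseline <- function(acq, n_scans, drift = 1) {
  grid <- mz_grid(acq)
  template <- .deposit_peaks(numeric(length(grid)), grid,
                             acq$lockmass_mz * drift, acq$lockmass_intensity,
                             acq$peak_width_sigma, acq$grid_step)
  noise_budget <- max(acq$baseline_tic - acq$lockmass_intensity, 0)
  scans <- matrix(template, nrow = n_scans, ncol = length(grid), byrow = TRUE)
  if (noise_budget > 0) {
    acq_b <- acq
    acq_b$noise_tic <- noise_budget
    for (s in seq_len(n_scans)) scans[s, ] <- .noise_scan(scans[s, ], acq_b)
  }
  scans
}

#' Simulate a full labelled run for one sample
#'
#' A run alternates inter-burn baseline blocks with `k` burns, `k` drawn
#' uniformly from `cuts_per_sample`. Ground-truth burn boundaries are stored
#' in the run metadata so segmentation can be checked against them.
#'
#' @inheritParams simulate_burn
#' @param cuts_per_sample,scans_per_cut Integer intervals `c(lo, hi)`.
#' @param run_id Identifier stored in the metadata.
#' @return An object of class `reims_run`: list with elements `mz` (grid),
#'   `scans` (matrix, rows in acquisition order), `clock` (seconds since
#'   stream start) and `meta` (run id, label, drift, burn boundary table).
#' @export
simulate_run <- function(profile, acq = acquisition_config(),
                         cuts_per_sample = c(8L, 12L),
                         scans_per_cut = c(6L, 10L),
                         run_id = profile$name, seed = NULL) {
  stopifnot(inherits(profile, "reims_profile"), inherits(acq, "reims_acq"))
  with_seed(seed, {
    drift <- 1 + stats::rnorm(1, 0, profile$drift_ppm_sd) * 1e-6
    k <- sample_range(cuts_per_sample[1], cuts_per_sample[2])
    blocks <- vector("list", 2L * k + 1L)
    burn_start <- integer(k)
    burn_end <- integer(k)
    pos <- 0L
    for (b in seq_len(k)) {
      n_base <- sample(2:4, 1L)
      blocks[[2L * b - 1L]] <- .simulate_baseline(acq, n_base, drift)
      pos <- pos + n_base
      n_burn <- sample_range(scans_per_cut[1], scans_per_cut[2])
      blocks[[2L * b]] <- simulate_burn(profile, acq, n_burn, drift = drift)
      burn_start[b] <- pos + 1L
      pos <- pos + n_burn
      burn_end[b] <- pos + 1L  # half-open end
    }
    blocks[[2L * k + 1L]] <- .simulate_baseline(acq, sample(2:4, 1L), drift)
    scans <- do.call(rbind, blocks)
    structure(
      list(mz = mz_grid(acq),
           scans = scans,
           clock = (seq_len(nrow(scans)) - 1L) * acq$scan_period,
           meta = list(run_id = run_id, label = profile$name, drift = drift,
                       scan_period = acq$scan_period,
                       burns = data.frame(start = burn_start, end = burn_end))),
      class = "reims_run"
    )
  })
}

#' @export
print.reims_run <- function(x, ...) {
  cat(sprintf("<reims_run> %s (label %s): %d scans, %d burns, m/z %g-%g, drift %.2f ppm\n",
              x$meta$run_id, x$meta$label, nrow(x$scans), nrow(x$meta$burns),
              min(x$mz), max(x$mz), (x$meta$drift - 1) * 1e6))
  invisible(x)
}

# Iterate over the samples of a design in a fixed RNG order, calling
# `fn(profile, run_id, index)` for each; labels are shuffled at the end.
.design_walk <- function(design, acq, fn) {
  out <- with_seed(design$seed, {
    res <- list()
    idx <- 0L
    for (cls in names(design$profiles)) {
      for (j in seq_len(design$n_samples[[cls]])) {
        idx <- idx + 1L
        run_id <- sprintf("%s_%03d", cls, j)
        res[[idx]] <- fn(design$profiles[[cls]], run_id, idx)
      }
    }
    ord <- sample.int(idx)
    list(res = res[ord], ord = ord)
  })
  out
}

#' Simulate a labelled dataset of raw runs
#'
#' Generates one run per sample in the design and returns the runs in
#' randomized order together with a label manifest. Fully determined by
#' `design$seed`. Raw runs are memory-hungry (continuum scans); for large
#' designs prefer [simulate_features()], which streams each run through
#' preprocessing and keeps only its fingerprint.
#'
#' @param design A [dataset_design()].
#' @param acq An [acquisition_config()].
#' @return List with elements `runs` (list of `reims_run`) and `manifest`
#'   (data frame `run_id`, `label`).
#' @export
simulate_dataset <- function(design, acq = acquisition_config()) {
  out <- .design_walk(design, acq, function(profile, run_id, idx) {
    simulate_run(profile, acq,
                 cuts_per_sample = design$cuts_per_sample,
                 scans_per_cut = design$scans_per_cut,
                 run_id = run_id)
  })
  runs <- out$res
  manifest <- data.frame(
    run_id = vapply(runs, function(r) r$meta$run_id, ""),
    label = vapply(runs, function(r) r$meta$label, "")
  )
  list(runs = runs, manifest = manifest)
}

#' Simulate a dataset and preprocess it straight to fingerprints
#'
#' Streaming equivalent of [simulate_dataset()] followed by
#' [run_to_features()]: each raw run is generated, reduced to its
#' fingerprint vector(s) and discarded, so memory stays flat. With the same
#' design (incl. seed) the generated runs are identical to
#' [simulate_dataset()]'s.
#'
#' @param design A [dataset_design()].
#' @param cfg A [preprocess_config()].
#' @param acq An [acquisition_config()].
#' @param mode `"per_sample"` (one vector per run) or `"per_burn"`.
#' @return List with `x` (feature matrix, rows = samples or burns),
#'   `labels` (character), `manifest` (run id, label, and for `per_burn`
#'   the burn index).
#' @export
simulate_features <- function(design, cfg = preprocess_config(),
                              acq = acquisition_config(),
                              mode = c("per_sample", "per_burn")) {
  mode <- match.arg(mode)
  out <- .design_walk(design, acq, function(profile, run_id, idx) {
    run <- simulate_run(profile, acq,
                        cuts_per_sample = design$cuts_per_sample,
                        scans_per_cut = design$scans_per_cut,
                        run_id = run_id)
    v <- run_to_features(run, cfg, mode = mode)
    if (mode == "per_sample") v <- matrix(v, nrow = 1L,
                                          dimnames = list(NULL, names(v)))
    list(x = v, run_id = run_id, label = profile$name)
  })
  res <- out$res
  x <- do.call(rbind, lapply(res, `[[`, "x"))
  nb <- vapply(res, function(r) nrow(r$x), 0L)
  manifest <- data.frame(
    run_id = rep(vapply(res, `[[`, "", "run_id"), nb),
    label = rep(vapply(res, `[[`, "", "label"), nb)
  )
  if (mode == "per_burn") {
    manifest$burn <- unlist(lapply(nb, seq_len), use.names = FALSE)
  }
  rownames(x) <- manifest$run_id
  list(x = x, labels = manifest$label, manifest = manifest)
}

#' Fast fingerprint-level synthetic data
#'
#' Emulates the *distribution of preprocessed fingerprints* without
#' synthesising continuum scans: per sample, ion intensities are jittered
#' lognormally (variance reduced by burn averaging at the sample level),
#' sparse sub-threshold chemical noise is added, and the point spectrum is
#' pushed through the same binning / intensity-floor / TIC-normalisation
#' chain as real runs. Orders of magnitude faster than the raw-stream path;
#' used for statistically heavy experiments (cross-validation sweeps,
#' permutation tests).
#'
#' @param design A [dataset_design()].
#' @param cfg A [preprocess_config()].
#' @param acq An [acquisition_config()] (supplies intensity scales).
#' @param level `"sample"` emulates per-sample averaged fingerprints
#'   (burn-to-burn jitter averaged over ~10 cuts); `"burn"` emulates single
#'   burn fingerprints (full jitter).
#' @return List with `x` (matrix, rows = samples), `labels`, `manifest`.
#' @export
simulate_fingerprints <- function(design, cfg = preprocess_config(),
                                  acq = acquisition_config(),
                                  level = c("sample", "burn")) {
  level <- match.arg(level)
  k_avg <- mean(seq.int(design$cuts_per_sample[1], design$cuts_per_sample[2]))
  out <- .design_walk(design, acq, function(profile, run_id, idx) {
    ions <- rbind(profile$base_ions, profile$marker_ions)
    cv <- profile$intensity_cv
    if (level == "sample") cv <- cv / sqrt(k_avg)
    w <- ions$intensity
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      w <- w * stats::rlnorm(length(w), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    ion_budget <- acq$burn_tic_scale - acq$lockmass_intensity - acq$noise_tic
    w <- w * ion_budget / sum(ions$intensity)
    n_noise <- 25L
    mz <- c(ions$mz,
            stats::runif(n_noise, cfg$model_mz_min, cfg$model_mz_max))
    intensity <- c(w, stats::rexp(n_noise, rate = n_noise / acq$noise_tic))
    spec <- new_spectrum(mz, intensity, provenance = run_id)
    v <- tic_normalize(bin_spectrum(spec, cfg))
    list(v = v, run_id = run_id, label = profile$name)
  })
  res <- out$res
  x <- do.call(rbind, lapply(res, `[[`, "v"))
  manifest <- data.frame(run_id = vapply(res, `[[`, "", "run_id"),
                         label = vapply(res, `[[`, "", "label"))
  rownames(x) <- manifest$run_id
  list(x = x, labels = manifest$label, manifest = manifest)
}

#' Serialize a run to a plain-text directory
#'
#' Writes `metadata.txt` (key-value lines incl. ground-truth burn table)
#' and `scans.csv` (scan index, clock seconds, then one column per grid
#' point; the header row carries the m/z grid). [read_run_dir()] restores
#' the run; the round trip preserves values to full double precision.
#'
#' @param run A `reims_run`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_run_dir <- function(run, path) {
  stopifnot(inherits(run, "reims_run"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- c(
    sprintf("run_id\t%s", run$meta$run_id),
    sprintf("label\t%s", run$meta$label),
    sprintf("drift\t%.17g", run$meta$drift),
    sprintf("scan_period\t%.17g", run$meta$scan_period),
    sprintf("burn\t%d\t%d", run$meta$burns$start, run$meta$burns$end)
  )
  writeLines(meta, file.path(path, "metadata.txt"))
  con <- file(file.path(path, "scans.csv"), "w")
  on.exit(close(con))
  writeLines(paste(c("scan", "clock", sprintf("%.17g", run$mz)), collapse = ","), con)
  for (s in seq_len(nrow(run$scans))) {
    writeLines(paste(c(sprintf("%d", s), sprintf("%.17g", run$clock[s]),
                       sprintf("%.17g", run$scans[s, ])), collapse = ","), con)
  }
  invisible(path)
}

#' Read a run written by [write_run_dir()]
#' @param path Directory containing `metadata.txt` and `scans.csv`.
#' @return A `reims_run`.
#' @export
read_run_dir <- function(path) {
  meta_lines <- readLines(file.path(path, "metadata.txt"))
  kv <- strsplit(meta_lines, "\t", fixed = TRUE)
  get1 <- function(key) {
    hit <- kv[vapply(kv, function(x) x[1] == key, TRUE)]
    if (!length(hit)) stop("missing metadata key: ", key, call. = FALSE)
    hit[[1]][2]
  }
  burns <- do.call(rbind, lapply(kv[vapply(kv, function(x) x[1] == "burn", TRUE)],
                                 function(x) as.integer(x[2:3])))
  tab <- utils::read.csv(file.path(path, "scans.csv"), check.names = FALSE)
  mz <- as.numeric(colnames(tab)[-(1:2)])
  scans <- as.matrix(tab[, -(1:2), drop = FALSE])
  dimnames(scans) <- NULL
  structure(
    list(mz = mz, scans = scans, clock = tab$clock,
         meta = list(run_id = get1("run_id"), label = get1("label"),
                     drift = as.numeric(get1("drift")),
                     scan_period = as.numeric(get1("scan_period")),
                     burns = data.frame(start = burns[, 1], end = burns[, 2]))),
    class = "reims_run"
  )
}
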