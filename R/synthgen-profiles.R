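#' Species ion profile for the synthetic REIMS generator
#'
#' A `reims_profile` describes the lipid ion content that electrosurgical
#' burns of one tissue class deposit into the spectrometer: a set of base
#' ions shared across species (with class-specific intensity weights) plus
#' one or more marker ions enriched in this class. Intensities are relative
#' weights; [simulate_burn()] rescales them so a burn reaches the configured
#' total ion count.
#'
#' @param name Class label, e.g. `"cod"`.
#' @param base_ions Data frame with columns `mz` (Da) and `intensity`
#'   (relative weight > 0); ions shared across species.
#' @param marker_ions Data frame with the same columns; ions enriched in
#'   this class. Marker masses must lie inside the modelled window
#'   (m/z 600-950) so they survive binning.
#' @param intensity_cv Coefficient of variation (unitless, >= 0) of the
#'   lognormal per-burn intensity multiplier applied to every ion.
#' @param drift_ppm_sd Standard deviation (ppm) of the per-run mass-axis
#'   scale error, corrected downstream by the lockmass.
#' @return An object of class `reims_profile`.
#' @seealso [default_species_profiles()], [simulate_burn()]
#' @export
species_profile <- function(name, base_ions, marker_ions = NULL,
                            intensity_cv = 0.25, drift_ppm_sd = 15) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_ions <- function(df, lo, hi, what) {
    if (is.null(df)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
    stopifnot(is.data.frame(df), all(c("mz", "intensity") %in% names(df)))
    if (any(df$mz <= lo | df$mz >= hi)) {
      stop(sprintf("%s m/z must lie in (%g, %g)", what, lo, hi), call. = FALSE)
    }
    if (any(df$intensity <= 0)) {
      stop(sprintf("%s intensities must be > 0", what), call. = FALSE)
    }
    df[c("mz", "intensity")]
  }
  base_ions <- check_ions(base_ions, 200, 1200, "base ion")
  marker_ions <- check_ions(marker_ions, 600, 950, "marker ion")
  if (intensity_cv < 0) stop("'intensity_cv' must be >= 0", call. = FALSE)
  if (drift_ppm_sd < 0) stop("'drift_ppm_sd' must be >= 0", call. = FALSE)
  structure(
    list(name = name, base_ions = base_ions, marker_ions = marker_ions,
         intensity_cv = intensity_cv, drift_ppm_sd = drift_ppm_sd),
    class = "reims_profile"
  )
}

#' @export
print.reims_profile <- function(x, ...) {
  cat(sprintf("<reims_profile> %s: %d base ions, %d marker ions (cv = %.2f, drift sd = %g ppm)\n",
              x$name, nrow(x$base_ions), nrow(x$marker_ions),
              x$intensity_cv, x$drift_ppm_sd))
  if (nrow(x$marker_ions)) {
    cat("  markers at m/z:", paste(format(x$marker_ions$mz), collapse = ", "), "\n")
  }
  invisible(x)
}

# Common phospholipid-like base masses shared by all white-fish profiles.
# Deliberately spread over the modelled m/z 600-950 window, none colliding
# with a species or catch-method marker bin.
.base_ion_mz <- c(
  609.50, 621.48, 633.52, 645.50, 671.47, 683.51, 695.46, 699.50,
  703.52, 716.52, 718.54, 722.51, 724.53, 734.47, 738.51, 742.54,
  744.55, 746.57, 747.52, 750.54, 760.51, 762.53, 766.54, 768.55,
  770.57, 772.58, 774.54, 786.53, 794.55, 806.55
)

#' Built-in species profiles for the five white-fish classes
#'
#' Returns the default set of synthetic ion profiles: the five modelled
#' species (cod, coley, haddock, pollock, whiting), each carrying its
#' reported marker ion(s) at elevated intensity (cod m/z 788.5, coley 817.5,
#' haddock 810.5, pollock 629.5/655.5/667.5, whiting 790.5); two
#' out-of-model profiles (seabass, seabream) whose base-ion weights are
#' perturbed strongly enough that a trained five-class model rejects them as
#' outliers; and two haddock catch-method sub-profiles (trawl, enriched at
#' m/z 764.5; line, enriched at m/z 819.5).
#'
#' All profiles share ~30 common base ions whose class-specific weights are
#' fixed constants (drawn once from a lognormal and frozen), so class
#' separation rests on whole-profile differences, not single ions.
#'
#' @param intensity_cv,drift_ppm_sd Noise parameters passed to every profile.
#' @return Named list of [species_profile()] objects.
#' @export
default_species_profiles <- function(intensity_cv = 0.25, drift_ppm_sd = 15) {
  n <- length(.base_ion_mz)
  base_w <- with_seed(1871L, stats::rlnorm(n, meanlog = 0, sdlog = 0.5))
  mk_mult <- function(seed, sdlog) with_seed(seed, exp(stats::rnorm(n, 0, sdlog)))
  marker_scale <- 3 * stats::median(base_w)

  markers <- list(
    cod     = 788.5,
    coley   = 817.5,
    haddock = 810.5,
    pollock = c(629.5, 655.5, 667.5),
    whiting = 790.5
  )
  mult_seed <- c(cod = 101L, coley = 102L, haddock = 103L,
                 pollock = 104L, whiting = 105L)

  profiles <- lapply(names(markers), function(sp) {
    w <- base_w * mk_mult(mult_seed[[sp]], 0.35)
    species_profile(
      name = sp,
      base_ions = data.frame(mz = .base_ion_mz, intensity = w),
      marker_ions = data.frame(mz = markers[[sp]],
                               intensity = rep(marker_scale, length(markers[[sp]]))),
      intensity_cv = intensity_cv, drift_ppm_sd = drift_ppm_sd
    )
  })
  names(profiles) <- names(markers)

  # Out-of-model species: same base masses, strongly perturbed weights so
  # their whole-profile shape lies far from every trained class.
  for (sp in c("seabass", "seabream")) {
    seed <- if (sp == "seabass") 201L else 202L
    w <- base_w * mk_mult(seed, 1.3)
    profiles[[sp]] <- species_profile(
      name = sp,
      base_ions = data.frame(mz = .base_ion_mz, intensity = w),
      marker_ions = NULL,
      intensity_cv = intensity_cv, drift_ppm_sd = drift_ppm_sd
    )
  }

  # Haddock catch-method contrast: trawl enriched at m/z 764.5, line at 819.5.
  had <- profiles$haddock
  catch_scale <- 2 * stats::median(base_w)
  for (cm in c("trawl", "line")) {
    mz <- if (cm == "trawl") 764.5 else 819.5
    profiles[[paste0("haddock_", cm)]] <- species_profile(
      name = paste0("haddock_", cm),
      base_ions = had$base_ions,
      marker_ions = rbind(had$marker_ions,
                          data.frame(mz = mz, intensity = catch_scale)),
      intensity_cv = intensity_cv, drift_ppm_sd = drift_ppm_sd
    )
  }
  profiles
}

#' Acquisition settings for the synthetic REIMS stream
#'
#' Mirrors the instrument setup being emulated: scans over m/z 200-1200 at
#' 0.5 s per scan, a continuously infused leucine-enkephalin lockmass at
#' m/z 554.2615, low-TIC chemical background between burns, and burns whose
#' total ion count clears the real-time recognition gate of 1e8 counts.
#'
#' @param mz_min,mz_max Acquired mass range (Da).
#' @param grid_step Continuum sampling spacing (Da).
#' @param scan_period Scan time (s).
#' @param lockmass_mz Reference mass (Da).
#' @param lockmass_intensity Lockmass peak total intensity (counts).
#' @param baseline_tic Inter-burn background TIC (counts); must stay below
#'   the 1e8 burn gate.
#' @param burn_tic_scale Peak TIC during a burn (counts); must clear 1e8.
#' @param peak_width_sigma Gaussian peak width (Da) used for continuum
#'   synthesis.
#' @param noise_tic Expected total chemical-noise intensity per scan
#'   (counts); 0 disables additive noise.
#' @param noise_points Number of grid points receiving noise per scan.
#' @return An object of class `reims_acq`.
#' @export
acquisition_config <- function(mz_min = 200, mz_max = 1200, grid_step = 0.02,
                               scan_period = 0.5, lockmass_mz = 554.2615,
                               lockmass_intensity = 1e6, baseline_tic = 2e6,
                               burn_tic_scale = 5e8, peak_width_sigma = 0.05,
                               noise_tic = 5e5, noise_points = 300L) {
  stopifnot(mz_min < lockmass_mz, lockmass_mz < mz_max, grid_step > 0,
            scan_period > 0, peak_width_sigma > 0, lockmass_intensity > 0,
            noise_tic >= 0, noise_points >= 1L)
  if (!(baseline_tic < 1e8 && 1e8 < burn_tic_scale)) {
    stop("need baseline_tic < 1e8 (burn gate) < burn_tic_scale", call. = FALSE)
  }
  structure(
    list(mz_min = mz_min, mz_max = mz_max, grid_step = grid_step,
         scan_period = scan_period, lockmass_mz = lockmass_mz,
         lockmass_intensity = lockmass_intensity, baseline_tic = baseline_tic,
         burn_tic_scale = burn_tic_scale, peak_width_sigma = peak_width_sigma,
         noise_tic = noise_tic, noise_points = as.integer(noise_points)),
    class = "reims_acq"
  )
}

#' Continuum m/z sampling grid of an acquisition configuration
#' @param acq An [acquisition_config()] object.
#' @return Numeric vector of grid m/z values.
#' @export
mz_grid <- function(acq) {
  seq(acq$mz_min, acq$mz_max, by = acq$grid_step)
}

#' Design of a labelled synthetic dataset
#'
#' @param profiles Named list of [species_profile()] objects.
#' @param n_samples Named integer vector (same names) of samples per class.
#' @param cuts_per_sample Integer interval `c(lo, hi)`: burns per sample
#'   (default 8-12 cuts).
#' @param scans_per_cut Integer interval: scans per burn (default 6-10,
#'   i.e. 3-5 s at 0.5 s per scan).
#' @param seed Integer seed; the design fully determines the dataset.
#' @return An object of class `reims_design`.
#' @export
dataset_design <- function(profiles, n_samples, cuts_per_sample = c(8L, 12L),
                           scans_per_cut = c(6L, 10L), seed = 1L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "reims_profile")))
  if (is.null(names(profiles))) names(profiles) <- vapply(profiles, `[[`, "", "name")
  stopifnot(!is.null(names(n_samples)), setequal(names(n_samples), names(profiles)),
            all(n_samples >= 1))
  chk_iv <- function(iv, nm) {
    if (length(iv) != 2L || any(iv < 1) || iv[1] > iv[2]) {
      stop(sprintf("'%s' must be an ordered positive interval c(lo, hi)", nm),
           call. = FALSE)
    }
    as.integer(iv)
  }
  structure(
    list(profiles = profiles,
         n_samples = n_samples[names(profiles)],
         cuts_per_sample = chk_iv(cuts_per_sample, "cuts_per_sample"),
         scans_per_cut = chk_iv(scans_per_cut, "scans_per_cut"),
         seed = as.integer(seed)),
    class = "reims_design"
  )
}
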