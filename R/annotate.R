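# Ion-mass arithmetic for putative lipid annotation of negative-mode REIMS
# bins: deprotonated species, [2M-H]- dimers, neutral losses, and tolerance
# matching of observed masses against a candidate table.

# IUPAC/CODATA monoisotopic atomic masses (Da).
.atomic_mass <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668
)

# Mass of a proton; electron mass is neglected relative to the 0.05 Da
# matching tolerance (all printed masses are two-decimal).
.proton <- 1.007276

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string such as `"C22H32O2"` (element symbols
#'   followed by optional counts). The empty string has mass 0.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("C22H32O2")  # docosahexaenoic acid, 328.2402
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) return(0)
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  total <- 0
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(.atomic_mass)) {
      stop("unknown element '", el, "' in formula ", formula, call. = FALSE)
    }
    total <- total + .atomic_mass[[el]] * cnt
  }
  total
}

#' m/z of the deprotonated ion [M-H]-
#' @param mass Neutral monoisotopic mass (Da), greater than a proton mass.
#' @return `mass - 1.007276`.
#' @export
mz_deprotonated <- function(mass) {
  stop_if_not_scalar_num(mass, "mass")
  out <- mass - .proton
  if (out <= 0) stop("mass must exceed the proton mass", call. = FALSE)
  out
}

#' m/z of the deprotonated dimer [2M-H]-
#' @param mass Neutral monoisotopic mass (Da, > 0).
#' @return `2 * mass - 1.007276`.
#' @export
mz_dimer_deprotonated <- function(mass) {
  stop_if_not_scalar_num(mass, "mass")
  if (mass <= 0) stop("mass must be > 0", call. = FALSE)
  2 * mass - .proton
}

#' Fragment m/z after a neutral loss
#'
#' @param precursor_mz Precursor ion m/z (Da).
#' @param loss Neutral-loss formula (e.g. `"CO2"`) or a numeric mass in Da.
#'   The empty formula loses nothing.
#' @return `precursor_mz - mass(loss)`.
#' @export
neutral_loss <- function(precursor_mz, loss) {
  stop_if_not_scalar_num(precursor_mz, "precursor_mz")
  loss_mass <- if (is.numeric(loss)) loss else formula_mass(loss)
  out <- precursor_mz - loss_mass
  if (out <= 0) {
    stop("neutral loss exceeds the precursor mass", call. = FALSE)
  }
  out
}

#' Built-in candidate lipid table
#'
#' Reads the packaged CSV of putative identifications for the reported
#' species-marker ions: diacyl phosphatidylethanolamine (PE) and
#' phosphatidylserine (PS) candidates with molecular formulas, the
#' docosahexaenoic acid (DHA) dimer behind the pollock ion at m/z 655.5,
#' and `unknown`-class entries (observed mass and MS/MS fragments only)
#' for the ions that resisted identification. Neutral masses are computed
#' from the formulas at load time. The CSV ships in `extdata` and is meant
#' to be user-editable.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Data frame with columns `name`, `species`, `lipid_class`,
#'   `formula`, `adduct`, `observed_mz`, `fragments` (semicolon-separated
#'   m/z), `neutral_mass`.
#' @export
default_lipid_table <- function(path = system.file("extdata",
                                                   "lipid_table.csv",
                                                   package = "reimsid")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$neutral_mass <- vapply(tab$formula, function(f) {
    if (is.na(f) || !nzchar(f)) NA_real_ else formula_mass(f)
  }, numeric(1), USE.NAMES = FALSE)
  tab
}

#' Match an observed m/z against candidate lipids
#'
#' For every record with a molecular formula both adduct hypotheses,
#' [M-H]- and [2M-H]-, are tested within the tolerance; `unknown`-class
#' records are compared against their stored observed mass. Multiple hits
#' are expected — without chromatographic separation isobaric and isomeric
#' lipids cannot be resolved — and are returned sorted by absolute mass
#' error.
#'
#' @param query_mz Observed m/z (Da).
#' @param table Candidate table in the layout of [default_lipid_table()].
#' @param tolerance Matching tolerance in Da (> 0 normally; 0 keeps exact
#'   matches only).
#' @return Data frame of hits: `name`, `species`, `lipid_class`, `adduct`,
#'   `candidate_mz`, `error` (query - candidate); zero rows if nothing
#'   matches.
#' @export
match_bin <- function(query_mz, table = default_lipid_table(),
                      tolerance = 0.05) {
  stop_if_not_scalar_num(query_mz, "query_mz")
  if (tolerance < 0) stop("'tolerance' must be >= 0", call. = FALSE)
  hits <- list()
  for (i in seq_len(nrow(table))) {
    rec <- table[i, ]
    cand <- if (!is.na(rec$neutral_mass)) {
      data.frame(adduct = c("[M-H]-", "[2M-H]-"),
                 candidate_mz = c(mz_deprotonated(rec$neutral_mass),
                                  mz_dimer_deprotonated(rec$neutral_mass)))
    } else if (!is.na(rec$observed_mz)) {
      data.frame(adduct = "observed", candidate_mz = rec$observed_mz)
    } else {
      next
    }
    err <- query_mz - cand$candidate_mz
    ok <- abs(err) <= tolerance
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        name = rec$name, species = rec$species,
        lipid_class = rec$lipid_class, adduct = cand$adduct[ok],
        candidate_mz = cand$candidate_mz[ok], error = err[ok]
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(name = character(0), species = character(0),
                      lipid_class = character(0), adduct = character(0),
                      candidate_mz = numeric(0), error = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(abs(out$error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
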