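# Streaming recognition: consume scans in acquisition order, gate burns at
# the 1e8 TIC limit, classify each burn as it closes, aggregate a verdict.

#' Recognise burns in a scan stream as they complete
#'
#' Walks the scans of a run in acquisition order and performs online burn
#' segmentation: a burn opens with the first scan whose TIC exceeds the
#' gate and closes at the first sub-gate scan (or end of stream). On
#' closure the burn's scans are averaged, lockmass-corrected, binned,
#' floored, TIC-normalised and classified, and an event is emitted. The
#' event classifications are identical to offline
#' `run_to_features(run, cfg, "per_burn")` followed by `predict()` on the
#' same data. If the lockmass cannot be found within a burn the event is
#' flagged `corrected = FALSE` and classification proceeds on uncorrected
#' masses.
#'
#' @param run A `reims_run` (its scans are consumed in time order).
#' @param model A fitted [reims_pcalda()] model.
#' @param cfg A [preprocess_config()].
#' @return An object of class `reims_events`: data frame with one row per
#'   gated burn — `burn`, `start`, `end` (half-open scan interval),
#'   `clock` (seconds at emission, i.e. when the burn closed), `label`,
#'   `distance` (sigma units) and `corrected`.
#' @export
stream_recognize <- function(run, model, cfg = preprocess_config()) {
  stopifnot(inherits(run, "reims_run"), inherits(model, "reims_pcalda"))
  n <- nrow(run$scans)
  events <- list()
  open_start <- NA_integer_
  burn_idx <- 0L
  close_burn <- function(start, end, clock) {
    v <- .scans_to_feature(run$scans[start:(end - 1L), , drop = FALSE], run$mz,
                           cfg, sprintf("%s/burn%02d", run$meta$run_id, burn_idx))
    res <- predict(model, matrix(v, nrow = 1L))
    data.frame(burn = burn_idx, start = start, end = end, clock = clock,
               label = res$label, distance = res$distance,
               corrected = attr(v, "lockmass_corrected"))
  }
  for (s in seq_len(n)) {
    hot <- sum(run$scans[s, ]) > cfg$burn_gate_tic
    if (hot && is.na(open_start)) {
      open_start <- s
    } else if (!hot && !is.na(open_start)) {
      burn_idx <- burn_idx + 1L
      events[[burn_idx]] <- close_burn(open_start, s, run$clock[s])
      open_start <- NA_integer_
    }
  }
  if (!is.na(open_start)) {
    burn_idx <- burn_idx + 1L
    events[[burn_idx]] <- close_burn(open_start, n + 1L, run$clock[n])
  }
  out <- if (burn_idx == 0L) {
    data.frame(burn = integer(0), start = integer(0), end = integer(0),
               clock = numeric(0), label = character(0),
               distance = numeric(0), corrected = logical(0))
  } else {
    do.call(rbind, events)
  }
  class(out) <- c("reims_events", class(out))
  attr(out, "run_id") <- run$meta$run_id
  out
}

#' @export
print.reims_events <- function(x, ...) {
  cat(sprintf("<reims_events> run %s: %d gated burns\n",
              attr(x, "run_id"), nrow(x)))
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}

#' Aggregate burn events into a per-sample verdict
#'
#' Proportions are `100 * class counts / burn count` over the assigned
#' labels (including `"outlier"`); the verdict is the label with the
#' largest proportion, with ties resolved to `"outlier"` since an
#' ambiguous sample should not be certified as any species.
#'
#' @param events A `reims_events` data frame with >= 1 row.
#' @return An object of class `reims_verdict`: `proportions` (named, %),
#'   `verdict`, `n_burns`.
#' @export
aggregate_sample <- function(events) {
  if (nrow(events) < 1L) {
    stop("no recognition events to aggregate", call. = FALSE)
  }
  counts <- sort(table(events$label), decreasing = TRUE)
  prop <- 100 * as.numeric(counts) / nrow(events)
  names(prop) <- names(counts)
  top <- names(counts)[counts == max(counts)]
  verdict <- if (length(top) > 1L) "outlier" else top[1]
  structure(list(proportions = prop, verdict = verdict,
                 n_burns = nrow(events)),
            class = "reims_verdict")
}

#' @export
print.reims_verdict <- function(x, ...) {
  cat(sprintf("<reims_verdict> %s (%d burns)\n", x$verdict, x$n_burns))
  for (i in seq_along(x$proportions)) {
    cat(sprintf("  %-10s %5.1f%%\n", names(x$proportions)[i], x$proportions[i]))
  }
  invisible(x)
}

#' Full recognition of one run: events, burn verdict, average-spectrum call
#'
#' Convenience wrapper combining [stream_recognize()],
#' [aggregate_sample()] and the whole-sample average-spectrum
#' classification. The burn-majority verdict is what an operator sees
#' live; the single average spectrum is what the statistical validation
#' workflow classifies, and resolves samples whose burns split between
#' labels.
#'
#' @inheritParams stream_recognize
#' @return An object of class `reims_recognition` with `events`,
#'   `verdict` and `sample_call` (a one-row classification data frame).
#' @export
recognize_run <- function(run, model, cfg = preprocess_config()) {
  events <- stream_recognize(run, model, cfg)
  if (nrow(events) == 0L) {
    stop("no gated burns in run ", run$meta$run_id, call. = FALSE)
  }
  verdict <- aggregate_sample(events)
  v <- suppressWarnings(run_to_features(run, cfg, mode = "per_sample"))
  sample_call <- predict(model, matrix(v, nrow = 1L))
  sample_call$id <- run$meta$run_id
  structure(list(events = events, verdict = verdict,
                 sample_call = sample_call, run_id = run$meta$run_id),
            class = "reims_recognition")
}

#' @export
print.reims_recognition <- function(x, ...) {
  cat(sprintf("<reims_recognition> run %s\n", x$run_id))
  cat(sprintf("  burn-majority verdict: %s (%d burns)\n",
              x$verdict$verdict, x$verdict$n_burns))
  cat(sprintf("  average-spectrum call: %s (distance %.2f sigma)\n",
              x$sample_call$label, x$sample_call$distance))
  invisible(x)
}
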