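#' ELISA positivity cutoff from nonallergic control sera
#'
#' Cutoff = 3 x the arithmetic mean OD450 of the nonallergic (negative)
#' sera; the multiplier is exposed for sensitivity analyses.
#'
#' @param negative_ods numeric vector of OD450 readings from nonallergic
#'   sera (>= 1 value, all non-negative).
#' @param multiplier cutoff multiplier, default 3.
#' @return the cutoff OD450.
#' @export
elisa_cutoff <- function(negative_ods, multiplier = 3) {
  if (length(negative_ods) == 0) stop("no negative-control ODs supplied")
  if (any(negative_ods < 0)) stop("OD values must be non-negative")
  if (multiplier <= 0) stop("multiplier must be positive")
  multiplier * mean(negative_ods)
}

#' Read an OD plate table
#'
#' TSV with columns `serum_id`, `status` (`allergic`/`nonallergic`),
#' `antigen`, `od` and optionally `replicate`.
#'
#' @param path file path.
#' @return a `data.frame` of class `od_plate`.
#' @export
read_od_plate <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  od_plate(df)
}

#' Validate an OD plate table
#'
#' @param df data.frame with columns `serum_id`, `status`, `antigen`, `od`.
#' @return the validated `data.frame`, classed `od_plate`.
#' @export
od_plate <- function(df) {
  need <- c("serum_id", "status", "antigen", "od")
  if (!all(need %in% names(df))) {
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$status %in% c("allergic", "nonallergic"))) {
    stop("status must be 'allergic' or 'nonallergic'")
  }
  if (any(df$od < 0)) stop("OD values must be non-negative")
  if (!any(df$status == "nonallergic")) {
    stop("at least one nonallergic serum is required for cutoff derivation")
  }
  class(df) <- c("od_plate", "data.frame")
  df
}

#' Call seropositivity against a cutoff
#'
#' Replicate readings of a serum are averaged before comparison; a serum
#' is positive when its mean OD is strictly above the cutoff (ties are
#' negative).
#'
#' @param plate an [od_plate()] (optionally filtered to one antigen).
#' @param cutoff cutoff OD450 (>= 0), e.g. from [elisa_cutoff()].
#' @return data.frame with one row per (serum, antigen): mean `od`, `sd`
#'   across replicates, `status` and logical `positive`.
#' @export
call_positives <- function(plate, cutoff) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  agg <- stats::aggregate(od ~ serum_id + status + antigen, data = plate,
                          FUN = mean)
  sdv <- stats::aggregate(od ~ serum_id + status + antigen, data = plate,
                          FUN = function(x) if (length(x) > 1) stats::sd(x) else NA_real_)
  agg$sd <- sdv$od
  agg$positive <- agg$od > cutoff
  agg[order(agg$antigen, agg$serum_id), ]
}

#' Sensitization rate from positivity calls
#'
#' Percent of tested sera showing IgE reactivity, rounded to one decimal
#' place, reported with its counts.
#'
#' @param calls logical vector of per-serum positivity calls.
#' @param antigen optional antigen id carried into the result.
#' @return object of class `sensitization_result`: list with `antigen`,
#'   `n_tested`, `n_positive`, `rate` (percent, 1 decimal).
#' @export
sensitization_rate <- function(calls, antigen = NA_character_) {
  if (length(calls) == 0) stop("no positivity calls supplied")
  if (anyNA(calls)) stop("positivity calls contain NA")
  calls <- as.logical(calls)
  structure(list(antigen = antigen, n_tested = length(calls),
                 n_positive = sum(calls),
                 rate = round(100 * sum(calls) / length(calls), 1)),
            class = "sensitization_result")
}

#' @export
print.sensitization_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d positive sera, sensitization rate %.1f%%\n",
              if (is.na(x$antigen)) "antigen" else x$antigen,
              x$n_positive, x$n_tested, x$rate))
  invisible(x)
}

#' Percent inhibition of an immunoassay signal
#'
#' `100 x (signal_no_inhibitor - signal_with_inhibitor) /
#' signal_no_inhibitor`, used identically for inhibition ELISA (OD450) and
#' inhibition immunoblot (band intensity). Values can be negative when the
#' inhibitor enhances the signal; they are reported, not clamped.
#'
#' @param signal_no_inhibitor reference signal, strictly positive.
#' @param signal_with_inhibitor signal after pre-incubation with the
#'   inhibitor, non-negative (vectorized).
#' @return percent inhibition (<= 100).
#' @export
percent_inhibition <- function(signal_no_inhibitor, signal_with_inhibitor) {
  if (any(signal_no_inhibitor <= 0)) {
    stop("signal without inhibitor must be strictly positive")
  }
  if (any(signal_with_inhibitor < 0)) {
    stop("signal with inhibitor must be non-negative")
  }
  100 * (signal_no_inhibitor - signal_with_inhibitor) / signal_no_inhibitor
}

#' Construct an inhibition dilution series
#'
#' @param inhibitor inhibitor id.
#' @param concentrations inhibitor concentrations (ug/mL), strictly
#'   increasing.
#' @param signals signal (OD or band intensity) at each concentration.
#' @param signal_no_inhibitor reference signal without inhibitor (> 0).
#' @return object of class `inhibition_series` with a derived
#'   `percent_inhibition` vector.
#' @export
inhibition_series <- function(inhibitor, concentrations, signals,
                              signal_no_inhibitor) {
  if (length(concentrations) != length(signals)) {
    stop("concentrations and signals differ in length")
  }
  if (any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing")
  }
  if (signal_no_inhibitor <= 0) stop("no-inhibitor signal must be positive")
  structure(list(
    inhibitor = inhibitor, concentrations = concentrations,
    signals = signals, signal_no_inhibitor = signal_no_inhibitor,
    percent_inhibition = percent_inhibition(signal_no_inhibitor, signals)
  ), class = "inhibition_series")
}

#' Read an inhibition series table
#'
#' TSV with columns `inhibitor`, `concentration_ug_ml`, `signal`; the row
#' with concentration 0 is the no-inhibitor reference.
#'
#' @param path file path.
#' @return a list of [inhibition_series()] objects, one per inhibitor.
#' @export
read_inhibition_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("inhibitor", "concentration_ug_ml", "signal")
  if (!all(need %in% names(df))) {
    stop("inhibition table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$inhibitor), function(d) {
    d <- d[order(d$concentration_ug_ml), ]
    ref <- d$signal[d$concentration_ug_ml == 0]
    if (length(ref) != 1) {
      stop("inhibitor ", d$inhibitor[1],
           ": need exactly one 0-concentration reference row")
    }
    d2 <- d[d$concentration_ug_ml > 0, ]
    inhibition_series(d$inhibitor[1], d2$concentration_ug_ml, d2$signal, ref)
  })
}

#' Summarize an inhibition dose-response series
#'
#' Reports the maximum percent inhibition, the concentration at which it
#' occurs, and whether the series is dose-dependent: non-decreasing with
#' concentration within a tolerance (2 percentage points by default, so
#' small replicate jitter does not break a monotone pattern).
#'
#' @param series an [inhibition_series()] with >= 3 concentrations.
#' @param tolerance allowed decrease (percentage points) between
#'   consecutive concentrations before dose-dependence is rejected.
#' @return list with `max_inhibition`, `concentration_at_max`,
#'   `dose_dependent`, `any_negative`.
#' @export
inhibition_summary <- function(series, tolerance = 2) {
  pi <- series$percent_inhibition
  if (length(pi) < 3) stop("need at least 3 concentrations")
  imax <- which.max(pi)
  list(max_inhibition = pi[imax],
       concentration_at_max = series$concentrations[imax],
       dose_dependent = all(diff(pi) >= -tolerance),
       any_negative = any(pi < 0))
}
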