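#' KDIGO acute kidney injury detection on a creatinine series
#'
#' Applies the creatinine arms of the KDIGO AKI definition to one stay's
#' creatinine series: AKI is flagged when creatinine rises by at least
#' 0.3 mg/dL within 48 hours, or reaches at least 1.5 times baseline
#' within 7 days, where baseline is the minimum value observed in the
#' 7 days preceding the candidate elevation (rolling-minimum convention).
#' Urine-output criteria are out of scope (no urine data in the pipeline).
#'
#' @param times Observation times, `POSIXct` or numeric hours; must be
#'   sorted (the function sorts defensively, keeping value alignment).
#' @param values Creatinine values in mg/dL, same length as `times`.
#' @return `TRUE` if any KDIGO creatinine criterion fires; `FALSE`
#'   otherwise (including singleton series).
#' @examples
#' detect_aki_kdigo(c(0, 24), c(1.0, 1.4))       # TRUE: +0.4 within 48 h
#' detect_aki_kdigo(c(0, 120), c(1.0, 1.6))      # TRUE: 1.6 >= 1.5 x baseline
#' detect_aki_kdigo(c(0, 24, 48), c(1, 1, 1))    # FALSE
#' @export
detect_aki_kdigo <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(values) < 2L) return(FALSE)
  h <- as_hours(times)
  o <- order(h)
  h <- h[o]; v <- values[o]
  n <- length(v)
  for (j in 2:n) {
    prior <- which(h < h[j])
    # absolute-rise arm: >= 0.3 mg/dL within 48 h
    w48 <- prior[h[j] - h[prior] <= 48]
    if (length(w48) && any(v[j] - v[w48] >= 0.3)) return(TRUE)
    # relative arm: >= 1.5 x baseline, baseline = min over preceding 7 days
    w7 <- prior[h[j] - h[prior] <= 7 * 24]
    if (length(w7) && v[j] >= 1.5 * min(v[w7])) return(TRUE)
  }
  FALSE
}

#' Reverted (transient) AKI detection
#'
#' Flags the recovery pattern that distinguishes transient kidney injury
#' from chronic disease: a creatinine value falling below 66 % of the
#' maximum value observed in the preceding 7 days. A pure ratio rule —
#' invariant to rescaling the whole series.
#'
#' @inheritParams detect_aki_kdigo
#' @return `TRUE` if any observation drops below 0.66 times its 7-day
#'   rolling maximum, else `FALSE`.
#' @examples
#' detect_reverted_aki(c(0, 72), c(3.0, 1.8))   # TRUE: 1.8 < 0.66 * 3.0
#' detect_reverted_aki(c(0, 72), c(3.0, 2.2))   # FALSE
#' @export
detect_reverted_aki <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(values) < 2L) return(FALSE)
  h <- as_hours(times)
  o <- order(h)
  h <- h[o]; v <- values[o]
  n <- length(v)
  for (j in 2:n) {
    w7 <- which(h < h[j] & h[j] - h <= 7 * 24)
    if (length(w7) && v[j] < 0.66 * max(v[w7])) return(TRUE)
  }
  FALSE
}

# Accept POSIXct, Date, or numeric-hour time axes.
as_hours <- function(times) {
  if (inherits(times, "POSIXct")) {
    as.numeric(times) / 3600
  } else if (inherits(times, "Date")) {
    as.numeric(times) * 24
  } else {
    as.numeric(times)
  }
}
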