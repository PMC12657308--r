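#' CKD-EPI 2009 equation parameters
#'
#' Constants of the 2009 CKD-EPI creatinine equation, without the race
#' term (it is never applied in this package, in line with current
#' European laboratory-medicine recommendations).
#'
#' @return A list with elements `constant` (141), `kappa` (named numeric,
#'   mg/dL: female 0.7, male 0.9), `alpha` (named numeric: female -0.329,
#'   male -0.411), `slope_exp` (-1.209), `age_factor` (0.993 per year) and
#'   `female_multiplier` (1.018).
#' @export
egfr_parameters <- function() {
  list(
    constant          = 141,
    kappa             = c(female = 0.7, male = 0.9),
    alpha             = c(female = -0.329, male = -0.411),
    slope_exp         = -1.209,
    age_factor        = 0.993,
    female_multiplier = 1.018
  )
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop("`sex` must be 'male' or 'female', got: ",
         paste(unique(sex[bad]), collapse = ", "), call. = FALSE)
  }
  sex
}

#' Estimated glomerular filtration rate (CKD-EPI 2009, no race factor)
#'
#' Computes eGFR from serum creatinine, age and sex:
#' \deqn{141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'       \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot
#'       1.018\,[\mathrm{if\ female}]}
#' with \eqn{\kappa} = 0.7 (female) / 0.9 (male) and \eqn{\alpha} = -0.329
#' (female) / -0.411 (male). The race factor is never applied.
#'
#' @param creatinine Serum creatinine in mg/dL (values in µmol/L must be
#'   divided by 88.4 at ingestion). Strictly positive.
#' @param age Age in years at measurement; must be >= 18 (the equation is
#'   an adult equation).
#' @param sex `"male"` or `"female"` (vectorised, recycled against
#'   `creatinine`).
#' @return eGFR in mL/min/1.73 m², full precision (no rounding).
#' @examples
#' compute_egfr(0.9, 40, "male")    # ~106.5
#' compute_egfr(0.7, 40, "female")  # ~108.4
#' @export
compute_egfr <- function(creatinine, age, sex) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    stop("`creatinine` must be finite and > 0 (mg/dL)", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("`age` must be finite and >= 18 years", call. = FALSE)
  }
  sex <- check_sex(sex)
  p <- egfr_parameters()
  kappa <- unname(p$kappa[sex])
  alpha <- unname(p$alpha[sex])
  ratio <- creatinine / kappa
  egfr <- p$constant *
    pmin(ratio, 1)^alpha *
    pmax(ratio, 1)^p$slope_exp *
    p$age_factor^age
  egfr * ifelse(sex == "female", p$female_multiplier, 1)
}

#' Invert the CKD-EPI 2009 equation: creatinine from a target eGFR
#'
#' Closed-form piecewise inversion used by the synthetic-data generator:
#' given a target eGFR, age and sex, returns the unique serum creatinine
#' that the CKD-EPI 2009 equation maps back to that eGFR. The equation is
#' continuous and strictly decreasing in creatinine, so the inverse exists
#' for every positive target; non-positive or non-finite targets are
#' signalled as errors rather than clamped.
#'
#' @param target_egfr Target eGFR in mL/min/1.73 m², > 0.
#' @param age Age in years, >= 18.
#' @param sex `"male"` or `"female"`.
#' @return Serum creatinine in mg/dL such that
#'   `compute_egfr(result, age, sex)` equals `target_egfr` to floating
#'   point accuracy.
#' @examples
#' invert_egfr_to_creatinine(106.46, 40, "male")  # ~0.9 mg/dL
#' @export
invert_egfr_to_creatinine <- function(target_egfr, age, sex) {
  if (any(!is.finite(target_egfr)) || any(target_egfr <= 0)) {
    stop("`target_egfr` must be finite and > 0; the CKD-EPI curve only ",
         "reaches positive eGFR values", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("`age` must be finite and >= 18 years", call. = FALSE)
  }
  sex <- check_sex(sex)
  p <- egfr_parameters()
  kappa <- unname(p$kappa[sex])
  alpha <- unname(p$alpha[sex])
  base <- p$constant * p$age_factor^age *
    ifelse(sex == "female", p$female_multiplier, 1)
  # r is the residual factor min(x,1)^alpha * max(x,1)^slope with x = Scr/kappa:
  # r > 1 on the low-creatinine branch (x < 1), r < 1 on the high branch.
  r <- target_egfr / base
  ifelse(r >= 1,
         kappa * r^(1 / alpha),        # x <= 1 branch, alpha < 0
         kappa * r^(1 / p$slope_exp))  # x >= 1 branch
}
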