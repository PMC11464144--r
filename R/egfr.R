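#' Estimated GFR from serum creatinine (CKD-EPI 2021, race-free)
#'
#' \deqn{142 \times \min(Scr/\kappa, 1)^\alpha \times \max(Scr/\kappa, 1)^{-1.200}
#'   \times 0.9938^{age} \times 1.012[\mathrm{female}]}
#' with \eqn{\kappa = 0.7} (female) / 0.9 (male) and \eqn{\alpha = -0.241}
#' (female) / -0.302 (male).
#'
#' @param scr serum creatinine, mg/dL, strictly positive.
#' @param age age in years.
#' @param sex `"male"` or `"female"` (vectorized).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_creatinine(0.8, 70, "female")  # ~79.2
#' @export
egfr_creatinine <- function(scr, age, sex) {
  if (any(scr <= 0)) stop("serum creatinine must be strictly positive")
  female <- check_sex(sex, length(scr))
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  r <- scr / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^-1.200 * 0.9938^age *
    ifelse(female, 1.012, 1)
}

#' Estimated GFR from serum cystatin C (CKD-EPI 2012 cystatin C)
#'
#' \deqn{133 \times \min(Scys/0.8, 1)^{-0.499} \times \max(Scys/0.8, 1)^{-1.328}
#'   \times 0.996^{age} \times 0.932[\mathrm{female}]}
#'
#' @param scys serum cystatin C, mg/L, strictly positive.
#' @param age age in years.
#' @param sex `"male"` or `"female"` (vectorized).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_cystatin(1.0, 70, "female")  # ~69.6
#' @export
egfr_cystatin <- function(scys, age, sex) {
  if (any(scys <= 0)) stop("serum cystatin C must be strictly positive")
  female <- check_sex(sex, length(scys))
  r <- scys / 0.8
  133 * pmin(r, 1)^-0.499 * pmax(r, 1)^-1.328 * 0.996^age *
    ifelse(female, 0.932, 1)
}

#' Chronic kidney disease flag
#'
#' CKD is defined as eGFR strictly below 60 mL/min/1.73 m^2; exactly 60 is
#' not CKD.
#'
#' @param egfr eGFR in mL/min/1.73 m^2, nonnegative.
#' @return logical vector.
#' @export
ckd_flag <- function(egfr) {
  if (any(egfr < 0)) stop("eGFR must be nonnegative")
  egfr < 60
}

check_sex <- function(sex, n) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  rep_len(sex == "female", n)
}
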