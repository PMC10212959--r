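#' LMS reference vital capacity configuration
#'
#' Per-sex log-linear coefficients of the adult LMS (lambda-mu-sigma)
#' reference for vital capacity, the age-dependent spline contribution
#' (m - s), and the spread/skewness settings used to form the lower limit
#' of normal. Default coefficients:
#' male `exp(-8.8317 + 2.1043 ln h - 0.1382 ln a + (m - s))`,
#' female `exp(-8.0707 + 1.9399 ln h - 0.1678 ln a + (m - s))`,
#' with h height in cm and a age in years.
#'
#' The spline defaults to identically zero because the published lookup
#' tables it would interpolate are external data; supply `spline` as a
#' `function(age)` or a data.frame `(age, m_minus_s)` (linearly
#' interpolated) to use them. `sigma_cv` (coefficient of variation, default
#' 0.12) and `lambda_skew` (default 1) are conservative demonstration
#' values, not published reference constants.
#'
#' @param male,female numeric `c(intercept, ln_height_coef, ln_age_coef)`.
#' @param spline `NULL` (zero), a function of age, or a data.frame with
#'   columns `age` and `m_minus_s`.
#' @param lln_z standard-normal quantile defining the lower limit of
#'   normal (default -1.645, the 5th percentile).
#' @param sigma_cv coefficient of variation S; scalar or
#'   `function(sex, age)`.
#' @param lambda_skew Box-Cox skewness L; scalar or `function(sex, age)`.
#' @param lln_family `"lms"` for `M (1 + L S z)^(1/L)` (reducing to
#'   `M (1 + S z)` at L = 1) or `"lognormal"` for `M exp(S z)`.
#' @return an object of class `coughvc_lms_config`.
#' @export
lms_config <- function(male = c(-8.8317, 2.1043, -0.1382),
                       female = c(-8.0707, 1.9399, -0.1678),
                       spline = NULL,
                       lln_z = -1.645,
                       sigma_cv = 0.12,
                       lambda_skew = 1,
                       lln_family = c("lms", "lognormal")) {
  lln_family <- match.arg(lln_family)
  spline_fn <- if (is.null(spline)) {
    function(age) rep(0, length(age))
  } else if (is.function(spline)) {
    spline
  } else if (is.data.frame(spline)) {
    stopifnot(all(c("age", "m_minus_s") %in% names(spline)))
    local({
      tab <- spline[order(spline$age), ]
      function(age) stats::approx(tab$age, tab$m_minus_s, xout = age,
                                  rule = 2)$y
    })
  } else stop("spline must be NULL, a function, or a data.frame")
  as_fn <- function(v) if (is.function(v)) v else function(sex, age) {
    rep(v, length(age))
  }
  structure(list(coefs = list(male = male, female = female),
                 spline = spline_fn, lln_z = lln_z,
                 sigma_fn = as_fn(sigma_cv),
                 lambda_fn = as_fn(lambda_skew),
                 lln_family = lln_family),
            class = "coughvc_lms_config")
}

check_hw <- function(sex, height, age) {
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  if (any(height <= 100 | height >= 230))
    stop("height must lie in (100, 230) cm")
  if (any(age < 18)) stop("age must be >= 18 years (adult equations)")
  sex
}

#' LMS reference vital capacity
#'
#' Evaluates the sex-specific log-linear LMS median
#' `VC_LMS = exp(intercept + c_h ln(height) + c_a ln(age) + spline(age))`
#' in liters. Strictly increasing in height and decreasing in age under the
#' default coefficients.
#'
#' @param sex `"male"` or `"female"` (vectorised, recycled).
#' @param height height in cm, in (100, 230).
#' @param age age in years, >= 18.
#' @param cfg an [lms_config()].
#' @return reference vital capacity (L).
#' @export
vc_lms <- function(sex, height, age, cfg = lms_config()) {
  stopifnot(inherits(cfg, "coughvc_lms_config"))
  n <- max(length(sex), length(height), length(age))
  sex <- rep_len(sex, n); height <- rep_len(height, n); age <- rep_len(age, n)
  sex <- check_hw(sex, height, age)
  cf <- t(vapply(sex, function(s) cfg$coefs[[s]], numeric(3)))
  unname(exp(cf[, 1] + cf[, 2] * log(height) + cf[, 3] * log(age) +
               cfg$spline(age)))
}

#' Lower limit of normal vital capacity
#'
#' The LMS percentile at `z = lln_z` around the reference median M:
#' `LLN = M (1 + L S z)^(1/L)` (family `"lms"`; the L = 1 case reduces to
#' `M (1 + S z)`), or `M exp(S z)` (family `"lognormal"`). Below-LLN vital
#' capacity conventionally flags possible respiratory dysfunction.
#'
#' @inheritParams vc_lms
#' @return lower limit of normal (L); always < the reference median for
#'   `lln_z < 0` and `S > 0`.
#' @export
lln <- function(sex, height, age, cfg = lms_config()) {
  stopifnot(inherits(cfg, "coughvc_lms_config"))
  m <- vc_lms(sex, height, age, cfg)
  n <- length(m)
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  s <- cfg$sigma_fn(sex, age)
  if (any(s < 0)) stop("sigma_cv must be >= 0")
  if (cfg$lln_family == "lognormal") return(m * exp(s * cfg$lln_z))
  l <- cfg$lambda_fn(sex, age)
  base <- 1 + l * s * cfg$lln_z
  if (any(base <= 0)) stop("invalid LMS percentile: 1 + L*S*z <= 0")
  ifelse(abs(l) < 1e-12, m * exp(s * cfg$lln_z), m * base^(1 / l))
}
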