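#' Cough peak flow model parameters
#'
#' Constants of the exponential flow-sound model
#' `CPS = (a1 + a2 * age) * (exp(beta * SPL) - 1)` mapping a session sound
#' pressure level (dB) and age (years) to a cough peak flow (L/min).
#'
#' The packaged defaults (a1 = 42, a2 = -0.2, beta = 0.025) were chosen so
#' that synthetic cohorts produce realistic cough SPLs (~95--102 dB) and
#' flows (~250--450 L/min); they are NOT calibration constants from any
#' clinical study and should be refit ([fit_cps_params()]) for real data.
#'
#' @param a1 baseline amplitude (L/min).
#' @param a2 age slope ((L/min)/year).
#' @param beta exponential rate (1/dB); must be > 0.
#' @param age_range ages (years) over which `a1 + a2*age` must stay
#'   positive; checked at construction.
#' @return an object of class `coughvc_cps_params`.
#' @export
cps_params <- function(a1 = 42, a2 = -0.2, beta = 0.025,
                       age_range = c(18, 100)) {
  if (beta <= 0) stop("beta must be > 0")
  if (any(a1 + a2 * age_range <= 0))
    stop("a1 + a2*age must be positive over the declared age range")
  structure(list(a1 = a1, a2 = a2, beta = beta, age_range = age_range),
            class = "coughvc_cps_params")
}

age_amplitude <- function(age, params) {
  amp <- params$a1 + params$a2 * age
  if (any(amp <= 0))
    stop("age outside calibrated range: a1 + a2*age <= 0 at age ",
         paste(age[amp <= 0], collapse = ", "))
  amp
}

#' Compute cough peak flow from SPL and age
#'
#' `CPS = (a1 + a2 * age) * (exp(beta * SPL) - 1)`, in L/min; strictly
#' increasing in SPL and exactly 0 at SPL = 0.
#'
#' @param spl session sound pressure level (dB), >= 0. Vectorised.
#' @param age age (years). Vectorised.
#' @param params a [cps_params()].
#' @return cough peak flow (L/min).
#' @export
compute_cps <- function(spl, age, params = cps_params()) {
  stopifnot(inherits(params, "coughvc_cps_params"))
  if (any(spl < 0)) stop("spl must be >= 0")
  age_amplitude(age, params) * (exp(params$beta * spl) - 1)
}

#' Invert the cough peak flow model for SPL
#'
#' Returns the SPL (dB) that the flow-sound model maps to the given cough
#' peak flow at the given age: `spl = ln(cpf/(a1 + a2*age) + 1) / beta`.
#' Used by the synthetic-waveform generator.
#'
#' @param cpf cough peak flow (L/min), >= 0. Vectorised.
#' @param age age (years). Vectorised.
#' @param params a [cps_params()].
#' @return SPL in dB.
#' @export
invert_cps <- function(cpf, age, params = cps_params()) {
  stopifnot(inherits(params, "coughvc_cps_params"))
  amp <- age_amplitude(age, params)
  ratio <- cpf / amp
  if (any(ratio <= -1)) stop("cpf/(a1 + a2*age) <= -1: inverse undefined")
  log1p(ratio) / params$beta
}

#' Fit the flow-sound model constants from calibration triples
#'
#' Ordinary least squares on flow: minimises
#' `sum((cpf - (a1 + a2*age)*(exp(beta*spl) - 1))^2)` with `beta > 0`.
#' Initialisation is deterministic: beta from a log-linear regression of
#' `log(cpf + eps)` on SPL, then (a1, a2) by a linear solve at that beta,
#' so the fit has no seed dependence.
#'
#' @param triples data.frame with columns `age`, `spl`, `cpf` (>= 10 rows
#'   spanning >= 2 distinct ages and >= 3 distinct SPLs).
#' @param init optional [cps_params()] starting point (overrides the
#'   automatic initialisation).
#' @param beta_bounds lower/upper bounds for beta.
#' @return a [cps_params()] with attributes `rmse`, `converged` and
#'   `n_obs`; warns when a single distinct age makes (a1, a2) jointly
#'   unidentifiable.
#' @export
fit_cps_params <- function(triples, init = NULL,
                           beta_bounds = c(1e-6, 1)) {
  stopifnot(is.data.frame(triples),
            all(c("age", "spl", "cpf") %in% names(triples)))
  if (nrow(triples) < 10) stop("need >= 10 calibration triples")
  if (length(unique(triples$spl)) < 3) stop("need >= 3 distinct SPL values")
  single_age <- length(unique(triples$age)) < 2
  if (single_age)
    warning("single distinct age: a1 and a2 are jointly unidentifiable; ",
            "only a1 + a2*age is determined")
  age <- triples$age; spl <- triples$spl; cpf <- triples$cpf

  # profile objective: given beta, (a1, a2) solve a linear LS problem
  design <- function(beta) cbind(exp(beta * spl) - 1,
                                 age * (exp(beta * spl) - 1))
  rss_at <- function(beta) {
    X <- design(beta)
    # single age: only a1 + a2*age is identified; fit that combination
    if (single_age) X <- X[, 1, drop = FALSE]
    fit <- stats::lm.fit(X, cpf)
    sum(fit$residuals^2)
  }
  if (is.null(init)) {
    beta0 <- unname(coef(lm(log(pmax(cpf, 1e-9) + 1e-6) ~ spl))[2])
    beta0 <- min(max(beta0, beta_bounds[1]), beta_bounds[2])
  } else {
    stopifnot(inherits(init, "coughvc_cps_params"))
    beta0 <- init$beta
  }
  opt <- stats::optimize(rss_at, interval = beta_bounds, tol = 1e-12)
  # refine around the deterministic start if optimize found a worse basin
  if (rss_at(beta0) < opt$objective) {
    opt <- stats::optim(beta0, rss_at, method = "Brent",
                        lower = beta_bounds[1], upper = beta_bounds[2])
    beta_hat <- opt$par; rss <- opt$value
  } else {
    beta_hat <- opt$minimum; rss <- opt$objective
  }
  X <- design(beta_hat)
  if (single_age) {
    # report the identified combination through a1 with a2 = 0
    a_comb <- stats::lm.fit(X[, 1, drop = FALSE], cpf)$coefficients[1]
    ab <- c(a_comb, 0)
  } else {
    ab <- stats::lm.fit(X, cpf)$coefficients
  }
  out <- cps_params(a1 = unname(ab[1]), a2 = unname(ab[2]), beta = beta_hat,
                    age_range = range(age))
  attr(out, "rmse") <- sqrt(rss / nrow(triples))
  attr(out, "converged") <- TRUE
  attr(out, "n_obs") <- nrow(triples)
  out
}
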