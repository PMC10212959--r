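# Seeded synthetic cough cohorts and waveforms.
#
# The generator states a simple explicit world: a two-generation cohort
# whose true vital capacity is a log-normal perturbation of the LMS
# reference, a cough peak flow affine in vital capacity (with an optional
# extra vocal-aging decline), and per-trial cough bursts whose peak sound
# pressure encodes that flow through the inverse flow-sound model. It is
# deliberately not a physiological cough model: only the peak pressure,
# the band location of the burst, and the out-of-band contamination matter
# to the pipeline under test.

# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# named substream seed below 2^31, derived deterministically from a master
# seed and a stream label
stream_seed <- function(seed, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.double(seed) * 48271 + h * 1009 + index * 7919) %% 2147483629
}

#' Synthetic cohort parameters
#'
#' Defaults reproduce the study design the package targets: 31 young
#' (21.3 +/- 0.5 y, 164.3 +/- 8.4 cm, 19 male) and 25 elderly
#' (80.4 +/- 6.1 y, 154.1 +/- 8.3 cm, 11 male) adults. Group height means
#' are split by sex around the pooled mean with a `sex_height_offset`
#' (default 10 cm, male taller), preserving the pooled group mean.
#'
#' @param n_young,n_elderly group sizes (>= 1).
#' @param male_fraction_young,male_fraction_elderly male proportions.
#' @param age_mean_young,age_sd_young,age_mean_elderly,age_sd_elderly years.
#' @param height_mean_young,height_sd_young,height_mean_elderly,height_sd_elderly
#'   pooled group height moments (cm).
#' @param sex_height_offset male-minus-female height gap (cm) used to split
#'   the pooled group mean by sex.
#' @param weight_mean_young,weight_sd_young,weight_mean_elderly,weight_sd_elderly
#'   body mass moments (kg); carried for completeness, unused downstream.
#' @param vc_lognoise_sd SD of the log-deviation of true VC from the LMS
#'   reference (dimensionless). Default 0.12 mirrors the default reference
#'   coefficient of variation.
#' @param cpf_slope,cpf_intercept,cpf_noise_sd affine cough-peak-flow model
#'   `CPF = intercept + slope*VC + noise` ((L/min)/L, L/min, L/min).
#' @param vocal_aging_slope extra age effect on cough strength
#'   ((L/min)/year applied to age - 20); default 0.
#' @param cpf_min floor for generated cough peak flow (L/min), > 0.
#' @param lms an [lms_config()] defining the reference and the LLN labels.
#' @param cps a [cps_params()] -- the generator's true flow-sound
#'   constants, inverted to set each participant's target SPL.
#' @param seed master seed; every generator stream derives from it.
#' @return an object of class `coughvc_cohort_params`.
#' @export
cohort_params <- function(n_young = 31, n_elderly = 25,
                          male_fraction_young = 19 / 31,
                          male_fraction_elderly = 11 / 25,
                          age_mean_young = 21.3, age_sd_young = 0.5,
                          age_mean_elderly = 80.4, age_sd_elderly = 6.1,
                          height_mean_young = 164.3, height_sd_young = 8.4,
                          height_mean_elderly = 154.1, height_sd_elderly = 8.3,
                          sex_height_offset = 10,
                          weight_mean_young = 58.0, weight_sd_young = 11.5,
                          weight_mean_elderly = 55.7, weight_sd_elderly = 12.0,
                          vc_lognoise_sd = 0.12,
                          cpf_slope = 80, cpf_intercept = 50,
                          cpf_noise_sd = 30,
                          vocal_aging_slope = 0,
                          cpf_min = 30,
                          lms = lms_config(),
                          cps = cps_params(),
                          seed = 1L) {
  stopifnot(n_young >= 1, n_elderly >= 1,
            age_sd_young >= 0, age_sd_elderly >= 0,
            height_sd_young >= 0, height_sd_elderly >= 0,
            vc_lognoise_sd >= 0, cpf_noise_sd >= 0, cpf_min > 0,
            male_fraction_young >= 0, male_fraction_young <= 1,
            male_fraction_elderly >= 0, male_fraction_elderly <= 1,
            inherits(lms, "coughvc_lms_config"),
            inherits(cps, "coughvc_cps_params"))
  structure(as.list(environment()), class = "coughvc_cohort_params")
}

#' Generate a synthetic two-generation cough cohort
#'
#' Draws demographics from the group- and sex-specific normal
#' distributions (ages clipped at 18 y, heights to 130--200 cm), sets
#' `true_vc = VC_LMS * exp(eps)` with `eps ~ N(0, vc_lognoise_sd)`,
#' `true_cpf = cpf_intercept + cpf_slope*true_vc +
#' vocal_aging_slope*(age - 20) + N(0, cpf_noise_sd)` floored at
#' `cpf_min`, and the per-participant target SPL by inverting the
#' flow-sound model under the generator's true constants. `measured_vc`
#' equals `true_vc` (the spirometric target of estimation).
#'
#' @param params a [cohort_params()].
#' @return data.frame with one row per participant: `participant_id`,
#'   `group`, `sex`, `age`, `height`, `weight`, `measured_vc`, `true_vc`,
#'   `true_cpf`, `target_spl`, `below_lln`. Identical `params` (including
#'   `seed`) give identical tables.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "coughvc_cohort_params"))
  p <- params
  groups <- list(
    young = list(n = p$n_young, mf = p$male_fraction_young,
                 age = c(p$age_mean_young, p$age_sd_young),
                 height = c(p$height_mean_young, p$height_sd_young),
                 weight = c(p$weight_mean_young, p$weight_sd_young)),
    elderly = list(n = p$n_elderly, mf = p$male_fraction_elderly,
                   age = c(p$age_mean_elderly, p$age_sd_elderly),
                   height = c(p$height_mean_elderly, p$height_sd_elderly),
                   weight = c(p$weight_mean_elderly, p$weight_sd_elderly)))
  rows <- list()
  for (g in names(groups)) {
    gr <- groups[[g]]
    n_male <- round(gr$mf * gr$n)
    sex <- rep(c("male", "female"), c(n_male, gr$n - n_male))
    hm <- gr$height[1] + ifelse(sex == "male", (1 - gr$mf), -gr$mf) *
      p$sex_height_offset
    demo <- with_seed(stream_seed(p$seed, paste0("demographics_", g)), {
      age <- pmax(18, rnorm(gr$n, gr$age[1], gr$age[2]))
      height <- pmin(200, pmax(130, rnorm(gr$n, hm, gr$height[2])))
      weight <- pmax(30, rnorm(gr$n, gr$weight[1], gr$weight[2]))
      eps <- rnorm(gr$n, 0, p$vc_lognoise_sd)
      cpf_noise <- rnorm(gr$n, 0, p$cpf_noise_sd)
      list(age = age, height = height, weight = weight, eps = eps,
           cpf_noise = cpf_noise)
    })
    ref <- vc_lms(sex, demo$height, demo$age, p$lms)
    true_vc <- ref * exp(demo$eps)
    true_cpf <- pmax(p$cpf_min,
                     p$cpf_intercept + p$cpf_slope * true_vc +
                       p$vocal_aging_slope * (demo$age - 20) +
                       demo$cpf_noise)
    rows[[g]] <- data.frame(
      participant_id = paste0(substr(g, 1, 1), sprintf("%03d", seq_len(gr$n))),
      group = g, sex = sex, age = demo$age, height = demo$height,
      weight = demo$weight, true_vc = true_vc, true_cpf = true_cpf,
      stringsAsFactors = FALSE)
  }
  out <- rbind(rows$young, rows$elderly)
  out$measured_vc <- out$true_vc
  out$target_spl <- vapply(seq_len(nrow(out)), function(i) {
    tryCatch(invert_cps(out$true_cpf[i], out$age[i], p$cps),
             error = function(e) stop("participant ", out$participant_id[i],
                                      ": ", conditionMessage(e),
                                      call. = FALSE))
  }, numeric(1))
  out$below_lln <- out$true_vc < lln(out$sex, out$height, out$age, p$lms)
  rownames(out) <- NULL
  out[, c("participant_id", "group", "sex", "age", "height", "weight",
          "measured_vc", "true_vc", "true_cpf", "target_spl", "below_lln")]
}

#' Contamination settings for synthetic cough trials
#'
#' Out-of-band artifacts added to each trial: a low-frequency tone
#' (< 140 Hz, emulating heart-sound/motion artifact) and a high-frequency
#' tone (> 2000 Hz, emulating hiss), with amplitudes relative to the cough
#' burst's peak pressure.
#'
#' @param lf_freq,lf_rel_amp low-frequency artifact frequency (Hz) and
#'   relative amplitude (0 disables).
#' @param hf_freq,hf_rel_amp high-frequency artifact frequency (Hz) and
#'   relative amplitude (0 disables).
#' @return an object of class `coughvc_contamination`.
#' @export
contamination_spec <- function(lf_freq = 40, lf_rel_amp = 0,
                               hf_freq = 6000, hf_rel_amp = 0) {
  if (lf_rel_amp > 0 && lf_freq >= 140)
    stop("low-frequency contamination must be below 140 Hz")
  if (hf_rel_amp > 0 && hf_freq <= 2000)
    stop("high-frequency contamination must be above 2000 Hz")
  structure(list(lf_freq = lf_freq, lf_rel_amp = lf_rel_amp,
                 hf_freq = hf_freq, hf_rel_amp = hf_rel_amp),
            class = "coughvc_contamination")
}

#' Synthesize a session of cough trial waveforms
#'
#' Each 20-s trial holds one exponentially decaying tone burst (5 ms rise,
#' 40 ms decay) at an in-band carrier, normalised so its raw peak sound
#' pressure is exactly `P0 * 10^(spl_i/20)` with
#' `spl_i = target_spl - |jitter_i|`; the first trial is forced to zero
#' jitter so the session maximum equals `target_spl` exactly. Pressure is
#' converted to voltage through the microphone model, burst onset is
#' randomised within the trial, and contamination tones are superposed
#' over the whole record.
#'
#' @param truth a single-row data.frame (or list) with `participant_id`
#'   and `target_spl`, e.g. one row of [generate_cohort()].
#' @param mic a [microphone_model()].
#' @param fs sampling rate (Hz), >= 8000.
#' @param n_trials number of trials (>= 3).
#' @param trial_jitter_db SD of the (negative half-normal) per-trial SPL
#'   jitter (dB).
#' @param contamination a [contamination_spec()].
#' @param seed integer seed; identical inputs give identical samples.
#' @param carrier_hz burst carrier frequency (Hz); must lie inside the
#'   140--2000 Hz analysis band (300--1500 enforced, keeping the carrier
#'   clear of the band edges so the SPL round trip holds).
#' @param duration trial length (s).
#' @return list of `n_trials` [waveform()] objects.
#' @export
synthesize_cough_waveform <- function(truth, mic = microphone_model(),
                                      fs = 20000, n_trials = 3,
                                      trial_jitter_db = 1,
                                      contamination = contamination_spec(),
                                      seed = 1L, carrier_hz = 800,
                                      duration = 20) {
  truth <- as.list(truth)
  stopifnot(is.finite(truth$target_spl), fs >= 8000, n_trials >= 3,
            inherits(mic, "coughvc_mic"),
            inherits(contamination, "coughvc_contamination"))
  if (carrier_hz < 300 || carrier_hz > 1500)
    stop("carrier_hz must lie in [300, 1500] Hz (inside the analysis band)")
  jitter <- with_seed(stream_seed(seed, "trial_jitter"), {
    j <- abs(rnorm(n_trials, 0, trial_jitter_db))
    j[1] <- 0
    j
  })
  n <- round(duration * fs)
  t_all <- (seq_len(n) - 1) / fs
  lapply(seq_len(n_trials), function(i) {
    spl_i <- truth$target_spl - jitter[i]
    peak_pa <- mic$reference_pressure * 10^(spl_i / 20)
    onset <- with_seed(stream_seed(seed, "burst_onset", i),
                       runif(1, 2.5, duration - 2.5))
    tp <- t_all - onset
    burst <- numeric(n)
    act <- tp >= 0 & tp < 0.5
    env <- (1 - exp(-tp[act] / 0.005)) * exp(-tp[act] / 0.04)
    burst[act] <- sin(2 * pi * carrier_hz * tp[act]) * env
    burst <- burst / max(abs(burst)) * peak_pa
    if (contamination$lf_rel_amp > 0)
      burst <- burst + contamination$lf_rel_amp * peak_pa *
        sin(2 * pi * contamination$lf_freq * t_all)
    if (contamination$hf_rel_amp > 0)
      burst <- burst + contamination$hf_rel_amp * peak_pa *
        sin(2 * pi * contamination$hf_freq * t_all)
    waveform(burst * mic$voltage_per_pa, fs,
             participant_id = truth$participant_id, trial_index = i)
  })
}
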