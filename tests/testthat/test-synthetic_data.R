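test_that("noiseless cohorts sit exactly on the stated model", {
  p <- cohort_params(n_young = 8, n_elderly = 8, vc_lognoise_sd = 0,
                     cpf_noise_sd = 0, seed = 3)
  co <- generate_cohort(p)
  expect_equal(co$true_vc, vc_lms(co$sex, co$height, co$age, p$lms),
               tolerance = 1e-12)
  expect_equal(co$true_cpf,
               pmax(p$cpf_min, p$cpf_intercept + p$cpf_slope * co$true_vc),
               tolerance = 1e-12)
  # target SPL is the exact inverse of the flow-sound model
  expect_equal(compute_cps(co$target_spl, co$age, p$cps), co$true_cpf,
               tolerance = 1e-9)
})

test_that("default cohort reproduces the stated group moments", {
  co <- generate_cohort(cohort_params(seed = 42))
  expect_equal(nrow(co), 56)
  expect_equal(sum(co$group == "young"), 31)
  expect_equal(sum(co$group == "elderly"), 25)
  expect_equal(sum(co$sex == "male" & co$group == "young"), 19)
  expect_equal(sum(co$sex == "male" & co$group == "elderly"), 11)
  # sample means within 3 standard errors of the stated moments
  expect_lt(abs(mean(co$age[co$group == "young"]) - 21.3),
            3 * 0.5 / sqrt(31))
  expect_lt(abs(mean(co$age[co$group == "elderly"]) - 80.4),
            3 * 6.1 / sqrt(25))
  expect_lt(abs(mean(co$height[co$group == "young"]) - 164.3),
            3 * 8.4 / sqrt(31))
  expect_true(all(co$age >= 18 & co$height >= 130 & co$height <= 200))
  expect_true(all(co$true_vc > 0 & co$true_cpf > 0))
  # label consistency with the generator's LLN config
  p <- cohort_params(seed = 42)
  expect_equal(co$below_lln,
               co$true_vc < lln(co$sex, co$height, co$age, p$lms))
})

test_that("cohort generation is seed-deterministic", {
  a <- generate_cohort(cohort_params(seed = 7))
  b <- generate_cohort(cohort_params(seed = 7))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_params(seed = 8))
  expect_false(identical(a$age, c2$age))
})

test_that("below-LLN fraction is monotone in the log-noise SD", {
  sds <- c(0.05, 0.12, 0.30)
  frac <- vapply(sds, function(s) {
    mean(vapply(1:20, function(seed)
      mean(generate_cohort(cohort_params(n_young = 15, n_elderly = 15,
                                         vc_lognoise_sd = s,
                                         seed = seed))$below_lln),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("noiseless synthesized sessions hit the target SPL", {
  tr <- quick_session(100, fs = 16000)
  expect_length(tr, 3)
  s <- session_spl(tr, microphone_model())
  expect_lt(abs(s$session_spl_db - 100), 0.2)
  expect_lt(max(abs(s$per_trial_max_db - 100)), 0.2)
})

test_that("jittered sessions keep the max at the target", {
  tr <- synthesize_cough_waveform(list(participant_id = "p", target_spl = 97),
                                  fs = 16000, n_trials = 4,
                                  trial_jitter_db = 2, seed = 11)
  s <- session_spl(tr, microphone_model())
  expect_lt(abs(s$session_spl_db - 97), 0.2)
  expect_equal(which.max(s$per_trial_max_db), 1L)  # forced zero jitter
})

test_that("out-of-band contamination barely moves the session SPL", {
  s0 <- session_spl(quick_session(100, fs = 16000), microphone_model())
  s1 <- session_spl(quick_session(100, fs = 16000,
                                  contamination = contamination_spec(
                                    lf_freq = 40, lf_rel_amp = 10)),
                    microphone_model())
  expect_lt(abs(s1$session_spl_db - s0$session_spl_db), 1)
  s2 <- session_spl(quick_session(100, fs = 16000,
                                  contamination = contamination_spec(
                                    hf_freq = 5000, hf_rel_amp = 3)),
                    microphone_model())
  expect_lt(abs(s2$session_spl_db - s0$session_spl_db), 1)
})

test_that("waveform synthesis is deterministic and guards the carrier", {
  a <- quick_session(95, fs = 16000, seed = 5)
  b <- quick_session(95, fs = 16000, seed = 5)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_error(quick_session(95, fs = 16000, carrier_hz = 100), "carrier")
  expect_error(quick_session(95, fs = 16000, carrier_hz = 1900), "carrier")
  expect_error(contamination_spec(lf_freq = 200, lf_rel_amp = 1), "140")
  expect_error(contamination_spec(hf_freq = 500, hf_rel_amp = 1), "2000")
})

test_that("noiseless round trip: pipeline recovers true cough peak flow", {
  p <- cohort_params(n_young = 2, n_elderly = 2, vc_lognoise_sd = 0,
                     cpf_noise_sd = 0, seed = 9)
  co <- generate_cohort(p)
  mic <- microphone_model()
  for (i in seq_len(nrow(co))) {
    tr <- synthesize_cough_waveform(co[i, ], mic = mic, fs = 16000,
                                    trial_jitter_db = 0,
                                    seed = 100 + i)
    spl <- session_spl(tr, mic)$session_spl_db
    cps <- compute_cps(spl, co$age[i], p$cps)
    expect_lt(abs(cps - co$true_cpf[i]) / co$true_cpf[i], 0.005)
  }
})
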