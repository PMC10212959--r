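# Independent oracles shared across tests. These deliberately avoid the
# package's own code paths.

# |H(f)| of one pass of an analog Butterworth band-pass (prototype order
# N = order/2); forward-backward filtering squares this. Bilinear warping
# is negligible at the fs/f ratios used in the tests.
butter_bp_gain <- function(f, low, high, order = 4) {
  N <- order / 2
  wp <- (f^2 - low * high) / (f * (high - low))
  1 / sqrt(1 + wp^(2 * N))
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# all permutations of seq_len(n), built by simple recursion
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    q <- c(p[seq_len(k - 1L)], n, p[seq.int(k, length.out = n - k)])
    out[[length(out) + 1L]] <- q
  }
  out
}

rmse_of <- function(a, b) sqrt(mean((a - b)^2))

# a quiet constant-pressure tone trial for acoustics tests
tone_trial <- function(freq, amp_v, fs, dur = 6, id = "t", trial = 1L) {
  tt <- (0:(dur * fs - 1)) / fs
  waveform(amp_v * sin(2 * pi * freq * tt), fs, id, trial)
}

# small synthetic session: one burst per trial with known target SPL
quick_session <- function(target_spl = 100, fs = 16000, seed = 7, ...) {
  synthesize_cough_waveform(list(participant_id = "p1",
                                 target_spl = target_spl),
                            mic = microphone_model(), fs = fs,
                            n_trials = 3, trial_jitter_db = 0,
                            seed = seed, ...)
}
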