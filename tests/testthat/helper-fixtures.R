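# Shared fixtures, built in code and memoized so expensive objects are
# generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# One clean normal recording (10 s, 72 bpm) with ground truth, preprocessed.
clean_fixture <- function() {
  memo("clean", {
    r <- generate_recording(synth_config(seed = 101))
    r$prep <- pcg_preprocess(r$recording)
    r$cycles <- pcg_cycles(r$truth_segmentation, r$prep)
    r
  })
}

# Small labeled dataset for model/experiment tests: 15 normal, 15 abnormal,
# ~10% noisy, 6 s recordings with strong murmurs, features from ground truth.
small_dataset <- function() {
  memo("small_ds", {
    ds <- generate_dataset(15, 15, 0.1, seed = 202,
                           config = synth_config(duration = 6,
                                                 murmur_snr = 0))
    list(
      dataset = ds,
      features = extract_feature_table(ds, segmenter = "truth"),
      labels = synth_labels(ds)
    )
  })
}

# Hand-built segmentation: 3 cycles with printed sample counts at 1000 Hz.
# Cycle starts at 0, 1000, 2100 (so RR = 1000, 1100 samples);
# per cycle: S1 = 100, systole = 300, S2 = 80, diastole = rest.
toy_segmentation <- function() {
  starts <- c(0, 1000, 2100)
  dia <- c(1000, 1100, 900) - (100 + 300 + 80)
  iv <- do.call(rbind, lapply(1:3, function(i) {
    b <- starts[i] + cumsum(c(0, 100, 300, 80))
    data.frame(
      state = c("S1", "systole", "S2", "diastole"),
      start_sample = b,
      end_sample = c(b[-1], b[4] + dia[i])
    )
  }))
  pcg_segmentation(iv)
}

# Deterministic toy recording whose cycles have prescribed per-state
# constant absolute amplitudes; useful for hand-arithmetic oracles.
toy_amplitude_cycles <- function(amp) {
  # amp: matrix cycles x 4 (s1, sys, s2, dia) of absolute amplitudes
  lapply(seq_len(nrow(amp)), function(i) {
    cyc <- list(
      s1 = rep(amp[i, 1], 4) * c(1, -1, 1, -1),
      systole = rep(amp[i, 2], 4) * c(1, -1, 1, -1),
      s2 = rep(amp[i, 3], 4) * c(1, -1, 1, -1),
      diastole = rep(amp[i, 4], 4) * c(1, -1, 1, -1)
    )
    cyc$cycle <- c(cyc$s1, cyc$systole, cyc$s2, cyc$diastole)
    cyc
  })
}
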