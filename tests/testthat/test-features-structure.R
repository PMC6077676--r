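test_that("the canonical schema has 515 features with the fixed domain sizes", {
  schema <- pcg_feature_names()
  expect_identical(nrow(schema), 515L)
  expect_false(anyDuplicated(schema$name) > 0)
  counts <- pcg_domain_counts()
  expect_identical(
    counts,
    c(time_interval = 20L, freq_state = 308L, amplitude = 12L, energy = 47L,
      freq_record = 27L, cepstrum = 65L, cyclostationarity = 4L, hos = 16L,
      entropy = 16L)
  )
  expect_identical(sum(counts), 515L)
  expect_identical(as.integer(table(schema$domain)[names(counts)]),
                   as.integer(counts))
})

test_that("extract_features is complete, ordered and deterministic", {
  r <- clean_fixture()
  fv1 <- extract_features(r$prep, r$truth_segmentation)
  fv2 <- extract_features(r$prep, r$truth_segmentation)
  expect_length(fv1, 515)
  expect_identical(names(fv1), pcg_feature_names()$name)
  expect_identical(unclass(fv1), unclass(fv2))
  expect_error(extract_features(r$prep, NULL), "segmentation")
})

test_that("time-interval features match a hand-arithmetic oracle", {
  fv <- time_interval_features(toy_segmentation(), 1000)
  # cycles: RR = 1.0, 1.1 s; S1 = 0.1, sys = 0.3, S2 = 0.08 s every cycle;
  # diastole = 0.52, 0.62, 0.42 s -- recomputed by explicit arithmetic
  expect_equal(fv[["m_RR"]], (1.0 + 1.1) / 2)
  expect_equal(fv[["sd_RR"]], stats::sd(c(1.0, 1.1)))
  expect_equal(fv[["m_IntS1"]], 0.1)
  expect_equal(fv[["sd_IntS1"]], 0)
  expect_equal(fv[["m_IntS2"]], 0.08)
  expect_equal(fv[["m_IntSys"]], 0.3)
  expect_equal(fv[["m_IntDia"]], mean(c(0.52, 0.62, 0.42)))
  expect_equal(fv[["sd_IntDia"]], stats::sd(c(0.52, 0.62, 0.42)))
  expect_equal(fv[["m_Ratio_SysRR"]], mean(c(0.3 / 1.0, 0.3 / 1.1)))
  expect_equal(fv[["sd_Ratio_SysRR"]], stats::sd(c(0.3 / 1.0, 0.3 / 1.1)))
  expect_equal(fv[["m_Ratio_DiaRR"]], mean(c(0.52 / 1.0, 0.62 / 1.1)))
  expect_equal(fv[["m_Ratio_SysDia"]],
               mean(c(0.3 / 0.52, 0.3 / 0.62, 0.3 / 0.42)))
  expect_equal(fv[["m_Ratio_S1RR"]], mean(c(0.1 / 1.0, 0.1 / 1.1)))
  expect_equal(fv[["m_Ratio_S2RR"]], mean(c(0.08 / 1.0, 0.08 / 1.1)))
  expect_length(fv, 20)
})

test_that("a perfectly periodic segmentation zeroes every SD feature", {
  iv <- do.call(rbind, lapply(0:3, function(i) {
    b <- i * 1000 + cumsum(c(0, 100, 300, 80))
    data.frame(state = c("S1", "systole", "S2", "diastole"),
               start_sample = b, end_sample = c(b[-1], (i + 1) * 1000))
  }))
  fv <- time_interval_features(pcg_segmentation(iv), 1000)
  sd_feats <- fv[grep("^sd_", names(fv))]
  expect_true(all(sd_feats == 0))
})

test_that("too few cycles marks all time-interval features missing", {
  iv <- data.frame(state = c("S1", "systole", "S2", "diastole"),
                   start_sample = c(0, 100, 400, 480),
                   end_sample = c(100, 400, 480, 1000))
  fv <- time_interval_features(pcg_segmentation(iv), 1000)
  expect_true(all(is.na(fv)))
})

test_that("amplitude features match hand arithmetic and detect symmetry", {
  # two cycles with prescribed constant absolute amplitudes per state
  amp <- rbind(c(2, 1, 4, 0.5),   # s1, sys, s2, dia
               c(3, 1, 6, 1))
  fv <- amplitude_features(toy_amplitude_cycles(amp))
  expect_equal(fv[["m_Amp_SysS1"]], mean(c(1 / 2, 1 / 3)))
  expect_equal(fv[["sd_Amp_SysS1"]], stats::sd(c(1 / 2, 1 / 3)))
  expect_equal(fv[["m_Amp_DiaS2"]], mean(c(0.5 / 4, 1 / 6)))
  expect_equal(fv[["m_Amp_S1S2"]], mean(c(2 / 4, 3 / 6)))
  expect_equal(fv[["sd_Amp_S1S2"]], 0)
  expect_equal(fv[["m_Amp_S1Dia"]], mean(c(2 / 0.5, 3 / 1)))
  expect_equal(fv[["m_Amp_SysDia"]], mean(c(1 / 0.5, 1 / 1)))
  expect_equal(fv[["m_Amp_S2Sys"]], mean(c(4 / 1, 6 / 1)))
  expect_length(fv, 12)

  # S1 and S2 rendered identically -> m_Amp_S1S2 = 1
  sym <- amplitude_features(toy_amplitude_cycles(rbind(c(2, 1, 2, 1),
                                                       c(3, 1, 3, 1))))
  expect_equal(sym[["m_Amp_S1S2"]], 1, tolerance = 0.05)

  # zero-amplitude denominator cycles are excluded, all-zero -> missing
  z <- amplitude_features(toy_amplitude_cycles(rbind(c(2, 1, 0, 1),
                                                     c(3, 1, 0, 1))))
  expect_true(is.na(z[["m_Amp_DiaS2"]]))
})

test_that("band-energy ratios localize tones and match a direct-form oracle", {
  fs <- 2000
  tone <- pcg_recording(sin(2 * pi * 55 * (0:9999) / fs), fs)
  be <- band_energy_features(tone)
  expect_length(be, 27)
  expect_gte(be[["Ratio_band_energy_40_70Hz"]], 0.9)
  nonadjacent <- be[-(1:3)]
  expect_true(all(nonadjacent < 0.05))
  expect_true(all(be >= 0 & be <= 1.01))

  # independent oracle: direct-form IIR recursion on a 64-sample input
  set.seed(1)
  x <- stats::rnorm(64)
  bf <- signal::butter(5, c(40, 70) / (fs / 2), type = "pass")
  b <- bf$b; a <- bf$a
  y <- numeric(64)
  for (n in seq_len(64)) {
    acc <- 0
    for (k in seq_along(b)) if (n - k + 1 >= 1) acc <- acc + b[k] * x[n - k + 1]
    for (k in 2:length(a)) if (n - k + 1 >= 1) acc <- acc - a[k] * y[n - k + 1]
    y[n] <- acc / a[1]
  }
  ratio_oracle <- sum(y^2) / sum(x^2)
  be_small <- band_energy_features(pcg_recording(x, fs))
  expect_equal(be_small[["Ratio_band_energy_40_70Hz"]], ratio_oracle,
               tolerance = 1e-9)

  expect_error(band_energy_features(pcg_recording(numeric(100), fs)),
               "zero-energy")
})

test_that("state-energy ratios match hand arithmetic and partition to one", {
  # printed 8-sample toy cycle: 2 samples per state
  cyc <- list(s1 = c(3, 4), systole = c(1, 2), s2 = c(2, 2), diastole = c(1, 1))
  cyc$cycle <- c(cyc$s1, cyc$systole, cyc$s2, cyc$diastole)
  fv <- state_energy_features(list(cyc, cyc))
  # energies: s1 = 25, sys = 5, s2 = 8, dia = 2, cycle = 40
  expect_equal(fv[["m_Ratio_state_energy_S1_cycle"]], 25 / 40)
  expect_equal(fv[["m_Ratio_state_energy_S2_cycle"]], 8 / 40)
  expect_equal(fv[["m_Ratio_state_energy_sys_cycle"]], 5 / 40)
  expect_equal(fv[["m_Ratio_state_energy_dia_cycle"]], 2 / 40)
  expect_equal(fv[["m_Ratio_state_energy_S1_S2"]], 25 / 8)
  expect_equal(fv[["m_Ratio_state_energy_S1_sys"]], 25 / 5)
  expect_equal(fv[["m_Ratio_state_energy_S1_dia"]], 25 / 2)
  expect_equal(fv[["m_Ratio_state_energy_S2_sys"]], 8 / 5)
  expect_equal(fv[["m_Ratio_state_energy_S2_dia"]], 8 / 2)
  expect_equal(fv[["m_Ratio_state_energy_dia_sys"]], 2 / 5)
  expect_true(all(fv[grep("^sd_", names(fv))] == 0))
  expect_length(fv, 20)

  # partition identity on real cycles
  cycles <- clean_fixture()$cycles
  for (cy in cycles[1:3]) {
    parts <- c(sum(cy$s1^2), sum(cy$systole^2), sum(cy$s2^2),
               sum(cy$diastole^2))
    expect_equal(sum(parts) / sum(cy$cycle^2), 1, tolerance = 1e-12)
  }
})

test_that("record-spectrum ratios sum to one and localize tones", {
  r <- clean_fixture()
  rs <- record_spectrum_features(r$prep)
  expect_length(rs, 27)
  expect_equal(sum(rs), 1, tolerance = 1e-9)

  tone <- pcg_recording(sin(2 * pi * 100 * (0:9999) / 2000), 2000)
  rt <- record_spectrum_features(tone)
  expect_gt(rt[["Ratio_spec_mag_70_100Hz"]] + rt[["Ratio_spec_mag_100_130Hz"]],
            0.9)
  expect_error(record_spectrum_features(pcg_recording(numeric(10), 2000)),
               "zero")
})

test_that("per-state spectra have 308 entries and find injected tones", {
  r <- clean_fixture()
  fs <- 2000
  cycles <- r$cycles
  # replace every S1 slice by a pure 100 Hz tone
  for (i in seq_along(cycles)) {
    L <- length(cycles[[i]]$s1)
    cycles[[i]]$s1 <- sin(2 * pi * 100 * (0:(L - 1)) / fs)
  }
  fv <- state_spectrum_features(cycles, fs)
  expect_length(fv, 308)
  s1_spec <- fv[sprintf("Spec_S1_%dHz", seq(30, 790, 10))]
  expect_identical(names(which.max(s1_spec)), "Spec_S1_100Hz")

  # zero-signal state gives 77 zeros
  for (i in seq_along(cycles)) cycles[[i]]$diastole[] <- 0
  fv0 <- state_spectrum_features(cycles, fs)
  expect_true(all(fv0[sprintf("Spec_dia_%dHz", seq(30, 790, 10))] == 0))
})

test_that("amplitude and energy features are invariant to global scaling", {
  r <- clean_fixture()
  seg <- r$truth_segmentation
  scaled <- r$prep
  # scale by a power of two so the identity is exact even through the
  # marginally-damped low-band IIR recursions
  scaled$samples <- scaled$samples * 4
  cyc1 <- pcg_cycles(seg, r$prep)
  cyc5 <- pcg_cycles(seg, scaled)
  expect_equal(amplitude_features(cyc5), amplitude_features(cyc1),
               tolerance = 1e-12)
  expect_equal(state_energy_features(cyc5), state_energy_features(cyc1),
               tolerance = 1e-12)
  expect_equal(band_energy_features(scaled), band_energy_features(r$prep),
               tolerance = 1e-12)
  expect_equal(record_spectrum_features(scaled),
               record_spectrum_features(r$prep), tolerance = 1e-12)
})
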