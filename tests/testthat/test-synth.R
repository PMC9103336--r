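# Synthetic four-channel NI-FECG generator.

test_that("beat trains honour rate, jitter and error contracts", {
  idx <- generate_beat_train(60, 10, 0, fs = 1000)
  expect_true(length(idx) %in% c(10L, 11L))
  expect_true(all(diff(idx) == 1000L))

  idx2 <- generate_beat_train(140, 60, 0.03, fs = 1000, seed = 7)
  expect_gte(length(idx2), 136)
  expect_lte(length(idx2), 144)
  rr_nom <- 60 / 140 * 1000
  expect_true(all(abs(diff(idx2) - rr_nom) <= 3 * 0.03 * rr_nom + 1))
  expect_true(all(diff(idx2) > 0))

  expect_error(generate_beat_train(0, 10), "positive")
  expect_error(generate_beat_train(60, -1), "positive")
})

test_that("rendering places dominant R lobes at the beat indices", {
  expect_identical(render_ecg(ecg_template(), integer(), 1000, 500),
                   numeric(500))

  # single centred beat of a symmetric template renders symmetrically
  sym <- data.frame(lobe = c("P", "Q", "R", "S", "T"),
                    amplitude = c(0.2, -0.1, 1, -0.1, 0.2),
                    center = c(-0.8, -0.3, 0, 0.3, 0.8),
                    width = c(0.2, 0.1, 0.1, 0.1, 0.2))
  y <- render_ecg(ecg_template(sym), 1001L, 1000, 2001L)
  expect_lt(max(abs(y - rev(y))), 1e-9)

  # two beats one second apart are near-identical template copies
  y2 <- render_ecg(ecg_template(), c(1000L, 2000L), 1000, 3000L)
  w1 <- y2[801:1200]; w2 <- y2[1801:2200]
  expect_gte(stats::cor(w1, w2), 0.99)

  # the global |max| lies within 20 ms of a beat
  ce <- clean_ecg(80)
  expect_lte(min(abs(which.max(abs(ce$x)) - ce$beats)), 20)

  expect_error(render_ecg(ecg_template(), 5000L, 1000, 100L), "outside")
})

test_that("template invariants are enforced", {
  bad <- data.frame(lobe = "X", amplitude = 1, center = 0, width = 1)
  expect_error(ecg_template(bad), "5 lobes")
  wp <- ecg_template()$wave_params
  wp$width[2] <- -1
  expect_error(ecg_template(wp), "positive")
  wp2 <- ecg_template()$wave_params
  wp2$amplitude[5] <- 2   # T exceeds R
  expect_error(ecg_template(wp2), "largest")
})

test_that("snr_db matches analytic powers", {
  x <- stats::rnorm(1000)
  expect_equal(snr_db(x, x), 0)
  expect_equal(snr_db(2 * x, x) - snr_db(x, x), 20 * log10(2))
  t <- seq(0, 10, by = 1e-3)
  s <- sqrt(2) * sin(2 * pi * 7 * t)       # power 1
  set.seed(1)
  n <- stats::rnorm(length(t))             # power ~1
  expect_lt(abs(snr_db(s, n)), 0.2)
  expect_error(snr_db(x, numeric(1000)), "power")
  expect_error(snr_db(x, x[1:10]), "length")
})

test_that("recordings mix components as declared", {
  cfg <- synth_config(duration_s = 6, noise_sigma = 0, baseline_amp = 0,
                      powerline_amp = 0, foetal_gain_per_channel = c(0, 0, 0),
                      seed = 2)
  rec <- generate_recording(cfg)
  m <- render_ecg(ecg_template(), rec$mqrs, 1000, nrow(rec$channels))
  for (j in 1:3) {
    ratio <- rec$channels[, j + 1] / ifelse(abs(m) > 1e-3, m, NA)
    ratio <- ratio[!is.na(ratio)]
    expect_lt(stats::sd(ratio), 1e-10)
    expect_equal(mean(ratio), cfg$maternal_gain_per_channel[j],
                 tolerance = 1e-10)
  }
})

test_that("generation is deterministic and labels follow the threshold", {
  cfg <- synth_config(duration_s = 5, seed = 31, target_foetal_snr_db = 12)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$fqrs, r2$fqrs)
  expect_identical(r1$label, "good")

  cfg$target_foetal_snr_db <- -6
  expect_identical(generate_recording(cfg)$label, "bad")

  # label monotone in the target SNR
  labs <- vapply(c(-6, 0, 3, 6, 12), function(s) {
    cfg$target_foetal_snr_db <- s
    generate_recording(cfg)$label
  }, character(1))
  expect_identical(labs, c("bad", "bad", "good", "good", "good"))
})

test_that("achieved foetal SNR matches the target within 0.5 dB", {
  for (seed in 1:8) {
    tgt <- c(-6, 3, 12)[seed %% 3 + 1]
    cfg <- synth_config(duration_s = 6, target_foetal_snr_db = tgt,
                        seed = seed)
    rec <- generate_recording(cfg)
    n <- nrow(rec$channels)
    m <- render_ecg(ecg_template(), rec$mqrs, 1000, n)
    f <- render_ecg(foetal_template(), rec$fqrs, 1000, n)
    achieved <- vapply(1:3, function(j) {
      fj <- rec$meta$foetal_gains[j] * f
      noise <- rec$channels[, j + 1] -
        cfg$maternal_gain_per_channel[j] * m - fj
      snr_db(fj, noise)
    }, numeric(1))
    expect_lt(abs(max(achieved) - tgt), 0.5)
  }
})

test_that("any 2.5 s window holds 4-6 foetal beats for FHR 110-140", {
  for (fhr in c(110, 125, 140)) {
    cfg <- synth_config(duration_s = 12, fhr_bpm = fhr, seed = fhr)
    rec <- generate_recording(cfg)
    for (start in seq(1, nrow(rec$channels) - 2500, by = 500)) {
      k <- sum(rec$fqrs >= start & rec$fqrs < start + 2500)
      expect_gte(k, 4); expect_lte(k, 6)
    }
  }
})

test_that("datasets have the requested composition and are reproducible", {
  base <- synth_config(duration_s = 5)
  ds <- generate_dataset(5, 5, base, seed = 4)
  expect_length(ds, 10)
  labs <- vapply(ds, `[[`, character(1), "label")
  expect_identical(sum(labs == "good"), 5L)
  expect_identical(sum(labs == "bad"), 5L)

  ds2 <- generate_dataset(5, 5, base, seed = 4)
  expect_identical(lapply(ds, `[[`, "channels"),
                   lapply(ds2, `[[`, "channels"))

  # recovered foetal rates inside the sampled range
  rates <- vapply(ds, function(r) {
    (length(r$fqrs) - 1) / diff(range(r$fqrs)) * r$fs * 60
  }, numeric(1))
  expect_true(all(rates >= 105 & rates <= 165))

  expect_error(generate_dataset(2, 2, base,
                                snr_ranges = list(good = c(0, 10),
                                                  bad = c(-5, 2))),
               "disjoint")
})
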