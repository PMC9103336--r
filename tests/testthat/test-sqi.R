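# Classical signal-quality indices and the 45-feature vector.

test_that("moment indices agree with definitional brute-force sums", {
  set.seed(10)
  for (n in c(10, 100, 10000)) {
    x <- stats::rnorm(n) * 3 + 1
    mu <- sum(x) / n
    m2 <- sum((x - mu)^2) / n
    m3 <- sum((x - mu)^3) / n
    m4 <- sum((x - mu)^4) / n
    expect_equal(std_sqi(x), sqrt(m2), tolerance = 1e-9)
    expect_equal(s_sqi(x), m3 / m2^1.5, tolerance = 1e-9)
    expect_equal(k_sqi(x), m4 / m2^2, tolerance = 1e-9)
  }

  tri <- c(seq(-1, 1, by = 0.01), seq(1, -1, by = -0.01))  # symmetric
  expect_lt(abs(s_sqi(tri)), 1e-9)

  set.seed(11)
  expect_equal(k_sqi(stats::rnorm(1e6)), 3, tolerance = 0.02)
  expect_equal(k_sqi(rep(c(-1, 1), 50)), 1)

  expect_warning(k0 <- k_sqi(rep(2, 10)), "constant")
  expect_identical(k0, 0)
  expect_error(std_sqi(3), "2 samples")
})

test_that("spectral indices match analytic band assignments", {
  fs <- 1000
  t <- (0:2499) / fs
  expect_equal(p_sqi(sin(2 * pi * 10 * t), fs), 0)
  expect_equal(p_sqi(sin(2 * pi * 30 * t), fs), 1)
  expect_identical(p_sqi(sin(2 * pi * 60 * t), fs), 0)  # sentinel
  expect_gte(bas_sqi(sin(2 * pi * 1 * t), fs), 0.99)
  expect_lte(bas_sqi(sin(2 * pi * 50 * t), fs), 0.01)
  expect_identical(bas_sqi(numeric(2500), fs), 0)
  expect_error(p_sqi(t, 80), "90")
})

test_that("detection-agreement indices follow their formulas", {
  fs <- 1000
  a <- qrs_annotation(seq(500, 9500, 1000), fs)
  expect_equal(b_sqi(a, a), 1)
  b <- qrs_annotation(a$indices + 400, fs)
  expect_equal(b_sqi(a, b), 0)
  ref <- qrs_annotation(seq(400, 9400, 1000), fs)       # 10 beats
  tst <- qrs_annotation(ref$indices[1:5], fs)           # 5 hits, 0 extras
  expect_equal(b_sqi(tst, ref), 2 * 5 / 15, tolerance = 1e-12)
  expect_identical(b_sqi(qrs_annotation(integer(), fs),
                         qrs_annotation(integer(), fs)), 0)

  leads <- list(a, a, a)
  expect_equal(i_sqi(leads, 1), 1)
  expect_equal(i_sqi(list(a, qrs_annotation(integer(), fs), a), 1), 0)
  cur <- qrs_annotation(c(1000, 2000, 3000, 4000), fs)
  oth <- qrs_annotation(c(1000, 2000, 3000), fs)
  expect_equal(i_sqi(list(cur, oth, oth), 1), 0.75)

  expect_equal(mi_sqi(a, a), 0)            # all foetal beats on MQRS
  far <- qrs_annotation(a$indices + 500, fs)
  expect_equal(mi_sqi(far, a), 1)
  expect_identical(mi_sqi(qrs_annotation(integer(), fs), a), 0)
})

test_that("rate-regularity index counts HR outliers", {
  fs <- 1000
  rr <- rep(429L, 9)                       # ~140 bpm metronome, 10 beats
  expect_equal(r_sqi(qrs_annotation(cumsum(c(500L, rr)), fs)), 1)
  rr2 <- rr; rr2[c(3, 7)] <- 214L          # 2 halved intervals -> HR doubles
  expect_equal(r_sqi(qrs_annotation(cumsum(c(500L, rr2)), fs)), 0.8)
  expect_identical(r_sqi(qrs_annotation(c(100L, 600L), fs)), 0)
})

test_that("morphology and extravagance indices behave on constructed beats", {
  fs <- 1000
  beat <- exp(-((-50:50)^2) / 200)
  x <- numeric(5000)
  idx <- seq(500, 4500, by = 500)
  for (i in idx) x[(i - 50):(i + 50)] <- beat
  ann <- qrs_annotation(idx, fs)
  expect_equal(c_sqi(x, ann), 1, tolerance = 1e-9)

  # half the beats negated (at reduced gain so the mean template stays on
  # the base shape): correlations {1, 0 after clipping} average to 0.5
  x2 <- numeric(5000)
  idx10 <- seq(400, 4900, by = 500)
  for (k in seq_along(idx10)) {
    g <- if (k %% 2 == 0) 1 else -0.5
    x2[(idx10[k] - 50):(idx10[k] + 50)] <- beat * g
  }
  expect_equal(c_sqi(x2, qrs_annotation(idx10, fs)), 0.5, tolerance = 1e-9)
  expect_identical(c_sqi(x, qrs_annotation(500L, fs)), 0)

  imp <- numeric(5000); imp[idx] <- 1
  expect_equal(x_sqi(imp, ann), 1)
  expect_identical(x_sqi(numeric(5000), ann), 0)
  set.seed(3)
  wn <- stats::rnorm(5000)
  expect_lt(abs(x_sqi(wn, ann) - 0.5), 0.05)

  expect_lt(abs(mx_sqi(wn, ann) - 0.5), 0.05)
  clean <- numeric(5000); clean[idx + 250] <- 1   # energy only off-MQRS
  expect_equal(mx_sqi(clean, ann), 1)
  expect_identical(mx_sqi(numeric(5000), ann), 0)
})

test_that("maternal harmonic power and coherence indices", {
  fs <- 1000
  idx <- seq(500, 9500, by = 500)          # 2 Hz fundamental (exact bin)
  ann <- qrs_annotation(idx, fs)
  t <- (0:9999) / fs
  tone <- sin(2 * pi * 2 * t)
  expect_gte(mp_sqi(tone, ann, fs, "a"), 0.95)
  set.seed(4)
  wn <- stats::rnorm(10000)
  # harmonic bands cover ~5 x 0.4 Hz of the 99.5 Hz total band
  expect_lt(mp_sqi(wn, ann, fs, "a"), 0.1)
  expect_identical(mp_sqi(wn, qrs_annotation(integer(), fs), fs, "a"), 0)

  x <- stats::rnorm(2500)
  xd <- c(numeric(5), x[1:2495])           # delayed copy
  expect_gte(mc_sqi(x, xd, fs), 0.95)
  expect_lte(mc_sqi(x, stats::rnorm(2500), fs), 0.3)
  expect_error(mc_sqi(x, x[1:100], fs), "length")
})

test_that("feature vectors have the documented 45-name layout", {
  nm <- sqi_feature_names()
  expect_length(nm, 45)
  expect_identical(anyDuplicated(nm), 0L)
  expect_identical(sum(startsWith(nm, "bSQI_")), 10L)
  expect_identical(sum(startsWith(nm, "iSQI_")), 5L)

  sd <- small_dataset()
  seg <- sd$pp[[1]]$segments[[2]]
  fv1 <- feature_vector(seg)
  fv2 <- feature_vector(seg)
  expect_length(fv1, 45)
  expect_identical(names(fv1), nm)
  expect_identical(as.numeric(fv1), as.numeric(fv2))  # deterministic
  expect_true(attr(fv1, "quality_mask") %in% c(TRUE, FALSE))
  # range law on the non-time-domain entries
  bounded <- setdiff(nm, c("stdSQI", "sSQI", "kSQI"))
  expect_true(all(fv1[bounded] >= 0 & fv1[bounded] <= 1))
})

test_that("xSQI separates high from low foetal SNR segments", {
  good <- generate_dataset(4, 0, synth_config(duration_s = 10), seed = 201)
  bad <- generate_dataset(0, 4, synth_config(duration_s = 10), seed = 202)
  xsqi_of <- function(recs) {
    vals <- c()
    for (r in recs) {
      pp <- preprocess_recording(r)
      for (s in pp$segments[1:2]) {
        vals <- c(vals, feature_vector(s)[["xSQI_pan_tompkins"]])
      }
    }
    vals
  }
  expect_gt(mean(xsqi_of(good)), mean(xsqi_of(bad)))
})

test_that("bounded indices stay in [0,1] and are amplitude-invariant", {
  set.seed(30)
  fs <- 1000
  for (i in 1:12) {
    x <- stats::rnorm(3000) * 10^stats::runif(1, -2, 2)
    idx <- sort(sample(200:2800, 8))
    idx <- idx[c(TRUE, diff(idx) > 160)]
    ann <- qrs_annotation(idx, fs)
    vals <- c(p_sqi(x, fs), bas_sqi(x, fs), r_sqi(ann), c_sqi(x, ann),
              x_sqi(x, ann), mx_sqi(x, ann), mp_sqi(x, ann, fs, "a"),
              mp_sqi(x, ann, fs, "b"), mc_sqi(x, stats::rnorm(3000), fs),
              mi_sqi(ann, ann))
    expect_true(all(vals >= 0 & vals <= 1))
    # positive rescaling leaves ratio/correlation indices unchanged
    for (f in list(p_sqi = function(z) p_sqi(z, fs),
                   bas_sqi = function(z) bas_sqi(z, fs),
                   c_sqi = function(z) c_sqi(z, ann),
                   x_sqi = function(z) x_sqi(z, ann))) {
      expect_equal(f(x), f(4.2 * x), tolerance = 1e-9)
    }
  }
})
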