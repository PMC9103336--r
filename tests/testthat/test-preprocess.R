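# Normalization, bandpass, segmentation and spectrogram images.

test_that("min-max normalization attains -1/+1 exactly", {
  out <- normalize_signal(c(0, 5, 10))
  expect_identical(out$signal, c(-1, 0, 1))
  expect_identical(out$params, list(x_min = 0, x_max = 10))

  x <- c(-1, -0.2, 0.7, 1)   # already canonical, endpoints attained
  expect_equal(normalize_signal(x)$signal, x, tolerance = 1e-15)

  set.seed(1)
  for (i in 1:20) {
    z <- stats::rnorm(50) * 10^stats::runif(1, -3, 3)
    s <- normalize_signal(z)$signal
    expect_identical(min(s), -1)
    expect_identical(max(s), 1)
    expect_identical(order(s), order(z))   # order-preserving affine map
  }

  expect_error(normalize_signal(c(2, 2, 2)), "constant")
  expect_error(normalize_signal(numeric()), "non-empty")
})

test_that("bandpass meets its designed response contract", {
  fs <- 1000
  # designed response: within 3 dB over [6, 80]; >= 40 dB down a decade
  # below the low edge; >= 18 dB (3rd-order octave roll-off) at 2 x high
  pb <- bandpass_response(seq(6, 80, by = 2), fs)
  expect_true(all(pb >= 10^(-3 / 20) & pb <= 10^(3 / 20)))
  expect_lt(bandpass_response(0.3, fs), 0.01)
  expect_lt(bandpass_response(200, fs), 10^(-18 / 20))

  # time-domain checks
  t <- seq(0, 5, by = 1 / fs)
  y30 <- bandpass_filter(sin(2 * pi * 30 * t), fs)
  amp <- max(abs(y30[2000:4000]))          # steady state
  expect_lt(abs(20 * log10(amp)), 1)
  y03 <- bandpass_filter(sin(2 * pi * 0.3 * t), fs)
  expect_lte(max(abs(y03[3000:5000])), 0.01)
  ydc <- bandpass_filter(rep(2, 3000), fs)
  expect_lt(mean(abs(ydc[1000:3000])), 0.02)

  expect_error(bandpass_filter(t, fs, low = 0), "edges")
  expect_error(bandpass_filter(t, fs, low = 10, high = 600), "edges")
})

test_that("segmentation count, overlap and label inheritance", {
  mk <- function(dur) {
    n <- round(dur * 1000)
    fecg_recording(matrix(stats::rnorm(4 * n), ncol = 4), 1000,
                   label = "good", id = "r")
  }
  segs <- segment_recording(mk(60))
  expect_length(segs, 24)   # floor((60 - 2.5)/2.4) + 1
  expect_length(segment_recording(mk(2.5)), 1)
  expect_warning(s0 <- segment_recording(mk(2.4)), "shorter")
  expect_length(s0, 0)

  # consecutive windows share exactly the overlap samples
  r <- mk(10)
  segs <- segment_recording(r)
  expect_identical(segs[[2]]$start_sample - segs[[1]]$start_sample, 2400L)
  shared_a <- segs[[1]]$channels[2401:2500, ]
  shared_b <- segs[[2]]$channels[1:100, ]
  expect_identical(shared_a, shared_b)
  expect_true(all(vapply(segs, `[[`, character(1), "label") == "good"))

  # conservation: all samples covered except a trailing stub
  last <- segs[[length(segs)]]
  expect_lt(nrow(r$channels) - (last$start_sample + 2499), 2400)

  expect_error(segment_recording(r, window_s = 1, overlap_s = 2), "exceed")
})

test_that("spectrogram images satisfy the 40 x 126 greyscale contract", {
  set.seed(2)
  for (i in 1:5) {
    img <- stft_image(stats::rnorm(2500) * 10^(i - 3))
    expect_identical(dim(img$pixels), c(40L, 126L))
    expect_gte(min(img$pixels), 0)
    expect_lte(max(img$pixels), 128)
    expect_identical(max(img$pixels), 128)   # min-max rescale attains 128
  }
  expect_identical(stft_image(numeric(2500))$pixels,
                   matrix(0, 40L, 126L))
  expect_error(stft_image(stats::rnorm(100)), "2500")
})

test_that("spectrogram frequency rows and framing variants are correct", {
  t <- (0:2499) / 1000
  img <- stft_image(sin(2 * pi * 100 * t))
  # 12.5 Hz bins starting at bin 1: 100 Hz is the 8th row
  expect_identical(unname(which.max(rowSums(img$pixels))), 8L)
  expect_equal(img$freq_axis[8], 100)
  expect_equal(img$freq_axis[1], 12.5)
  expect_equal(img$freq_axis[40], 500)

  # literal hop-25 framing without centring yields 97 frames
  img25 <- stft_image(sin(2 * pi * 100 * t), hop = 25, centered = FALSE)
  expect_identical(ncol(img25$pixels), 97L)

  # amplitude invariance of the min-max rescale
  x <- stats::rnorm(2500)
  expect_equal(stft_image(3.7 * x)$pixels, stft_image(x)$pixels,
               tolerance = 1e-12)
})

test_that("the full chain produces 4 images per segment", {
  rec <- generate_recording(synth_config(duration_s = 10, seed = 12))
  pp <- preprocess_recording(rec)
  expect_length(pp$segments, 4)   # floor((10 - 2.5)/2.4) + 1
  expect_true(all(vapply(pp$images, length, integer(1)) == 4L))
  for (im in pp$images[[1]]) {
    expect_identical(dim(im$pixels), c(40L, 126L))
    expect_gte(min(im$pixels), 0)
    expect_lte(max(im$pixels), 128)
  }

  rec$channels[, "A2"] <- 1   # dead electrode
  expect_error(preprocess_recording(rec), "A2")

  rec2 <- generate_recording(synth_config(duration_s = 10, seed = 12))
  rec2$fs <- 500
  expect_error(preprocess_recording(rec2), "1 kHz")
})
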