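# QRS detector families and annotation matching.

test_that("every detector reaches F1 >= 0.95 on clean synthetic ECG", {
  cases <- rbind(
    expand.grid(bpm = c(60, 80, 100), target = "maternal",
                stringsAsFactors = FALSE),
    expand.grid(bpm = c(120, 140, 160), target = "foetal",
                stringsAsFactors = FALSE))
  for (r in seq_len(nrow(cases))) {
    tpl <- if (cases$target[r] == "foetal") foetal_template() else ecg_template()
    ce <- clean_ecg(cases$bpm[r], template = tpl, seed = 5 + r)
    for (m in qrs_detectors()) {
      ann <- detect_qrs(ce$x, ce$fs, m, cases$target[r])
      f1 <- f1_of(ann, ce$beats)
      expect_gte(f1, 0.95)
      # detections land within 20 ms of true beats
      hits <- vapply(ann$indices, function(i) min(abs(ce$beats - i)),
                     numeric(1))
      expect_lte(stats::median(hits), 20)
    }
  }
})

test_that("detector edge cases behave as specified", {
  expect_length(detect_qrs(numeric(2000), 1000)$indices, 0)
  expect_length(detect_qrs(rep(3.2, 2000), 1000)$indices, 0)
  expect_error(detect_qrs(stats::rnorm(2000), 1000, method = "nope"))
  expect_error(detect_qrs(stats::rnorm(100), 1000), "1 s")
  expect_identical(qrs_detectors(),
                   c("maxsearch", "jqrs", "pan_tompkins", "gqrs", "wqrs"))

  # refractory invariant: consecutive detections separated accordingly
  ce <- clean_ecg(100)
  for (m in qrs_detectors()) {
    idx <- detect_qrs(ce$x, 1000, m, "maternal")$indices
    if (length(idx) > 1) expect_true(all(diff(idx) >= 200))
  }
})

test_that("annotation matching follows greedy one-to-one semantics", {
  fs <- 1000
  a <- qrs_annotation(seq(500, 9500, by = 1000), fs)
  expect_identical(match_annotations(a, a),
                   c(tp = 10L, fp = 0L, fn = 0L))
  b <- qrs_annotation(a$indices + 150, fs)   # shift of 3 x tol
  expect_identical(match_annotations(b, a, tol_ms = 50),
                   c(tp = 0L, fp = 10L, fn = 10L))
  ref <- qrs_annotation(c(1000, 2000), fs)
  tst <- qrs_annotation(c(1010, 2000, 3000), fs)
  expect_identical(match_annotations(tst, ref, 50),
                   c(tp = 2L, fp = 1L, fn = 0L))
  expect_error(match_annotations(a, qrs_annotation(1:3, 500)), "rate")
})

test_that("matching agrees with a brute-force assignment oracle", {
  # oracle: maximum bipartite matching within tolerance found by exhaustive
  # search over assignment orders (small n)
  brute_tp <- function(ti, ri, tol) {
    best <- 0L
    rec <- function(i, used, count) {
      if (count + (length(ti) - i + 1) <= best) return()
      if (i > length(ti)) { best <<- max(best, count); return() }
      rec(i + 1L, used, count)
      for (j in seq_along(ri)) {
        if (!used[j] && abs(ti[i] - ri[j]) <= tol) {
          used[j] <- TRUE
          rec(i + 1L, used, count + 1L)
          used[j] <- FALSE
        }
      }
    }
    rec(1L, logical(length(ri)), 0L)
    best
  }
  set.seed(8)
  for (i in 1:15) {
    ti <- sort(sample(1:3000, sample(2:6, 1)))
    ri <- sort(sample(1:3000, sample(2:6, 1)))
    ti <- ti[c(TRUE, diff(ti) > 100)]
    ri <- ri[c(TRUE, diff(ri) > 100)]
    m <- match_annotations(qrs_annotation(ti, 1000),
                           qrs_annotation(ri, 1000), 50)
    expect_identical(unname(m[["tp"]]), brute_tp(ti, ri, 50))
    expect_identical(m[["tp"]] + m[["fp"]], length(ti))
    expect_identical(m[["tp"]] + m[["fn"]], length(ri))
    # symmetry: swapping roles swaps fp/fn
    m2 <- match_annotations(qrs_annotation(ri, 1000),
                            qrs_annotation(ti, 1000), 50)
    expect_identical(m[["tp"]], m2[["tp"]])
    expect_identical(m[["fp"]], m2[["fn"]])
  }
})

test_that("mean F1 degrades monotonically with added noise", {
  set.seed(21)
  sigmas <- c(0, 0.3, 1.2)
  mean_f1 <- vapply(sigmas, function(s) {
    f1s <- c()
    for (k in 1:5) {
      ce <- clean_ecg(80, duration_s = 8, seed = 30 + k)
      x <- ce$x + stats::rnorm(length(ce$x), 0, s)
      for (m in qrs_detectors()) {
        f1s <- c(f1s, f1_of(detect_qrs(x, 1000, m, "maternal"), ce$beats))
      }
    }
    mean(f1s)
  }, numeric(1))
  expect_true(all(diff(mean_f1) <= 1e-9))
})
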