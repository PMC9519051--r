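test_that("LoG detection finds planted nuclei and ignores blank noise", {
  blank <- matrix(rnorm(120 * 120, 20, 3), 120)
  expect_equal(nrow(detect_nuclei(blank)), 0)
  expect_error(detect_nuclei(matrix(numeric(0), 0, 0)), "empty")

  # 10 planted Gaussian nuclei at SNR 10: all found within 1 px
  mv <- small_movie(seed = 5, n_nuclei = 10, n_responders = 0,
                    amp_range = c(30, 30), noise_sd = 3)
  det <- detect_nuclei(mv)
  expect_equal(nrow(det), 10)
  m <- match_rois(det, mv$rois, max_dist = 1)
  expect_equal(nrow(m), 10)

  # protocol-density field: recall >= 0.95
  big <- simulate_calcium_movie(n_nuclei = 420, n_responders = 0, seed = 6,
                                recovery_s = 2, baseline_s = 2.5,
                                stim_s = 0.5)
  detb <- detect_nuclei(big)
  mb <- match_rois(detb, big$rois, max_dist = 2)
  expect_gte(nrow(mb) / 420, 0.95)
})

test_that("frame registration recovers planted translations", {
  mv0 <- small_movie(seed = 7, n_nuclei = 20, n_responders = 0,
                     drift_px = c(0, 0))
  tf0 <- register_frames(mv0)
  expect_lt(max(abs(c(tf0$dy_px, tf0$dx_px))), 0.3)

  mv <- small_movie(seed = 7, n_nuclei = 20, n_responders = 0,
                    drift_px = c(3, 0))
  tf <- register_frames(mv)
  last <- tf[nrow(tf), ]
  expect_lt(abs(last$dy_px - 3), 0.5)
  expect_lt(abs(last$dx_px - 0), 0.5)
  # registered ROI jitter (residual) well below the raw planted drift
  resid <- sqrt((tf$dy_px - mv$drift$dy_px)^2 + (tf$dx_px - mv$drift$dx_px)^2)
  raw <- sqrt(mv$drift$dy_px^2 + mv$drift$dx_px^2)
  expect_lt(sqrt(mean(resid^2)), 0.5)
  expect_lt(sqrt(mean(resid^2)), sqrt(mean(raw^2)))

  flat <- array(1, c(12, 2, 20, 20))
  expect_error(register_frames(flat), "flat")
})

test_that("trace extraction normalises the baseline window to exactly 1", {
  mv <- small_movie(seed = 8, n_nuclei = 15, n_responders = 3)
  tr <- extract_traces(mv, mv$rois)
  bm <- tr |>
    dplyr::filter(window == "baseline") |>
    dplyr::group_by(roi) |>
    dplyr::summarise(m = mean(dRR))
  expect_true(all(abs(bm$m - 1) < 1e-9))
  expect_true(all(tr$signal >= 0 & tr$reference >= 0))

  # identical channels give dRR identically 1
  arr <- array(0, c(12, 2, 40, 40))
  base <- matrix(rnorm(1600, 100, 5), 40)
  for (f in 1:12) { arr[f, 1, , ] <- base; arr[f, 2, , ] <- base }
  rois <- tibble::tibble(id = 1L, y_px = 20, x_px = 20, radius_px = 3)
  tid <- extract_traces(arr, rois, baseline = 1:6, stimulus = 7:9)
  expect_true(all(abs(tid$dRR - 1) < 1e-12))

  # signal doubling during the stimulus gives dRR ~= 2
  arr2 <- arr
  for (f in 7:9) arr2[f, 1, , ] <- 2 * base
  td <- extract_traces(arr2, rois, baseline = 1:6, stimulus = 7:9)
  expect_equal(mean(td$dRR[td$window == "stimulus"]), 2, tolerance = 1e-9)

  expect_error(extract_traces(arr, rois, baseline = 1:6, stimulus = 5:8),
               "disjoint")
  expect_error(extract_traces(arr, rois, baseline = 1:6, stimulus = 20:22),
               "within")
  out <- tibble::tibble(id = 1L, y_px = 2, x_px = 2, radius_px = 3)
  expect_error(extract_traces(arr, out, baseline = 1:6, stimulus = 7:9),
               "outside")
})

test_that("ratiometric traces cancel common per-frame gain", {
  mv <- small_movie(seed = 9, n_nuclei = 10, n_responders = 2)
  gains <- runif(dim(mv$movie)[1], 0.5, 1.5)
  scaled <- mv
  for (f in seq_along(gains)) {
    scaled$movie[f, , , ] <- mv$movie[f, , , ] * gains[f]
  }
  t0 <- extract_traces(mv, mv$rois)
  t1 <- extract_traces(scaled, scaled$rois)
  expect_equal(t1$dRR, t0$dRR, tolerance = 1e-9)
})

test_that("responder classification implements the k-SD rule", {
  # constructed trace: stimulus level at baseline mean + 4 SD -> responder
  set.seed(1)
  nf <- 30
  base_noise <- rnorm(20, 1, 0.01)
  tr <- tibble::tibble(
    roi = 1L, frame = 1:nf,
    signal = 1, reference = 1, ratio = 1,
    dRR = c(base_noise, rep(mean(base_noise) + 4 * sd(base_noise), 10)),
    window = rep(c("baseline", "stimulus"), c(20, 10))
  )
  attr(tr, "windows") <- list(baseline = 1:20, stimulus = 21:30)
  cl <- classify_responders(tr)
  expect_true(cl$responder)

  # flat noisy trace -> non-responder
  tr2 <- tr
  tr2$dRR <- c(base_noise, rnorm(10, 1, 0.01))
  expect_false(classify_responders(tr2)$responder)

  # exactly flat baseline falls back to any-increase and is flagged
  tr3 <- tr
  tr3$dRR <- c(rep(1, 20), rep(1.2, 10))
  cl3 <- classify_responders(tr3)
  expect_true(cl3$flat_baseline)
  expect_true(cl3$responder)

  short <- tr[tr$frame > 17, ]
  attr(short, "windows") <- list(baseline = 18:20, stimulus = 21:30)
  expect_error(classify_responders(short), "baseline")
})

test_that("end-to-end pipeline recovers planted responders on small movies", {
  for (s in 1:3) {
    mv <- small_movie(seed = s + 20, drift_px = c(2, 1))
    res <- run_calcium_pipeline(mv)
    sc <- responder_score(res, mv)
    expect_gte(sc$precision, 0.95)
    expect_gte(sc$recall, 0.95)
  }
})

test_that("registration improves classification recall under drift", {
  rec <- vapply(1:3, function(s) {
    mv <- small_movie(seed = s + 40, drift_px = c(4, 3))
    with_reg <- responder_score(run_calcium_pipeline(mv, register = TRUE), mv)
    no_reg <- responder_score(run_calcium_pipeline(mv, register = FALSE), mv)
    c(with_reg$recall, no_reg$recall)
  }, numeric(2))
  expect_gt(mean(rec[1, ]), mean(rec[2, ]))
})
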