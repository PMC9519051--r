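test_that("generators are deterministic under a fixed seed", {
  a <- simulate_cohort(4, seed = 11)
  b <- simulate_cohort(4, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(cohort_truth(a), cohort_truth(b))

  e1 <- simulate_escape_trials(5, 10, 0.7, seed = 3)
  e2 <- simulate_escape_trials(5, 10, 0.7, seed = 3)
  expect_identical(e1, e2)

  r1 <- simulate_righting_assay(3, seed = 5)
  r2 <- simulate_righting_assay(3, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  m1 <- small_movie(seed = 7, n_nuclei = 12, n_responders = 2)
  m2 <- small_movie(seed = 7, n_nuclei = 12, n_responders = 2)
  expect_identical(m1$movie, m2$movie)

  mask <- array(1, c(4, 4, 2))
  v1 <- simulate_ratio_volumes(2, mask, seed = 9)
  v2 <- simulate_ratio_volumes(2, mask, seed = 9)
  expect_identical(v1$num, v2$num)

  c1 <- simulate_count_matrix(50, 3, seed = 13)
  c2 <- simulate_count_matrix(50, 3, seed = 13)
  expect_identical(c1$counts, c2$counts)
})

test_that("cohort simulator validates inputs and respects arena bounds", {
  expect_error(simulate_cohort(0), "n_fish")
  expect_error(simulate_cohort(2, arena_mm = -1), "arena")
  expect_error(simulate_cohort(2, depths = 1.4, weights = 1), "depths")
  expect_error(bout_model(turn_rate_baseline = 1.3), "rates")
  expect_error(bout_model(turn_rate_baseline = 0.7, fwd_rate_baseline = 0.6),
               "exceed 1")
  expect_error(bout_model(disp_mean_baseline = NaN), "displacements")

  tr <- simulate_cohort(5, seed = 2)
  expect_true(all(tr$x_mm > -0.1 & tr$x_mm < 10.1))
  expect_true(all(tr$y_mm > -0.1 & tr$y_mm < 10.1))
  expect_setequal(unique(tr$phase), c("baseline", "post"))
})

test_that("depth-0 cohorts keep post-stimulus speed at the baseline level", {
  tr <- simulate_cohort(50, seed = 21, depths = 0, weights = 1)
  ep <- epoch_speeds(tr)
  st <- arrest_statistic(ep)
  m <- mean(st$normalized_speed)
  sem <- sd(st$normalized_speed) / sqrt(nrow(st))
  expect_lt(abs(m - 1), 2 * sem + 0.02)
  # mean normalised first-epoch speed stays in [0.9, 1.1] at n >= 50
  expect_gt(m, 0.9)
  expect_lt(m, 1.1)
})

test_that("increasing arrest depth strictly decreases first-epoch speed", {
  speeds <- vapply(c(0, 0.3, 0.6, 0.9), function(d) {
    tr <- simulate_cohort(40, seed = 31, depths = d, weights = 1)
    st <- arrest_statistic(epoch_speeds(tr))
    mean(st$normalized_speed)
  }, numeric(1))
  expect_true(all(diff(speeds) < 0))
})

test_that("escape-trial simulation hits degenerate probabilities exactly", {
  all_resp <- simulate_escape_trials(4, 10, p_respond = 1, seed = 1)
  expect_equal(responsiveness(all_resp)$percent, 100)
  none <- simulate_escape_trials(4, 10, p_respond = 0, seed = 1)
  expect_equal(responsiveness(none)$percent, 0)
  expect_true(all(is.na(none$latency_ms)))
  expect_error(simulate_escape_trials(4, 0, 0.5), "n_trials")
  expect_error(simulate_escape_trials(4, 5, 1.5), "p_respond")
})

test_that("righting series are monotone and enumerate epoch ends correctly", {
  ri <- simulate_righting_assay(1, 5, latencies = c(0.3, 0.7, 1.2, 1.2, 1.9))
  expect_true(all(diff(ri$n_unbalanced) <= 0))
  # last fish (1.9 s) balances by the end of epoch 4 (2.0 s)
  expect_equal(time_to_balanced(ri)$t_balanced_s, 2.0)

  zero <- simulate_righting_assay(1, 5, latencies = rep(0, 5))
  expect_equal(time_to_balanced(zero)$t_balanced_s, 0.5)

  never <- simulate_righting_assay(1, 5, latencies = c(0.2, 0.4, 0.6, 1, 20))
  tb <- time_to_balanced(never)
  expect_equal(tb$t_balanced_s, 15)
  expect_true(tb$censored)

  many <- simulate_righting_assay(20, 5, seed = 8)
  grp <- dplyr::group_by(many, group)
  expect_true(all(dplyr::summarise(grp, ok = all(diff(n_unbalanced) <= 0))$ok))
})

test_that("count simulator plants fold changes and depth factors as stated", {
  sim <- simulate_count_matrix(300, 6, planted = data.frame(gene = 7,
                                                            log2fc = 9),
                               dispersion = 0.01, seed = 4)
  cnt <- sim$counts
  tgt <- sim$groups$group == "target"
  lfc <- log2(mean(cnt[7, tgt]) / mean(cnt[7, !tgt]))
  expect_lt(abs(lfc - 9), 0.5)

  # non-planted genes share means across groups
  other <- cnt[-7, ]
  rel <- rowMeans(other[, tgt]) / rowMeans(other[, !tgt])
  expect_lt(abs(median(rel, na.rm = TRUE) - 1), 0.1)

  dep <- simulate_count_matrix(2000, n_per_group = 1,
                               depth_factors = c(1, 2), dispersion = 0.01,
                               seed = 5)
  libs <- colSums(dep$counts)
  expect_lt(abs(libs[2] / libs[1] - 2), 0.15)

  expect_error(simulate_count_matrix(10, 2, dispersion = -1), "dispersion")
  expect_error(simulate_count_matrix(10, 2,
                                     planted = data.frame(gene = 99,
                                                          log2fc = 2)),
               "gene set")
})

test_that("ratio-volume simulator realises the planted masked effect", {
  mask <- array(0, c(8, 8, 3)); mask[3:6, 3:6, 2] <- 1
  null <- simulate_ratio_volumes(6, mask, effect = 1, noise_sd = 0.02,
                                 seed = 6)
  mr0 <- group_masked_ratios(null, mask)
  diff0 <- mean(mr0$masked_mean[mr0$group == "treated"]) -
    mean(mr0$masked_mean[mr0$group == "control"])
  expect_lt(abs(diff0), 0.05)

  eff <- simulate_ratio_volumes(6, mask, effect = 1.5, noise_sd = 0.02,
                                seed = 6)
  mr1 <- group_masked_ratios(eff, mask)
  diff1 <- mean(mr1$masked_mean[mr1$group == "treated"]) -
    mean(mr1$masked_mean[mr1$group == "control"])
  expect_lt(abs(diff1 - 0.5), 0.05)

  expect_error(simulate_ratio_volumes(2, array(0, c(2, 2, 2))), "mask")
  expect_error(simulate_ratio_volumes(2, mask, effect = -2), "effect")
})

test_that("calcium movie honours the indicator peak lag and drift bookkeeping", {
  tt <- seq(0, 10, by = 0.001)
  peak <- tt[which.max(gcamp_kernel(tt))]
  expect_lt(abs(peak - 1.1), 0.05)

  mv <- small_movie(seed = 2, n_nuclei = 12, n_responders = 0,
                    drift_px = c(3, 0))
  expect_equal(mv$drift$dy_px[nrow(mv$drift)], 3)
  expect_equal(mv$drift$dx_px[nrow(mv$drift)], 0)
  expect_error(simulate_calcium_movie(n_nuclei = 100, n_responders = 1,
                                      side_px = 30),
               "density")
  expect_error(simulate_calcium_movie(n_nuclei = 5, n_responders = 9),
               "n_responders")

  # no responders: stimulus-window dRR stays statistically flat
  tr <- extract_traces(mv, mv$rois, transforms = register_frames(mv))
  cl <- classify_responders(tr)
  expect_lt(mean(abs(cl$stim_stat - 1)), 0.02)
})
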