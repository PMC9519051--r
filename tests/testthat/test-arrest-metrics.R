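test_that("epoch speeds match hand-derived constant-motion values", {
  pr <- stim_protocol()
  # stationary fish: all epoch speeds zero
  still <- straight_trajectory(0, pr)
  ep0 <- epoch_speeds(still, pr, smooth_window = 1)
  expect_true(all(ep0$speed_mm_s == 0))

  # constant 2 mm/s: 0.1-mm steps at 20 Hz; the first epoch of each phase
  # has 99 within-epoch steps (9.9 mm / 5 s = 1.98), later epochs 100
  tr <- straight_trajectory(2, pr)
  ep <- epoch_speeds(tr, pr, smooth_window = 1)
  firsts <- ep$speed_mm_s[ep$epoch == 1]
  expect_equal(firsts, rep(1.98, 2), tolerance = 1e-9)
  later <- ep$speed_mm_s[ep$epoch > 1]
  expect_equal(later, rep(2, length(later)), tolerance = 1e-9)
  expect_equal(unique(ep$baseline_mean),
               mean(ep$speed_mm_s[ep$phase == "baseline"]))
})

test_that("epoch speeds equal a brute-force distance sum on random cohorts", {
  pr <- stim_protocol(baseline_dur = 20, recovery_dur = 30)
  for (s in 1:5) {
    tr <- simulate_cohort(3, pr, seed = s)
    ep <- epoch_speeds(tr, pr, smooth_window = 1)
    bf <- brute_force_epoch_speed(tr, pr)
    j <- dplyr::inner_join(ep, bf, by = c("fish_id", "phase", "epoch"))
    expect_equal(j$speed_mm_s, j$speed, tolerance = 1e-9)
  }
})

test_that("epoch_speeds rejects malformed trajectories", {
  pr <- stim_protocol()
  tr <- straight_trajectory(1, pr)
  bad <- tr; bad$t_s[5] <- bad$t_s[4]
  expect_error(epoch_speeds(bad, pr), "increasing")
  nonfin <- tr; nonfin$x_mm[2] <- Inf
  expect_error(epoch_speeds(nonfin, pr), "finite")
  expect_error(epoch_speeds(tr[0, ], NULL), "protocol")
})

test_that("cohort filtering applies the threshold and optional band", {
  fake <- tibble::tibble(fish_id = 1:4, phase = "baseline", epoch = 1,
                         speed_mm_s = c(0.4, 2.5, 1, 3.5),
                         baseline_mean = c(0.4, 2.5, 1, 3.5))
  part <- filter_cohort(fake)
  expect_equal(part$retained, c(FALSE, TRUE, TRUE, TRUE))
  expect_match(part$reason[1], "0.5")

  banded <- filter_cohort(fake, band = c(2, 3))
  expect_equal(banded$retained, c(FALSE, TRUE, FALSE, FALSE))

  expect_warning(filter_cohort(fake[1, ]), "retained")
  expect_error(filter_cohort(fake[0, ]), "empty")
})

make_epochs <- function(baseline_speeds, post_speeds,
                        protocol = stim_protocol()) {
  out <- dplyr::bind_rows(
    tibble::tibble(fish_id = 1L, phase = "baseline",
                   epoch = seq_along(baseline_speeds),
                   speed_mm_s = baseline_speeds),
    tibble::tibble(fish_id = 1L, phase = "post",
                   epoch = seq_along(post_speeds),
                   speed_mm_s = post_speeds)
  )
  out$baseline_mean <- mean(baseline_speeds)
  attr(out, "protocol") <- protocol
  out
}

test_that("arrest statistic follows the baseline-vs-first-epoch definition", {
  st <- arrest_statistic(make_epochs(c(2, 2), c(2, 2, 2)))
  expect_equal(st$delta_speed, 0)

  st2 <- arrest_statistic(make_epochs(c(2, 2), c(1, 2, 2)))
  expect_equal(st2$delta_speed, -1)
  expect_equal(st2$normalized_speed, 0.5)

  st3 <- arrest_statistic(make_epochs(c(0.4, 0.4), c(0.2, 0.4)))
  expect_true(st3$excluded)
  expect_equal(st3$delta_speed, -0.2)

  expect_error(
    arrest_statistic(dplyr::filter(make_epochs(c(2, 2), c(1, 1)),
                                   phase == "baseline")),
    "post")
})

test_that("half-recovery time follows the epoch convention and censors", {
  # immediate recovery: first epoch already at baseline -> 5 s
  expect_equal(half_recovery_time(make_epochs(c(2, 2), c(2, 2)))$t_half_s, 5)

  # baseline 2, post (0.5, 0.8, 1.2, ...): third epoch is first >= 1 -> 15 s
  ep2 <- make_epochs(c(2, 2), c(0.5, 0.8, 1.2, 1.5))
  expect_equal(half_recovery_time(ep2)$t_half_s, 15)

  # never recovering: censored exactly at 210 s
  hr3 <- half_recovery_time(make_epochs(c(2, 2), rep(0.5, 42)))
  expect_equal(hr3$t_half_s, 210)
  expect_true(hr3$censored)

  # group-mean variant returns a single cohort-level row
  g <- half_recovery_time(ep2, method = "group_mean")
  expect_equal(nrow(g), 1)
  expect_equal(g$t_half_s, 15)

  expect_error(half_recovery_time(make_epochs(c(0, 0), c(1, 1))),
               "baseline_mean")
})

test_that("censoring fraction grows with simulated non-recovery probability", {
  frac <- vapply(c(0, 0.5, 1), function(p) {
    tr <- simulate_cohort(15, stim_protocol(baseline_dur = 30),
                          recovery = recovery_model(nonrecovery_prob = p),
                          seed = 41, depths = 1, weights = 1)
    hr <- half_recovery_time(epoch_speeds(tr))
    expect_true(all(hr$t_half_s <= 210))
    mean(hr$censored)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_equal(frac[3], 1)
})

test_that("half-recovery tracks known latencies within one epoch", {
  # the estimator reads out on a 5-s grid at the first epoch that is mostly
  # recovered, so per-fish estimates sit 0 to ~7.5 s above the true latency
  # (one epoch plus the within-epoch crossing margin); on average the median
  # estimate stays within one epoch of the true median latency
  meds <- vapply(1:8, function(s) {
    tr <- simulate_cohort(20, stim_protocol(baseline_dur = 30),
                          recovery = recovery_model(latency_median = 16),
                          seed = s + 60, depths = 1, weights = 1)
    hr <- half_recovery_time(epoch_speeds(tr))
    median(hr$t_half_s) - median(cohort_truth(tr)$latency_s)
  }, numeric(1))
  expect_true(all(meds > -1e-9))
  expect_true(all(meds <= 10))   # epoch grid + crossing margin + cohort noise
  expect_lte(mean(abs(meds)), 5)
})

test_that("path angles use the four-quadrant arctangent in degrees", {
  pr <- stim_protocol()
  px <- straight_trajectory(2, pr, heading_deg = 0)
  a <- path_angles(px, smooth_window = 1)
  expect_true(all(abs(a$angle_deg) < 1e-9))

  py <- straight_trajectory(2, pr, heading_deg = 90)
  ay <- path_angles(py, smooth_window = 1)
  expect_true(all(abs(ay$angle_deg - 90) < 1e-9))

  p45 <- straight_trajectory(2, pr, heading_deg = 45)
  a45 <- path_angles(p45, smooth_window = 1)
  expect_true(all(abs(a45$angle_deg - 45) < 1e-9))
  st <- path_straightness(a45)
  expect_true(all(st$circ_sd_deg < 1e-6))

  # zero-length steps are skipped, not errors
  still <- straight_trajectory(0, pr)
  expect_equal(nrow(path_angles(still, smooth_window = 1)), 0)
})
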