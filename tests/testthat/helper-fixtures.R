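# trajectory builders used across the suite --------------------------------

# straight-line motion at constant speed (mm/s), 20 Hz, baseline+post phases
straight_trajectory <- function(speed, protocol = stim_protocol(),
                                hz = 20, heading_deg = 0, fish_id = 1L) {
  post_start <- protocol$baseline_dur + protocol$stim_dur + protocol$post_gap
  t_base <- seq(0, protocol$baseline_dur - 1 / hz, by = 1 / hz)
  t_post <- seq(post_start, post_start + protocol$recovery_dur - 1 / hz,
                by = 1 / hz)
  t_s <- c(t_base, t_post)
  step <- speed / hz
  th <- heading_deg * pi / 180
  tibble::tibble(
    fish_id = fish_id, t_s = t_s,
    x_mm = step * seq_along(t_s) * cos(th),
    y_mm = step * seq_along(t_s) * sin(th),
    phase = rep(c("baseline", "post"), c(length(t_base), length(t_post)))
  )
}

# trajectory with per-epoch target speeds: moves the required distance within
# each 5-s epoch along +x, evenly over samples
epoch_speed_trajectory <- function(baseline_speeds, post_speeds,
                                   protocol = stim_protocol(
                                     baseline_dur = 5 * length(baseline_speeds),
                                     recovery_dur = 210),
                                   hz = 20) {
  ep <- protocol$epoch_len
  post_start <- protocol$baseline_dur + protocol$stim_dur + protocol$post_gap
  build <- function(speeds, t0) {
    n_per <- ep * hz
    t_s <- t0 + seq(0, length(speeds) * ep - 1 / hz, by = 1 / hz)
    steps <- rep(speeds / hz, each = n_per)
    tibble::tibble(t_s = t_s, x_mm = cumsum(steps))
  }
  n_post_ep <- floor(protocol$recovery_dur / ep)
  post_speeds <- c(post_speeds, rep(0, max(0, n_post_ep - length(post_speeds))))
  base <- build(baseline_speeds, 0)
  post <- build(post_speeds, post_start)
  post$x_mm <- post$x_mm + max(base$x_mm)
  out <- dplyr::bind_rows(
    dplyr::mutate(base, phase = "baseline"),
    dplyr::mutate(post, phase = "post")
  ) |>
    dplyr::mutate(fish_id = 1L, y_mm = 0, .before = 1)
  attr(out, "protocol") <- protocol
  out
}

# brute-force per-epoch speed: loop over samples, no vectorised shortcuts
brute_force_epoch_speed <- function(traj, protocol) {
  ep <- protocol$epoch_len
  post_start <- protocol$baseline_dur + protocol$stim_dur + protocol$post_gap
  out <- list()
  for (fid in unique(traj$fish_id)) {
    for (ph in unique(traj$phase)) {
      d <- traj[traj$fish_id == fid & traj$phase == ph, ]
      d <- d[order(d$t_s), ]
      if (nrow(d) < 2) next
      t0 <- if (ph == "baseline") 0 else post_start
      n_ep <- if (ph == "baseline") floor(protocol$baseline_dur / ep) else
        floor(protocol$recovery_dur / ep)
      acc <- numeric(n_ep)
      for (i in 2:nrow(d)) {
        k <- floor((d$t_s[i] - t0) / ep) + 1
        if (k >= 1 && k <= n_ep) {
          acc[k] <- acc[k] + sqrt((d$x_mm[i] - d$x_mm[i - 1])^2 +
                                    (d$y_mm[i] - d$y_mm[i - 1])^2)
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        fish_id = fid, phase = ph, epoch = seq_len(n_ep), speed = acc / ep)
    }
  }
  dplyr::bind_rows(out)
}

# 1000-Hz trace with movement bursts at given onsets (s): each burst moves
# `disp` mm over `dur` s with a raised-cosine profile along `angle_deg`
burst_trace <- function(onsets, disp = 2, dur = 0.15, total = 3,
                        angle_deg = 0, hz = 1000, noise_sd = 0,
                        profile = c("cosine", "square")) {
  profile <- match.arg(profile)
  n <- total * hz
  dx <- numeric(n); dy <- numeric(n)
  m <- round(dur * hz)
  w <- if (profile == "square") rep(1, m) else
    1 - cos(2 * pi * (seq_len(m) - 0.5) / m)
  w <- w / sum(w)
  for (i in seq_along(onsets)) {
    idx <- round(onsets[i] * hz) + seq_len(m)
    a <- angle_deg[(i - 1) %% length(angle_deg) + 1] * pi / 180
    dx[idx] <- disp * w * cos(a)
    dy[idx] <- disp * w * sin(a)
  }
  tibble::tibble(
    fish_id = 1L, t_s = (seq_len(n) - 1) / hz,
    x_mm = 5 + cumsum(dx) + rnorm(n, 0, noise_sd),
    y_mm = 5 + cumsum(dy) + rnorm(n, 0, noise_sd),
    phase = "baseline"
  )
}

# small calcium movie for module tests
small_movie <- function(seed = 1, n_nuclei = 60, n_responders = 6, ...) {
  simulate_calcium_movie(n_nuclei = n_nuclei, n_responders = n_responders,
                         seed = seed, ...)
}

# map predicted responder detections onto truth ids
responder_score <- function(res, mv, max_dist = 2) {
  m <- match_rois(res$rois, mv$rois, max_dist = max_dist)
  pred <- res$responders$roi[res$responders$responder]
  pred_truth <- m$truth_id[match(pred, m$detected_id)]
  truth <- mv$rois$id[mv$rois$responder]
  tp <- length(intersect(pred_truth, truth))
  list(n_pred = length(pred), tp = tp,
       precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = tp / length(truth))
}
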