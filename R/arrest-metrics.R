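#' Per-epoch swim speeds
#'
#' Bins a tracked trajectory into fixed-length epochs and computes, per fish
#' and epoch, the total path distance divided by the epoch length (mm/s).
#' Positions are optionally smoothed with a centred moving average before
#' distances are taken (tracking jitter otherwise inflates apparent movement,
#' especially in stationary fish). Baseline epochs are aligned to the start
#' of the trial; post-stimulus epochs are aligned to `post_gap` after
#' stimulus offset. Incomplete trailing epochs are dropped. A step between
#' consecutive samples is assigned to the epoch containing its ending sample.
#'
#' @param trajectory Tibble with `fish_id`, `t_s`, `x_mm`, `y_mm`, `phase`
#'   (as produced by [simulate_cohort()] or read with [read_trajectory()]).
#' @param protocol A [stim_protocol()]; defaults to the one attached to the
#'   trajectory.
#' @param smooth_window Moving-average window in samples (1 = no smoothing).
#' @param baseline_window Trailing window of the baseline over which
#'   `baseline_mean` is computed, seconds.
#'
#' @return A tibble: `fish_id`, `phase`, `epoch`, `t_start`, `t_end` (trial
#'   clock, s), `speed_mm_s`, `baseline_mean` (mm/s, repeated per fish).
#' @export
epoch_speeds <- function(trajectory, protocol = NULL, smooth_window = 5,
                         baseline_window = 60) {
  if (is.null(protocol)) protocol <- attr(trajectory, "protocol")
  if (is.null(protocol)) stop("no protocol supplied or attached", call. = FALSE)
  stopifnot(all(c("fish_id", "t_s", "x_mm", "y_mm", "phase") %in%
                  names(trajectory)))
  if (any(!is.finite(trajectory$x_mm)) || any(!is.finite(trajectory$y_mm))) {
    stop("non-finite coordinates in trajectory", call. = FALSE)
  }

  ep_len <- protocol$epoch_len
  post_start <- stim_offset(protocol) + protocol$post_gap
  n_base_ep <- floor(protocol$baseline_dur / ep_len)
  n_post_ep <- floor(protocol$recovery_dur / ep_len)

  steps <- trajectory |>
    dplyr::group_by(.data$fish_id, .data$phase) |>
    dplyr::group_modify(function(d, key) {
      if (is.unsorted(d$t_s, strictly = TRUE)) {
        stop("timestamps must be strictly increasing within fish and phase",
             call. = FALSE)
      }
      if (nrow(d) >= 3) {
        est_hz <- 1 / stats::median(diff(d$t_s))
        if (est_hz < 2) stop("sampling rate must be >= 2 Hz", call. = FALSE)
      }
      x <- smooth_ma(d$x_mm, smooth_window)
      y <- smooth_ma(d$y_mm, smooth_window)
      ok <- !is.na(x)
      x <- x[ok]; y <- y[ok]; t_s <- d$t_s[ok]
      if (length(x) < 2) return(tibble::tibble(t_s = numeric(),
                                               step = numeric()))
      tibble::tibble(t_s = t_s[-1],
                     step = sqrt(diff(x)^2 + diff(y)^2))
    }) |>
    dplyr::ungroup()

  steps <- steps |>
    dplyr::mutate(
      epoch = dplyr::if_else(
        .data$phase == "baseline",
        floor(.data$t_s / ep_len) + 1,
        floor((.data$t_s - post_start) / ep_len) + 1
      )
    ) |>
    dplyr::filter(
      (.data$phase == "baseline" & .data$epoch >= 1 &
         .data$epoch <= n_base_ep) |
        (.data$phase == "post" & .data$epoch >= 1 & .data$epoch <= n_post_ep)
    )

  grid <- tidyr::expand_grid(
    fish_id = unique(trajectory$fish_id),
    dplyr::bind_rows(
      tibble::tibble(phase = "baseline", epoch = seq_len(n_base_ep)),
      tibble::tibble(phase = "post", epoch = seq_len(n_post_ep))
    )
  )

  out <- steps |>
    dplyr::group_by(.data$fish_id, .data$phase, .data$epoch) |>
    dplyr::summarise(speed_mm_s = sum(.data$step) / ep_len, .groups = "drop") |>
    dplyr::right_join(grid, by = c("fish_id", "phase", "epoch")) |>
    dplyr::mutate(speed_mm_s = dplyr::coalesce(.data$speed_mm_s, 0)) |>
    dplyr::arrange(.data$fish_id, .data$phase != "baseline", .data$epoch) |>
    dplyr::mutate(
      t_start = dplyr::if_else(.data$phase == "baseline",
                               (.data$epoch - 1) * ep_len,
                               post_start + (.data$epoch - 1) * ep_len),
      t_end = .data$t_start + ep_len
    )

  # drop epochs entirely outside the tracked record (short recordings)
  tmax <- max(trajectory$t_s)
  out <- dplyr::filter(out, .data$t_start < tmax + ep_len)

  base_means <- out |>
    dplyr::filter(.data$phase == "baseline",
                  .data$t_end > protocol$baseline_dur - baseline_window) |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(baseline_mean = mean(.data$speed_mm_s), .groups = "drop")

  out <- dplyr::left_join(out, base_means, by = "fish_id")
  attr(out, "protocol") <- protocol
  out
}

# centred moving average; NA at the edges (dropped by the caller)
smooth_ma <- function(v, window) {
  if (window <= 1) return(v)
  as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
}

#' Partition a cohort by baseline-activity criteria
#'
#' Fish with a baseline mean speed below `min_baseline` (default 0.5 mm/s)
#' are excluded from analysis; optionally, only fish inside a baseline band
#' (e.g. 2-3 mm/s, used when comparing conditions that alter baseline
#' locomotion) are retained.
#'
#' @param epochs Output of [epoch_speeds()] (or any tibble with `fish_id`
#'   and `baseline_mean`).
#' @param min_baseline Exclusion threshold, mm/s.
#' @param band Optional `c(low, high)` baseline band, mm/s.
#'
#' @return One row per fish: `fish_id`, `baseline_mean`, `retained`,
#'   `reason` (`NA` when retained). Warns (does not error) when no fish
#'   survive.
#' @export
filter_cohort <- function(epochs, min_baseline = 0.5, band = NULL) {
  if (nrow(epochs) == 0) stop("empty cohort", call. = FALSE)
  out <- dplyr::distinct(epochs, .data$fish_id, .data$baseline_mean)
  reason <- rep(NA_character_, nrow(out))
  reason[out$baseline_mean < min_baseline] <-
    sprintf("baseline < %g mm/s", min_baseline)
  if (!is.null(band)) {
    off_band <- is.na(reason) &
      (out$baseline_mean < band[1] | out$baseline_mean > band[2])
    reason[off_band] <- sprintf("baseline outside [%g, %g] mm/s",
                                band[1], band[2])
  }
  out$reason <- reason
  out$retained <- is.na(reason)
  if (!any(out$retained)) {
    warning("no fish retained after baseline filtering", call. = FALSE)
  }
  out
}

#' The arrest statistic
#'
#' Behavioural arrest is quantified per fish as the change in speed between
#' the pre-stimulus baseline average and the first epoch of the post-stimulus
#' condition: `delta_speed = first post epoch - baseline_mean` (negative
#' under arrest) and `normalized_speed = first post epoch / baseline_mean`.
#' Fish whose baseline mean falls below the exclusion threshold are flagged
#' but their statistics are still reported.
#'
#' @param epochs Output of [epoch_speeds()].
#' @param min_baseline Exclusion threshold, mm/s.
#'
#' @return One row per fish: `fish_id`, `baseline_mean`, `first_post_speed`,
#'   `delta_speed`, `normalized_speed` (`NA` when `baseline_mean` is 0),
#'   `excluded`, `reason`.
#' @export
arrest_statistic <- function(epochs, min_baseline = 0.5) {
  first_post <- epochs |>
    dplyr::filter(.data$phase == "post") |>
    dplyr::group_by(.data$fish_id)
  if (nrow(dplyr::summarise(first_post, .groups = "drop")) == 0) {
    stop("no post-stimulus epochs", call. = FALSE)
  }
  first_post <- first_post |>
    dplyr::slice_min(.data$epoch, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("fish_id", first_post_speed = "speed_mm_s")

  base <- dplyr::distinct(epochs, .data$fish_id, .data$baseline_mean)
  dplyr::left_join(base, first_post, by = "fish_id") |>
    dplyr::mutate(
      delta_speed = .data$first_post_speed - .data$baseline_mean,
      normalized_speed = dplyr::if_else(
        .data$baseline_mean > 0,
        .data$first_post_speed / .data$baseline_mean, NA_real_),
      excluded = .data$baseline_mean < min_baseline,
      reason = dplyr::if_else(.data$excluded,
                              sprintf("baseline < %g mm/s", min_baseline),
                              NA_character_)
    )
}

#' Censored half-recovery time
#'
#' The half-recovery time (T0.5) of a fish is the end time, relative to
#' stimulus offset and on the epoch grid, of the first post-stimulus epoch
#' whose speed reaches half the baseline mean. Fish that never reach half
#' baseline within the recovery window are censored at the window end
#' (210 s under the default protocol).
#'
#' @param epochs Output of [epoch_speeds()].
#' @param protocol A [stim_protocol()]; defaults to the attached one.
#' @param method `"per_fish"` (default) estimates T0.5 for each fish;
#'   `"group_mean"` first averages normalised speed across fish per epoch
#'   and returns a single cohort-level estimate.
#'
#' @return A tibble: `fish_id` (`NA` for `"group_mean"`), `t_half_s`,
#'   `censored`, `method`.
#' @export
half_recovery_time <- function(epochs, protocol = NULL,
                               method = c("per_fish", "group_mean")) {
  method <- match.arg(method)
  if (is.null(protocol)) protocol <- attr(epochs, "protocol")
  if (is.null(protocol)) stop("no protocol supplied or attached", call. = FALSE)
  ep_len <- protocol$epoch_len
  cens <- protocol$recovery_dur

  post <- dplyr::filter(epochs, .data$phase == "post")
  if (any(post$baseline_mean == 0)) {
    stop("baseline_mean is 0 for at least one fish; T0.5 undefined",
         call. = FALSE)
  }

  if (method == "group_mean") {
    curve <- post |>
      dplyr::mutate(norm = .data$speed_mm_s / .data$baseline_mean) |>
      dplyr::group_by(.data$epoch) |>
      dplyr::summarise(norm = mean(.data$norm), .groups = "drop") |>
      dplyr::arrange(.data$epoch)
    hit <- which(curve$norm >= 0.5)
    t_half <- if (length(hit)) curve$epoch[hit[1]] * ep_len else cens
    return(tibble::tibble(fish_id = NA_integer_, t_half_s = t_half,
                          censored = length(hit) == 0, method = method))
  }

  post |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::arrange(.data$epoch, .by_group = TRUE) |>
    dplyr::summarise(
      hit = list(which(.data$speed_mm_s >= 0.5 * .data$baseline_mean[1])),
      first = dplyr::first(.data$epoch),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      censored = purrr::map_lgl(.data$hit, ~ length(.x) == 0),
      t_half_s = purrr::map2_dbl(.data$hit, .data$first, function(h, f) {
        if (length(h) == 0) cens else (f + h[1] - 1) * ep_len
      }),
      method = method
    ) |>
    dplyr::select("fish_id", "t_half_s", "censored", "method")
}

#' Per-step heading angles
#'
#' The heading of each displacement vector between consecutive (smoothed)
#' positions, as the four-quadrant arctangent of `(dy, dx)` in degrees.
#' Zero-length steps are skipped.
#'
#' @param trajectory Trajectory tibble (see [epoch_speeds()]).
#' @param smooth_window Moving-average window in samples.
#' @return A tibble: `fish_id`, `phase`, `t_s` (end of step), `angle_deg`
#'   in `(-180, 180]`.
#' @export
path_angles <- function(trajectory, smooth_window = 5) {
  trajectory |>
    dplyr::group_by(.data$fish_id, .data$phase) |>
    dplyr::group_modify(function(d, key) {
      x <- smooth_ma(d$x_mm, smooth_window)
      y <- smooth_ma(d$y_mm, smooth_window)
      ok <- !is.na(x)
      x <- x[ok]; y <- y[ok]; t_s <- d$t_s[ok]
      if (length(x) < 2) {
        return(tibble::tibble(t_s = numeric(), angle_deg = numeric()))
      }
      dx <- diff(x); dy <- diff(y)
      nz <- dx != 0 | dy != 0
      tibble::tibble(t_s = t_s[-1][nz],
                     angle_deg = atan2(dy[nz], dx[nz]) * 180 / pi)
    }) |>
    dplyr::ungroup()
}

#' Path straightness from heading angles
#'
#' Circular standard deviation of heading angles over moving windows of
#' steps; a perfectly straight path has circular SD 0, looping paths have
#' large values.
#'
#' @param angles Output of [path_angles()].
#' @param window Number of consecutive steps per window.
#' @return One row per fish and phase: `fish_id`, `phase`, `circ_sd_deg`
#'   (mean over windows), `n_steps`.
#' @export
path_straightness <- function(angles, window = 20) {
  angles |>
    dplyr::group_by(.data$fish_id, .data$phase) |>
    dplyr::summarise(
      circ_sd_deg = mean_window_circ_sd(.data$angle_deg, window),
      n_steps = dplyr::n(),
      .groups = "drop"
    )
}

# mean over moving windows of the circular SD, degrees
mean_window_circ_sd <- function(angle_deg, window) {
  n <- length(angle_deg)
  if (n == 0) return(NA_real_)
  window <- min(window, n)
  starts <- seq_len(n - window + 1)
  sds <- vapply(starts, function(s) {
    a <- angle_deg[s:(s + window - 1)] * pi / 180
    r <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
    sqrt(pmax(-2 * log(pmax(r, 1e-12)), 0)) * 180 / pi
  }, numeric(1))
  mean(sds)
}
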