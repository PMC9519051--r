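#' Segment a high-speed trajectory into swim bouts
#'
#' Larval swimming is burst-like: discrete bouts separated by quiescence.
#' Bouts are found by hysteresis thresholding of instantaneous speed - a
#' bout starts when speed rises above `speed_on` and ends when it falls
#' below `speed_off` - and annotated with duration, net displacement and
#' net heading change (heading of the last step minus heading of the first
#' step, wrapped to `(-180, 180]`).
#'
#' Instantaneous speed is estimated over a short stride (`speed_dt`,
#' default 10 ms) on smoothed positions, which keeps the speed-noise floor
#' of high-rate tracking well below the hysteresis thresholds. Heading
#' change is measured between the net displacement of the first and last
#' thirds of the bout, so tiny noisy edge steps do not dominate.
#'
#' @param trajectory High-speed trajectory tibble (`fish_id`, `t_s`, `x_mm`,
#'   `y_mm`); sampling rate must be >= 100 Hz.
#' @param speed_on,speed_off Hysteresis thresholds, mm/s (`speed_on >=
#'   speed_off`).
#' @param smooth_window Moving-average window applied to positions first.
#' @param speed_dt Stride over which instantaneous speed is estimated,
#'   seconds.
#' @param turn_threshold Absolute heading change at or above which a bout is
#'   classified as a turn, degrees.
#'
#' @return A tibble of bout events: `fish_id`, `onset_s`, `duration_s`,
#'   `heading_change_deg`, `displacement_mm` (net start-to-end), `type`
#'   (`"turn"` / `"forward"`).
#' @export
segment_bouts <- function(trajectory, speed_on = 4, speed_off = 1,
                          smooth_window = 5, speed_dt = 0.01,
                          turn_threshold = 30) {
  if (speed_off > speed_on) {
    stop("speed_off must not exceed speed_on", call. = FALSE)
  }
  trajectory |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::group_modify(function(d, key) {
      dt <- stats::median(diff(d$t_s))
      if (1 / dt < 100) stop("sampling rate must be >= 100 Hz", call. = FALSE)
      x <- smooth_ma(d$x_mm, smooth_window)
      y <- smooth_ma(d$y_mm, smooth_window)
      ok <- !is.na(x)
      x <- x[ok]; y <- y[ok]; t_s <- d$t_s[ok]
      n <- length(x)
      if (n < 3) return(empty_bouts())

      stride <- max(1L, round(speed_dt / dt))
      ns <- n - stride
      if (ns < 1) return(empty_bouts())
      speed <- sqrt((x[1:ns + stride] - x[1:ns])^2 +
                      (y[1:ns + stride] - y[1:ns])^2) / (stride * dt)

      state <- hysteresis_state(speed, speed_on, speed_off)
      d_on <- diff(c(FALSE, state))
      starts <- which(d_on == 1)
      ends <- which(d_on == -1) - 1 + stride   # speed interval covers +stride
      if (length(ends) < length(starts)) ends <- c(ends, n)
      ends <- pmin(ends, n)
      if (length(starts) == 0) return(empty_bouts())

      purrr::map2(starts, ends, function(s, e) {
        third <- max(1, floor((e - s) / 3))
        a0 <- atan2(y[s + third] - y[s], x[s + third] - x[s])
        a1 <- atan2(y[e] - y[e - third], x[e] - x[e - third])
        still <- (y[s + third] == y[s] && x[s + third] == x[s]) ||
          (y[e] == y[e - third] && x[e] == x[e - third])
        tibble::tibble(
          onset_s = t_s[s],
          duration_s = (e - s) * dt,
          heading_change_deg = if (still) 0 else wrap_deg((a1 - a0) * 180 / pi),
          displacement_mm = sqrt((x[e] - x[s])^2 + (y[e] - y[s])^2)
        )
      }) |>
        dplyr::bind_rows()
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(type = classify_bouts(.data$heading_change_deg,
                                        turn_threshold))
}

empty_bouts <- function() {
  tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                 heading_change_deg = numeric(), displacement_mm = numeric())
}

# TRUE while in a bout; enters above `on`, leaves below `off`
hysteresis_state <- function(speed, on, off) {
  state <- logical(length(speed))
  active <- FALSE
  for (i in seq_along(speed)) {
    if (!active && speed[i] > on) active <- TRUE
    else if (active && speed[i] < off) active <- FALSE
    state[i] <- active
  }
  state
}

wrap_deg <- function(a) ((a + 180) %% 360) - 180

#' Classify bouts as turns or forward swims
#'
#' A bout is a turn when its absolute net heading change is at or above the
#' threshold (ties count as turns), otherwise a forward swim. The threshold
#' is a configurable convention of this pipeline, not a measured quantity.
#'
#' @param heading_change_deg Signed net heading change, degrees.
#' @param turn_threshold Threshold, degrees (default 30).
#' @return Character vector, `"turn"` or `"forward"`.
#' @examples
#' classify_bouts(c(5, 60, -30))
#' @export
classify_bouts <- function(heading_change_deg, turn_threshold = 30) {
  as.character(ifelse(abs(heading_change_deg) >= turn_threshold,
                      "turn", "forward"))
}

#' Bout-initiation frequency per 400-ms epoch
#'
#' The percentage of epochs whose *first* bout is of each type. Each epoch
#' contributes at most one bout, so the turn and forward percentages sum to
#' at most 100%.
#'
#' @param bouts Output of [segment_bouts()].
#' @param epoch_len Epoch length, seconds (default 0.4).
#' @param window `c(start, end)` observation window in seconds; defaults to
#'   `c(0, max onset)` rounded up to a whole epoch.
#'
#' @return One row per fish and bout type (`turn`, `forward`):
#'   `fish_id`, `type`, `n_epochs`, `n_initiated`, `percent`.
#' @export
initiation_frequency <- function(bouts, epoch_len = 0.4, window = NULL) {
  if (is.null(window)) {
    end <- if (nrow(bouts)) max(bouts$onset_s) else 0
    window <- c(0, ceiling(end / epoch_len + 1e-9) * epoch_len)
  }
  n_epochs <- floor((window[2] - window[1]) / epoch_len + 1e-9)
  if (n_epochs < 1) stop("empty observation window", call. = FALSE)

  fish <- unique(bouts$fish_id)
  if (length(fish) == 0) fish <- NA_integer_

  firsts <- bouts |>
    dplyr::filter(.data$onset_s >= window[1], .data$onset_s < window[2]) |>
    dplyr::mutate(epoch = floor((.data$onset_s - window[1]) / epoch_len)) |>
    dplyr::group_by(.data$fish_id, .data$epoch) |>
    dplyr::slice_min(.data$onset_s, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::count(.data$fish_id, .data$type, name = "n_initiated")

  tidyr::expand_grid(fish_id = fish, type = c("turn", "forward")) |>
    dplyr::left_join(firsts, by = c("fish_id", "type")) |>
    dplyr::mutate(
      n_epochs = n_epochs,
      n_initiated = dplyr::coalesce(.data$n_initiated, 0L),
      percent = 100 * .data$n_initiated / n_epochs
    ) |>
    dplyr::select("fish_id", "type", "n_epochs", "n_initiated", "percent")
}
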