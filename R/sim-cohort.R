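#' Simulate a tracked cohort through the arrest assay
#'
#' Generates bout-structured 2-D trajectories for a cohort of larvae run
#' through a [stim_protocol()]: a tracked baseline, an un-tracked stimulus
#' train plus post-stimulus gap, and a tracked recovery window. Each fish
#' draws an arrest depth from a mixture (heterogeneous sensitivity: immobile,
#' speed-reduced, and unresponsive individuals) and an abrupt recovery
#' latency; during arrest its bout-initiation rates and per-bout displacement
#' are scaled by `sqrt(1 - depth)` so the expected speed is reduced by
#' `depth`.
#'
#' Fish move in a square arena with reflective walls; tracked positions carry
#' isotropic Gaussian jitter (`noise_sd` of the [bout_model()]).
#'
#' @param n_fish Number of fish (>= 1).
#' @param protocol A [stim_protocol()].
#' @param bouts A [bout_model()]. The arrest-state rates/displacement of the
#'   model are additionally scaled by each fish's arrest depth.
#' @param recovery A [recovery_model()].
#' @param seed Integer seed; identical inputs reproduce the table exactly.
#' @param depths,weights Arrest-depth mixture (defaults:
#'   [reference_arrest_config()]).
#' @param hz Sampling rate, Hz (20 for arena tracking; use 1000 for
#'   kinematic analyses).
#' @param arena_mm Side of the square arena, mm.
#'
#' @return A tibble with columns `fish_id`, `t_s`, `x_mm`, `y_mm`, `phase`
#'   (`"baseline"` or `"post"`). Ground truth (per-fish depth and latency) is
#'   attached as attribute `"truth"` and retrieved with [cohort_truth()];
#'   analysis functions never read it.
#' @examples
#' traj <- simulate_cohort(3, seed = 1)
#' cohort_truth(traj)
#' @export
simulate_cohort <- function(n_fish, protocol = stim_protocol(),
                            bouts = bout_model(),
                            recovery = recovery_model(), seed = 1,
                            depths = c(1, 0.5, 0), weights = c(1, 1, 1) / 3,
                            hz = 20, arena_mm = 10) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(bouts, "bout_model"),
            inherits(recovery, "recovery_model"))
  if (n_fish < 1) stop("n_fish must be >= 1", call. = FALSE)
  if (!is.finite(arena_mm) || arena_mm <= 0) {
    stop("arena bounds must be positive", call. = FALSE)
  }
  if (any(depths < 0 | depths > 1)) stop("depths must lie in [0, 1]", call. = FALSE)
  weights <- weights / sum(weights)

  withr::with_seed(seed, {
    truth <- tibble::tibble(
      fish_id = seq_len(n_fish),
      depth = sample(depths, n_fish, replace = TRUE, prob = weights),
      recovers = stats::runif(n_fish) >= recovery$nonrecovery_prob,
      latency_s = stats::rlnorm(n_fish, meanlog = log(recovery$latency_median),
                                sdlog = recovery$latency_sdlog)
    )
    truth$latency_s[!truth$recovers] <- Inf

    traj <- purrr::pmap(truth, function(fish_id, depth, recovers, latency_s) {
      simulate_fish(fish_id, depth, latency_s, protocol, bouts, hz, arena_mm)
    })
    traj <- dplyr::bind_rows(traj)
  })

  attr(traj, "truth") <- truth
  attr(traj, "protocol") <- protocol
  attr(traj, "hz") <- hz
  traj
}

#' Ground truth of a simulated cohort
#'
#' @param x A trajectory tibble from [simulate_cohort()].
#' @return A tibble with `fish_id`, `depth`, `recovers`, `latency_s`.
#' @export
cohort_truth <- function(x) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("no ground truth attached to this object", call. = FALSE)
  truth
}

# one fish; state switches baseline -> arrest at stimulus onset and back to
# baseline at (stimulus offset + latency)
simulate_fish <- function(fish_id, depth, latency_s, protocol, bouts, hz,
                          arena_mm) {
  ep_len <- 0.4                      # bout-initiation epoch
  offset <- stim_offset(protocol)
  total <- offset + protocol$post_gap + protocol$recovery_dur
  n_ep <- ceiling(total / ep_len)
  te <- (seq_len(n_ep) - 1) * ep_len # epoch start times

  arrested <- te >= protocol$baseline_dur & te < offset + latency_s
  scl <- sqrt(1 - depth)             # splits depth between rate and amplitude
  tr <- ifelse(arrested, bouts$turn_rate_arrest * scl, bouts$turn_rate_baseline)
  fr <- ifelse(arrested, bouts$fwd_rate_arrest * scl, bouts$fwd_rate_baseline)
  dm <- ifelse(arrested, bouts$disp_mean_arrest * scl, bouts$disp_mean_baseline)

  u <- stats::runif(n_ep)
  is_turn <- u < tr
  is_fwd <- !is_turn & u < tr + fr
  has_bout <- is_turn | is_fwd
  nb <- sum(has_bout)

  m <- max(2L, round(bouts$bout_dur * hz))   # samples per bout
  n_samp <- ceiling(total * hz)
  dx <- numeric(n_samp)
  dy <- numeric(n_samp)

  if (nb > 0) {
    dtheta <- numeric(nb)
    turn_b <- is_turn[has_bout]
    dtheta[turn_b] <- sample(c(-1, 1), sum(turn_b), replace = TRUE) *
      stats::rnorm(sum(turn_b), bouts$turn_angle_mean, bouts$turn_angle_sd)
    dtheta[!turn_b] <- stats::rnorm(sum(!turn_b), 0, bouts$fwd_angle_sd)
    disp <- stats::rgamma(nb, shape = 4, scale = dm[has_bout] / 4)

    heading0 <- stats::runif(1, 0, 360)
    heading <- heading0 + cumsum(dtheta)
    heading_prev <- c(heading0, heading[-nb])

    w <- 1 - cos(2 * pi * (seq_len(m) - 0.5) / m)   # raised-cosine profile
    w <- w / sum(w)
    cw <- cumsum(w)                                 # heading interpolation

    # n_bouts x m matrices of per-sample directions and step lengths
    dirs <- outer(heading_prev, rep(1, m)) + outer(dtheta, cw)
    steps <- outer(disp, w)
    idx <- outer(floor(te[has_bout] * hz), seq_len(m) - 1, `+`) + 1L
    keep <- idx <= n_samp
    rad <- dirs * pi / 180
    dx[idx[keep]] <- (steps * cos(rad))[keep]
    dy[idx[keep]] <- (steps * sin(rad))[keep]
  }

  x <- reflect_fold(stats::runif(1, 0.1, 0.9) * arena_mm + cumsum(dx), arena_mm)
  y <- reflect_fold(stats::runif(1, 0.1, 0.9) * arena_mm + cumsum(dy), arena_mm)
  t_s <- (seq_len(n_samp) - 1) / hz

  if (bouts$noise_sd > 0) {
    x <- x + stats::rnorm(n_samp, 0, bouts$noise_sd)
    y <- y + stats::rnorm(n_samp, 0, bouts$noise_sd)
  }

  post_start <- offset + protocol$post_gap
  phase <- rep(NA_character_, n_samp)
  phase[t_s < protocol$baseline_dur] <- "baseline"
  phase[t_s >= post_start] <- "post"
  keep <- !is.na(phase)

  tibble::tibble(fish_id = fish_id, t_s = t_s[keep], x_mm = x[keep],
                 y_mm = y[keep], phase = phase[keep])
}

# reflective arena walls: fold positions back into [0, L]
reflect_fold <- function(p, L) {
  m <- p %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}
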