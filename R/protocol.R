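#' Stimulus protocol for the arrest assay
#'
#' Describes the timing of one behavioural trial: a pre-stimulus baseline, a
#' train of vibratory pulses, a short un-tracked gap after stimulus offset
#' (residual water movement makes the fish untrackable), and a recovery
#' window. Locomotion is summarised in fixed-length epochs.
#'
#' The default protocol is the reference assay: a 60-s tracked baseline, 95
#' pulses over 15 s, recording resuming 0.5 s after stimulus offset, a 210-s
#' recovery window, and 5-s epochs.
#'
#' @param baseline_dur Tracked baseline duration, seconds.
#' @param stim_dur Stimulus-train duration, seconds.
#' @param n_pulses Number of pulses in the train.
#' @param amplitude_db Stimulus amplitude, dB re 1 m/s^2.
#' @param post_gap Delay between stimulus offset and the first post-stimulus
#'   sample, seconds.
#' @param recovery_dur Recovery window duration, seconds.
#' @param epoch_len Epoch length for speed summaries, seconds.
#'
#' @return An object of class `stim_protocol` (a named list).
#' @examples
#' stim_protocol()
#' @export
stim_protocol <- function(baseline_dur = 60, stim_dur = 15, n_pulses = 95,
                          amplitude_db = 26, post_gap = 0.5,
                          recovery_dur = 210, epoch_len = 5) {
  durs <- c(baseline_dur = baseline_dur, stim_dur = stim_dur,
            post_gap = post_gap, recovery_dur = recovery_dur,
            epoch_len = epoch_len)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all protocol durations must be finite and > 0", call. = FALSE)
  }
  if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  structure(
    list(baseline_dur = baseline_dur, stim_dur = stim_dur,
         n_pulses = n_pulses, amplitude_db = amplitude_db,
         post_gap = post_gap, recovery_dur = recovery_dur,
         epoch_len = epoch_len),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>\n")
  cat(sprintf("  baseline %g s | %d pulses / %g s @ %g dB | gap %g s | recovery %g s | epochs %g s\n",
              x$baseline_dur, x$n_pulses, x$stim_dur, x$amplitude_db,
              x$post_gap, x$recovery_dur, x$epoch_len))
  invisible(x)
}

# time (s, trial clock) at which the stimulus train ends
stim_offset <- function(protocol) protocol$baseline_dur + protocol$stim_dur

#' Bout-level locomotion model
#'
#' Spontaneous larval swimming is a sequence of discrete bouts - routine
#' turns and slow forward swims - initiated within 400-ms epochs. The model
#' holds per-epoch initiation probabilities and per-bout displacement for
#' the baseline state and for the arrest state, plus heading-change
#' distributions and tracking jitter.
#'
#' Default baseline rates (0.3 + 0.3 initiations per 400-ms epoch) with a
#' 1.7-mm mean displacement give an expected speed of ~2.6 mm/s, inside the
#' 2-3 mm/s band used for between-condition comparisons.
#'
#' @param turn_rate_baseline,fwd_rate_baseline Probability that a turn
#'   (resp. forward swim) is initiated in a 400-ms epoch at baseline.
#' @param turn_rate_arrest,fwd_rate_arrest Same, during arrest.
#' @param disp_mean_baseline,disp_mean_arrest Mean per-bout displacement, mm.
#' @param turn_angle_mean,turn_angle_sd Signed-magnitude heading change of
#'   turns, degrees (location/scale of a normal; sign is random).
#' @param fwd_angle_sd Heading-change scale of forward swims, degrees.
#' @param bout_dur Mean bout duration, seconds.
#' @param noise_sd Isotropic per-sample tracking jitter, mm.
#'
#' @return An object of class `bout_model`.
#' @export
bout_model <- function(turn_rate_baseline = 0.3, fwd_rate_baseline = 0.3,
                       turn_rate_arrest = turn_rate_baseline,
                       fwd_rate_arrest = fwd_rate_baseline,
                       disp_mean_baseline = 1.7,
                       disp_mean_arrest = disp_mean_baseline,
                       turn_angle_mean = 60, turn_angle_sd = 12,
                       fwd_angle_sd = 8, bout_dur = 0.2,
                       noise_sd = 0.01) {
  rates <- c(turn_rate_baseline, fwd_rate_baseline,
             turn_rate_arrest, fwd_rate_arrest)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("bout initiation rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (turn_rate_baseline + fwd_rate_baseline > 1 ||
      turn_rate_arrest + fwd_rate_arrest > 1) {
    stop("turn + forward rates must not exceed 1 per epoch", call. = FALSE)
  }
  disps <- c(disp_mean_baseline, disp_mean_arrest)
  if (any(!is.finite(disps)) || any(disps < 0)) {
    stop("per-bout displacements must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(turn_rate_baseline = turn_rate_baseline,
         fwd_rate_baseline = fwd_rate_baseline,
         turn_rate_arrest = turn_rate_arrest,
         fwd_rate_arrest = fwd_rate_arrest,
         disp_mean_baseline = disp_mean_baseline,
         disp_mean_arrest = disp_mean_arrest,
         turn_angle_mean = turn_angle_mean, turn_angle_sd = turn_angle_sd,
         fwd_angle_sd = fwd_angle_sd, bout_dur = bout_dur,
         noise_sd = noise_sd),
    class = "bout_model"
  )
}

#' Per-fish recovery model
#'
#' Recovery from arrest is abrupt in individual fish: a fish swims with
#' arrest-state bout parameters until its latency, then switches back to
#' baseline parameters. Latencies are log-normal (heavy right tail, matching
#' the wide spread of individual recovery times); a configurable fraction of
#' fish never recovers within the recovery window.
#'
#' @param latency_median Median recovery latency, seconds.
#' @param latency_sdlog Log-scale SD of the log-normal latency distribution.
#' @param nonrecovery_prob Probability that a fish stays arrested for the
#'   whole recovery window.
#'
#' @return An object of class `recovery_model`.
#' @export
recovery_model <- function(latency_median = 20, latency_sdlog = 0.4,
                           nonrecovery_prob = 0) {
  if (!is.finite(latency_median) || latency_median < 0) {
    stop("latency_median must be finite and >= 0", call. = FALSE)
  }
  if (nonrecovery_prob < 0 || nonrecovery_prob > 1) {
    stop("nonrecovery_prob must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(latency_median = latency_median, latency_sdlog = latency_sdlog,
         nonrecovery_prob = nonrecovery_prob),
    class = "recovery_model"
  )
}

#' Reference arrest cohort configuration
#'
#' The calibrated study condition used throughout the package's worked
#' examples: the group-level first-epoch speed is half the baseline mean, but
#' that 50% reduction is carried by heterogeneous individuals - one third
#' fully immobile (arrest depth 1), one third with speed halved (depth 0.5),
#' and one third unaffected (depth 0) - and recovery latencies are log-normal
#' with a 20-s median.
#'
#' @param depths Arrest depths of the mixture components (expected fractional
#'   speed reduction per fish).
#' @param weights Mixture weights; recycled/normalised to sum to 1.
#' @param recovery A [recovery_model()].
#' @param bouts A [bout_model()] for the baseline state.
#'
#' @return A named list with elements `bouts`, `recovery`, `depths`, `weights`.
#' @export
reference_arrest_config <- function(depths = c(1, 0.5, 0),
                                    weights = c(1, 1, 1) / 3,
                                    recovery = recovery_model(),
                                    bouts = bout_model()) {
  if (length(depths) != length(weights)) {
    stop("depths and weights must have equal length", call. = FALSE)
  }
  if (any(depths < 0 | depths > 1)) stop("depths must lie in [0, 1]", call. = FALSE)
  weights <- weights / sum(weights)
  list(bouts = bouts, recovery = recovery, depths = depths, weights = weights)
}
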