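#' Simulate single-pulse escape-response trials
#'
#' Each trial is a Bernoulli draw at the per-pulse response probability;
#' responding trials carry a response latency in ms. Trials are spaced at a
#' fixed inter-stimulus interval (30 s for acoustic, 60 s for dark-flash
#' stimuli) to mirror the habituation-minimising protocol.
#'
#' @param n_fish Number of fish.
#' @param n_trials Trials per fish (>= 1).
#' @param p_respond Per-trial response probability.
#' @param latency_mean,latency_sd Latency distribution (normal, truncated at
#'   0), ms.
#' @param stimulus `"acoustic"`, `"dark_flash"` or `"electric"`.
#' @param phase Assay phase label (`"baseline"`, `"arrest"`, `"recovery"`).
#' @param isi_s Inter-stimulus interval, seconds; defaults to 30 s for
#'   acoustic/electric and 60 s for dark-flash stimuli.
#' @param seed Integer seed.
#'
#' @return A tibble: `fish_id`, `trial`, `t_s`, `stimulus`, `phase`,
#'   `responded`, `latency_ms` (`NA` when not responded).
#' @examples
#' trials <- simulate_escape_trials(8, 25, p_respond = 0.96, seed = 1)
#' responsiveness(trials)
#' @export
simulate_escape_trials <- function(n_fish, n_trials, p_respond = 0.96,
                                   latency_mean = 10, latency_sd = 3,
                                   stimulus = c("acoustic", "dark_flash",
                                                "electric"),
                                   phase = "baseline", isi_s = NULL,
                                   seed = 1) {
  stimulus <- match.arg(stimulus)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (p_respond < 0 || p_respond > 1) {
    stop("p_respond must be in [0, 1]", call. = FALSE)
  }
  if (is.null(isi_s)) isi_s <- if (stimulus == "dark_flash") 60 else 30

  withr::with_seed(seed, {
    out <- tidyr::expand_grid(fish_id = seq_len(n_fish),
                              trial = seq_len(n_trials))
    out$t_s <- (out$trial - 1) * isi_s
    out$stimulus <- stimulus
    out$phase <- phase
    out$responded <- stats::runif(nrow(out)) < p_respond
    lat <- abs(stats::rnorm(nrow(out), latency_mean, latency_sd))
    out$latency_ms <- ifelse(out$responded, lat, NA_real_)
    out
  })
}

#' Simulate the group righting-reflex assay
#'
#' Groups of fish are destabilised by a brief high-amplitude stimulus; a
#' blinded observer records the number still unbalanced at the end of each
#' 500-ms epoch over a 15-s window. Here each fish draws a righting latency
#' and the per-epoch unbalanced count is the number of latencies exceeding
#' the epoch end, which makes the series monotone non-increasing by
#' construction.
#'
#' @param n_groups Number of arenas (groups).
#' @param group_size Fish per arena (default 5).
#' @param latency_median,latency_sdlog Log-normal righting-latency
#'   parameters, seconds.
#' @param window_s Observation window, seconds.
#' @param epoch_s Epoch length, seconds.
#' @param seed Integer seed.
#' @param latencies Optional explicit latency vector (length `group_size`),
#'   applied to every group; overrides the random draw.
#'
#' @return A tibble: `group`, `epoch_end_s`, `n_unbalanced`, `group_size`.
#'   Per-fish latencies are attached as attribute `"truth"`.
#' @export
simulate_righting_assay <- function(n_groups, group_size = 5,
                                    latency_median = 1.5,
                                    latency_sdlog = 0.6,
                                    window_s = 15, epoch_s = 0.5, seed = 1,
                                    latencies = NULL) {
  if (group_size < 1) stop("group_size must be >= 1", call. = FALSE)
  ends <- seq(epoch_s, window_s, by = epoch_s)

  withr::with_seed(seed, {
    lat <- purrr::map(seq_len(n_groups), function(g) {
      if (is.null(latencies)) {
        stats::rlnorm(group_size, log(latency_median), latency_sdlog)
      } else {
        if (length(latencies) != group_size) {
          stop("latencies must have length group_size", call. = FALSE)
        }
        latencies
      }
    })
  })

  out <- purrr::imap(lat, function(l, g) {
    tibble::tibble(group = g, epoch_end_s = ends,
                   n_unbalanced = vapply(ends, function(e) sum(l > e),
                                         integer(1)),
                   group_size = group_size)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "truth") <- tibble::tibble(
    group = rep(seq_len(n_groups), each = group_size),
    fish = rep(seq_len(group_size), n_groups),
    latency_s = unlist(lat)
  )
  out
}
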