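#' Categorise startle responses by latency
#'
#' Responded trials are split into short-latency (SLC) and long-latency
#' (LLC) C-start responses at a latency boundary (default 15 ms, the
#' convention of the acoustic-startle literature; a latency exactly at the
#' boundary counts as SLC). Dark-flash trials are categorised as O-bends by
#' stimulus type alone. Non-responses are `"none"`.
#'
#' @param trials Trial tibble with `responded`, `latency_ms` and optionally
#'   `stimulus`.
#' @param slc_boundary SLC/LLC latency boundary, ms.
#' @return The input with a `category` column
#'   (`"SLC"`, `"LLC"`, `"O-bend"`, `"none"`).
#' @export
categorize_startle <- function(trials, slc_boundary = 15) {
  if (any(trials$responded & (is.na(trials$latency_ms) |
                              trials$latency_ms < 0))) {
    stop("responded trials must carry a non-negative latency", call. = FALSE)
  }
  stim <- if ("stimulus" %in% names(trials)) trials$stimulus else "acoustic"
  trials$category <- dplyr::case_when(
    !trials$responded ~ "none",
    stim == "dark_flash" ~ "O-bend",
    trials$latency_ms <= slc_boundary ~ "SLC",
    TRUE ~ "LLC"
  )
  trials
}

#' Responsiveness with a binomial interval
#'
#' Percentage of trials with a scored response, per stratum (any combination
#' of grouping columns present, typically `phase` and `stimulus`), with an
#' exact (Clopper-Pearson) 95% binomial confidence interval.
#'
#' @param trials Trial tibble with a logical `responded` column.
#' @param ... Grouping columns (tidy-select), e.g. `phase, stimulus`;
#'   default none (one overall stratum).
#' @param conf_level Confidence level of the interval.
#'
#' @return One row per stratum: grouping columns, `n_trials`, `n_responses`,
#'   `percent`, `ci_low`, `ci_high` (percent scale).
#' @examples
#' responsiveness(simulate_escape_trials(8, 25, 0.96, seed = 1))
#' @export
responsiveness <- function(trials, ..., conf_level = 0.95) {
  if (nrow(trials) == 0) stop("empty stratum", call. = FALSE)
  trials |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_responses = sum(.data$responded),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent = 100 * .data$n_responses / .data$n_trials,
      ci = purrr::map2(.data$n_responses, .data$n_trials, function(k, n) {
        ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
        tibble::tibble(ci_low = 100 * ci[1], ci_high = 100 * ci[2])
      })
    ) |>
    tidyr::unnest("ci")
}

#' Validate inter-stimulus spacing of a trial table
#'
#' Startle protocols space stimuli (30 s acoustic/electric, 60 s dark flash)
#' to minimise habituation. Warns when consecutive trials of a fish are
#' closer than the expected interval.
#'
#' @param trials Trial tibble with `fish_id`, `t_s`, `stimulus`.
#' @param expected_isi Named vector of minimum intervals (s) per stimulus
#'   type.
#' @return `TRUE` (invisibly) when spacing is valid, otherwise `FALSE` with
#'   a warning.
#' @export
check_stimulus_spacing <- function(trials,
                                   expected_isi = c(acoustic = 30,
                                                    electric = 30,
                                                    dark_flash = 60)) {
  bad <- trials |>
    dplyr::group_by(.data$fish_id, .data$stimulus) |>
    dplyr::arrange(.data$t_s, .by_group = TRUE) |>
    dplyr::summarise(
      min_isi = if (dplyr::n() > 1) min(diff(.data$t_s)) else Inf,
      .groups = "drop"
    ) |>
    dplyr::mutate(expected = unname(expected_isi[.data$stimulus])) |>
    dplyr::filter(.data$min_isi < .data$expected - 1e-9)
  if (nrow(bad) > 0) {
    warning(sprintf("%d fish/stimulus strata violate the expected inter-stimulus interval",
                    nrow(bad)), call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Time for a group to return to balance
#'
#' From a righting-reflex series (unbalanced count at the end of each 500-ms
#' epoch), the time at which all fish in the arena first show a dorsal-up
#' posture; censored at the window end when the group never fully balances.
#'
#' @param righting Output of [simulate_righting_assay()] (columns `group`,
#'   `epoch_end_s`, `n_unbalanced`).
#' @return One row per group: `group`, `t_balanced_s`, `censored`.
#' @export
time_to_balanced <- function(righting) {
  righting |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$epoch_end_s, .by_group = TRUE) |>
    dplyr::summarise(
      t_balanced_s = {
        hit <- which(.data$n_unbalanced == 0)
        if (length(hit)) .data$epoch_end_s[hit[1]] else
          max(.data$epoch_end_s)
      },
      censored = !any(.data$n_unbalanced == 0),
      .groups = "drop"
    )
}
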