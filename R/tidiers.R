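#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname zfa_tidiers
#' @title Tidiers for fitted objects
#' @description `tidy()` returns the per-comparison (or per-gene) table of a
#'   fitted object as a tibble; `glance()` returns a one-row summary.
#' @param x A `zfa_boot`, `zfa_test` or `zfa_enrichment` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy zfa_boot
#' @export
tidy.zfa_boot <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_low = x$ci_low,
                 ci_high = x$ci_high, conf_level = x$conf_level,
                 cohens_d = x$cohens_d)
}

#' @rdname zfa_tidiers
#' @method glance zfa_boot
#' @export
glance.zfa_boot <- function(x, ...) {
  tibble::tibble(n_a = x$n_a, n_b = x$n_b, n_boot = x$n_boot,
                 conf_level = x$conf_level)
}

#' @rdname zfa_tidiers
#' @method tidy zfa_test
#' @export
tidy.zfa_test <- function(x, ...) x$comparisons

#' @rdname zfa_tidiers
#' @method glance zfa_test
#' @export
glance.zfa_test <- function(x, ...) {
  tibble::tibble(test = x$test, n_groups = x$n_groups,
                 n_total = sum(x$n), min_p = min(x$comparisons$p))
}

#' @rdname zfa_tidiers
#' @method tidy zfa_enrichment
#' @export
tidy.zfa_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname zfa_tidiers
#' @method glance zfa_enrichment
#' @export
glance.zfa_enrichment <- function(x, ...) {
  th <- attr(x, "thresholds")
  flt <- attr(x, "filter")
  tibble::tibble(n_tested = nrow(x), n_filtered = flt$n_filtered,
                 n_enriched = sum(x$enriched), fc_threshold = th$fc,
                 fdr = th$fdr)
}
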