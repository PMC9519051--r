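#' Cohen's d
#'
#' Standardised effect size: mean difference (`b - a`, i.e. treated minus
#' control) divided by the pooled standard deviation (variances pooled with
#' `n - 1` weights).
#'
#' @param a,b Numeric vectors (control and treated), each of length >= 2.
#' @return A single number.
#' @examples
#' cohens_d(rnorm(20), rnorm(20, 1))
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("pooled SD is zero", call. = FALSE)
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Bootstrap mean difference with percentile interval
#'
#' Resamples each group with replacement and reports the observed mean
#' difference (`b - a`) with a percentile bootstrap confidence interval -
#' the estimation-statistics summary shown in Gardner-Altman-style plots.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param n_boot Number of bootstrap resamples (>= 1000; default 5000).
#' @param conf_level Interval coverage.
#' @param seed Integer seed (same seed, same interval).
#' @return An object of class `zfa_boot` with `estimate`, `ci_low`,
#'   `ci_high`, `cohens_d`, `n_a`, `n_b`, `boots` (the resampled
#'   differences).
#' @export
bootstrap_mean_diff <- function(a, b, n_boot = 5000, conf_level = 0.95,
                                seed = 1) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (n_boot < 1000) stop("n_boot must be >= 1000", call. = FALSE)
  boots <- withr::with_seed(seed, {
    ma <- matrix(sample(a, length(a) * n_boot, replace = TRUE), ncol = n_boot)
    mb <- matrix(sample(b, length(b) * n_boot, replace = TRUE), ncol = n_boot)
    colMeans(mb) - colMeans(ma)
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
  structure(
    list(estimate = mean(b) - mean(a), ci_low = ci[1], ci_high = ci[2],
         conf_level = conf_level, cohens_d = d,
         n_a = length(a), n_b = length(b), n_boot = n_boot, boots = boots),
    class = "zfa_boot"
  )
}

#' @export
print.zfa_boot <- function(x, ...) {
  cat(sprintf("mean difference %.4g  [%.4g, %.4g] (%d%% percentile bootstrap, %d resamples)\n",
              x$estimate, x$ci_low, x$ci_high, round(100 * x$conf_level),
              x$n_boot))
  cat(sprintf("Cohen's d %.3g (n = %d vs %d)\n", x$cohens_d, x$n_a, x$n_b))
  invisible(x)
}

#' Standard test battery
#'
#' The hypothesis tests used throughout the pipeline, on tidy data
#' (`value`, `group`, optionally `pair`): two-sample Welch t test, paired t
#' test, one-way ANOVA, or many-to-one Dunnett comparisons against a control
#' group with the p-value taken from a seeded Monte-Carlo max-|t| null.
#'
#' @param data Tibble with columns `value` and `group` (and `pair` for
#'   `test = "paired_t"`).
#' @param test One of `"welch_t"`, `"paired_t"`, `"anova"`, `"dunnett"`.
#' @param control Control group label (required for `"dunnett"`; for the t
#'   tests, the first group level is the control unless given).
#' @param n_mc Monte-Carlo draws for the Dunnett null (default 1e5).
#' @param seed Seed for the Monte-Carlo null.
#'
#' @return An object of class `zfa_test`: a list with `test`, `comparisons`
#'   (tibble of estimates, statistics and p-values) and bookkeeping fields.
#' @export
test_battery <- function(data, test = c("welch_t", "paired_t", "anova",
                                        "dunnett"),
                         control = NULL, n_mc = 1e5, seed = 1) {
  test <- match.arg(test)
  stopifnot(all(c("value", "group") %in% names(data)))
  groups <- unique(as.character(data$group))
  if (length(groups) < 2) stop("at least two groups required", call. = FALSE)
  vals <- split(data$value, as.character(data$group))[groups]

  comparisons <- switch(
    test,
    welch_t = {
      if (is.null(control)) control <- groups[1]
      other <- setdiff(groups, control)[1]
      ht <- stats::t.test(vals[[other]], vals[[control]])
      tibble::tibble(comparison = paste(other, "vs", control),
                     estimate = mean(vals[[other]]) - mean(vals[[control]]),
                     statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p = ht$p.value)
    },
    paired_t = {
      stopifnot("pair" %in% names(data))
      if (is.null(control)) control <- groups[1]
      other <- setdiff(groups, control)[1]
      wide <- data |>
        dplyr::filter(.data$group %in% c(control, other)) |>
        tidyr::pivot_wider(id_cols = "pair", names_from = "group",
                           values_from = "value")
      ht <- stats::t.test(wide[[other]], wide[[control]], paired = TRUE)
      tibble::tibble(comparison = paste(other, "vs", control),
                     estimate = mean(wide[[other]] - wide[[control]]),
                     statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p = ht$p.value)
    },
    anova = {
      fit <- stats::aov(value ~ factor(group), data = data)
      sm <- summary(fit)[[1]]
      tibble::tibble(comparison = "one-way ANOVA",
                     estimate = NA_real_, statistic = sm$`F value`[1],
                     df = sm$Df[1], p = sm$`Pr(>F)`[1])
    },
    dunnett = {
      if (is.null(control)) stop("dunnett requires a control group",
                                 call. = FALSE)
      dunnett_mc(vals, control, n_mc = n_mc, seed = seed)
    }
  )

  structure(list(test = test, comparisons = comparisons, control = control,
                 n_groups = length(groups),
                 n = vapply(vals, length, integer(1))),
            class = "zfa_test")
}

#' @export
print.zfa_test <- function(x, ...) {
  cat(sprintf("<zfa_test: %s, %d groups>\n", x$test, x$n_groups))
  print(as.data.frame(x$comparisons), row.names = FALSE)
  invisible(x)
}

# many-to-one comparisons with a Monte-Carlo max-|t| reference distribution;
# observed statistics are pooled-variance two-sample t's against the control
dunnett_mc <- function(vals, control, n_mc = 1e5, seed = 1) {
  if (!control %in% names(vals)) stop("unknown control group", call. = FALSE)
  others <- setdiff(names(vals), control)
  n <- vapply(vals, length, integer(1))
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)

  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  t_obs <- vapply(others, function(g) pooled_t(vals[[g]], vals[[control]]),
                  numeric(1))

  # null: all groups standard normal with the observed sizes
  max_t <- withr::with_seed(seed, {
    sims <- lapply(names(vals), function(g) {
      m <- matrix(stats::rnorm(n[[g]] * n_mc), nrow = n[[g]])
      list(mean = colMeans(m), ss = colSums(m^2) - n[[g]] * colMeans(m)^2,
           n = n[[g]])
    })
    names(sims) <- names(vals)
    ctl <- sims[[control]]
    tmat <- vapply(others, function(g) {
      s <- sims[[g]]
      sp2 <- (s$ss + ctl$ss) / (s$n + ctl$n - 2)
      abs((s$mean - ctl$mean) / sqrt(sp2 * (1 / s$n + 1 / ctl$n)))
    }, numeric(n_mc))
    if (length(others) == 1) abs(tmat) else apply(tmat, 1, max)
  })

  tibble::tibble(
    comparison = paste(others, "vs", control),
    estimate = vapply(others, function(g) mean(vals[[g]]) - mean(vals[[control]]),
                      numeric(1)),
    statistic = t_obs,
    df = NA_real_,
    p = vapply(t_obs, function(t0) mean(max_t >= abs(t0)), numeric(1))
  )
}
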