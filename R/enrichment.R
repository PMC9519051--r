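#' Median-of-ratios size factors
#'
#' Per-sample normalisation scalars for a count matrix: for each gene with
#' non-zero counts in every sample, the ratio of its count to its geometric
#' mean across samples is formed; a sample's size factor is the median of
#' those ratios. Normalised counts are `counts / factor`.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(rpois(60, 20), 10)
#' size_factors(cbind(m, 2 * m[, 1]))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene expressed in all samples; size factors undefined",
         call. = FALSE)
  }
  lg <- log(counts[all_pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Per-gene enrichment against a reference group
#'
#' The transcript-enrichment analysis used for manually isolated neuron
#' pools: genes with fewer than `min_reads` summed raw reads across the
#' target-group samples are filtered out; counts are normalised by
#' median-of-ratios [size_factors()]; each remaining gene is tested with a
#' two-sided Wilcoxon rank-sum test on normalised counts; p-values are
#' Benjamini-Hochberg adjusted; a gene is flagged enriched when its log2
#' fold change (target over reference, pseudocount 1 on normalised group
#' means) exceeds `fc_threshold` and its adjusted p-value is below `fdr`.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Tibble/data.frame with `sample` and `group` columns, or a
#'   vector of group labels in column order.
#' @param target,reference Group labels (defaults `"target"` vs
#'   `"reference"`).
#' @param min_reads Raw-read filter on target-group totals (default 5000).
#' @param fc_threshold log2 fold-change flag threshold (default 8).
#' @param fdr FDR level for the enriched flag (default 0.05).
#'
#' @return An object of class `zfa_enrichment`: a tibble sorted by `q` then
#'   decreasing `|log2fc|` with columns `gene`, `mean_reference`,
#'   `mean_target` (normalised), `log2fc`, `p`, `q`, `enriched`, `degenerate`
#'   (all-tied gene, p set to 1). Size factors and the filter are recorded
#'   as attributes.
#' @export
enrichment <- function(counts, groups, target = "target",
                       reference = "reference", min_reads = 5000,
                       fc_threshold = 8, fdr = 0.05) {
  counts <- as.matrix(counts)
  if (is.data.frame(groups)) {
    grp <- groups$group[match(colnames(counts), groups$sample)]
  } else {
    grp <- as.character(groups)
  }
  tgt <- which(grp == target)
  ref <- which(grp == reference)
  if (length(tgt) < 2 || length(ref) < 2) {
    stop("each compared group needs >= 2 samples", call. = FALSE)
  }

  keep <- rowSums(counts[, tgt, drop = FALSE]) >= min_reads
  if (!any(keep)) stop("no genes pass the read filter", call. = FALSE)
  sf <- size_factors(counts)
  norm <- sweep(counts[keep, , drop = FALSE], 2, sf, `/`)

  res <- purrr::map(seq_len(nrow(norm)), function(i) {
    a <- norm[i, ref]
    b <- norm[i, tgt]
    degenerate <- length(unique(c(a, b))) == 1
    p <- if (degenerate) 1 else
      suppressWarnings(stats::wilcox.test(b, a)$p.value)
    tibble::tibble(
      mean_reference = mean(a), mean_target = mean(b),
      log2fc = log2((mean(b) + 1) / (mean(a) + 1)),
      p = p, degenerate = degenerate
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(gene = rownames(norm), .before = 1)

  res$q <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$log2fc > fc_threshold & res$q < fdr
  res <- dplyr::arrange(res, .data$q, dplyr::desc(abs(.data$log2fc)))

  structure(res,
            class = c("zfa_enrichment", class(res)),
            size_factors = sf,
            filter = list(min_reads = min_reads, n_filtered = sum(!keep)),
            thresholds = list(fc = fc_threshold, fdr = fdr),
            fold_change_basis = "normalized group means, pseudocount 1")
}
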