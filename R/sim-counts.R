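#' Simulate a gene-by-sample count matrix with planted enrichment
#'
#' Negative-binomial counts for a target group (e.g. manually isolated
#' prepontine neurons) against a reference group, with unequal sequencing
#' depths and a chosen set of genes shifted in the target group by stated
#' log2 fold changes. Non-planted genes share their mean across groups.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (>= 2).
#' @param planted A tibble/data.frame with columns `gene` (index or name) and
#'   `log2fc`; `NULL` for a null matrix.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2; > 0).
#' @param depth_factors Per-sample relative depths, length `2 * n_per_group`
#'   (reference samples first); default all 1.
#' @param base_meanlog,base_sdlog Log-normal distribution of per-gene base
#'   means.
#' @param planted_base_mean Base mean assigned to planted genes in the
#'   reference group (keeps their target-group totals above typical
#'   low-expression filters).
#' @param seed Integer seed.
#'
#' @return A list: `counts` (integer matrix, genes x samples), `groups`
#'   (tibble `sample`, `group` with levels `"reference"`, `"target"`), and
#'   `truth` (planted table, possibly empty).
#' @export
simulate_count_matrix <- function(n_genes = 2000, n_per_group = 6,
                                  planted = NULL, dispersion = 0.1,
                                  depth_factors = NULL,
                                  base_meanlog = log(2000), base_sdlog = 1.5,
                                  planted_base_mean = 3, seed = 1) {
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("dispersion must be finite and > 0", call. = FALSE)
  }
  n_samp <- 2 * n_per_group
  if (is.null(depth_factors)) depth_factors <- rep(1, n_samp)
  if (length(depth_factors) != n_samp || any(depth_factors <= 0)) {
    stop("depth_factors must be positive, one per sample", call. = FALSE)
  }
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    gi <- if (is.numeric(planted$gene)) planted$gene else
      match(planted$gene, genes)
    if (any(is.na(gi)) || any(gi < 1 | gi > n_genes)) {
      stop("planted genes must be part of the gene set", call. = FALSE)
    }
  }

  withr::with_seed(seed, {
    mu_ref <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    mu_tgt <- mu_ref
    if (!is.null(planted)) {
      mu_ref[gi] <- planted_base_mean
      mu_tgt[gi] <- planted_base_mean * 2^planted$log2fc
    }
    mu <- cbind(matrix(mu_ref, n_genes, n_per_group),
                matrix(mu_tgt, n_genes, n_per_group))
    mu <- sweep(mu, 2, depth_factors, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n_genes, n_samp)
  })

  dimnames(counts) <- list(genes,
                           c(sprintf("ref_%02d", seq_len(n_per_group)),
                             sprintf("tgt_%02d", seq_len(n_per_group))))
  groups <- tibble::tibble(
    sample = colnames(counts),
    group = rep(c("reference", "target"), each = n_per_group)
  )
  truth <- if (is.null(planted)) {
    tibble::tibble(gene = character(), log2fc = numeric())
  } else {
    tibble::tibble(gene = genes[gi], log2fc = planted$log2fc)
  }
  list(counts = counts, groups = groups, truth = truth)
}
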