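#' Masked mean of a voxelwise ratio
#'
#' Computes the voxelwise numerator/denominator ratio (e.g. pERK over tERK)
#' and averages it over the voxels of a binary mask. Voxels with a zero
#' denominator are excluded from the mean and counted; the computation is
#' ratio-then-mean, which is invariant to a common rescaling of both
#' volumes.
#'
#' @param num,den Numeric arrays of identical shape (numerator and
#'   denominator volumes).
#' @param mask Binary array of the same shape; must select at least one
#'   voxel, and the denominator must be positive on at least 99% of masked
#'   voxels.
#' @param specimen,group Optional labels carried into the output.
#'
#' @return A one-row tibble: `specimen`, `group`, `masked_mean`,
#'   `n_voxels` (used), `n_zero_den` (excluded).
#' @examples
#' m <- array(1, c(4, 4, 2))
#' masked_ratio(array(2, dim(m)), array(1, dim(m)), m)
#' @export
masked_ratio <- function(num, den, mask, specimen = NA_character_,
                         group = NA_character_) {
  if (!identical(dim(num), dim(den)) || !identical(dim(num), dim(mask))) {
    stop("volumes and mask must share a shape", call. = FALSE)
  }
  sel <- which(mask > 0)
  if (length(sel) == 0) stop("empty mask", call. = FALSE)
  d <- den[sel]
  zero <- d <= 0
  if (mean(zero) > 0.01) {
    stop("denominator must be positive on >= 99% of mask voxels",
         call. = FALSE)
  }
  ratio <- num[sel][!zero] / d[!zero]
  if (any(!is.finite(ratio))) stop("non-finite ratios in mask", call. = FALSE)
  tibble::tibble(specimen = specimen, group = group,
                 masked_mean = mean(ratio),
                 n_voxels = sum(!zero), n_zero_den = sum(zero))
}

#' Masked ratios for a cohort of paired volumes
#'
#' Applies [masked_ratio()] to every specimen of a volume table (as produced
#' by [simulate_ratio_volumes()]).
#'
#' @param volumes Tibble with `specimen`, `group` and list-columns `num`,
#'   `den`.
#' @param mask Binary array.
#' @return One row per specimen (see [masked_ratio()]).
#' @export
group_masked_ratios <- function(volumes, mask) {
  purrr::pmap(volumes, function(specimen, group, num, den, ...) {
    masked_ratio(num, den, mask, specimen = specimen, group = group)
  }) |>
    dplyr::bind_rows()
}
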