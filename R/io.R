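#' Read and write trajectory tables
#'
#' Trajectories are plain TSV/CSV with columns `fish_id`, `t_s`, `x_mm`,
#' `y_mm`, `phase`; the delimiter is inferred from the file extension.
#'
#' @param path File path.
#' @param trajectory Trajectory tibble.
#' @return `read_trajectory()` returns a tibble; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  out <- reader(path, show_col_types = FALSE)
  stopifnot(all(c("fish_id", "t_s", "x_mm", "y_mm", "phase") %in% names(out)))
  out
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(trajectory, path) {
  writer <- if (grepl("\\.csv$", path)) readr::write_csv else readr::write_tsv
  writer(trajectory[, c("fish_id", "t_s", "x_mm", "y_mm", "phase")], path)
  invisible(path)
}

#' Read and write a count matrix with a group sidecar
#'
#' Counts are TSV with genes as rows (first column `gene`) and samples as
#' columns; group labels live in a sidecar TSV with columns `sample`,
#' `group`.
#'
#' @param counts_path,groups_path File paths.
#' @return A list with `counts` (integer matrix) and `groups` (tibble).
#' @export
read_counts <- function(counts_path, groups_path) {
  df <- readr::read_tsv(counts_path, show_col_types = FALSE)
  counts <- as.matrix(df[, -1])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  groups <- readr::read_tsv(groups_path, show_col_types = FALSE)
  list(counts = counts, groups = groups)
}

#' @rdname read_counts
#' @param counts Integer matrix, genes x samples.
#' @param groups Tibble with `sample` and `group`.
#' @export
write_counts <- function(counts, groups, counts_path, groups_path) {
  df <- tibble::as_tibble(counts, rownames = "gene")
  readr::write_tsv(df, counts_path)
  readr::write_tsv(groups, groups_path)
  invisible(counts_path)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Movies use a channel-major page order: for each frame, one page per
#' channel (`[t, c, y, x]` arrays); plain 3-D volumes are written one page
#' per slice. Intensities are scaled into `[0, 1]` on write with the scale
#' recorded in the calling code's hands (`max_val`).
#'
#' @param path TIFF path.
#' @param n_channels Number of interleaved channels (1 for volumes).
#' @param max_val Intensity ceiling used to (un)scale the data.
#' @return `read_stack()` returns a `[t, c, y, x]` array (channel dimension
#'   dropped when `n_channels = 1` is requested via `drop = TRUE`).
#' @export
read_stack <- function(path, n_channels = 1, max_val = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nf <- length(pages) / n_channels
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- array(0, c(nf, n_channels, ny, nx))
  for (f in seq_len(nf)) {
    for (ch in seq_len(n_channels)) {
      out[f, ch, , ] <- pages[[(f - 1) * n_channels + ch]] * max_val
    }
  }
  out
}

#' @rdname read_stack
#' @param stack `[t, c, y, x]` or `[z, y, x]` array.
#' @export
write_stack <- function(stack, path, max_val = max(stack)) {
  d <- dim(stack)
  pages <- list()
  if (length(d) == 4) {
    for (f in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        pages[[length(pages) + 1]] <- pmin(pmax(stack[f, ch, , ] / max_val,
                                                0), 1)
      }
    }
  } else if (length(d) == 3) {
    for (z in seq_len(d[1])) {
      pages[[length(pages) + 1]] <- pmin(pmax(stack[z, , ] / max_val, 0), 1)
    }
  } else {
    stop("stack must be a 3-D or 4-D array", call. = FALSE)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
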