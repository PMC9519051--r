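#' Detect nuclei by Laplacian-of-Gaussian blob detection
#'
#' Runs scale-normalised LoG filtering of the (time-averaged) reference
#' channel at a small range of scales around the expected nuclear radius,
#' finds spatial local maxima across scales, and applies greedy
#' non-maximum suppression. The detection threshold defaults to a multiple
#' of a robust (MAD-based) noise estimate of the response map, so blank
#' noise images yield no detections.
#'
#' @param reference A 2-D image matrix, a 3-D array of frames `[t, y, x]`
#'   (averaged before detection), or the list returned by
#'   [simulate_calcium_movie()] (its reference channel is used).
#' @param radius_px Expected nuclear radius, px; scales are derived from it.
#' @param scales Optional explicit vector of Gaussian scales (sigma, px);
#'   overrides `radius_px`.
#' @param threshold Absolute response threshold; `NULL` (default) derives it
#'   as `thresh_k` times the response-map noise SD, obtained by propagating a
#'   robust pixel-noise estimate of the image through the LoG kernel norm.
#' @param thresh_k Multiplier for the automatic threshold.
#' @param min_sep Minimum separation between detections, px.
#'
#' @return A tibble of ROIs: `id`, `y_px`, `x_px`, `radius_px`
#'   (`sqrt(2) * sigma` of the best scale), `scale`, `response`.
#' @export
detect_nuclei <- function(reference, radius_px = 3, scales = NULL,
                          threshold = NULL, thresh_k = 6,
                          min_sep = radius_px) {
  img <- reference_image(reference)
  if (length(img) == 0) stop("empty image", call. = FALSE)
  if (is.null(scales)) scales <- radius_px * c(0.8, 1.0, 1.25) / sqrt(2)

  resp <- lapply(scales, function(s) log_response(img, s))
  stack <- simplify2array(resp)                       # y, x, scale
  best <- apply(stack, c(1, 2), which.max)
  rmax <- apply(stack, c(1, 2), max)

  if (is.null(threshold)) {
    # pixel noise from horizontal first differences, mapped through the
    # LoG kernel 2-norm at the smallest scale (largest noise gain)
    px_sd <- stats::mad(diff(as.vector(t(img)))) / sqrt(2)
    gain <- max(vapply(scales, log_kernel_norm, numeric(1)))
    threshold <- thresh_k * px_sd * gain
  }

  peak <- local_maxima(rmax) & rmax > threshold
  idx <- which(peak, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(id = integer(), y_px = numeric(), x_px = numeric(),
                          radius_px = numeric(), scale = numeric(),
                          response = numeric()))
  }
  # parabolic sub-pixel refinement of each peak on the response map
  refine <- function(iy, ix) {
    py <- rmax[(iy - 1):(iy + 1), ix]
    px <- rmax[iy, (ix - 1):(ix + 1)]
    sub <- function(v) {
      den <- v[1] - 2 * v[2] + v[3]
      if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (v[1] - v[3]) / den))
    }
    c(iy + sub(py), ix + sub(px))
  }
  ctr <- t(mapply(refine, idx[, 1], idx[, 2]))

  cand <- tibble::tibble(
    y_px = ctr[, 1], x_px = ctr[, 2],
    scale = scales[best[idx]], response = rmax[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$response))

  keep <- nms_keep(cand$y_px, cand$x_px, min_sep)
  cand <- cand[keep, ]
  tibble::tibble(
    id = seq_len(nrow(cand)),
    y_px = cand$y_px, x_px = cand$x_px,
    radius_px = sqrt(2) * cand$scale,
    scale = cand$scale, response = cand$response
  )
}

# movie lists are reduced to the mean of the first `k` reference-channel
# frames (the same early-movie reference registration uses, so detected
# coordinates live in reference space even under drift)
reference_image <- function(reference, k = 10) {
  if (is.list(reference) && !is.null(reference$movie)) {
    k <- min(k, dim(reference$movie)[1])
    reference <- reference$movie[seq_len(k), 2, , , drop = FALSE]
    dim(reference) <- dim(reference)[c(1, 3, 4)]
  }
  if (is.matrix(reference)) return(reference)
  if (is.array(reference) && length(dim(reference)) == 3) {
    return(colMeans(reference))                      # mean over frames
  }
  stop("reference must be a matrix, [t, y, x] array, or simulated movie",
       call. = FALSE)
}

# scale-normalised negative LoG response (bright blobs -> positive peaks),
# via the separable decomposition LoG = G''_x G_y + G_x G''_y
log_response <- function(img, sigma) {
  hw <- max(2L, ceiling(4 * sigma))
  u <- -hw:hw
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  g2 <- (u^2 / sigma^4 - 1 / sigma^2) * g            # second derivative of G
  a <- conv_sep(img, g2, g)
  b <- conv_sep(img, g, g2)
  -sigma^2 * (a + b)
}

# 2-norm of the effective scale-normalised LoG kernel
log_kernel_norm <- function(sigma) {
  hw <- max(2L, ceiling(4 * sigma))
  u <- -hw:hw
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  g2 <- (u^2 / sigma^4 - 1 / sigma^2) * g
  k2d <- sigma^2 * (outer(g2, g) + outer(g, g2))
  sqrt(sum(k2d^2))
}

# separable 2-D convolution with replicate padding: ky along rows (y), kx
# along columns (x)
conv_sep <- function(m, ky, kx) {
  m <- conv_axis(m, ky)
  t(conv_axis(t(m), kx))
}

conv_axis <- function(m, k) {
  hw <- (length(k) - 1) %/% 2
  pad <- rbind(m[rep(1, hw), , drop = FALSE], m,
               m[rep(nrow(m), hw), , drop = FALSE])
  out <- stats::filter(pad, rev(k), sides = 2)
  matrix(out[(hw + 1):(hw + nrow(m)), ], nrow(m), ncol(m))
}

# strict 8-neighbour local maxima (edges excluded)
local_maxima <- function(m) {
  n <- nrow(m); p <- ncol(m)
  sh <- function(dy, dx) {
    out <- matrix(-Inf, n, p)
    ys <- max(1, 1 + dy):min(n, n + dy)
    xs <- max(1, 1 + dx):min(p, p + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  res <- m > sh(1, 0) & m > sh(-1, 0) & m > sh(0, 1) & m > sh(0, -1) &
    m > sh(1, 1) & m > sh(1, -1) & m > sh(-1, 1) & m > sh(-1, -1)
  res[c(1, n), ] <- FALSE
  res[, c(1, p)] <- FALSE
  res
}

# greedy non-maximum suppression on points sorted by decreasing response
nms_keep <- function(y, x, min_sep) {
  n <- length(y)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (y[keep] - y[i])^2 + (x[keep] - x[i])^2
    if (min(d2) >= min_sep^2) keep[i] <- TRUE
  }
  keep
}

#' Estimate per-frame translation against an early-movie reference
#'
#' Registers every frame of the reference channel to the mean of the first
#' `k` frames by FFT cross-correlation with sub-pixel (parabolic) peak
#' refinement. The returned shifts place reference-frame ROI coordinates
#' into each frame: an ROI at `(y, x)` in the reference sits at
#' `(y + dy_px, x + dx_px)` in frame `f`.
#'
#' @param movie Movie array `[t, channel, y, x]` or the list from
#'   [simulate_calcium_movie()].
#' @param k Number of initial frames averaged into the reference
#'   (default 10).
#' @param channel Channel used for registration (2 = reference/dsRed).
#'
#' @return A tibble: `frame`, `dy_px`, `dx_px`.
#' @export
register_frames <- function(movie, k = 10, channel = 2) {
  arr <- movie_array(movie)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  nf <- dim(arr)[1]
  k <- min(k, nf)
  ref <- colMeans(arr[seq_len(k), channel, , , drop = FALSE][, 1, , ],
                  dims = 1)
  if (k == 1) ref <- arr[1, channel, , ]
  if (stats::sd(ref) == 0) stop("degenerate (flat) reference", call. = FALSE)

  fr <- stats::fft(ref - mean(ref))
  shifts <- vapply(seq_len(nf), function(f) {
    frame <- arr[f, channel, , ]
    cc <- Re(stats::fft(stats::fft(frame - mean(frame)) * Conj(fr),
                        inverse = TRUE))
    peak_shift(cc)
  }, numeric(2))

  tibble::tibble(frame = seq_len(nf), dy_px = shifts[1, ], dx_px = shifts[2, ])
}

movie_array <- function(movie) {
  if (is.list(movie) && !is.null(movie$movie)) movie <- movie$movie
  if (!is.array(movie) || length(dim(movie)) != 4) {
    stop("movie must be a [t, channel, y, x] array", call. = FALSE)
  }
  movie
}

# location of the circular cross-correlation peak as a signed sub-pixel shift
peak_shift <- function(cc) {
  n <- nrow(cc); p <- ncol(cc)
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  refine <- function(vals) {
    denom <- vals[1] - 2 * vals[2] + vals[3]
    if (denom == 0) 0 else 0.5 * (vals[1] - vals[3]) / denom
  }
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  iy <- ij[1]; ix <- ij[2]
  ym <- cc[c((iy - 2) %% n + 1, iy, iy %% n + 1), ix]
  xm <- cc[iy, c((ix - 2) %% p + 1, ix, ix %% p + 1)]
  c(wrap(iy, n) + refine(ym), wrap(ix, p) + refine(xm))
}

#' Extract ratiometric calcium traces
#'
#' For each ROI and frame, mean intensity of both channels over a disc of
#' the ROI radius (ROI centres are shifted per frame when registration
#' transforms are supplied). The ratio (signal / reference) is normalised to
#' its baseline-window mean, so `dRR` averages exactly 1 over the baseline
#' window for every ROI.
#'
#' @param movie Movie array `[t, channel, y, x]` or the list from
#'   [simulate_calcium_movie()].
#' @param rois ROI tibble (`id`, `y_px`, `x_px`, `radius_px`), e.g. from
#'   [detect_nuclei()].
#' @param baseline,stimulus Frame-index windows; default to the windows
#'   attached to a simulated movie. Must be disjoint and within the movie.
#' @param transforms Optional output of [register_frames()].
#' @param qc_min_ref_frac An ROI whose reference-channel intensity drops
#'   below this fraction of its baseline mean at any frame is flagged
#'   (z-drift proxy).
#' @param qc_max_disp Frames whose registered displacement exceeds this many
#'   px are flagged (struggle proxy).
#'
#' @return A long tibble: `roi`, `frame`, `signal`, `reference`, `ratio`,
#'   `dRR`, `window` (`"baseline"`, `"stimulus"`, `"other"`). Per-ROI QC
#'   flags are attached as attribute `"qc"`; windows as attribute
#'   `"windows"`.
#' @export
extract_traces <- function(movie, rois, baseline = NULL, stimulus = NULL,
                           transforms = NULL, qc_min_ref_frac = 0.5,
                           qc_max_disp = 5) {
  arr <- movie_array(movie)
  if (is.list(movie) && !is.null(movie$windows)) {
    if (is.null(baseline)) baseline <- movie$windows$baseline
    if (is.null(stimulus)) stimulus <- movie$windows$stimulus
  }
  if (is.null(baseline) || is.null(stimulus)) {
    stop("baseline and stimulus windows are required", call. = FALSE)
  }
  nf <- dim(arr)[1]; ny <- dim(arr)[3]; nx <- dim(arr)[4]
  if (any(c(baseline, stimulus) < 1) || any(c(baseline, stimulus) > nf)) {
    stop("windows must lie within the movie", call. = FALSE)
  }
  if (length(intersect(baseline, stimulus)) > 0) {
    stop("baseline and stimulus windows must be disjoint", call. = FALSE)
  }

  r <- round(stats::median(rois$radius_px))
  off <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  off <- off[off[, 1]^2 + off[, 2]^2 <= r^2, , drop = FALSE]
  npx <- nrow(off)
  nroi <- nrow(rois)

  dy <- rep(0, nf); dx <- rep(0, nf)
  if (!is.null(transforms)) {
    dy <- transforms$dy_px; dx <- transforms$dx_px
  }

  sig <- matrix(NA_real_, nroi, nf)
  refm <- matrix(NA_real_, nroi, nf)
  roi_id <- rep(seq_len(nroi), each = npx)
  for (f in seq_len(nf)) {
    yy <- round(rep(rois$y_px, each = npx) + off[, 1] + dy[f])
    xx <- round(rep(rois$x_px, each = npx) + off[, 2] + dx[f])
    if (any(yy < 1 | yy > ny | xx < 1 | xx > nx)) {
      stop("ROI disc outside image", call. = FALSE)
    }
    ii <- cbind(yy, xx)
    s <- arr[f, 1, , ][ii]
    rr <- arr[f, 2, , ][ii]
    sig[, f] <- rowsum(s, roi_id)[, 1] / npx
    refm[, f] <- rowsum(rr, roi_id)[, 1] / npx
  }

  ratio <- sig / refm
  base_mean <- rowMeans(ratio[, baseline, drop = FALSE])
  drr <- ratio / base_mean

  window <- rep("other", nf)
  window[baseline] <- "baseline"
  window[stimulus] <- "stimulus"

  out <- tibble::tibble(
    roi = rep(rois$id, times = nf),
    frame = rep(seq_len(nf), each = nroi),
    signal = as.vector(sig),
    reference = as.vector(refm),
    ratio = as.vector(ratio),
    dRR = as.vector(drr),
    window = rep(window, each = nroi)
  )

  ref_base <- rowMeans(refm[, baseline, drop = FALSE])
  qc <- tibble::tibble(
    roi = rois$id,
    min_ref_frac = apply(refm / ref_base, 1, min),
    zdrift = apply(refm / ref_base, 1, min) < qc_min_ref_frac
  )
  struggle_frames <- which(sqrt(dy^2 + dx^2) > qc_max_disp)

  attr(out, "qc") <- qc
  attr(out, "struggle_frames") <- struggle_frames
  attr(out, "windows") <- list(baseline = baseline, stimulus = stimulus)
  class(out) <- c("zfa_traces", class(out))
  out
}

#' Classify stimulus-responsive cells
#'
#' A cell is a responder when its stimulus-window statistic of the
#' baseline-normalised ratio (`dRR`) exceeds the baseline mean by more than
#' `k_sd` baseline standard deviations. The statistic defaults to the mean
#' over the stimulus window (the max is available via `stat = "max"`, but a
#' max over several frames carries a scale-invariant false-positive floor).
#' A flat baseline (SD exactly 0, which only synthetic traces produce) falls
#' back to "any increase" and is flagged.
#'
#' @param traces Output of [extract_traces()].
#' @param k_sd SD multiplier (default 3).
#' @param stat `"mean"` or `"max"` over the stimulus window.
#' @param exclude_qc Drop ROIs flagged by extraction QC (z-drift proxy).
#'
#' @return One row per ROI: `roi`, `baseline_mean`, `baseline_sd`,
#'   `stim_stat`, `responder`, `flat_baseline`.
#' @export
classify_responders <- function(traces, k_sd = 3, stat = c("mean", "max"),
                                exclude_qc = TRUE) {
  stat <- match.arg(stat)
  win <- attr(traces, "windows")
  if (sum(traces$window == "baseline") / length(unique(traces$roi)) < 5) {
    stop("baseline window must have >= 5 frames", call. = FALSE)
  }

  keep_roi <- unique(traces$roi)
  if (exclude_qc && !is.null(attr(traces, "qc"))) {
    qc <- attr(traces, "qc")
    keep_roi <- setdiff(keep_roi, qc$roi[qc$zdrift])
  }

  traces |>
    dplyr::filter(.data$roi %in% keep_roi) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      baseline_mean = mean(.data$dRR[.data$window == "baseline"]),
      baseline_sd = stats::sd(.data$dRR[.data$window == "baseline"]),
      stim_stat = if (stat == "mean") {
        mean(.data$dRR[.data$window == "stimulus"])
      } else {
        max(.data$dRR[.data$window == "stimulus"])
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flat_baseline = .data$baseline_sd == 0,
      responder = dplyr::if_else(
        .data$flat_baseline,
        .data$stim_stat > .data$baseline_mean,
        .data$stim_stat > .data$baseline_mean + k_sd * .data$baseline_sd
      )
    )
}

#' Run the full calcium responder pipeline
#'
#' Convenience wrapper: detect nuclei on the time-averaged reference
#' channel, register frames, extract ratiometric traces at the registered
#' positions, and classify responders with the `k_sd` rule.
#'
#' @param movie The list from [simulate_calcium_movie()] (or an array plus
#'   explicit windows).
#' @param baseline,stimulus Frame windows (default: attached windows).
#' @param radius_px Expected nuclear radius for detection.
#' @param k_sd SD multiplier for classification.
#' @param register Estimate and apply per-frame translations (default TRUE).
#' @param stat Stimulus-window statistic for classification.
#'
#' @return A list: `rois` (detections), `transforms`, `traces`,
#'   `responders` (classification tibble).
#' @export
run_calcium_pipeline <- function(movie, baseline = NULL, stimulus = NULL,
                                 radius_px = 3, k_sd = 3, register = TRUE,
                                 stat = "mean") {
  rois <- detect_nuclei(movie, radius_px = radius_px)
  transforms <- if (register) register_frames(movie) else NULL
  traces <- extract_traces(movie, rois, baseline = baseline,
                           stimulus = stimulus, transforms = transforms)
  responders <- classify_responders(traces, k_sd = k_sd, stat = stat)
  list(rois = rois, transforms = transforms, traces = traces,
       responders = responders)
}

#' Match detected ROIs to ground-truth nuclei
#'
#' Greedy nearest-neighbour matching within a distance cap, used to score
#' detection and classification against the simulator's truth table.
#'
#' @param detected,truth ROI tibbles with `id`, `y_px`, `x_px`.
#' @param max_dist Maximum centre distance for a match, px.
#' @return A tibble: `detected_id`, `truth_id`, `dist_px`.
#' @export
match_rois <- function(detected, truth, max_dist = 2) {
  if (nrow(detected) == 0 || nrow(truth) == 0) {
    return(tibble::tibble(detected_id = integer(), truth_id = integer(),
                          dist_px = numeric()))
  }
  d2 <- outer(detected$y_px, truth$y_px, `-`)^2 +
    outer(detected$x_px, truth$x_px, `-`)^2
  pairs <- which(d2 <= max_dist^2, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(detected_id = integer(), truth_id = integer(),
                          dist_px = numeric()))
  }
  ord <- order(d2[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_d <- logical(nrow(detected)); used_t <- logical(nrow(truth))
  out <- vector("list", nrow(pairs))
  j <- 0
  for (i in seq_len(nrow(pairs))) {
    di <- pairs[i, 1]; ti <- pairs[i, 2]
    if (used_d[di] || used_t[ti]) next
    used_d[di] <- TRUE; used_t[ti] <- TRUE
    j <- j + 1
    out[[j]] <- tibble::tibble(detected_id = detected$id[di],
                               truth_id = truth$id[ti],
                               dist_px = sqrt(d2[di, ti]))
  }
  dplyr::bind_rows(out[seq_len(j)])
}
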