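#' Nuclear GCaMP6s indicator impulse kernel
#'
#' Difference-of-exponentials impulse response of the nuclear-localised
#' calcium indicator, normalised to peak 1. With the default rise and decay
#' constants the kernel peaks ~1.1 s after an impulse, matching the slow
#' kinetics of nuclear GCaMP6s.
#'
#' @param t Time since the impulse, seconds (vector).
#' @param rise Rise time constant, seconds.
#' @param decay Decay time constant, seconds.
#' @return Kernel values in `[0, 1]`.
#' @examples
#' tt <- seq(0, 10, by = 0.01)
#' tt[which.max(gcamp_kernel(tt))]  # ~1.1
#' @export
gcamp_kernel <- function(t, rise = 0.55, decay = 3.5) {
  h <- (1 - exp(-pmax(t, 0) / rise)) * exp(-pmax(t, 0) / decay)
  tpk <- rise * log(1 + decay / rise)
  hpk <- (1 - exp(-tpk / rise)) * exp(-tpk / decay)
  ifelse(t < 0, 0, h / hpk)
}

#' Simulate a two-channel nuclear calcium movie
#'
#' Builds a static field of Gaussian nuclei (the dsRed reference channel) and
#' a co-expressed signal channel (GCaMP6s). A minority of nuclei are
#' responders: their signal is multiplied by `1 + amplitude * r(t)` where the
#' response `r(t)` is a linear ramp over the stimulus period convolved with
#' the [gcamp_kernel()], so fluorescence builds slowly and peaks at the
#' cessation of the stimulus. The whole field can drift linearly (rigid
#' translation, applied by bilinear interpolation); Gaussian pixel noise is
#' added independently per frame and channel.
#'
#' The default protocol is a 10-s baseline, 5 s of 1-Hz pulses, and a 45-s
#' recovery, acquired at 2 Hz.
#'
#' @param n_nuclei Total nuclei to plant.
#' @param n_responders Number of responders (`<= n_nuclei`).
#' @param frame_rate Acquisition rate, Hz.
#' @param baseline_s,stim_s,recovery_s Protocol durations, seconds.
#' @param amplitude Peak fractional fluorescence increase of responders.
#' @param radius_px Nuclear radius, px (spots rendered with
#'   `sigma = radius_px / sqrt(2)`).
#' @param drift_px Total linear drift over the movie, `c(dy, dx)` px.
#' @param noise_sd Pixel noise SD (intensity units).
#' @param bg Background intensity.
#' @param amp_range Range of per-nucleus reference-channel amplitudes.
#' @param side_px Optional image side; by default the smallest jittered grid
#'   that holds `n_nuclei` at a minimum separation of `2 * radius_px`.
#' @param seed Integer seed.
#'
#' @return A list with elements `movie` (numeric array `[frame, channel, y,
#'   x]`, channel 1 = signal/GCaMP6s, channel 2 = reference/dsRed), `rois`
#'   (truth tibble: `id`, `y_px`, `x_px`, `radius_px`, `responder`), `drift`
#'   (tibble `frame`, `dy_px`, `dx_px`), and `windows` (baseline / stimulus /
#'   recovery frame indices).
#' @export
simulate_calcium_movie <- function(n_nuclei = 420, n_responders = 41,
                                   frame_rate = 2, baseline_s = 10,
                                   stim_s = 5, recovery_s = 45,
                                   amplitude = 1, radius_px = 3,
                                   drift_px = c(0, 0), noise_sd = 3,
                                   bg = 20, amp_range = c(150, 250),
                                   side_px = NULL, seed = 1) {
  if (n_responders > n_nuclei) {
    stop("n_responders must be <= n_nuclei", call. = FALSE)
  }
  jit <- 1.5
  spacing <- 2 * radius_px + 2 * jit + 1          # guarantees min separation
  margin <- 2 * radius_px + 4
  g <- ceiling(sqrt(n_nuclei))
  if (is.null(side_px)) {
    side_px <- ceiling(g * spacing + 2 * margin)
  } else {
    cap <- floor((side_px - 2 * margin) / spacing)^2
    if (cap < n_nuclei) {
      stop("nuclei cannot be placed at the requested density", call. = FALSE)
    }
    g <- floor((side_px - 2 * margin) / spacing)
  }

  nf <- round((baseline_s + stim_s + recovery_s) * frame_rate)
  fb <- seq_len(round(baseline_s * frame_rate))
  fs <- max(fb) + seq_len(round(stim_s * frame_rate))
  fr <- setdiff(seq_len(nf), c(fb, fs))

  withr::with_seed(seed, {
    cells <- sample(g * g, n_nuclei)              # grid cells, jittered
    cy <- margin + ((cells - 1) %/% g + 0.5) * spacing +
      stats::runif(n_nuclei, -jit, jit)
    cx <- margin + ((cells - 1) %% g + 0.5) * spacing +
      stats::runif(n_nuclei, -jit, jit)
    amp <- stats::runif(n_nuclei, amp_range[1], amp_range[2])
    sgain <- stats::runif(n_nuclei, 0.8, 1.2)     # per-cell GCaMP/dsRed ratio
    resp_id <- sample(n_nuclei, n_responders)
    is_resp <- seq_len(n_nuclei) %in% resp_id
    resp_amp <- stats::runif(n_nuclei, 0.8, 1.2) * amplitude
    resp_amp[!is_resp] <- 0

    sigma <- radius_px / sqrt(2)
    ref0 <- render_field(side_px, cy, cx, amp, sigma, bg)
    sig0 <- render_field(side_px, cy, cx, amp * sgain, sigma, bg)
    resp_field <- render_field(side_px, cy, cx, amp * sgain * resp_amp,
                               sigma, 0)

    # activation ramps over the stimulus, filtered by the indicator kernel
    tt <- (seq_len(nf) - 1) / frame_rate
    dt <- 0.05
    tfine <- seq(0, max(tt), by = dt)
    act <- pmin(pmax((tfine - baseline_s) / stim_s, 0), 1) *
      (tfine < baseline_s + stim_s)
    ker <- gcamp_kernel(seq(0, 20, by = dt))
    rfine <- stats::convolve(act, rev(ker), type = "open")[seq_along(tfine)]
    rfine <- rfine / max(rfine)
    r_t <- stats::approx(tfine, rfine, xout = tt, rule = 2)$y

    drift <- tibble::tibble(
      frame = seq_len(nf),
      dy_px = drift_px[1] * (seq_len(nf) - 1) / max(nf - 1, 1),
      dx_px = drift_px[2] * (seq_len(nf) - 1) / max(nf - 1, 1)
    )

    movie <- array(0, dim = c(nf, 2, side_px, side_px))
    for (f in seq_len(nf)) {
      sfield <- sig0 + r_t[f] * resp_field
      movie[f, 1, , ] <- shift_bilinear(sfield, drift$dy_px[f], drift$dx_px[f]) +
        stats::rnorm(side_px^2, 0, noise_sd)
      movie[f, 2, , ] <- shift_bilinear(ref0, drift$dy_px[f], drift$dx_px[f]) +
        stats::rnorm(side_px^2, 0, noise_sd)
    }
  })

  list(
    movie = movie,
    rois = tibble::tibble(id = seq_len(n_nuclei), y_px = cy, x_px = cx,
                          radius_px = radius_px,
                          responder = seq_len(n_nuclei) %in% resp_id),
    drift = drift,
    windows = list(baseline = fb, stimulus = fs, recovery = fr)
  )
}

# sum-of-Gaussians field on an integer pixel grid
render_field <- function(side, cy, cx, amp, sigma, bg) {
  field <- matrix(bg, side, side)
  hw <- ceiling(4 * sigma)
  off <- -hw:hw
  for (i in seq_along(cy)) {
    iy <- round(cy[i]) + off
    ix <- round(cx[i]) + off
    ok_y <- iy >= 1 & iy <= side
    ok_x <- ix >= 1 & ix <= side
    gy <- exp(-(iy[ok_y] - cy[i])^2 / (2 * sigma^2))
    gx <- exp(-(ix[ok_x] - cx[i])^2 / (2 * sigma^2))
    field[iy[ok_y], ix[ok_x]] <- field[iy[ok_y], ix[ok_x]] +
      amp[i] * outer(gy, gx)
  }
  field
}

# translate a matrix by (dy, dx) with bilinear interpolation, edge-replicated
shift_bilinear <- function(m, dy, dx) {
  if (dy == 0 && dx == 0) return(m)
  iy <- floor(dy); fy <- dy - iy
  ix <- floor(dx); fx <- dx - ix
  s <- function(a, b) shift_int(m, iy + a, ix + b)
  (1 - fy) * (1 - fx) * s(0, 0) + (1 - fy) * fx * s(0, 1) +
    fy * (1 - fx) * s(1, 0) + fy * fx * s(1, 1)
}

# integer translation with edge replication; positive dy moves content down
shift_int <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  ry <- pmin(pmax(seq_len(n) - dy, 1), n)
  rx <- pmin(pmax(seq_len(p) - dx, 1), p)
  m[ry, rx, drop = FALSE]
}

#' Simulate paired pERK/tERK ratio volumes for two groups
#'
#' Generates, for each specimen, a denominator (total-ERK) volume and a
#' numerator (phospho-ERK) volume. In the treated group the voxelwise ratio
#' inside the mask equals `effect`; everywhere else (and throughout the
#' control group) it is 1, up to multiplicative log-normal noise.
#'
#' @param n_per_group Specimens per group.
#' @param mask Binary 3-D array (the region of interest).
#' @param effect Ratio multiplier inside the mask for the treated group
#'   (> 0).
#' @param noise_sd SD of the log-normal voxel noise on the ratio.
#' @param base Mean denominator intensity.
#' @param seed Integer seed.
#'
#' @return A tibble with one row per specimen: `specimen`, `group`
#'   (`"control"` / `"treated"`), and list-columns `num`, `den` holding the
#'   volumes.
#' @export
simulate_ratio_volumes <- function(n_per_group = 12, mask, effect = 1.5,
                                   noise_sd = 0.05, base = 100, seed = 1) {
  if (!is.array(mask) || sum(mask > 0) == 0) {
    stop("mask must be a non-empty array", call. = FALSE)
  }
  if (!is.finite(effect) || effect <= 0) stop("effect must be > 0", call. = FALSE)
  dm <- dim(mask)
  nvox <- prod(dm)
  inmask <- as.numeric(mask > 0)

  withr::with_seed(seed, {
    specs <- tidyr::expand_grid(group = c("control", "treated"),
                                idx = seq_len(n_per_group))
    vols <- purrr::pmap(specs, function(group, idx) {
      den <- array(stats::rgamma(nvox, shape = 25, scale = base / 25), dm)
      ratio <- if (group == "treated") 1 + (effect - 1) * inmask else
        rep(1, nvox)
      num <- array(den * ratio * stats::rlnorm(nvox, 0, noise_sd), dm)
      list(num = num, den = den)
    })
  })

  tibble::tibble(
    specimen = sprintf("%s_%02d", specs$group, specs$idx),
    group = specs$group,
    num = purrr::map(vols, "num"),
    den = purrr::map(vols, "den")
  )
}
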