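#' Fraction of particles classified as dimeric by molecular brightness
#'
#' Classifies a particle as dimeric when its intensity meets a fixed
#' brightness threshold (default 8200 A.U., appropriate for mNeonGreen
#' tags on the reference instrument; the threshold is
#' instrument-specific and should be recalibrated per setup, e.g. with
#' [brightness_threshold()]).
#'
#' @param intensities per-particle intensity snapshot, arbitrary units
#'   (>= 100 particles).
#' @param threshold dimer classification threshold, same units.
#' @return Fraction of particles at or above the threshold, in `[0, 1]`.
#' @export
dimer_fraction <- function(intensities, threshold = 8200) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 100L)
    stop("need >= 100 particles for a dimer-fraction estimate (got ",
         length(intensities), ")")
  mean(intensities >= threshold)
}

#' Automatic brightness threshold between 1- and 2-fluorophore modes
#'
#' Fits a two-component Gaussian mixture to a pooled brightness sample
#' (EM on means, SDs and weight) and returns the antimode between the
#' two fitted components - an instrument-independent alternative to a
#' fixed A.U. cutoff.
#'
#' @param intensities pooled brightness sample.
#' @return Threshold intensity (scalar).
#' @export
brightness_threshold <- function(intensities) {
  x <- intensities[is.finite(intensities)]
  stopifnot(length(x) >= 200L)
  mu <- quantile(x, c(0.25, 0.85), names = FALSE)
  s <- rep(sd(x) / 2, 2)
  w <- 0.5
  for (it in 1:200) {
    d1 <- w * stats::dnorm(x, mu[1], s[1])
    d2 <- (1 - w) * stats::dnorm(x, mu[2], s[2])
    g <- d1 / (d1 + d2)
    w <- mean(g)
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    s[1] <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
    s[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); s <- rev(s); w <- 1 - w }
  # antimode: minimum of the mixture density between the two means
  grid <- seq(mu[1], mu[2], length.out = 512)
  dens <- w * stats::dnorm(grid, mu[1], s[1]) +
    (1 - w) * stats::dnorm(grid, mu[2], s[2])
  grid[which.min(dens)]
}

#' Count photobleaching steps in an intensity trace
#'
#' Offline change-point detection: binary segmentation into
#' piecewise-constant levels minimizing the residual sum of squares with
#' a BIC stopping rule, followed by a magnitude gate that keeps only
#' level changes of at least `3 * noise_sd` whose change points are
#' separated by at least `min_separation` frames.  Downward steps
#' (bleaching) have negative step sizes.
#'
#' @param trace intensity time series (length >= 10).
#' @param noise_sd camera noise standard deviation (> 0).
#' @param t optional time stamps (defaults to frame index).
#' @param min_separation minimum frames between change points.
#' @return Object of class `step_count`: `n_steps`, `step_times`,
#'   `step_sizes`, `levels`.
#' @export
count_bleach_steps <- function(trace, noise_sd, t = seq_along(trace),
                               min_separation = 2L) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop("`noise_sd` must be a positive scalar")
  stopifnot(length(trace) >= 10L, length(t) == length(trace))
  n <- length(trace)

  # best single split of segment [i, j] by RSS of two constant levels
  best_split <- function(i, j) {
    seg <- trace[i:j]
    m <- length(seg)
    if (m < 2L * min_separation) return(NULL)
    csum <- cumsum(seg); csq <- cumsum(seg^2)
    ks <- min_separation:(m - min_separation)   # split after index k
    s1 <- csum[ks]; n1 <- ks
    s2 <- csum[m] - s1; n2 <- m - ks
    rss <- (csq[m]) - s1^2 / n1 - s2^2 / n2
    kbest <- ks[which.min(rss)]
    list(k = i + kbest - 1L, rss = min(rss),
         rss0 = csq[m] - csum[m]^2 / m)
  }

  # binary segmentation with BIC stopping
  cps <- integer(0)
  segments <- list(c(1L, n))
  repeat {
    cand <- NULL
    for (sg in segments) {
      sp <- best_split(sg[1], sg[2])
      if (is.null(sp)) next
      gain <- sp$rss0 - sp$rss
      if (is.null(cand) || gain > cand$gain)
        cand <- list(seg = sg, k = sp$k, gain = gain)
    }
    if (is.null(cand)) break
    # BIC: accept split if RSS reduction beats the 2-parameter penalty
    n_seg <- length(segments)
    rss_tot <- sum(vapply(segments, function(sg) {
      seg <- trace[sg[1]:sg[2]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
    rss_new <- rss_tot - cand$gain
    bic_old <- n * log(max(rss_tot, 1e-12) / n) + (2 * n_seg) * log(n)
    bic_new <- n * log(max(rss_new, 1e-12) / n) + (2 * (n_seg + 1)) * log(n)
    if (bic_new >= bic_old) break
    cps <- sort(c(cps, cand$k))
    segments <- list()
    bounds <- c(0L, cps, n)
    for (i in seq_len(length(bounds) - 1L))
      segments[[i]] <- c(bounds[i] + 1L, bounds[i + 1L])
  }

  # magnitude gate on the segment levels
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(trace[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  keep <- abs(diff(levels)) >= 3 * noise_sd
  cps <- cps[keep]
  # recompute levels on the gated segmentation
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(trace[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  sizes <- diff(levels)

  out <- list(n_steps = length(cps),
              step_times = t[cps + 1L],
              step_sizes = sizes,
              levels = levels,
              change_points = cps)
  class(out) <- "step_count"
  out
}

#' @export
print.step_count <- function(x, ...) {
  cat(sprintf("Detected %d intensity step(s)\n", x$n_steps))
  if (x$n_steps > 0)
    cat("  at t =", paste(signif(x$step_times, 4), collapse = ", "),
        "; sizes:", paste(signif(x$step_sizes, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Dimer fraction over time during a photobleaching experiment
#'
#' Splits the acquisition into consecutive windows and reports, per
#' window, the dimer fraction among particles visible in that window.
#' New arrivals during the acquisition are included, which is why
#' experimental time courses plateau above the pure-bleaching decay.
#'
#' @param traces long-format intensity traces (`particle_id`, `frame`,
#'   `t`, `intensity`), aligned to illumination start (t = 0).
#' @param window window width, seconds.
#' @param threshold dimer brightness threshold (see [dimer_fraction()]).
#' @param detect_floor minimum mean window intensity for a particle to
#'   count as visible (filters fully bleached particles whose trace is
#'   pure camera noise).
#' @return Data frame `t` (window midpoint), `fraction`, `n_visible`.
#' @export
dimer_fraction_timecourse <- function(traces, window, threshold = 8200,
                                      detect_floor = threshold / 4) {
  stopifnot(all(c("particle_id", "t", "intensity") %in% names(traces)),
            window > 0)
  t_max <- max(traces$t)
  edges <- seq(0, t_max + window, by = window)
  res <- lapply(seq_len(length(edges) - 1L), function(i) {
    sel <- traces$t >= edges[i] & traces$t < edges[i + 1L]
    if (!any(sel)) return(NULL)
    mi <- tapply(traces$intensity[sel], traces$particle_id[sel], mean)
    visible <- mi >= detect_floor
    if (sum(visible) == 0L) return(NULL)
    data.frame(t = (edges[i] + edges[i + 1L]) / 2,
               fraction = mean(mi[visible] >= threshold),
               n_visible = sum(visible))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Brightness at first membrane attachment vs at binding equilibrium
#'
#' Two complementary brightness samples from a track table: the
#' *attachment* sample takes each track's first-frame intensity (the
#' oligomeric state molecules arrive in from solution), while the
#' *equilibrium* sample pools the intensities of all particles present
#' in randomly chosen frames (the steady-state membrane population).  A
#' membrane-dimerizing species shows a higher dimer fraction at
#' equilibrium than on attachment; a non-dimerizing control shows
#' indistinguishable samples.
#'
#' @param tracks a track table.
#' @param n_frames_sample number of random frames for the equilibrium
#'   sample.
#' @param seed optional integer seed for the frame draw.
#' @return List with numeric vectors `attachment` and `equilibrium`.
#' @export
attachment_vs_equilibrium_brightness <- function(tracks, n_frames_sample = 50L,
                                                 seed = NULL) {
  stopifnot(all(c("track_id", "frame", "intensity") %in% names(tracks)))
  if (!is.null(seed)) set.seed(stream_seed(seed, "eqbrightness"))
  first_idx <- !duplicated(tracks$track_id)
  attachment <- tracks$intensity[first_idx]
  frames <- unique(tracks$frame)
  pick <- sample(frames, min(n_frames_sample, length(frames)))
  equilibrium <- tracks$intensity[tracks$frame %in% pick]
  list(attachment = attachment, equilibrium = equilibrium)
}
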