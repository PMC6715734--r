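#' Bin events into genome-tiling windows
#'
#' Tiles each chromosome left to right at the given scale (terminal
#' partial bins are kept, with their true length recorded) and counts
#' events per bin for each event class.
#'
#' @param events data.frame with `chrom`, `pos` and optionally `class`
#'   (a single class is assumed when absent).
#' @param chrom_lengths chromosome lengths (bp).
#' @param scale bin width (bp).
#' @return list of class `binned_counts`: `bins` (chrom/start/end/len,
#'   0-based half-open) and `counts` (matrix, bins x classes).
#' @export
bin_events <- function(events, chrom_lengths, scale) {
  if (scale <= 0) stop("`scale` must be positive")
  if (scale > max(chrom_lengths))
    warning("scale exceeds the longest chromosome; single-bin chromosomes")
  bins <- genome_blocks(chrom_lengths, scale)
  classes <- if ("class" %in% names(events) && nrow(events) > 0)
    sort(unique(events$class)) else "all"
  counts <- matrix(0L, nrow(bins), length(classes),
                   dimnames = list(NULL, classes))
  if (nrow(events) > 0) {
    cls <- if ("class" %in% names(events)) events$class else
      rep("all", nrow(events))
    nb <- ceiling(chrom_lengths / scale)
    offset <- c(0, cumsum(nb))[seq_along(nb)]
    b <- offset[events$chrom] + floor((events$pos - 1) / scale) + 1
    ok <- events$pos >= 1 & events$pos <= chrom_lengths[events$chrom]
    for (cl in classes) {
      t_cl <- table(b[ok & cls == cl])
      counts[as.integer(names(t_cl)), cl] <- as.integer(t_cl)
    }
  }
  structure(list(bins = bins, counts = counts),
            class = "binned_counts")
}

#' Poisson-noise-corrected correlation of binned event counts
#'
#' Observed counts `N` are modelled as Poisson around underlying
#' binned rates `W`; since `Var(N) = E(W) + Var(W)` and
#' `Cov(N_j, N_k) = Cov(W_j, W_k)`, the underlying correlation is
#' estimated as
#' `Cov(N_j, N_k) / sqrt[(Var(N_j) - mean(N_j)) (Var(N_k) - mean(N_k))]`
#' using ordinary sample moments (unbiased, n-1 denominators). The
#' estimate is invalid when either variance excess is non-positive
#' (no detectable rate variation); finite-sample estimates outside
#' [-1, 1] are clipped for reporting with the raw value retained.
#'
#' @param Nj,Nk equal-length count vectors (one entry per bin).
#' @return list of class `corr_estimate`: `corr` (clipped), `raw`,
#'   `valid`, `n_bins`.
#' @export
poisson_corrected_correlation <- function(Nj, Nk) {
  if (length(Nj) != length(Nk)) stop("count vectors differ in length")
  if (length(Nj) < 10) stop("need at least 10 bins")
  vj <- stats::var(Nj) - mean(Nj)
  vk <- stats::var(Nk) - mean(Nk)
  cv <- stats::cov(Nj, Nk)
  valid <- is.finite(vj) && is.finite(vk) && vj > 0 && vk > 0
  raw <- if (valid) cv / sqrt(vj * vk) else NA_real_
  structure(list(corr = if (valid) max(-1, min(1, raw)) else NA_real_,
                 raw = raw, valid = valid, n_bins = length(Nj)),
            class = "corr_estimate")
}

#' Bootstrap CI for the corrected correlation
#'
#' Resamples bins with replacement and recomputes the corrected
#' correlation; returns the percentile interval over valid resamples
#' and the fraction of invalid ones.
#'
#' @param Nj,Nk count vectors.
#' @param B number of resamples.
#' @param level confidence level.
#' @return list: `ci`, `frac_invalid`, `boot` (resampled estimates).
#' @export
bootstrap_correlation_ci <- function(Nj, Nk, B = 10000, level = 0.95) {
  if (B <= 0) stop("`B` must be positive")
  if (B < 10) warning("very small B: degenerate interval")
  n <- length(Nj)
  boot <- vapply(seq_len(B), function(b) {
    ii <- sample.int(n, n, replace = TRUE)
    vj <- stats::var(Nj[ii]) - mean(Nj[ii])
    vk <- stats::var(Nk[ii]) - mean(Nk[ii])
    if (!is.finite(vj) || !is.finite(vk) || vj <= 0 || vk <= 0)
      return(NA_real_)
    stats::cov(Nj[ii], Nk[ii]) / sqrt(vj * vk)
  }, numeric(1))
  ok <- boot[!is.na(boot)]
  a <- (1 - level) / 2
  ci <- if (length(ok) >= 2)
    stats::quantile(pmax(-1, pmin(1, ok)), c(a, 1 - a), names = FALSE)
  else c(NA_real_, NA_real_)
  list(ci = ci, frac_invalid = mean(is.na(boot)), boot = boot)
}

#' Distance-to-chromosome-end profile with a scrambled null
#'
#' Bins events by the distance to the nearer chromosome end, builds a
#' null by uniformly re-positioning the same number of events on each
#' chromosome, and attaches 90% bootstrap bands (resampling events).
#'
#' @param events data.frame with `chrom`, `pos`.
#' @param chrom_lengths chromosome lengths (bp).
#' @param n_bins number of distance bins.
#' @param B bootstrap replicates for the bands.
#' @param n_null scrambled-null replicates.
#' @return list of class `end_profile`: `breaks`, `observed` (fraction
#'   per bin), `null` (mean fraction), `obs_band`, `null_band`
#'   (5%/95% rows), `n_events`.
#' @export
end_distance_profile <- function(events, chrom_lengths, n_bins = 20,
                                 B = 500, n_null = 200) {
  if (nrow(events) == 0) {
    warning("no events: empty profile")
    return(structure(list(breaks = numeric(), observed = numeric(),
                          null = numeric(), obs_band = NULL,
                          null_band = NULL, n_events = 0L),
                     class = "end_profile"))
  }
  end_dist <- function(chrom, pos)
    pmin(pos, chrom_lengths[chrom] - pos)
  dmax <- max(chrom_lengths) / 2
  breaks <- seq(0, dmax, length.out = n_bins + 1)
  frac <- function(d) {
    h <- graphics::hist(pmin(d, dmax), breaks = breaks, plot = FALSE)
    h$counts / length(d)
  }
  d_obs <- end_dist(events$chrom, events$pos)
  observed <- frac(d_obs)
  per_chrom <- table(factor(events$chrom,
                            levels = seq_along(chrom_lengths)))
  null_draw <- function() {
    d <- unlist(lapply(seq_along(chrom_lengths), function(ci) {
      n <- per_chrom[ci]
      if (n == 0) return(numeric())
      p <- stats::runif(n, 1, chrom_lengths[ci])
      pmin(p, chrom_lengths[ci] - p)
    }))
    frac(d)
  }
  null_mat <- t(vapply(seq_len(n_null), function(i) null_draw(),
                       numeric(n_bins)))
  obs_mat <- t(vapply(seq_len(B), function(b) {
    ii <- sample.int(nrow(events), nrow(events), replace = TRUE)
    frac(end_dist(events$chrom[ii], events$pos[ii]))
  }, numeric(n_bins)))
  band <- function(m) apply(m, 2, stats::quantile,
                            probs = c(0.05, 0.95))
  structure(list(breaks = breaks, observed = observed,
                 null = colMeans(null_mat),
                 obs_band = band(obs_mat),
                 null_band = band(null_mat),
                 n_events = nrow(events)),
            class = "end_profile")
}
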