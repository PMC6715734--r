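#' Build focal/nearby SNP pairs for tract-length estimation
#'
#' For every converted site of every NCO event (the focal site) and
#' every other SNP of the map within `window` bp on the same
#' chromosome, records the distance and whether that SNP was also
#' converted in the same event. Conditioning on SNP positions makes
#' the downstream estimator independent of SNP density. Focal sites
#' only pair with their own event's neighbourhood.
#'
#' @param ncos `nco_calls` data.frame (needs `chrom`, `converted_idx`).
#' @param snp_map the SNP map.
#' @param window maximum pair distance in bp.
#' @return data.frame with columns `d` (bp, > 0) and `x` (1 if the
#'   nearby SNP was co-converted, 0 otherwise).
#' @export
build_pairs <- function(ncos, snp_map, window = 1000) {
  if (window <= 0) stop("`window` must be positive")
  if (nrow(ncos) == 0)
    return(data.frame(d = numeric(), x = integer()))
  midx <- snp_index(snp_map)
  d_all <- vector("list", nrow(ncos))
  x_all <- vector("list", nrow(ncos))
  for (i in seq_len(nrow(ncos))) {
    conv <- ncos$converted_idx[[i]]
    if (length(conv) == 0) next
    cp <- snp_map$pos[conv]
    di <- xi <- list()
    for (k in seq_along(conv)) {
      nb <- snp_range_idx(midx, ncos$chrom[i], cp[k] - window,
                          cp[k] + window)
      nb <- setdiff(nb, conv[k])
      if (length(nb) == 0) next
      di[[length(di) + 1]] <- abs(snp_map$pos[nb] - cp[k])
      xi[[length(xi) + 1]] <- as.integer(nb %in% conv)
    }
    d_all[[i]] <- unlist(di)
    x_all[[i]] <- unlist(xi)
  }
  out <- data.frame(d = as.numeric(unlist(d_all)),
                    x = as.integer(unlist(x_all)))
  out[out$d > 0, , drop = FALSE]
}

#' Simulate observed NCO events on a SNP map
#'
#' Places exponential conversion tracts uniformly along the genome
#' (start uniform, length exponential with mean `mean_bp`) and keeps
#' those containing at least one SNP — the observability condition —
#' until `n_events` observed events are collected. All SNPs inside a
#' tract are converted (a fully heterozygous parent). Used for
#' estimator-calibration experiments.
#'
#' @param n_events number of observed (>= 1 SNP) events to produce.
#' @param snp_map the SNP map.
#' @param mean_bp true mean tract length.
#' @param chrom_lengths chromosome lengths (bp).
#' @return an `nco_calls`-style data.frame (`chrom`, `min_start`,
#'   `min_end`, `converted_idx`, `converted_pos`, `n_sites`).
#' @export
simulate_nco_events <- function(n_events, snp_map, mean_bp,
                                chrom_lengths) {
  midx <- snp_index(snp_map)
  rows <- vector("list", n_events)
  got <- 0L
  probs <- chrom_lengths / sum(chrom_lengths)
  while (got < n_events) {
    k <- n_events - got
    ci <- sample.int(length(chrom_lengths), k, replace = TRUE,
                     prob = probs)
    t0 <- stats::runif(k, 1, chrom_lengths[ci])
    len <- stats::rexp(k, 1 / mean_bp)
    for (j in seq_len(k)) {
      idx <- snp_range_idx(midx, ci[j], t0[j], t0[j] + len[j])
      if (length(idx) == 0) next
      got <- got + 1L
      rows[[got]] <- data.frame(
        sample_id = "sim", chrom = ci[j],
        min_start = min(snp_map$pos[idx]),
        min_end = max(snp_map$pos[idx]),
        n_sites = length(idx),
        recipient_bg = "unknown", complex = FALSE,
        inheritance = "unknown", parent = "unknown",
        hotspot_id = NA_integer_,
        converted_idx = I(list(idx)),
        converted_pos = I(list(snp_map$pos[idx])),
        donor_allele = I(list(rep("CAST", length(idx)))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nco_calls", "data.frame")
  out
}

#' Probability that a SNP near a converted site is co-converted
#'
#' Under an exponential tract model with rate `lambda`, a SNP at
#' distance `d` from a converted focal site lies in the same tract
#' with probability `exp(-lambda d)`.
#'
#' @param lambda tract rate parameter (1/bp), > 0.
#' @param d distance(s) in bp, >= 0.
#' @return probabilities.
#' @examples
#' co_conversion_prob(1 / 30, 30)  # exp(-1)
#' @export
co_conversion_prob <- function(lambda, d) {
  if (any(lambda <= 0)) stop("`lambda` must be positive")
  if (any(d < 0)) stop("`d` must be non-negative")
  exp(-lambda * d)
}

#' Composite log-likelihood of focal/nearby pairs
#'
#' Sum over pairs of `x * (-lambda d) + (1 - x) * log(1 - exp(-lambda d))`.
#'
#' @param lambda tract rate (1/bp).
#' @param pairs data.frame from [build_pairs()].
#' @return the composite log-likelihood (a single number).
#' @export
composite_log_likelihood <- function(lambda, pairs) {
  if (nrow(pairs) == 0) stop("`pairs` is empty")
  p_in <- exp(-lambda * pairs$d)
  out <- 1 - p_in
  if (any(out <= 0 & pairs$x == 0)) {
    warning("non-co-converted pair at distance ~0; using large negative term")
    out <- pmax(out, 1e-300)
  }
  sum(pairs$x * (-lambda * pairs$d) + (1 - pairs$x) * log(out))
}

# tabulated sufficient statistics: S1 = sum of d over co-converted
# pairs; (d0, c0) = unique distances and counts of non-co-converted
# pairs. The grid log-likelihood only needs these.
pair_stats <- function(pairs) {
  d0 <- pairs$d[pairs$x == 0]
  tab <- table(d0)
  list(S1 = sum(pairs$d[pairs$x == 1]),
       n1 = sum(pairs$x == 1),
       d0 = as.numeric(names(tab)),
       c0 = as.numeric(tab))
}

cll_from_stats <- function(lambda, st) {
  -lambda * st$S1 + sum(st$c0 * log1p(-exp(-lambda * st$d0)))
}

#' Fit mean NCO tract length by composite likelihood
#'
#' Grid search over mean tract length `1/lambda` from `grid_min` to
#' `grid_max` bp in steps of `grid_step`, maximising
#' [composite_log_likelihood()]. Ties break toward the smaller mean;
#' a maximum on the grid edge sets `at_boundary`.
#'
#' @param pairs data.frame from [build_pairs()].
#' @param grid_min,grid_max,grid_step grid over mean tract length (bp).
#' @return list of class `tract_fit`: `lambda`, `mean_bp`, `loglik`,
#'   `at_boundary`, `grid` spec, `n_pairs`.
#' @export
fit_tract_length <- function(pairs, grid_min = 1, grid_max = 1000,
                             grid_step = 0.1) {
  if (nrow(pairs) == 0) stop("`pairs` is empty")
  st <- pair_stats(pairs)
  if (st$n1 == 0)
    warning("no co-converted pairs: maximum at the smallest mean")
  if (length(st$d0) == 0)
    warning("all pairs co-converted: maximum at the largest mean")
  means <- seq(grid_min, grid_max, by = grid_step)
  ll <- vapply(means, function(m) cll_from_stats(1 / m, st), numeric(1))
  best <- which.max(ll)   # first maximum = smaller mean on ties
  mean_bp <- means[best]
  structure(list(lambda = 1 / mean_bp, mean_bp = mean_bp,
                 loglik = ll[best],
                 at_boundary = best == 1L || best == length(means),
                 grid = c(min = grid_min, max = grid_max,
                          step = grid_step),
                 n_pairs = nrow(pairs)),
            class = "tract_fit")
}

#' @export
print.tract_fit <- function(x, ...) {
  cat(sprintf(
    "tract_fit: mean %.1f bp (lambda %.3g /bp), logCL %.2f, %d pairs%s\n",
    x$mean_bp, x$lambda, x$loglik, x$n_pairs,
    if (x$at_boundary) " [at grid boundary]" else ""))
  invisible(x)
}

#' Block-bootstrap confidence interval for the tract-length fit
#'
#' Tiles the genome into non-overlapping blocks (default 10 Mb; the
#' last block of each chromosome is shorter), resamples blocks with
#' replacement with probability proportional to block length, refits
#' the tract mean on each resample's events, and returns the
#' percentile interval.
#'
#' @param ncos `nco_calls` events.
#' @param snp_map the SNP map.
#' @param chrom_lengths chromosome lengths in bp.
#' @param block_bp block size (default 10 Mb).
#' @param B number of bootstrap resamples.
#' @param window pair window passed to [build_pairs()].
#' @param level confidence level (default 0.95).
#' @param grid_step grid step for the per-resample refits.
#' @return list: `ci` (low/high, bp), `boot_means`, `n_blocks`.
#' @export
bootstrap_tract_ci <- function(ncos, snp_map, chrom_lengths,
                               block_bp = 10e6, B = 1000,
                               window = 1000, level = 0.95,
                               grid_step = 0.1) {
  if (B <= 0) stop("`B` must be positive")
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  blocks <- genome_blocks(chrom_lengths, block_bp)
  mid <- (ncos$min_start + ncos$min_end) / 2
  ncos$block <- vapply(seq_len(nrow(ncos)), function(i) {
    b <- which(blocks$chrom == ncos$chrom[i] & blocks$start < mid[i] &
                 blocks$end >= mid[i])
    if (length(b) == 0) NA_integer_ else b[1]
  }, integer(1))
  # per-block pair statistics, combined per resample
  stats_by_block <- lapply(seq_len(nrow(blocks)), function(b) {
    ev <- ncos[!is.na(ncos$block) & ncos$block == b, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    pair_stats(build_pairs(ev, snp_map, window))
  })
  means <- seq(1, 1000, by = grid_step)
  d_union <- sort(unique(unlist(lapply(stats_by_block,
                                       function(s) s$d0))))
  # grid x distance matrix of log(1 - exp(-d/mean)), computed once
  M <- if (length(d_union) > 0)
    log1p(-exp(-outer(1 / means, d_union))) else NULL
  boot_means <- numeric(B)
  for (b in seq_len(B)) {
    draw <- sample.int(nrow(blocks), nrow(blocks), replace = TRUE,
                       prob = blocks$len)
    S1 <- 0; cvec <- numeric(length(d_union))
    for (bl in draw) {
      s <- stats_by_block[[bl]]
      if (is.null(s)) next
      S1 <- S1 + s$S1
      if (length(s$d0) > 0)
        cvec[match(s$d0, d_union)] <-
          cvec[match(s$d0, d_union)] + s$c0
    }
    if (S1 == 0 && all(cvec == 0)) { boot_means[b] <- NA; next }
    ll <- -S1 / means + if (is.null(M)) 0 else as.numeric(M %*% cvec)
    boot_means[b] <- means[which.max(ll)]
  }
  ok <- boot_means[!is.na(boot_means)]
  a <- (1 - level) / 2
  list(ci = stats::quantile(ok, c(a, 1 - a), names = FALSE),
       boot_means = boot_means, n_blocks = nrow(blocks))
}

#' Tile a genome into blocks
#'
#' @param chrom_lengths chromosome lengths (bp).
#' @param block_bp block size; the last block per chromosome is shorter.
#' @return data.frame `chrom`, `start`, `end`, `len` (0-based half-open).
#' @export
genome_blocks <- function(chrom_lengths, block_bp = 10e6) {
  out <- lapply(seq_along(chrom_lengths), function(ci) {
    starts <- seq(0, chrom_lengths[ci] - 1, by = block_bp)
    ends <- pmin(starts + block_bp, chrom_lengths[ci])
    data.frame(chrom = ci, start = starts, end = ends,
               len = ends - starts)
  })
  do.call(rbind, out)
}

#' Probability that a conversion tract contains at least one SNP
#'
#' Monte-Carlo: tracts with exponential length `1/lambda` are placed
#' at hotspot-like positions (supplied centers plus a zero-mean normal
#' displacement); returns the fraction containing >= 1 SNP of the map,
#' with its Monte-Carlo standard error.
#'
#' @param lambda tract rate (1/bp).
#' @param snp_map the SNP map.
#' @param centers data.frame `chrom`, `center` of placement sites
#'   (e.g. hotspot motif centers).
#' @param center_sd sd of the displacement (bp).
#' @param n_mc number of Monte-Carlo tracts.
#' @return list `prob`, `se`, `n_mc`.
#' @export
prob_tract_contains_snp <- function(lambda, snp_map, centers,
                                    center_sd = 200, n_mc = 10000) {
  if (lambda <= 0) stop("`lambda` must be positive")
  if (nrow(snp_map) == 0) stop("`snp_map` is empty")
  if (nrow(centers) == 0) stop("`centers` is empty")
  midx <- snp_index(snp_map)
  pick <- sample.int(nrow(centers), n_mc, replace = TRUE)
  cen <- centers$center[pick] + stats::rnorm(n_mc, 0, center_sd)
  len <- stats::rexp(n_mc, lambda)
  hit <- logical(n_mc)
  for (i in seq_len(n_mc)) {
    idx <- snp_range_idx(midx, centers$chrom[pick[i]],
                         cen[i] - len[i] / 2, cen[i] + len[i] / 2)
    hit[i] <- length(idx) > 0
  }
  p <- mean(hit)
  list(prob = p, se = sqrt(p * (1 - p) / n_mc), n_mc = n_mc)
}

#' Probability that a conversion tract yields an observable event
#'
#' Monte-Carlo companion to [prob_tract_contains_snp()] under the
#' two-pathway heteroduplex-repair model: a tract is observable when
#' it contains at least one SNP *and* is not fully restored by the
#' GC-restoring pathway, which blocks single-mismatch tracts whose
#' recipient base is G/C with probability `p_block`. The recipient
#' homologue at each placement is drawn from the center's B6 binding
#' ratio `x` (column `x` of `centers`, 0.5 when absent).
#'
#' @inheritParams prob_tract_contains_snp
#' @param p_block GC-restoring pathway probability.
#' @param weights optional sampling weights over centers (e.g.
#'   heat x binding); uniform when `NULL`.
#' @return list: `prob` (observable), `p_snp` (>= 1 SNP),
#'   `p_single` (exactly 1 SNP), `se`, `n_mc`.
#' @export
prob_tract_observable <- function(lambda, snp_map, centers,
                                  center_sd = 200, p_block = 0.53,
                                  weights = NULL, n_mc = 10000) {
  if (lambda <= 0) stop("`lambda` must be positive")
  if (nrow(snp_map) == 0) stop("`snp_map` is empty")
  if (nrow(centers) == 0) stop("`centers` is empty")
  midx <- snp_index(snp_map)
  x <- if ("x" %in% names(centers)) centers$x else rep(0.5, nrow(centers))
  pick <- sample.int(nrow(centers), n_mc, replace = TRUE,
                     prob = weights)
  cen <- centers$center[pick] + stats::rnorm(n_mc, 0, center_sd)
  len <- stats::rexp(n_mc, lambda)
  n_in <- integer(n_mc)
  obs <- logical(n_mc)
  for (i in seq_len(n_mc)) {
    idx <- snp_range_idx(midx, centers$chrom[pick[i]],
                         cen[i] - len[i] / 2, cen[i] + len[i] / 2)
    n_in[i] <- length(idx)
    if (n_in[i] == 0) next
    if (n_in[i] == 1) {
      recip_b6 <- stats::runif(1) < x[pick[i]]
      rb <- if (recip_b6) snp_map$allele_b6[idx]
            else snp_map$allele_cast[idx]
      blocked <- base_class(rb) == "S" && stats::runif(1) < p_block
      obs[i] <- !blocked
    } else obs[i] <- TRUE
  }
  p <- mean(obs)
  list(prob = p, p_snp = mean(n_in >= 1), p_single = mean(n_in == 1),
       se = sqrt(p * (1 - p) / n_mc), n_mc = n_mc)
}

#' Estimate total homologue-templated DSBs per meiosis
#'
#' Scales observed NCO and CO counts by detection power, the
#' probability that a tract contains a SNP, and CO detection
#' probability, then divides by the number of contributing meioses.
#' The parametric bootstrap resamples the observed counts as Poisson.
#'
#' @param observed_nco,observed_co observed event counts.
#' @param n_meioses number of contributing meioses.
#' @param power NCO detection power (filters) in (0, 1].
#' @param p_snp probability a tract contains >= 1 SNP, in (0, 1].
#' @param co_detect_prob CO detection probability, in (0, 1].
#' @param B bootstrap replicates for the CI.
#' @param level confidence level.
#' @return list of class `dsb_estimate`: `total_per_meiosis`, `ci`,
#'   and the audit `components`.
#' @export
estimate_total_dsbs <- function(observed_nco, observed_co, n_meioses,
                                power, p_snp, co_detect_prob = 1,
                                B = 2000, level = 0.95) {
  if (n_meioses < 1) stop("`n_meioses` must be >= 1")
  probs <- c(power = power, p_snp = p_snp, co = co_detect_prob)
  if (any(probs <= 0) || any(probs > 1))
    stop("power, p_snp and co_detect_prob must lie in (0, 1]")
  total <- (observed_nco / (power * p_snp) +
              observed_co / co_detect_prob) / n_meioses
  nco_b <- stats::rpois(B, observed_nco)
  co_b <- stats::rpois(B, observed_co)
  tot_b <- (nco_b / (power * p_snp) + co_b / co_detect_prob) / n_meioses
  a <- (1 - level) / 2
  structure(list(
    total_per_meiosis = total,
    ci = stats::quantile(tot_b, c(a, 1 - a), names = FALSE),
    components = list(observed_nco = observed_nco,
                      observed_co = observed_co,
                      n_meioses = n_meioses, power = power,
                      p_snp = p_snp, co_detect_prob = co_detect_prob)),
    class = "dsb_estimate")
}

#' @export
print.dsb_estimate <- function(x, ...) {
  cat(sprintf("dsb_estimate: %.1f per meiosis (%.1f-%.1f)\n",
              x$total_per_meiosis, x$ci[1], x$ci[2]))
  invisible(x)
}
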