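#' Detection-power simulation by spliced genotype calls
#'
#' For each mean tract length on the grid: hotspots are sampled with
#' probability proportional to H3K4me3 enrichment; a tract center is
#' drawn from the motif-displacement distribution and its length from
#' an exponential with the grid mean; tracts containing no SNP are
#' not potentially detectable. For each detectable tract a recipient
#' sample is drawn, a donor sample with a conversion-consistent
#' background at the tract SNPs is sought (recipient homozygous with
#' a heterozygous donor, or vice versa), and the donor's call-level
#' information (GT/DP/AD) is copied onto the recipient at the
#' converted sites. The full filter cascade is then applied; power is
#' the fraction of detectable tracts whose spliced candidates survive.
#'
#' @param hotspots hotspot table (uses `h3k4_total` when present, else
#'   `heat`, as the sampling enrichment).
#' @param snp_map the SNP map.
#' @param calls named list of `sample_genotypes` (the candidate
#'   recipient/donor pool).
#' @param founder_calls list(b6 =, cast =) founder genotypes for the
#'   filter cascade (may be `NULL`).
#' @param fconfig a [filter_config()]; pass `NULL` to disable
#'   filtering entirely (power is then 1 by construction).
#' @param grid mean tract lengths (bp) to evaluate.
#' @param n_draws tracts sampled per grid value.
#' @param center_sd sd of the tract-center displacement (bp).
#' @return data.frame of class `power_result`: per grid mean the
#'   number of simulated, detectable (>= 1 SNP), donor-eligible and
#'   surviving tracts, the power and its Monte-Carlo SE; attribute
#'   `"per_hotspot"` holds detection bookkeeping for
#'   [detection_weights()].
#' @export
run_power_simulation <- function(hotspots, snp_map, calls,
                                 founder_calls = NULL,
                                 fconfig = filter_config(),
                                 grid = c(seq(10, 100, 10),
                                          seq(150, 300, 50)),
                                 n_draws = 2000, center_sd = 200) {
  if (length(grid) == 0) stop("`grid` is empty")
  midx <- snp_index(snp_map)
  enrich <- if ("h3k4_total" %in% names(hotspots))
    hotspots$h3k4_total else hotspots$heat
  enrich <- pmax(enrich, 0)
  if (sum(enrich) <= 0) stop("total enrichment must be positive")
  mcen <- (hotspots$motif_start + hotspots$motif_end) / 2
  ids <- names(calls)
  det_hot <- integer(0)  # hotspot id of each detected tract
  sim_hot <- integer(0)  # hotspot id of each with->=1SNP tract
  rows <- lapply(grid, function(mu) {
    hs <- sample.int(nrow(hotspots), n_draws, replace = TRUE,
                     prob = enrich)
    cen <- mcen[hs] + stats::rnorm(n_draws, 0, center_sd)
    len <- stats::rexp(n_draws, 1 / mu)
    n_snp <- 0L; n_eligible <- 0L; n_surv <- 0L; n_skip <- 0L
    for (t in seq_len(n_draws)) {
      idx <- snp_range_idx(midx, hotspots$chrom[hs[t]],
                           cen[t] - len[t] / 2, cen[t] + len[t] / 2)
      if (length(idx) == 0) next
      n_snp <- n_snp + 1L
      sim_hot <<- c(sim_hot, hotspots$id[hs[t]])
      rec_id <- sample(ids, 1)
      rec <- calls[[rec_id]]
      rc <- rec$call[idx]
      if (any(is.na(rc))) { n_skip <- n_skip + 1L; next }
      rec_hom <- all(rc %in% c(0L, 2L)) && length(unique(rc)) == 1
      rec_het <- all(rc == 1L)
      if (!rec_hom && !rec_het) { n_skip <- n_skip + 1L; next }
      # donor must carry the opposite configuration at every tract SNP
      donor_id <- NULL
      for (cand in sample(setdiff(ids, rec_id))) {
        dc <- calls[[cand]]$call[idx]
        if (any(is.na(dc))) next
        if (rec_hom && all(dc == 1L)) { donor_id <- cand; break }
        if (rec_het && all(dc %in% c(0L, 2L)) &&
            length(unique(dc)) == 1 && dc[1] != rc[1]) {
          donor_id <- cand; break
        }
      }
      if (is.null(donor_id)) { n_skip <- n_skip + 1L; next }
      n_eligible <- n_eligible + 1L
      if (is.null(fconfig)) {
        n_surv <- n_surv + 1L
        det_hot <<- c(det_hot, hotspots$id[hs[t]])
        next
      }
      don <- calls[[donor_id]]
      cand_df <- data.frame(
        sample_id = rec_id, chrom = snp_map$chrom[idx],
        snp_idx = idx, pos = snp_map$pos[idx],
        call = don$call[idx],
        state = BG_STATES[rc + 1L],
        recipient_bg = "unknown", recipient_allele = "B6",
        donor_allele = "CAST",
        dp = don$dp[idx], ad_b6 = don$ad_b6[idx],
        ad_cast = don$ad_cast[idx], stringsAsFactors = FALSE)
      res <- apply_filters(cand_df, founder_calls, snp_map, fconfig)
      if (nrow(res$events) > 0) {
        n_surv <- n_surv + 1L
        det_hot <<- c(det_hot, hotspots$id[hs[t]])
      }
    }
    denom <- n_snp - n_skip   # detectable tracts with an eligible donor
    data.frame(mean_bp = mu, n_simulated = n_draws,
               n_with_snp = n_snp, n_no_donor = n_skip,
               n_surviving = n_surv,
               power = if (denom > 0) n_surv / denom else NA_real_,
               se = if (denom > 0)
                 sqrt(n_surv / denom * (1 - n_surv / denom) / denom)
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_result", "data.frame")
  attr(out, "per_hotspot") <- list(simulated = sim_hot,
                                   detected = det_hot)
  out
}

#' Per-hotspot NCO detection weights
#'
#' The weight of a hotspot is its estimated detection probability —
#' the Monte-Carlo probability that an exponential tract placed at
#' its motif contains at least one SNP — normalised to mean 1 over
#' hotspots. Hotspots with no nearby SNPs get weight ~0; under
#' uniform SNP density all weights are ~1.
#'
#' @param hotspots hotspot table.
#' @param snp_map the SNP map.
#' @param mean_bp mean tract length used for the tract model.
#' @param center_sd sd of the tract-center displacement.
#' @param n_mc Monte-Carlo tracts per hotspot.
#' @return numeric weight per hotspot (mean 1).
#' @export
detection_weights <- function(hotspots, snp_map, mean_bp = 30,
                              center_sd = 200, n_mc = 200) {
  midx <- snp_index(snp_map)
  mcen <- (hotspots$motif_start + hotspots$motif_end) / 2
  p <- vapply(seq_len(nrow(hotspots)), function(i) {
    cen <- mcen[i] + stats::rnorm(n_mc, 0, center_sd)
    len <- stats::rexp(n_mc, 1 / mean_bp)
    hit <- vapply(seq_len(n_mc), function(t)
      length(snp_range_idx(midx, hotspots$chrom[i],
                           cen[t] - len[t] / 2,
                           cen[t] + len[t] / 2)) > 0, logical(1))
    mean(hit)
  }, numeric(1))
  if (sum(p) <= 0) stop("all detection probabilities are zero")
  p / mean(p)
}
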