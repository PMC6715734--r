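#' B6 binding/cutting ratio from homologue-assignable read counts
#'
#' `x = b6 / (b6 + cast)` when at least `min_informative` informative
#' reads are present, else `NA`. An optional background correction
#' (for H3K4me3, where input chromatin contributes reads) subtracts a
#' scaled input estimate from each homologue count before the ratio.
#'
#' @param b6_count,cast_count informative read counts.
#' @param min_informative minimum informative reads (default 10).
#' @param input_b6,input_cast matched input (background) counts.
#' @param input_factor scale factor applied to the input counts before
#'   subtraction (0 = no correction).
#' @return the ratio(s) in `[0, 1]`, `NA` where undefined.
#' @export
b6_ratio <- function(b6_count, cast_count, min_informative = 10,
                     input_b6 = 0, input_cast = 0, input_factor = 0) {
  if (any(b6_count < 0) || any(cast_count < 0))
    stop("counts must be non-negative")
  b6 <- pmax(0, b6_count - input_factor * input_b6)
  ca <- pmax(0, cast_count - input_factor * input_cast)
  tot_raw <- b6_count + cast_count
  out <- ifelse(tot_raw >= min_informative & (b6 + ca) > 0,
                b6 / (b6 + ca), NA_real_)
  out
}

#' Hotspot symmetry
#'
#' `4 x (1 - x)`: 0 when PRDM9 binds/cuts only one homologue, 1 when
#' both homologues are bound equally.
#'
#' @param x B6 binding/cutting ratio in `[0, 1]` (`NA` propagates).
#' @return symmetry in `[0, 1]`.
#' @examples
#' symmetry(0.5); symmetry(0.9)
#' @export
symmetry <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("`x` must lie in [0, 1]")
  4 * x * (1 - x)
}

#' Homologous heat
#'
#' Heat attributed to the repair-template homologue: an event whose
#' recipient (broken) chromosome is CAST is templated by the B6
#' homologue, so its homologous heat is `x h`; a B6-recipient event is
#' templated by CAST, giving `(1 - x) h`.
#'
#' @param x B6 binding ratio.
#' @param h total hotspot heat (> 0).
#' @param recipient `"B6"` or `"CAST"` (the homologue carrying the DSB).
#' @return homologous heat (`NA` where `x` is `NA`).
#' @export
homologous_heat <- function(x, h, recipient = c("CAST", "B6")) {
  recipient <- match.arg(recipient)
  if (any(h <= 0, na.rm = TRUE)) stop("`h` must be positive")
  if (recipient == "CAST") x * h else (1 - x) * h
}

#' Average homologous heat
#'
#' `2 h x (1 - x)`: homologous heat averaged over the homologue an
#' event initiates on, weighting by the initiation fractions `x` and
#' `1 - x`.
#'
#' @inheritParams homologous_heat
#' @return average homologous heat.
#' @export
average_homologous_heat <- function(x, h) {
  if (any(h <= 0, na.rm = TRUE)) stop("`h` must be positive")
  2 * h * x * (1 - x)
}

#' Bin hotspots by symmetry into equal predicted-event groups
#'
#' Orders hotspots by symmetry and cuts the cumulative predicted-event
#' mass (proportional to the supplied enrichment) into `n_bins` groups
#' of equal mass, so each bin is expected to contain the same number
#' of events. Hotspots with tied symmetry stay in one bin.
#'
#' @param hotspots hotspot table with a `symmetry` column.
#' @param enrichment per-hotspot predicted-event mass (e.g. DMC1
#'   counts).
#' @param n_bins number of bins (default 3: asymmetric, intermediate,
#'   symmetric).
#' @return integer bin per hotspot (1 = most asymmetric), NA where
#'   symmetry or enrichment is undefined.
#' @export
bin_by_symmetry <- function(hotspots, enrichment, n_bins = 3) {
  s <- hotspots$symmetry
  ok <- !is.na(s) & !is.na(enrichment) & enrichment >= 0
  if (length(unique(s[ok])) < n_bins)
    stop("degenerate binning: fewer distinct symmetry values than bins")
  ord <- order(s)
  bin <- rep(NA_integer_, length(s))
  mass <- ifelse(ok[ord], enrichment[ord], 0)
  total <- sum(mass)
  if (total <= 0) stop("total enrichment must be positive")
  cum_left <- cumsum(mass) - mass   # mass strictly below each hotspot
  raw <- pmin(n_bins,
              1L + as.integer(floor(cum_left / total * n_bins + 1e-12)))
  # keep tied symmetry values together (first bin they appear in)
  sv <- s[ord]
  for (i in seq_along(raw)[-1])
    if (!is.na(sv[i]) && !is.na(sv[i - 1]) && sv[i] == sv[i - 1])
      raw[i] <- raw[i - 1]
  bin[ord] <- raw
  bin[!ok] <- NA_integer_
  bin
}

#' Observed vs expected events across symmetry bins
#'
#' Expected fraction per bin is the (optionally detection-weighted)
#' enrichment mass; observed fractions are computed per event class,
#' with binomial CIs, and compared by a chi-square goodness-of-fit
#' test.
#'
#' @param event_hotspots list of integer vectors (one per event class,
#'   named) of hotspot ids the events were assigned to; events not
#'   assigned to a binned hotspot are dropped and counted.
#' @param hotspots hotspot table (with `id`).
#' @param bins integer bin per hotspot from [bin_by_symmetry()].
#' @param enrichment per-hotspot predicted mass (same as used for
#'   binning).
#' @param weights optional per-hotspot detection weights applied to
#'   the expected mass (default 1).
#' @return list of class `symmetry_bins`: `expected` (fraction per
#'   bin), per-class data.frame `observed` (counts, fractions, CI),
#'   `chisq` (stat, df, p per class), `n_dropped`.
#' @export
observed_vs_expected <- function(event_hotspots, hotspots, bins,
                                 enrichment, weights = NULL) {
  n_bins <- max(bins, na.rm = TRUE)
  if (n_bins < 2) stop("need at least 2 bins for a chi-square test")
  w <- if (is.null(weights)) rep(1, nrow(hotspots)) else weights
  mass <- tapply(enrichment * w, bins, sum)
  expected <- as.numeric(mass[as.character(seq_len(n_bins))])
  expected[is.na(expected)] <- 0
  if (any(expected == 0)) stop("a bin has zero expected mass")
  expected <- expected / sum(expected)
  bin_of <- bins[match(seq_len(max(hotspots$id)), hotspots$id)]
  observed <- list(); chisq <- list(); n_dropped <- integer()
  for (cl in names(event_hotspots)) {
    hid <- event_hotspots[[cl]]
    b <- bin_of[hid]
    n_dropped[cl] <- sum(is.na(b))
    b <- b[!is.na(b)]
    counts <- tabulate(b, nbins = n_bins)
    n <- sum(counts)
    ci <- t(vapply(seq_len(n_bins), function(k) {
      if (n == 0) return(c(NA_real_, NA_real_))
      as.numeric(stats::binom.test(counts[k], n)$conf.int)
    }, numeric(2)))
    observed[[cl]] <- data.frame(bin = seq_len(n_bins),
                                 count = counts,
                                 fraction = if (n > 0) counts / n else NA,
                                 ci_low = ci[, 1], ci_high = ci[, 2])
    exp_counts <- expected * n
    stat <- sum((counts - exp_counts)^2 / exp_counts)
    chisq[[cl]] <- c(stat = stat, df = n_bins - 1,
                     p = stats::pchisq(stat, n_bins - 1,
                                       lower.tail = FALSE))
  }
  structure(list(expected = expected, observed = observed,
                 chisq = chisq, n_dropped = n_dropped),
            class = "symmetry_bins")
}

#' Expected vs observed initiation on the less-bound homologue
#'
#' For each symmetry class, compares the H3K4me3 fraction on the
#' less-bound homologue (the PRDM9-binding expectation), the DMC1
#' fraction on that homologue, and the observed fraction of events
#' initiating there, with bootstrap CIs over hotspots/events.
#'
#' @param events `nco_calls`-style rows with `hotspot_id` and a known
#'   `recipient_bg` (`"B6"`/`"CAST"`).
#' @param hotspots hotspot table with ChIP count columns from
#'   [simulate_chip_counts()] (or equivalent).
#' @param symmetric_min symmetry threshold separating the symmetric
#'   class from the asymmetric one (default 0.75).
#' @param B bootstrap replicates.
#' @return data.frame per class: mean H3K4me3/DMC1/event fractions on
#'   the less-bound homologue with 95% bootstrap CIs and counts.
#' @export
initiation_fraction_less_bound <- function(events, hotspots,
                                           symmetric_min = 0.75,
                                           B = 1000) {
  ev <- events[!is.na(events$hotspot_id) &
                 events$recipient_bg %in% c("B6", "CAST"), ]
  if (nrow(ev) == 0) stop("no assigned events with known recipient")
  hs <- hotspots
  x_h <- b6_ratio(hs$h3k4_b6, hs$h3k4_cast)
  x_d <- b6_ratio(hs$dmc1_b6, hs$dmc1_cast)
  less_b6 <- x_h < 0.5          # B6 is the less-bound homologue
  h3_frac <- ifelse(less_b6, x_h, 1 - x_h)
  d_frac <- ifelse(less_b6, x_d, 1 - x_d)
  sym_class <- ifelse(symmetry(x_h) >= symmetric_min,
                      "symmetric", "asymmetric")
  hrow <- match(ev$hotspot_id, hs$id)
  ev_less <- (ev$recipient_bg == "B6") == less_b6[hrow]
  ev_class <- sym_class[hrow]
  out <- lapply(c("symmetric", "asymmetric"), function(cl) {
    hsel <- which(sym_class == cl & !is.na(h3_frac))
    esel <- which(ev_class == cl & !is.na(ev_less))
    boot <- function(v, n = length(v))
      vapply(seq_len(B), function(b)
        mean(v[sample.int(n, n, replace = TRUE)], na.rm = TRUE),
        numeric(1))
    ci <- function(v) if (length(v) < 2) c(NA, NA) else
      stats::quantile(boot(v), c(0.025, 0.975), names = FALSE)
    data.frame(class = cl,
               h3k4_frac = mean(h3_frac[hsel], na.rm = TRUE),
               h3k4_lo = ci(h3_frac[hsel])[1],
               h3k4_hi = ci(h3_frac[hsel])[2],
               dmc1_frac = mean(d_frac[hsel], na.rm = TRUE),
               dmc1_lo = ci(d_frac[hsel])[1],
               dmc1_hi = ci(d_frac[hsel])[2],
               event_frac = mean(ev_less[esel]),
               event_lo = ci(as.numeric(ev_less[esel]))[1],
               event_hi = ci(as.numeric(ev_less[esel]))[2],
               n_hotspots = length(hsel), n_events = length(esel))
  })
  do.call(rbind, out)
}

#' Fraction of hotspots with a variant-disrupted motif, per
#' initiation bin
#'
#' Restricts to hotspots with a confidently placed motif and enough
#' informative DMC1 reads, bins them by the B6 initiation fraction,
#' and reports the fraction whose motif interval overlaps at least
#' one variant.
#'
#' @param hotspots hotspot table with `motif_start`, `motif_end`,
#'   `motif_posterior` and DMC1 count columns.
#' @param variants data.frame `chrom`, `pos` (e.g. the SNP map).
#' @param breaks bin breaks on the B6 initiation fraction.
#' @param motif_posterior_min minimum motif posterior (default 0.99).
#' @param min_informative minimum informative DMC1 reads (default 20).
#' @return data.frame per bin: `bin`, `n`, `fraction_disrupted`.
#' @export
motif_disruption_fraction <- function(hotspots, variants,
                                      breaks = seq(0, 1, 0.1),
                                      motif_posterior_min = 0.99,
                                      min_informative = 20) {
  x <- b6_ratio(hotspots$dmc1_b6, hotspots$dmc1_cast,
                min_informative = min_informative)
  keep <- !is.na(x) & hotspots$motif_posterior > motif_posterior_min
  hs <- hotspots[keep, ]
  x <- x[keep]
  has_var <- vapply(seq_len(nrow(hs)), function(i)
    any(variants$chrom == hs$chrom[i] &
          variants$pos >= hs$motif_start[i] &
          variants$pos <= hs$motif_end[i]), logical(1))
  bin <- cut(x, breaks, include.lowest = TRUE)
  agg <- tapply(has_var, bin, function(v) c(length(v), mean(v)))
  out <- data.frame(bin = levels(bin),
                    n = vapply(agg, function(a)
                      if (is.null(a)) 0 else a[1], numeric(1)),
                    fraction_disrupted = vapply(agg, function(a)
                      if (is.null(a)) NA_real_ else a[2], numeric(1)))
  rownames(out) <- NULL
  out
}

#' Binomial GLM: does asymmetry or SNP density predict repair?
#'
#' Fits `has_event ~ symmetry + log(h3k4 + 1e-4) + density_100 +
#' density_500 + density_800` with a logit link across hotspots, where
#' the densities are SNP counts per bp around the motif center at
#' +/-100, 500 and 800 bp. For power-corrected NCO analyses the
#' hotspots are first resampled with replacement proportional to the
#' supplied detection weights (rejection sampling; hotspots may appear
#' several times).
#'
#' @param has_event logical per hotspot: >= 1 overlapping event.
#' @param hotspots hotspot table (needs `symmetry`, `h3k4_total`,
#'   motif columns).
#' @param snp_map the SNP map for the density predictors.
#' @param weights optional per-hotspot detection weights.
#' @param scales half-widths (bp) of the density windows.
#' @return data.frame of coefficients, standard errors and two-sided
#'   p-values; attribute `"separation"` flags non-convergence or
#'   fitted probabilities at 0/1.
#' @export
glm_symmetry_vs_density <- function(has_event, hotspots, snp_map,
                                    weights = NULL,
                                    scales = c(100, 500, 800)) {
  if (length(unique(has_event)) < 2)
    stop("degenerate fit: response is constant")
  midx <- snp_index(snp_map)
  mcen <- (hotspots$motif_start + hotspots$motif_end) / 2
  dens <- sapply(scales, function(s)
    vapply(seq_len(nrow(hotspots)), function(i)
      length(snp_range_idx(midx, hotspots$chrom[i], mcen[i] - s,
                           mcen[i] + s)) / (2 * s), numeric(1)))
  colnames(dens) <- paste0("density_", scales)
  h3 <- if ("h3k4_total" %in% names(hotspots)) hotspots$h3k4_total
        else hotspots$heat
  df <- data.frame(y = as.integer(has_event),
                   symmetry = hotspots$symmetry,
                   log_h3k4 = log(h3 + 1e-4), dens)
  if (!is.null(weights)) {
    idx <- sample.int(nrow(df), nrow(df), replace = TRUE,
                      prob = pmax(weights, 0))
    df <- df[idx, ]
  }
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  sep <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (sep) warning("possible separation: coefficients may be unstable")
  co <- summary(fit)$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1],
                    std_error = co[, 2], p_value = co[, 4],
                    row.names = NULL)
  attr(out, "separation") <- sep
  out
}

#' Distances from events to hotspot motifs
#'
#' Two variants are reported for NCOs: the distance from the motif
#' center to the nearest converted marker (0 if a converted marker
#' falls inside the motif) and the distance from the minimal-tract
#' midpoint to the motif center. Events farther than `max_dist` from
#' every motif are unassigned. The histogram is normalised by the SNP
#' count per distance bin to correct for detection power.
#'
#' @param ncos `nco_calls` rows.
#' @param hotspots hotspot table with motif columns.
#' @param snp_map the SNP map (for the normalisation).
#' @param max_dist association radius (default 1000 bp).
#' @param bin_width histogram bin width (bp).
#' @return list: `distances` (per event: `d_nearest_marker`,
#'   `d_midpoint`, `hotspot_id`), `histogram` (bin, count,
#'   snp_density_normalised).
#' @export
event_motif_distance <- function(ncos, hotspots, snp_map,
                                 max_dist = 1000, bin_width = 100) {
  if (nrow(hotspots) == 0) stop("no motifs supplied")
  mcen <- (hotspots$motif_start + hotspots$motif_end) / 2
  n <- nrow(ncos)
  d1 <- d2 <- rep(NA_real_, n)
  hid <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sel <- which(hotspots$chrom == ncos$chrom[i])
    if (length(sel) == 0) next
    mid <- (ncos$min_start[i] + ncos$min_end[i]) / 2
    k <- sel[which.min(abs(mcen[sel] - mid))]
    if (abs(mcen[k] - mid) > max_dist) next
    hid[i] <- hotspots$id[k]
    cp <- ncos$converted_pos[[i]]
    inside <- any(cp >= hotspots$motif_start[k] &
                    cp <= hotspots$motif_end[k])
    d1[i] <- if (inside) 0 else min(abs(cp - mcen[k]))
    d2[i] <- abs(mid - mcen[k])
  }
  breaks <- seq(0, max_dist + bin_width, by = bin_width)
  hcount <- graphics::hist(d2[!is.na(d2)], breaks = breaks,
                           plot = FALSE)$counts
  # SNPs per distance bin, pooled over assigned motifs
  snp_d <- unlist(lapply(which(!is.na(hid)), function(i) {
    k <- match(hid[i], hotspots$id)
    idx <- snp_range_idx(snp_index(snp_map), hotspots$chrom[k],
                         mcen[k] - max_dist, mcen[k] + max_dist)
    abs(snp_map$pos[idx] - mcen[k])
  }))
  scount <- graphics::hist(snp_d[snp_d <= max(breaks)],
                           breaks = breaks, plot = FALSE)$counts
  list(distances = data.frame(d_nearest_marker = d1,
                              d_midpoint = d2, hotspot_id = hid),
       histogram = data.frame(
         bin_start = breaks[-length(breaks)],
         count = hcount,
         normalised = ifelse(scount > 0, hcount / scount, NA_real_)))
}
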