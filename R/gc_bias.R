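#' Classify NCO conversions by donor/recipient base
#'
#' One record per converted site: recipient base (the replaced allele),
#' donor base (the copied-in allele), their strong/weak classes
#' (S = G/C, W = A/T), a strand-equivalence-collapsed type label
#' (a pair and its reverse complement pool together), the event's
#' tract-size class (single vs multi converted SNP) and the distance
#' from the site to its nearest neighbouring SNP. The recipient/donor
#' *alleles* are phase-free (they follow from the conversion
#' direction), so records are emitted even when the recipient
#' homologue is unknown.
#'
#' @param ncos `nco_calls` data.frame.
#' @param snp_map the SNP map.
#' @return data.frame of class `conversion_records`: `event`, `pos`,
#'   `recipient_base`, `donor_base`, `recipient_class`, `donor_class`,
#'   `type`, `tract_size_class`, `nearest_snp_dist`, `recipient_bg`.
#' @export
classify_conversions <- function(ncos, snp_map) {
  if (nrow(ncos) == 0)
    return(data.frame(event = integer(), pos = numeric(),
                      recipient_base = character(),
                      donor_base = character(),
                      recipient_class = character(),
                      donor_class = character(), type = character(),
                      tract_size_class = character(),
                      nearest_snp_dist = numeric(),
                      recipient_bg = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(ncos)), function(i) {
    idx <- ncos$converted_idx[[i]]
    if (length(idx) == 0) return(NULL)
    donor_lbl <- ncos$donor_allele[[i]]
    donor_base <- ifelse(donor_lbl == "B6", snp_map$allele_b6[idx],
                         snp_map$allele_cast[idx])
    recip_base <- ifelse(donor_lbl == "B6", snp_map$allele_cast[idx],
                         snp_map$allele_b6[idx])
    nd <- nearest_neighbour_dist(snp_map, idx)
    data.frame(event = i, pos = snp_map$pos[idx],
               recipient_base = recip_base, donor_base = donor_base,
               recipient_class = base_class(recip_base),
               donor_class = base_class(donor_base),
               type = strand_equiv_type(recip_base, donor_base),
               tract_size_class = if (length(idx) == 1) "single"
                                  else "multi",
               nearest_snp_dist = nd,
               recipient_bg = ncos$recipient_bg[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("conversion_records", "data.frame")
  out
}

# distance from each SNP (by row index) to its nearest same-chromosome
# neighbour; the map is sorted by (chrom, pos)
nearest_neighbour_dist <- function(snp_map, idx) {
  n <- nrow(snp_map)
  up <- ifelse(idx < n & snp_map$chrom[pmin(idx + 1L, n)] ==
                 snp_map$chrom[idx],
               snp_map$pos[pmin(idx + 1L, n)] - snp_map$pos[idx], Inf)
  dn <- ifelse(idx > 1L & snp_map$chrom[pmax(idx - 1L, 1L)] ==
                 snp_map$chrom[idx],
               snp_map$pos[idx] - snp_map$pos[pmax(idx - 1L, 1L)], Inf)
  pmin(up, dn)
}

# strand-equivalence collapse: (recipient, donor) pools with its
# reverse complement, e.g. C>A with G>T
strand_equiv_type <- function(recipient, donor) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a <- paste0(recipient, ">", donor)
  b <- paste0(comp[recipient], ">", comp[donor])
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' GC-bias fraction among W/S conversions
#'
#' Restricts records to conversions between a weak and a strong base
#' and reports the weak-to-strong fraction with an exact binomial CI
#' and a two-sided test against 0.5.
#'
#' @param records `conversion_records` (or a subset).
#' @return list: `fraction`, `k` (W to S), `n`, `ci`, `p_value`.
#' @export
gc_bias_fraction <- function(records) {
  ws <- records[records$recipient_class != records$donor_class, ]
  if (nrow(ws) == 0) stop("no W/S-informative conversions")
  k <- sum(ws$recipient_class == "W" & ws$donor_class == "S")
  n <- nrow(ws)
  bt <- stats::binom.test(k, n, 0.5)
  list(fraction = k / n, k = k, n = n,
       ci = as.numeric(bt$conf.int), p_value = bt$p.value)
}

#' Fisher test of GC-bias in single- vs multi-SNP tracts
#'
#' Two-by-two table of tract-size class against conversion direction
#' (W to S / S to W), tested by a two-sided Fisher exact test
#' (minimum-likelihood convention).
#'
#' @param records `conversion_records`.
#' @return list: `table`, `p_value`, `odds_ratio`.
#' @export
single_vs_multi_test <- function(records) {
  ws <- records[records$recipient_class != records$donor_class, ]
  tab <- table(factor(ws$tract_size_class,
                      levels = c("single", "multi")),
               factor(ifelse(ws$recipient_class == "W", "WtoS",
                             "StoW"), levels = c("WtoS", "StoW")))
  if (any(rowSums(tab) == 0))
    stop("both tract-size classes need W/S conversions")
  ft <- stats::fisher.test(tab)
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

#' GC-bias stratified by distance to the nearest SNP
#'
#' @param records `conversion_records`.
#' @param breaks distance bin breaks in bp (default log-spaced to
#'   1 kb).
#' @return data.frame per bin: `bin`, `n`, `fraction`, `ci_low`,
#'   `ci_high` (`NA` rows for empty bins).
#' @export
distance_stratified_bias <- function(records,
                                     breaks = c(0, 10, 30, 100, 300,
                                                1000, Inf)) {
  ws <- records[records$recipient_class != records$donor_class, ]
  bin <- cut(ws$nearest_snp_dist, breaks, include.lowest = TRUE)
  out <- lapply(levels(bin), function(lv) {
    sel <- which(bin == lv)
    if (length(sel) == 0)
      return(data.frame(bin = lv, n = 0L, fraction = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    k <- sum(ws$recipient_class[sel] == "W")
    bt <- stats::binom.test(k, length(sel))
    data.frame(bin = lv, n = length(sel), fraction = k / length(sel),
               ci_low = bt$conf.int[1], ci_high = bt$conf.int[2])
  })
  do.call(rbind, out)
}

#' Relative conversion proportions of single-SNP NCO types
#'
#' For each strand-equivalent donor/recipient type, the proportion of
#' observed single-SNP conversions of that type divided by the
#' corresponding proportion in a GC-bias-free reference composition
#' (nearest non-converted markers, or multi-SNP-event conversions).
#'
#' @param records single-SNP `conversion_records`.
#' @param reference data.frame with `type` and `prop` columns (or a
#'   `conversion_records` whose type composition is used).
#' @return data.frame per type: `type`, `n`, `prop`, `ref_prop`,
#'   `ratio`, `ci_low`, `ci_high` (binomial CI on the observed
#'   proportion, scaled by the reference).
#' @export
relative_conversion_proportions <- function(records, reference) {
  if ("prop" %in% names(reference)) {
    ref <- reference
  } else {
    tt <- table(reference$type)
    ref <- data.frame(type = names(tt),
                      prop = as.numeric(tt) / sum(tt))
  }
  tt <- table(records$type)
  n <- sum(tt)
  out <- lapply(ref$type, function(ty) {
    k <- if (ty %in% names(tt)) as.integer(tt[[ty]]) else 0L
    rp <- ref$prop[ref$type == ty]
    if (rp == 0)
      return(data.frame(type = ty, n = k, prop = NA_real_,
                        ref_prop = 0, ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    bt <- stats::binom.test(k, n)
    data.frame(type = ty, n = k, prop = k / n, ref_prop = rp,
               ratio = (k / n) / rp, ci_low = bt$conf.int[1] / rp,
               ci_high = bt$conf.int[2] / rp)
  })
  do.call(rbind, out)
}

#' Expected observed GC-bias under the two-pathway model
#'
#' With DSBs equally likely on either homologue at a W/S site, a
#' W-recipient heteroduplex always converts (donor-biased pathway)
#' while an S-recipient one converts only when the GC-restoring
#' pathway (probability `p_block`) does not act. The W-to-S fraction
#' among *observed* conversions is therefore `1 / (2 - p_block)`.
#'
#' @param p_block GC-restoring pathway probability in `[0, 1]`.
#' @return expected observed W-to-S fraction.
#' @examples
#' expected_observed_bias(0.53)  # ~0.68
#' @export
expected_observed_bias <- function(p_block) {
  if (any(p_block < 0 | p_block > 1)) stop("`p_block` must be in [0, 1]")
  1 / (2 - p_block)
}

#' Invert the two-pathway bias relation
#'
#' @param bias observed W-to-S fraction.
#' @return implied `p_block = 2 - 1/bias`; values `<= 0.5` are flagged
#'   (they imply a non-positive blocking probability).
#' @export
p_block_from_bias <- function(bias) {
  if (any(bias <= 0 | bias > 1)) stop("`bias` must be in (0, 1]")
  p <- 2 - 1 / bias
  if (any(p <= 0))
    warning("bias <= 0.5 implies p_block <= 0 (no GC-restoring pathway)")
  p
}

#' Bias cap when the GC-restoring pathway acts at only one base
#'
#' If the mechanism operates only at recipient G bases, or only at
#' recipient C bases, at most half of the S-recipient configurations
#' can be blocked even at full strength, capping the observed bias at
#' `1 / (2 - 0.5) = 2/3` (about 67%).
#'
#' @return the capped fraction (2/3).
#' @export
cap_bias_single_base <- function() {
  expected_observed_bias(0.5)
}

#' Tally blocked markers in complex events
#'
#' Counts the internal non-converted markers of complex events whose
#' recipient chromosome carries a strong (G/C) base, and tests the
#' fraction against 0.5 with an exact two-sided binomial test.
#'
#' @param ncos `nco_calls` (and/or complex CO rows with the same
#'   columns) — only rows with `complex == TRUE` are used.
#' @param snp_map the SNP map.
#' @return list: `k` (S-recipient blocked markers), `n`, `p_value`.
#' @export
blocked_marker_tally <- function(ncos, snp_map) {
  cx <- ncos[ncos$complex, , drop = FALSE]
  if (nrow(cx) == 0) stop("no complex events")
  k <- 0L; n <- 0L
  midx <- snp_index(snp_map)
  for (i in seq_len(nrow(cx))) {
    conv <- cx$converted_idx[[i]]
    inner <- snp_range_idx(midx, cx$chrom[i], min(snp_map$pos[conv]),
                           max(snp_map$pos[conv]))
    blocked <- setdiff(inner, conv)
    if (length(blocked) == 0) next
    # the recipient founder allele follows the event's conversion
    # direction (donor labels are phase-free)
    donor_lbl <- unique(cx$donor_allele[[i]])
    recip_founder <- if (length(donor_lbl) == 1)
      c(B6 = "CAST", CAST = "B6")[[donor_lbl]] else NA_character_
    if (is.na(recip_founder)) next
    rb <- if (recip_founder == "B6") snp_map$allele_b6[blocked]
          else snp_map$allele_cast[blocked]
    k <- k + sum(base_class(rb) == "S")
    n <- n + length(blocked)
  }
  if (n == 0) stop("complex events carry no internal blocked markers")
  list(k = k, n = n, p_value = stats::binom.test(k, n, 0.5)$p.value)
}

#' Exact two-sided binomial p-value for a blocked-marker count
#'
#' Convenience for printed-count checks: `P` of outcomes at most as
#' likely as `k` successes out of `n` at probability 0.5 (equals twice
#' the smaller tail by symmetry).
#'
#' @param k,n successes and trials.
#' @return the two-sided p-value.
#' @examples
#' binom_two_sided(18, 19)  # ~7.6e-5
#' @export
binom_two_sided <- function(k, n) {
  stats::binom.test(k, n, 0.5)$p.value
}

#' Required DSB totals under alternative observability models
#'
#' @param observable_fraction_strand_aware,observable_fraction_strand_unaware
#'   model-specific probabilities that a DSB repair yields an
#'   observable event, in (0, 1].
#' @param observed_total observed (or inferred observable) DSB total.
#' @return named vector of required totals under each model
#'   (`observed_total / observable_fraction`).
#' @export
required_dsb_ratio <- function(observable_fraction_strand_aware,
                               observable_fraction_strand_unaware,
                               observed_total) {
  f <- c(strand_aware = observable_fraction_strand_aware,
         strand_unaware = observable_fraction_strand_unaware)
  if (any(f <= 0 | f > 1))
    stop("observable fractions must lie in (0, 1]")
  observed_total / f
}
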