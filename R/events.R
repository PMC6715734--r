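#' Call crossovers from background segments
#'
#' One call per adjacent pair of same-chromosome segments with
#' different states; the breakpoint interval runs from the last SNP of
#' the left segment to the first SNP of the right segment. Pairs of
#' opposite switches that return to the original state within
#' `nco_like_max_snps` SNPs are flagged `nco_like` (they are better
#' explained as a conversion than as two crossovers).
#'
#' @param background a `background` object or its `segments` data.frame.
#' @param nco_like_max_snps maximum SNP span of an excursion for the
#'   `nco_like` flag.
#' @return data.frame of class `crossover_calls`: `sample_id`, `chrom`,
#'   `left_idx`, `right_idx`, `left_pos`, `right_pos`, `resolution`,
#'   `state_left`, `state_right`, `nco_like`, `inheritance`, `parent`,
#'   `complex`.
#' @export
call_crossovers <- function(background, nco_like_max_snps = 2) {
  seg <- if (inherits(background, "background")) background$segments
         else background
  out <- data.frame(sample_id = character(), chrom = integer(),
                    left_idx = integer(), right_idx = integer(),
                    left_pos = numeric(), right_pos = numeric(),
                    resolution = numeric(), state_left = character(),
                    state_right = character(), nco_like = logical(),
                    stringsAsFactors = FALSE)
  if (nrow(seg) >= 2) {
    i <- seq_len(nrow(seg) - 1)
    adj <- seg$chrom[i] == seg$chrom[i + 1] &
      seg$sample_id[i] == seg$sample_id[i + 1] &
      seg$state[i] != seg$state[i + 1]
    j <- i[adj]
    if (length(j) > 0) {
      out <- data.frame(
        sample_id = seg$sample_id[j], chrom = seg$chrom[j],
        left_idx = seg$last_idx[j], right_idx = seg$first_idx[j + 1],
        left_pos = seg$last_pos[j], right_pos = seg$first_pos[j + 1],
        resolution = seg$first_pos[j + 1] - seg$last_pos[j],
        state_left = seg$state[j], state_right = seg$state[j + 1],
        nco_like = FALSE, stringsAsFactors = FALSE)
      # flag A -> B -> A excursions spanning few SNPs
      if (nrow(out) >= 2) {
        k <- seq_len(nrow(out) - 1)
        span <- out$right_idx[k + 1] - out$left_idx[k] - 1L
        exc <- out$chrom[k] == out$chrom[k + 1] &
          out$sample_id[k] == out$sample_id[k + 1] &
          out$state_left[k] == out$state_right[k + 1] &
          span <= nco_like_max_snps
        out$nco_like[k][exc] <- TRUE
        out$nco_like[k + 1][exc] <- TRUE
      }
    }
  }
  out$inheritance <- rep("unknown", nrow(out))
  out$parent <- rep("unknown", nrow(out))
  out$complex <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("crossover_calls", "data.frame")
  out
}

#' Candidate converted sites
#'
#' Emits every SNP whose genotype call conflicts with its assigned
#' background state, with the implied conversion direction: the
#' recipient allele is the founder allele that was replaced and the
#' donor allele the one copied in. The recipient *background*
#' (homologue carrying the DSB) is known for conflicts in homozygous
#' segments and unknown in heterozygous (BC) segments, where phase is
#' ambiguous.
#'
#' @param genotypes a `sample_genotypes` object.
#' @param background matching `background` object.
#' @param snp_map the SNP map.
#' @return data.frame: `sample_id`, `chrom`, `snp_idx`, `pos`, `call`,
#'   `state`, `recipient_bg`, `recipient_allele`, `donor_allele`
#'   (founder labels `"B6"`/`"CAST"`), `dp`, `ad_b6`, `ad_cast`.
#' @export
call_nco_candidates <- function(genotypes, background, snp_map) {
  st <- background$state
  call <- genotypes$call
  conflict <- which(!is.na(st) & !is.na(call) & call != st)
  if (length(conflict) == 0)
    return(data.frame(sample_id = character(), chrom = integer(),
                      snp_idx = integer(), pos = numeric(),
                      call = integer(), state = character(),
                      recipient_bg = character(),
                      recipient_allele = character(),
                      donor_allele = character(), dp = integer(),
                      ad_b6 = integer(), ad_cast = integer(),
                      stringsAsFactors = FALSE))
  s <- st[conflict]
  cl <- call[conflict]
  # direction of the allele-level conversion
  donor <- ifelse(s == 0L & cl == 1L, "CAST",          # BB gained CAST
           ifelse(s == 2L & cl == 1L, "B6",            # CC gained B6
           ifelse(s == 1L & cl == 0L, "B6",            # BC -> homB6
           ifelse(s == 1L & cl == 2L, "CAST",          # BC -> homCAST
           ifelse(cl == 2L, "CAST", "B6")))))          # double switches
  recipient_allele <- ifelse(donor == "CAST", "B6", "CAST")
  recipient_bg <- ifelse(s == 0L & cl == 1L, "B6",
                  ifelse(s == 2L & cl == 1L, "CAST", "unknown"))
  data.frame(
    sample_id = genotypes$sample_id,
    chrom = snp_map$chrom[conflict],
    snp_idx = conflict,
    pos = snp_map$pos[conflict],
    call = cl,
    state = BG_STATES[s + 1L],
    recipient_bg = recipient_bg,
    recipient_allele = recipient_allele,
    donor_allele = donor,
    dp = genotypes$dp[conflict],
    ad_b6 = genotypes$ad_b6[conflict],
    ad_cast = genotypes$ad_cast[conflict],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Configuration of the false-positive filter cascade
#'
#' @param balance_p_min minimum two-sided binomial allele-balance p for
#'   a heterozygous candidate (sites with very unequal allele depths
#'   are discarded as artifacts).
#' @param het_min_depth minimum depth for a heterozygous candidate.
#' @param het_min_minor minimum reads of the rarer allele for a
#'   heterozygous candidate (singleton discordant reads are typical
#'   sequencing errors, not conversions).
#' @param min_depth minimum depth for a homozygous candidate (false
#'   homozygous calls are overwhelmingly low-depth heterozygous sites).
#' @param min_support minimum reads supporting the called allele of a
#'   homozygous candidate.
#' @param max_minor maximum reads of the non-called allele for a
#'   homozygous candidate (a genuine converted homozygote shows
#'   essentially none).
#' @param exclude data.frame (`chrom`, `start`, `end`) of regions whose
#'   candidates are dropped (e.g. incompletely inbred intervals).
#' @param co_guard_bp drop candidates within this distance of a called
#'   crossover breakpoint (0 disables the filter).
#' @param max_gap merge surviving candidates within this many bp of
#'   each other into a single NCO event.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(balance_p_min = 0.01, het_min_depth = 10,
                          het_min_minor = 2, min_depth = 12,
                          min_support = 10, max_minor = 0,
                          exclude = NULL, co_guard_bp = 0,
                          max_gap = 2000) {
  if (!is.null(exclude) &&
      !all(c("chrom", "start", "end") %in% names(exclude)))
    stop("`exclude` must have columns chrom, start, end")
  structure(list(balance_p_min = balance_p_min,
                 het_min_depth = het_min_depth,
                 het_min_minor = het_min_minor,
                 min_depth = min_depth,
                 min_support = min_support, max_minor = max_minor,
                 exclude = exclude,
                 co_guard_bp = co_guard_bp, max_gap = max_gap),
            class = "filter_config")
}

# exact two-sided binomial p at p0 = 0.5 (equals 2 * smaller tail,
# capped at 1), vectorised
binom_balance_p <- function(k, n) {
  m <- pmin(k, n - k)
  p <- 2 * stats::pbinom(m, n, 0.5)
  # avoid double-counting the central term when n even and k = n/2
  p <- ifelse(m == n - m, 1, p)
  pmin(p, 1)
}

#' Apply the false-positive filter cascade and merge NCO events
#'
#' Ordered cascade: (1) drop sites heterozygous or discordant in the
#' founders; (2) heterozygous candidates need allele-balance
#' p >= `balance_p_min`; (3) homozygous candidates need depth and
#' support minima; (4) drop excluded regions; (5) optionally drop
#' candidates near crossover breakpoints; (6) merge surviving adjacent
#' candidates within `max_gap` into NCO calls.
#'
#' @param candidates data.frame from [call_nco_candidates()] (possibly
#'   several samples' rows bound together).
#' @param founder_calls list with elements `b6` and `cast`, the two
#'   founders' `sample_genotypes` (may be `NULL` to skip filter 1).
#' @param snp_map the SNP map.
#' @param config a [filter_config()].
#' @param crossovers optional `crossover_calls` for filter 5.
#' @return list with `events` (data.frame of class `nco_calls`: one row
#'   per merged NCO with minimal/maximal tract, recipient background,
#'   complexity flag, converted site list) and `report` (data.frame of
#'   class `filter_report`: per-filter removal counts).
#' @export
apply_filters <- function(candidates, founder_calls, snp_map,
                          config = filter_config(), crossovers = NULL) {
  stopifnot(inherits(config, "filter_config"))
  n_input <- nrow(candidates)
  removed <- c(founder_discordant = 0L, allele_balance = 0L,
               hom_depth = 0L, excluded_region = 0L, co_guard = 0L)
  keep <- candidates

  if (!is.null(founder_calls)) {
    fb <- founder_calls$b6$call[keep$snp_idx]
    fc <- founder_calls$cast$call[keep$snp_idx]
    bad <- (!is.na(fb) & fb != 0L) | (!is.na(fc) & fc != 2L)
    removed["founder_discordant"] <- sum(bad)
    keep <- keep[!bad, ]
  }
  if (nrow(keep) > 0) {
    het <- keep$call == 1L
    pbal <- binom_balance_p(keep$ad_b6, keep$ad_b6 + keep$ad_cast)
    minor <- pmin(keep$ad_b6, keep$ad_cast)
    bad <- het & (pbal < config$balance_p_min |
                    keep$dp < config$het_min_depth |
                    minor < config$het_min_minor)
    removed["allele_balance"] <- sum(bad)
    keep <- keep[!bad, ]
  }
  if (nrow(keep) > 0) {
    hom <- keep$call %in% c(0L, 2L)
    supp <- ifelse(keep$call == 0L, keep$ad_b6, keep$ad_cast)
    minor <- pmin(keep$ad_b6, keep$ad_cast)
    bad <- hom & (keep$dp < config$min_depth |
                    supp < config$min_support |
                    minor > config$max_minor)
    removed["hom_depth"] <- sum(bad)
    keep <- keep[!bad, ]
  }
  if (!is.null(config$exclude) && nrow(keep) > 0) {
    bad <- rep(FALSE, nrow(keep))
    for (i in seq_len(nrow(config$exclude)))
      bad <- bad | (keep$chrom == config$exclude$chrom[i] &
                      keep$pos >= config$exclude$start[i] &
                      keep$pos <= config$exclude$end[i])
    removed["excluded_region"] <- sum(bad)
    keep <- keep[!bad, ]
  }
  if (config$co_guard_bp > 0 && !is.null(crossovers) &&
      nrow(crossovers) > 0 && nrow(keep) > 0) {
    bad <- rep(FALSE, nrow(keep))
    for (i in seq_len(nrow(crossovers))) {
      co <- crossovers[i, ]
      bad <- bad | (keep$sample_id == co$sample_id &
                      keep$chrom == co$chrom &
                      keep$pos >= co$left_pos - config$co_guard_bp &
                      keep$pos <= co$right_pos + config$co_guard_bp)
    }
    removed["co_guard"] <- sum(bad)
    keep <- keep[!bad, ]
  }

  events <- merge_candidates(keep, snp_map, config$max_gap)
  report <- data.frame(filter = c("input", names(removed), "surviving"),
                       count = c(n_input, as.integer(removed),
                                 nrow(keep)),
                       stringsAsFactors = FALSE)
  class(report) <- c("filter_report", "data.frame")
  list(events = events, report = report)
}

# merge surviving candidate sites into NCO calls
merge_candidates <- function(cand, snp_map, max_gap) {
  empty <- data.frame(sample_id = character(), chrom = integer(),
                      n_sites = integer(), min_start = numeric(),
                      min_end = numeric(), max_start = numeric(),
                      max_end = numeric(), recipient_bg = character(),
                      complex = logical(), inheritance = character(),
                      parent = character(), hotspot_id = integer(),
                      converted_pos = I(list()),
                      converted_idx = I(list()),
                      donor_allele = I(list()),
                      recipient_allele = I(list()),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0) { class(empty) <- c("nco_calls", "data.frame"); return(empty) }
  cand <- cand[order(cand$sample_id, cand$chrom, cand$pos), ]
  new_grp <- c(TRUE, cand$sample_id[-1] != cand$sample_id[-nrow(cand)] |
                 cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                 diff(cand$pos) > max_gap)
  grp <- cumsum(new_grp)
  rows <- lapply(split(seq_len(nrow(cand)), grp), function(ii) {
    g <- cand[ii, ]
    first <- min(g$snp_idx); last <- max(g$snp_idx)
    # maximal tract: nearest flanking non-candidate SNPs on the chromosome
    ci_rows <- which(snp_map$chrom == g$chrom[1])
    left_fl <- ci_rows[ci_rows < first]
    right_fl <- ci_rows[ci_rows > last]
    max_start <- if (length(left_fl)) snp_map$pos[max(left_fl)] else min(g$pos)
    max_end <- if (length(right_fl)) snp_map$pos[min(right_fl)] else max(g$pos)
    inner <- ci_rows[ci_rows > first & ci_rows < last]
    cmplx <- length(setdiff(inner, g$snp_idx)) > 0
    rb <- unique(g$recipient_bg)
    data.frame(sample_id = g$sample_id[1], chrom = g$chrom[1],
               n_sites = nrow(g), min_start = min(g$pos),
               min_end = max(g$pos), max_start = max_start,
               max_end = max_end,
               recipient_bg = if (length(rb) == 1) rb else "unknown",
               complex = cmplx, inheritance = "unknown",
               parent = "unknown", hotspot_id = NA_integer_,
               converted_pos = I(list(g$pos)),
               converted_idx = I(list(g$snp_idx)),
               donor_allele = I(list(g$donor_allele)),
               recipient_allele = I(list(g$recipient_allele)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nco_calls", "data.frame")
  out
}

#' Recipient homologue of an NCO call
#'
#' The recipient is the homologue whose allele was replaced: a
#' heterozygous call inside a homozygous-B6 segment implies a DSB on a
#' B6 haplotype (donor CAST), and vice versa. In heterozygous (BC)
#' segments phase is unknown and the recipient is `"unknown"`.
#'
#' @param ncos an `nco_calls` data.frame.
#' @return character vector of `"B6"`, `"CAST"` or `"unknown"`.
#' @export
assign_recipient_homologue <- function(ncos) {
  ncos$recipient_bg
}

#' Validated-fraction arithmetic
#'
#' Combines the hotspot-overlap fraction of events with in- and
#' out-of-hotspot confirmation rates into an overall fraction of
#' detected events estimated to be genuine.
#'
#' @param frac_in_hotspot fraction of events overlapping hotspots.
#' @param confirm_rate_in,confirm_rate_out confirmation rates for
#'   events inside / outside hotspots.
#' @return `frac_in * confirm_in + (1 - frac_in) * confirm_out`.
#' @examples
#' estimate_validated_fraction(0.842, 1.0, 0.44)  # ~0.9115
#' @export
estimate_validated_fraction <- function(frac_in_hotspot,
                                        confirm_rate_in,
                                        confirm_rate_out) {
  v <- c(frac_in_hotspot, confirm_rate_in, confirm_rate_out)
  if (any(v < 0 | v > 1)) stop("all inputs must lie in [0, 1]")
  frac_in_hotspot * confirm_rate_in +
    (1 - frac_in_hotspot) * confirm_rate_out
}
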