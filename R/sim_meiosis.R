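# Phased diploid genomes are lists with
#   haps: integer matrix [n_snps x 2], 0 = B6 allele, 1 = CAST allele
#   anc:  integer matrix [n_snps x 2], founder ancestry (0 = B6, 1 = CAST);
#         ancestry is unchanged by gene conversion, swapped by crossover
#   events: list of two data.frames, the recombination events carried on
#         each haplotype (with their original meiosis annotations)
# Event bookkeeping uses global SNP row indices into the snp_map.

empty_event_df <- function() {
  data.frame(event_id = integer(), meiosis_id = character(),
             generation = character(), sex = character(),
             kind = character(), chrom = integer(),
             hotspot_id = integer(), recipient = character(),
             breakpoint = numeric(), tract_start = numeric(),
             tract_end = numeric(), n_converted = integer(),
             converted = I(list()), blocked = I(list()),
             stringsAsFactors = FALSE)
}

#' Construct a founder genome
#'
#' @param n_snps number of SNPs in the map.
#' @param origin `"B6"` or `"CAST"`; both haplotypes carry that
#'   founder's alleles and ancestry.
#' @return a phased diploid genome (list with `haps`, `anc`, `events`).
#' @export
founder_genome <- function(n_snps, origin = c("B6", "CAST")) {
  origin <- match.arg(origin)
  a <- if (origin == "B6") 0L else 1L
  list(haps = matrix(a, n_snps, 2), anc = matrix(a, n_snps, 2),
       events = list(empty_event_df(), empty_event_df()))
}

#' Simulate one meiosis
#'
#' Produces a single transmitted gamete from a phased diploid parent.
#' The number of homologue-templated DSB repairs is Poisson with the
#' configured mean; each resolves as a crossover with probability
#' `co_fraction`, otherwise as a non-crossover gene conversion. DSBs
#' are assigned to hotspots with probability proportional to
#' heat x binding of the recipient (broken) homologue; at least one
#' crossover per chromosome is enforced by resampling. NCO tracts are
#' exponential with the controlling allele's mean, centred on the
#' hotspot motif with a zero-mean normal displacement, and copy donor
#' alleles onto the recipient haplotype. Single-mismatch tracts whose
#' recipient base is G or C are restored (blocked) with probability
#' `p_block`; interior G/C-recipient markers of multi-SNP tracts are
#' blocked at `complex_block_rate`, yielding rare complex events.
#'
#' All events of the meiosis are applied to the transmitted chromatid,
#' so the truth ledger counts events per meiosis on the same scale as
#' the downstream per-meiosis estimators.
#'
#' @param parent phased diploid genome (see [founder_genome()]).
#' @param snp_map SNP map ([simulate_snp_map()]).
#' @param hotspots hotspot table ([simulate_hotspots()]).
#' @param config a [sim_config()]. Uses the ambient RNG stream; seed at
#'   the caller (e.g. [simulate_pedigree()]).
#' @param meiosis_id identifier string stored on the new events.
#' @param sex `"maternal"` or `"paternal"` meiosis.
#' @param generation label for the parental generation (e.g. `"F4"`).
#' @return list with `hap`, `anc` (vectors over SNPs) and `events`
#'   (data.frame: events carried on the gamete, inherited + de novo).
#' @export
simulate_meiosis <- function(parent, snp_map, hotspots, config,
                             meiosis_id = "m", sex = "maternal",
                             generation = "F?") {
  if (nrow(hotspots) == 0) stop("hotspot list is empty")
  n_snps <- nrow(snp_map)
  stopifnot(nrow(parent$haps) == n_snps)
  chroms <- seq_along(config$chrom_lengths)
  midx <- snp_index(snp_map)
  hs_snp <- if (!is.null(hotspots$snp_idx)) hotspots$snp_idx
            else snp_nearest_idx(midx, hotspots$chrom, hotspots$center)

  heat_mult <- if (sex == "maternal") config$sex_heat_multiplier else 1
  n_dsb <- stats::rpois(1, config$dsb_per_meiosis_mean * heat_mult)
  n_co <- stats::rbinom(1, n_dsb, config$co_fraction)
  n_nco <- n_dsb - n_co

  ## --- crossovers -> breakpoints, enforce >= 1 per chromosome
  co_hs <- if (n_co > 0)
    sample.int(nrow(hotspots), n_co, replace = TRUE, prob = hotspots$heat)
  else integer()
  for (ci in chroms) {
    if (!any(hotspots$chrom[co_hs] == ci)) {
      on_ci <- which(hotspots$chrom == ci)
      if (length(on_ci) > 0)
        co_hs <- c(co_hs, on_ci[sample.int(length(on_ci), 1,
                                           prob = hotspots$heat[on_ci])])
    }
  }
  co_hs <- co_hs[!duplicated(co_hs)]  # one breakpoint per hotspot

  ## --- build the gamete's source vector (which parental haplotype)
  src <- integer(n_snps)
  for (ci in chroms) {
    idx <- which(snp_map$chrom == ci)
    if (length(idx) == 0) next
    bp <- sort(hotspots$center[co_hs[hotspots$chrom[co_hs] == ci]])
    s <- sample(1:2, 1)
    seg <- findInterval(snp_map$pos[idx], bp)  # 0..length(bp)
    src[idx] <- ifelse(seg %% 2 == 0, s, 3L - s)
  }
  hap <- parent$haps[cbind(seq_len(n_snps), src)]
  anc <- parent$anc[cbind(seq_len(n_snps), src)]

  ## --- carried (inherited) events from the parent's haplotypes
  inherited <- empty_event_df()
  for (h in 1:2) {
    ev <- parent$events[[h]]
    if (nrow(ev) == 0) next
    keep <- vapply(seq_len(nrow(ev)), function(i) {
      if (ev$kind[i] == "NCO") {
        cs <- ev$converted[[i]]
        if (length(cs) == 0) return(FALSE)  # unobservable, drop
        all(src[cs] == h)
      } else {
        k <- match(ev$chrom[i], midx$chroms)
        if (is.na(k)) return(FALSE)
        p <- midx$pos[[k]]
        j <- findInterval(ev$breakpoint[i], p)
        if (j < 1 || j >= length(p)) return(FALSE)
        src[midx$offset[k] + j] == h && src[midx$offset[k] + j + 1L] == h
      }
    }, logical(1))
    inherited <- rbind(inherited, ev[keep, ])
  }

  ## --- record the de novo crossovers
  new_events <- empty_event_df()
  if (length(co_hs) > 0) {
    s_idx <- hs_snp[co_hs]
    rec <- ifelse(!is.na(s_idx) & anc[pmax(s_idx, 1L)] == 0L,
                  "B6", "CAST")
    new_events <- rbind(new_events, data.frame(
      event_id = NA_integer_, meiosis_id = meiosis_id,
      generation = generation, sex = sex, kind = "CO",
      chrom = hotspots$chrom[co_hs], hotspot_id = hotspots$id[co_hs],
      recipient = rec, breakpoint = hotspots$center[co_hs],
      tract_start = NA_real_, tract_end = NA_real_,
      n_converted = 0L,
      converted = I(replicate(length(co_hs), integer(), simplify = FALSE)),
      blocked = I(replicate(length(co_hs), integer(), simplify = FALSE)),
      stringsAsFactors = FALSE))
  }

  ## --- non-crossovers
  if (n_nco > 0) {
    # recipient-homologue binding weight per hotspot, given the gamete
    ok <- !is.na(hs_snp)
    w <- numeric(nrow(hotspots))
    x <- hotspots$b6_binding_ratio
    w[ok] <- hotspots$heat[ok] *
      ifelse(anc[hs_snp[ok]] == 0L, x[ok], 1 - x[ok])
    if (config$asym_repair_deficit > 0)
      w <- w * (1 - config$asym_repair_deficit * (1 - hotspots$symmetry))
    if (sum(w) <= 0) stop("no hotspot has positive recipient weight")
    draws <- sample.int(nrow(hotspots), n_nco, replace = TRUE, prob = w)

    acc <- vector("list", length(draws))
    ai <- 0L
    for (k in draws) {
      ci <- hotspots$chrom[k]
      mean_len <- if (hotspots$controlling_allele[k] == "Cast")
        config$tract_mean_cast else config$tract_mean_hum
      center <- (hotspots$motif_start[k] + hotspots$motif_end[k]) / 2 +
        stats::rnorm(1, 0, config$tract_center_sd)
      len <- stats::rexp(1, 1 / mean_len)
      t0 <- center - len / 2
      t1 <- center + len / 2
      in_tract <- snp_range_idx(midx, ci, t0, t1)
      s_idx <- hs_snp[k]
      donor <- 3L - src[s_idx]
      mism <- in_tract[parent$haps[in_tract, donor] != hap[in_tract]]
      recipient <- if (anc[s_idx] == 0L) "B6" else "CAST"
      blocked <- integer()
      conv <- mism
      if (length(mism) == 1) {
        rb <- if (hap[mism] == 0L) snp_map$allele_b6[mism]
              else snp_map$allele_cast[mism]
        if (base_class(rb) == "S" &&
            stats::runif(1) < config$p_block) {
          blocked <- mism
          conv <- integer()
        }
      } else if (length(mism) >= 3) {
        interior <- mism[-c(1, length(mism))]
        rb <- ifelse(hap[interior] == 0L, snp_map$allele_b6[interior],
                     snp_map$allele_cast[interior])
        bl <- interior[base_class(rb) == "S" &
                         stats::runif(length(interior)) <
                           config$complex_block_rate]
        blocked <- bl
        conv <- setdiff(mism, bl)
      }
      if (length(conv) > 0)
        hap[conv] <- parent$haps[conv, donor]
      # a new conversion supersedes any inherited event it overwrites
      if (length(conv) > 0 && nrow(inherited) > 0) {
        clash <- vapply(inherited$converted, function(cs)
          length(intersect(cs, conv)) > 0, logical(1))
        inherited <- inherited[!clash, ]
      }
      ai <- ai + 1L
      acc[[ai]] <- data.frame(
        event_id = NA_integer_, meiosis_id = meiosis_id,
        generation = generation, sex = sex, kind = "NCO",
        chrom = ci, hotspot_id = hotspots$id[k], recipient = recipient,
        breakpoint = NA_real_, tract_start = t0, tract_end = t1,
        n_converted = length(conv),
        converted = I(list(conv)), blocked = I(list(blocked)),
        stringsAsFactors = FALSE)
    }
    if (ai > 0)
      new_events <- rbind(new_events, do.call(rbind, acc[seq_len(ai)]))
  }

  events <- rbind(inherited, new_events)
  rownames(events) <- NULL
  list(hap = hap, anc = anc, events = events)
}

#' Simulate the full intercross pedigree
#'
#' Builds the study's cross design on a synthetic genome: two inbred
#' founders (B6, CAST), two F1 hybrids, 11 sequenced F2 offspring of
#' the F1 pair, an internal F3 generation, 36 F4 parents (18 pairs) and
#' 72 F5 offspring (4 per F4 pair). Every gamete is produced by
#' [simulate_meiosis()] and truth events are retained per meiosis.
#'
#' @param config a [sim_config()].
#' @param snp_map,hotspots optional pre-built map/hotspots; generated
#'   from `config` when `NULL`.
#' @param seed optional integer overriding `config$seed + 2`.
#' @return list with `snp_map`, `hotspots`, `individuals` (named list;
#'   each has `id`, `generation`, `sex`, `mother`, `father`, `genome`),
#'   `sequenced` (ids of the F0/F2/F4/F5 samples), and `n_meioses_f2`
#'   (meioses ancestral to the F2 samples: 2 per F2).
#' @export
simulate_pedigree <- function(config, snp_map = NULL, hotspots = NULL,
                              seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(snp_map)) snp_map <- simulate_snp_map(config)
  snp_map <- with_snp_index(snp_map)
  if (is.null(hotspots)) hotspots <- simulate_hotspots(config, snp_map)
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  n_snps <- nrow(snp_map)

  individuals <- list()
  add_ind <- function(id, generation, sex, mother, father, genome) {
    individuals[[id]] <<- list(id = id, generation = generation,
                               sex = sex, mother = mother,
                               father = father, genome = genome)
  }
  cross <- function(mother_id, father_id, child_id, generation) {
    mo <- individuals[[mother_id]]$genome
    fa <- individuals[[father_id]]$genome
    gm <- simulate_meiosis(mo, snp_map, hotspots, config,
                           meiosis_id = paste0(child_id, ".mat"),
                           sex = "maternal",
                           generation = individuals[[mother_id]]$generation)
    gp <- simulate_meiosis(fa, snp_map, hotspots, config,
                           meiosis_id = paste0(child_id, ".pat"),
                           sex = "paternal",
                           generation = individuals[[father_id]]$generation)
    genome <- list(haps = cbind(gm$hap, gp$hap),
                   anc = cbind(gm$anc, gp$anc),
                   events = list(gm$events, gp$events))
    sex <- sample(c("F", "M"), 1)
    add_ind(child_id, generation, sex, mother_id, father_id, genome)
  }

  add_ind("F0.B6", "F0", "F", NA, NA, founder_genome(n_snps, "B6"))
  add_ind("F0.CAST", "F0", "M", NA, NA, founder_genome(n_snps, "CAST"))
  cross("F0.B6", "F0.CAST", "F1.1", "F1")
  cross("F0.B6", "F0.CAST", "F1.2", "F1")
  individuals[["F1.1"]]$sex <- "F"; individuals[["F1.2"]]$sex <- "M"

  f2_ids <- sprintf("F2.%02d", 1:11)
  for (id in f2_ids) cross("F1.1", "F1.2", id, "F2")

  # breeding chain: 4 F2 pairs -> 36 F3; 18 F3 pairs -> 36 F4;
  # 18 F4 pairs -> 72 F5 (two nominal per sex per family)
  f2_pairs <- matrix(f2_ids[1:8], ncol = 2, byrow = TRUE)
  f3_ids <- sprintf("F3.%02d", 1:36)
  for (i in seq_along(f3_ids)) {
    p <- f2_pairs[((i - 1) %% nrow(f2_pairs)) + 1, ]
    cross(p[1], p[2], f3_ids[i], "F3")
  }
  f3_pairs <- matrix(f3_ids, ncol = 2, byrow = TRUE)
  f4_ids <- sprintf("F4.%02d", 1:36)
  for (i in seq_along(f4_ids)) {
    p <- f3_pairs[((i - 1) %% nrow(f3_pairs)) + 1, ]
    cross(p[1], p[2], f4_ids[i], "F4")
  }
  f4_pairs <- matrix(f4_ids, ncol = 2, byrow = TRUE)
  f5_ids <- character(0)
  for (fam in seq_len(nrow(f4_pairs))) {
    for (k in 1:4) {
      id <- sprintf("F5.%02d.%d", fam, k)
      cross(f4_pairs[fam, 1], f4_pairs[fam, 2], id, "F5")
      individuals[[id]]$sex <- if (k <= 2) "F" else "M"
      f5_ids <- c(f5_ids, id)
    }
  }

  list(snp_map = snp_map, hotspots = hotspots,
       individuals = individuals,
       sequenced = c("F0.B6", "F0.CAST", f2_ids, f4_ids, f5_ids),
       f4_pairs = f4_pairs,
       n_meioses_f2 = 2L * length(f2_ids))
}

#' Truth events carried by an individual
#'
#' @param individual an element of `simulate_pedigree()$individuals`.
#' @return data.frame of the events on both haplotypes, with a
#'   `haplotype` column (1 = maternal, 2 = paternal).
#' @export
truth_events <- function(individual) {
  ev1 <- individual$genome$events[[1]]
  ev2 <- individual$genome$events[[2]]
  if (nrow(ev1) > 0) ev1$haplotype <- 1L
  if (nrow(ev2) > 0) ev2$haplotype <- 2L
  out <- rbind(ev1, ev2)
  if (nrow(out) == 0) { out$haplotype <- integer(0) }
  rownames(out) <- NULL
  out
}
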