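#' Simulate a founder-diagnostic SNP map
#'
#' Draws SNP positions independently per chromosome with geometric
#' (discretised exponential) inter-SNP gaps of the configured mean, and
#' assigns each site a B6 and a CAST allele (distinct bases, uniform
#' over ordered base pairs). Strong/weak classes follow the bases:
#' S = \{G, C\}, W = \{A, T\}.
#'
#' @param config a [sim_config()] object.
#' @param seed optional integer overriding `config$seed`.
#' @return a `data.frame` of class `snp_map` with columns `chrom`,
#'   `pos` (1-based, strictly increasing within chromosome),
#'   `allele_b6`, `allele_cast`, `class_b6`, `class_cast`.
#' @examples
#' sm <- simulate_snp_map(sim_config(chrom_lengths = 1e5, seed = 3))
#' head(sm)
#' @export
simulate_snp_map <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  maps <- lapply(seq_along(config$chrom_lengths), function(ci) {
    len <- config$chrom_lengths[ci]
    # expected count with safety margin, then trim to chromosome end
    n_guess <- ceiling(len / config$snp_spacing_mean * 1.25) + 50
    gaps <- 1 + stats::rgeom(n_guess, prob = 1 / config$snp_spacing_mean)
    pos <- cumsum(gaps)
    while (sum(gaps) < len) {          # rare under-draw
      extra <- 1 + stats::rgeom(n_guess, prob = 1 / config$snp_spacing_mean)
      pos <- c(pos, pos[length(pos)] + cumsum(extra))
      gaps <- c(gaps, extra)
    }
    pos <- pos[pos <= len]
    data.frame(chrom = ci, pos = as.numeric(pos))
  })
  sm <- do.call(rbind, maps)
  bases <- c("A", "C", "G", "T")
  n <- nrow(sm)
  sm$allele_b6 <- sample(bases, n, replace = TRUE)
  # draw the CAST allele uniformly among the three other bases
  shift <- sample(1:3, n, replace = TRUE)
  sm$allele_cast <- bases[((match(sm$allele_b6, bases) - 1 + shift) %% 4) + 1]
  sm$class_b6 <- base_class(sm$allele_b6)
  sm$class_cast <- base_class(sm$allele_cast)
  rownames(sm) <- NULL
  class(sm) <- c("snp_map", "data.frame")
  sm
}

#' Strong/weak class of a DNA base
#'
#' @param base character vector of bases.
#' @return `"S"` for G/C, `"W"` for A/T.
#' @keywords internal
base_class <- function(base) {
  ifelse(base %in% c("G", "C"), "S", "W")
}

#' Simulate recombination hotspots
#'
#' Places `n_hotspots` hotspot centers uniformly across the genome
#' (minimum 2 kb apart), draws heavy-tailed Pareto heats, assigns each
#' hotspot a controlling *Prdm9* allele, a B6 binding ratio `x`
#' (near 0.5 for symmetric hotspots; near 0 or 1 for the configured
#' asymmetric fraction), a +/-18 bp motif interval near the center, and
#' a motif-disruption flag (probability 0.96 for asymmetric hotspots,
#' matching the observed fraction of disrupted motifs at asymmetric
#' sites; 0.2 otherwise).
#'
#' @param config a [sim_config()] object.
#' @param snp_map SNP map from [simulate_snp_map()]; motif-overlapping
#'   SNP presence is taken from it.
#' @param seed optional integer overriding `config$seed + 1`.
#' @return a `data.frame` of class `hotspot_set` with columns `id`,
#'   `chrom`, `center`, `heat`, `b6_binding_ratio`, `controlling_allele`
#'   (`"Cast"`/`"Hum"`), `motif_start`, `motif_end`, `motif_strand`,
#'   `motif_posterior`, `motif_disrupted`, `symmetry`.
#' @export
simulate_hotspots <- function(config, snp_map, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(snp_map) == 0) stop("`snp_map` must be nonempty")
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  capacity <- floor(sum(config$chrom_lengths) / 2000)
  if (config$n_hotspots > capacity)
    stop("n_hotspots exceeds genome capacity at 2-kb spacing (",
         capacity, ")")
  n <- config$n_hotspots
  # allocate hotspots to chromosomes proportional to length, place on a
  # 2-kb lattice to guarantee spacing, then jitter within the cell
  probs <- config$chrom_lengths / sum(config$chrom_lengths)
  chrom <- sample(seq_along(probs), n, replace = TRUE, prob = probs)
  center <- numeric(n)
  for (ci in unique(chrom)) {
    idx <- which(chrom == ci)
    cells <- floor(config$chrom_lengths[ci] / 2000)
    if (length(idx) > cells) stop("hotspot spacing infeasible on chromosome ", ci)
    cell <- sort(sample.int(cells, length(idx)))
    center[idx] <- (cell - 1) * 2000 + sample(500:1500, length(idx), replace = TRUE)
  }
  heat <- pmin((1 - stats::runif(n))^(-1 / config$heat_shape),
               config$heat_max)          # truncated Pareto(1, alpha)
  controlling <- ifelse(stats::runif(n) < config$frac_cast_controlled,
                        "Cast", "Hum")
  asym <- stats::runif(n) < config$frac_asymmetric
  x <- numeric(n)
  x[!asym] <- stats::rbeta(sum(!asym), 20, 20)          # near 0.5
  x_a <- stats::rbeta(sum(asym), 1, 30)                 # near 0
  flip <- stats::runif(sum(asym)) < 0.5
  x[asym] <- ifelse(flip, 1 - x_a, x_a)
  disrupted <- ifelse(asym,
                      stats::runif(n) < 0.96,
                      stats::runif(n) < 0.2)
  # motif placement is tied to the disruption flag: a disrupted motif
  # is centred on a nearby SNP (the variant breaking PRDM9 binding on
  # one homologue); an intact motif is placed to avoid SNPs when a
  # SNP-free slot exists nearby
  motif_halfwidth <- 18
  midx <- snp_index(snp_map)
  mcen <- round(center)
  for (i in seq_len(n)) {
    near <- snp_range_idx(midx, chrom[i], center[i] - 600,
                          center[i] + 600)
    if (disrupted[i]) {
      if (length(near) > 0) {
        pick <- near[which.min(abs(snp_map$pos[near] - center[i]))]
        mcen[i] <- snp_map$pos[pick]
      } else disrupted[i] <- FALSE
    } else if (length(near) > 0) {
      for (offs in sample(seq(-300, 300, by = 37))) {
        cand <- round(center[i]) + offs
        hitsnp <- snp_range_idx(midx, chrom[i],
                                cand - motif_halfwidth,
                                cand + motif_halfwidth)
        if (length(hitsnp) == 0) { mcen[i] <- cand; break }
      }
    }
  }
  motif_start <- pmax(1, mcen - motif_halfwidth)
  motif_end <- mcen + motif_halfwidth
  hs <- data.frame(
    id = seq_len(n),
    chrom = chrom,
    center = center,
    heat = heat,
    b6_binding_ratio = x,
    controlling_allele = controlling,
    motif_start = motif_start,
    motif_end = motif_end,
    motif_strand = sample(c("+", "-"), n, replace = TRUE),
    motif_posterior = stats::rbeta(n, 40, 1),
    motif_disrupted = disrupted,
    stringsAsFactors = FALSE
  )
  hs$symmetry <- symmetry(hs$b6_binding_ratio)
  hs <- hs[order(hs$chrom, hs$center), ]
  hs$id <- seq_len(n)   # ids follow genome order
  rownames(hs) <- NULL
  hs$snp_idx <- snp_nearest_idx(snp_index(snp_map), hs$chrom, hs$center)
  class(hs) <- c("hotspot_set", "data.frame")
  hs
}
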