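#' Simulate depth-bearing genotype calls for a sample
#'
#' Per-SNP sequencing depth is Poisson with the generation's mean
#' coverage (10x founders/F4, 20x F2/F5 by default). Read counts for
#' the CAST allele are binomial given the true genotype, with per-read
#' miscalls at `base_error_rate`. Calls: depth 0 is missing; otherwise
#' the maximum-likelihood genotype given the allele depths and error
#' rate, as a standard variant caller would produce. Artifact modes
#' are injected on top to exercise the filter cascade: false
#' heterozygous calls with skewed allele balance at `false_het_rate`,
#' and false homozygous calls with low depth at `false_hom_rate`.
#'
#' @param genome phased diploid genome of the sample.
#' @param generation one of `"F0"`, `"F1"`, `"F2"`, `"F3"`, `"F4"`, `"F5"`.
#' @param config a [sim_config()].
#' @param sample_id identifier stored on the result.
#' @return a list of class `sample_genotypes`: `sample_id`,
#'   `generation`, and per-SNP integer vectors `call` (0 = homB6,
#'   1 = het, 2 = homCAST, `NA` = missing), `dp`, `ad_b6`, `ad_cast`.
#' @export
simulate_genotype_calls <- function(genome, generation, config,
                                    sample_id = "s") {
  stopifnot(inherits(config, "sim_config"))
  if (config$base_error_rate < 0 || config$false_het_rate < 0 ||
      config$false_hom_rate < 0)
    stop("rates must be non-negative")
  g <- genome$haps[, 1] + genome$haps[, 2]   # CAST-allele count, 0/1/2
  n <- length(g)
  mean_depth <- if (generation %in% c("F0", "F4"))
    config$depth_founder else config$depth_offspring
  dp <- stats::rpois(n, mean_depth)
  e <- config$base_error_rate
  p_cast <- c(e, 0.5, 1 - e)[g + 1]
  ad_cast <- stats::rbinom(n, dp, p_cast)
  ad_b6 <- dp - ad_cast
  call <- ml_genotype(ad_b6, ad_cast, e)

  # artifact injection
  if (config$false_het_rate > 0) {
    hom <- which(call %in% c(0L, 2L))
    hit <- hom[stats::runif(length(hom)) < config$false_het_rate]
    if (length(hit) > 0) {
      minor <- pmax(1L, stats::rbinom(length(hit), dp[hit], 0.12))
      is_b6 <- call[hit] == 0L
      ad_cast[hit] <- ifelse(is_b6, minor, dp[hit] - minor)
      ad_b6[hit] <- dp[hit] - ad_cast[hit]
      call[hit] <- 1L
    }
  }
  if (config$false_hom_rate > 0) {
    het <- which(call == 1L)
    hit <- het[stats::runif(length(het)) < config$false_hom_rate]
    if (length(hit) > 0) {
      lowd <- 1L + stats::rpois(length(hit), 1)
      to_cast <- stats::runif(length(hit)) < 0.5
      dp[hit] <- lowd
      ad_cast[hit] <- ifelse(to_cast, lowd, 0L)
      ad_b6[hit] <- dp[hit] - ad_cast[hit]
      call[hit] <- ifelse(to_cast, 2L, 0L)
    }
  }
  structure(list(sample_id = sample_id, generation = generation,
                 call = call, dp = dp, ad_b6 = ad_b6, ad_cast = ad_cast),
            class = "sample_genotypes")
}

#' Maximum-likelihood genotype from allele depths
#'
#' Log-likelihoods of homB6 / het / homCAST given binomial read counts
#' with per-read error `e`; depth 0 gives `NA` (missing).
#'
#' @param ad_b6,ad_cast allele depths.
#' @param e per-read error probability (floored at 1e-4).
#' @return integer vector: 0 homB6, 1 het, 2 homCAST, `NA` missing.
#' @export
ml_genotype <- function(ad_b6, ad_cast, e = 0.001) {
  e <- max(e, 1e-4)
  d <- ad_b6 + ad_cast
  ll0 <- ad_cast * log(e) + ad_b6 * log(1 - e)
  ll1 <- d * log(0.5)
  ll2 <- ad_b6 * log(e) + ad_cast * log(1 - e)
  call <- max.col(cbind(ll0, ll1, ll2), ties.method = "first") - 1L
  call[d == 0] <- NA_integer_
  as.integer(call)
}

#' Noise-free genotype calls from a truth genome
#'
#' Deterministic calls equal to the true genotypes, with constant
#' depth and exactly split allele depths: the zero-noise limit of
#' [simulate_genotype_calls()] (which, even at zero error rate,
#' retains binomial read-sampling noise).
#'
#' @param genome phased diploid genome.
#' @param sample_id identifier.
#' @param generation generation label.
#' @param depth constant per-site depth.
#' @return a `sample_genotypes` object.
#' @export
perfect_genotype_calls <- function(genome, sample_id = "s",
                                   generation = "F2", depth = 20) {
  g <- genome$haps[, 1] + genome$haps[, 2]
  n <- length(g)
  ad_cast <- as.integer(round(depth * g / 2))
  structure(list(sample_id = sample_id, generation = generation,
                 call = as.integer(g), dp = rep(as.integer(depth), n),
                 ad_b6 = as.integer(depth) - ad_cast,
                 ad_cast = ad_cast),
            class = "sample_genotypes")
}

#' Simulate genotype calls for every sequenced pedigree sample
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed + 3`.
#' @return named list of [simulate_genotype_calls()] results, one per
#'   sequenced sample.
#' @export
simulate_pedigree_calls <- function(pedigree, config, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 3L else seed)
  out <- list()
  for (id in pedigree$sequenced) {
    ind <- pedigree$individuals[[id]]
    out[[id]] <- simulate_genotype_calls(ind$genome, ind$generation,
                                         config, sample_id = id)
  }
  out
}

#' Simulate homologue-assignable ChIP-seq counts per hotspot
#'
#' H3K4me3 totals are Poisson with mean `alpha * heat`, with B6 counts
#' binomial at the hotspot's B6 binding ratio `x`. DMC1 totals are
#' Poisson with mean `beta * heat * delay(x)`, where
#' `delay(x) = 1 + (delay_factor - 1) * (1 - 4x(1-x))` interpolates to
#' `delay_factor` (default 2, i.e. roughly two-fold DMC1:H3K4me3
#' elevation) as symmetry goes to 0, reflecting slower repair when the
#' homologue is unbound. The DMC1 B6 fraction is optionally shifted
#' toward the more-bound homologue (whose breaks persist longer).
#'
#' @param hotspots hotspot table.
#' @param config a [sim_config()].
#' @param alpha,beta positive scale factors for H3K4me3 and DMC1 mean
#'   counts per unit heat.
#' @param delay_factor DMC1 elevation at fully asymmetric hotspots.
#' @param dmc1_shift logical; shift DMC1 allele fractions toward the
#'   more-bound homologue (on by default).
#' @param seed optional integer overriding `config$seed + 4`.
#' @return the hotspot table with columns `h3k4_total`, `h3k4_b6`,
#'   `h3k4_cast`, `dmc1_total`, `dmc1_b6`, `dmc1_cast` appended.
#' @export
simulate_chip_counts <- function(hotspots, config, alpha = 60,
                                 beta = 60, delay_factor = 2,
                                 dmc1_shift = TRUE, seed = NULL) {
  if (nrow(hotspots) == 0) stop("hotspot list is empty")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  set.seed(if (is.null(seed)) config$seed + 4L else seed)
  h <- hotspots$heat
  x <- hotspots$b6_binding_ratio
  n <- nrow(hotspots)
  h3_tot <- stats::rpois(n, alpha * h)
  h3_b6 <- stats::rbinom(n, h3_tot, x)
  delay <- 1 + (delay_factor - 1) * (1 - 4 * x * (1 - x))
  d_tot <- stats::rpois(n, beta * h * delay)
  if (dmc1_shift) {
    f <- delay_factor
    w_b6 <- x * ifelse(x >= 0.5, f, 1)
    w_cast <- (1 - x) * ifelse(x < 0.5, f, 1)
    x_d <- w_b6 / (w_b6 + w_cast)
  } else x_d <- x
  d_b6 <- stats::rbinom(n, d_tot, x_d)
  out <- hotspots
  out$h3k4_total <- h3_tot
  out$h3k4_b6 <- h3_b6
  out$h3k4_cast <- h3_tot - h3_b6
  out$dmc1_total <- d_tot
  out$dmc1_b6 <- d_b6
  out$dmc1_cast <- d_tot - d_b6
  out
}
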