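#' Simulation configuration for the synthetic intercross generator
#'
#' Bundles every generative constant used by the synthetic-data module:
#' genome layout, SNP spacing, hotspot number and heat distribution,
#' per-meiosis DSB counts, conversion-tract means per controlling
#' *Prdm9* allele, sequencing depths and error/artifact rates.
#'
#' Defaults emulate the hybrid-intercross study design this package
#' targets: ~1 diagnostic SNP per 170 bp, ~300 homologue-templated DSB
#' repairs per meiosis of which ~10% resolve as crossovers, mean
#' conversion-tract lengths of 30 bp (Cast-controlled hotspots) and
#' 41 bp (humanised-allele hotspots), and mean coverages of 10x for
#' founders/F4 and 20x for F2/F5 animals. The default genome is a
#' scaled-down twin (three autosomes, 75 Mb) of a mouse genome.
#'
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param snp_spacing_mean mean inter-SNP gap in bp.
#' @param n_hotspots number of recombination hotspots genome-wide.
#' @param heat_shape Pareto tail index of the hotspot heat distribution
#'   (smaller = heavier tail).
#' @param heat_max truncation of the heat distribution (in units of
#'   the minimum heat). The heavy tail is calibrated so the hottest
#'   sixth of hotspots carries over half the total heat, while the
#'   truncation keeps any single hotspot's share of events small, as
#'   in real hotspot maps.
#' @param frac_cast_controlled fraction of hotspots controlled by the
#'   Cast allele (the rest by the humanised allele).
#' @param frac_asymmetric fraction of hotspots with strongly asymmetric
#'   homologue binding (x near 0 or 1).
#' @param tract_mean_cast,tract_mean_hum mean exponential NCO tract
#'   length (bp) at Cast- and humanised-controlled hotspots.
#' @param dsb_per_meiosis_mean mean number of homologue-templated DSB
#'   repairs per meiosis (Poisson).
#' @param co_fraction fraction of DSB repairs resolving as crossovers.
#' @param depth_founder,depth_offspring mean sequencing fold-coverage
#'   for F0/F4 and for F2/F5 samples.
#' @param base_error_rate per-read base miscall probability.
#' @param false_het_rate,false_hom_rate per-site rates at which
#'   artifactual heterozygous / homozygous calls are injected, to
#'   exercise the downstream filter cascade.
#' @param tract_center_sd sd (bp) of the zero-mean normal displacement
#'   of NCO tract centers from the hotspot motif center.
#' @param asym_repair_deficit multiplicative reduction of repair
#'   probability at fully asymmetric hotspots (0 = no deficit; 0.8
#'   means symmetry-0 hotspots repair at 20% of the symmetric rate).
#'   Off by default: the generator's null has no deficit.
#' @param sex_heat_multiplier per-sex multiplier on hotspot heat for
#'   female meioses (1 = sexes identical, the default).
#' @param p_block probability that the GC-restoring pathway acts at a
#'   single-mismatch heteroduplex whose recipient base is G/C.
#' @param complex_block_rate probability that an interior G/C-recipient
#'   marker of a multi-SNP tract is individually restored, producing a
#'   rare complex event with a blocked marker.
#' @param seed integer seed making every generator call reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(chrom_lengths = c(2e6, 1e6), n_hotspots = 60, seed = 1)
#' cfg$snp_spacing_mean
#' @export
sim_config <- function(chrom_lengths = c(30e6, 25e6, 20e6),
                       snp_spacing_mean = 170,
                       n_hotspots = 1200,
                       heat_shape = 1.3,
                       heat_max = 300,
                       frac_cast_controlled = 0.5,
                       frac_asymmetric = 0.2,
                       tract_mean_cast = 30,
                       tract_mean_hum = 41,
                       dsb_per_meiosis_mean = 300,
                       co_fraction = 0.10,
                       depth_founder = 10,
                       depth_offspring = 20,
                       base_error_rate = 0.001,
                       false_het_rate = 2e-5,
                       false_hom_rate = 2e-5,
                       tract_center_sd = 200,
                       asym_repair_deficit = 0,
                       sex_heat_multiplier = 1,
                       p_block = 0.53,
                       complex_block_rate = 0.005,
                       seed = 1L) {
  if (length(chrom_lengths) == 0)
    stop("`chrom_lengths` must contain at least one chromosome")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive and finite")
  if (snp_spacing_mean < 1) stop("`snp_spacing_mean` must be >= 1 bp")
  if (n_hotspots <= 0) stop("`n_hotspots` must be positive")
  if (heat_shape <= 0) stop("`heat_shape` must be positive")
  if (heat_max <= 1) stop("`heat_max` must exceed 1")
  fracs <- c(frac_cast_controlled = frac_cast_controlled,
             frac_asymmetric = frac_asymmetric,
             co_fraction = co_fraction,
             p_block = p_block,
             complex_block_rate = complex_block_rate)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("fractions must lie in [0, 1]: ", paste(names(fracs)[bad], collapse = ", "))
  if (tract_mean_cast < 1 || tract_mean_hum < 1)
    stop("tract means must be >= 1 bp")
  if (dsb_per_meiosis_mean <= 0) stop("`dsb_per_meiosis_mean` must be positive")
  if (depth_founder <= 0 || depth_offspring <= 0)
    stop("depths must be positive")
  rates <- c(base_error_rate, false_het_rate, false_hom_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("error/artifact rates must lie in [0, 1]")
  if (tract_center_sd < 0) stop("`tract_center_sd` must be >= 0")
  if (asym_repair_deficit < 0 || asym_repair_deficit > 1)
    stop("`asym_repair_deficit` must lie in [0, 1]")
  if (sex_heat_multiplier <= 0) stop("`sex_heat_multiplier` must be positive")

  structure(list(
    chrom_lengths = as.numeric(chrom_lengths),
    snp_spacing_mean = snp_spacing_mean,
    n_hotspots = as.integer(n_hotspots),
    heat_shape = heat_shape,
    heat_max = heat_max,
    frac_cast_controlled = frac_cast_controlled,
    frac_asymmetric = frac_asymmetric,
    tract_mean_cast = tract_mean_cast,
    tract_mean_hum = tract_mean_hum,
    dsb_per_meiosis_mean = dsb_per_meiosis_mean,
    co_fraction = co_fraction,
    depth_founder = depth_founder,
    depth_offspring = depth_offspring,
    base_error_rate = base_error_rate,
    false_het_rate = false_het_rate,
    false_hom_rate = false_hom_rate,
    tract_center_sd = tract_center_sd,
    asym_repair_deficit = asym_repair_deficit,
    sex_heat_multiplier = sex_heat_multiplier,
    p_block = p_block,
    complex_block_rate = complex_block_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      length(x$chrom_lengths), "chromosomes,",
      sprintf("%.0f Mb total;", sum(x$chrom_lengths) / 1e6),
      x$n_hotspots, "hotspots;",
      "1 SNP /", x$snp_spacing_mean, "bp;",
      x$dsb_per_meiosis_mean, "DSBs/meiosis,",
      sprintf("CO fraction %.2f\n", x$co_fraction))
  invisible(x)
}
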