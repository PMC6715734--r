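# Shared simulated fixtures, built lazily once per test run.
.fix <- new.env(parent = emptyenv())

# small intercross: 2 chromosomes, ~70k SNPs, 150 hotspots, 50 DSBs
# per meiosis — enough events for calling tests at test-scale runtime
small_sim <- function() {
  if (!is.null(.fix$small)) return(.fix$small)
  cfg <- sim_config(chrom_lengths = c(6e6, 4e6), n_hotspots = 150,
                    dsb_per_meiosis_mean = 50, seed = 11)
  ped <- simulate_pedigree(cfg)
  calls <- simulate_pedigree_calls(ped, cfg)
  .fix$small <- list(cfg = cfg, ped = ped, calls = calls,
                     snp_map = ped$snp_map, hotspots = ped$hotspots)
  .fix$small
}

# noise-free calls for a subset of samples of the small pedigree
perfect_calls_for <- function(sim, ids) {
  out <- lapply(ids, function(id)
    perfect_genotype_calls(sim$ped$individuals[[id]]$genome, id,
                           sim$ped$individuals[[id]]$generation))
  names(out) <- ids
  out
}

founder_perfect <- function(sim) {
  list(b6 = perfect_genotype_calls(
         sim$ped$individuals[["F0.B6"]]$genome, "F0.B6", "F0"),
       cast = perfect_genotype_calls(
         sim$ped$individuals[["F0.CAST"]]$genome, "F0.CAST", "F0"))
}

# truth NCO converted-site sets for a sample, restricted to events
# with >= 1 converted SNP
truth_nco_sites <- function(sim, id) {
  te <- truth_events(sim$ped$individuals[[id]])
  te <- te[te$kind == "NCO" & te$n_converted > 0, ]
  lapply(te$converted, identity)
}
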