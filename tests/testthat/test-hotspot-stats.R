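test_that("binding ratio and symmetry follow their definitions", {
  expect_equal(b6_ratio(50, 50), 0.5)
  expect_equal(b6_ratio(30, 10), 0.75)
  expect_true(is.na(b6_ratio(9, 0)))
  expect_error(b6_ratio(-1, 5), "non-negative")
  # background correction shifts the ratio
  expect_equal(b6_ratio(60, 30, input_b6 = 20, input_cast = 0,
                        input_factor = 1), 40 / 70)

  expect_equal(symmetry(0.5), 1)
  expect_equal(symmetry(1), 0)
  expect_equal(symmetry(0.9), 0.36)
  expect_error(symmetry(1.2), "\\[0, 1\\]")
  # homologue-label invariance
  x <- runif(20)
  expect_equal(symmetry(x), symmetry(1 - x))
})

test_that("homologous heat attributes heat to the template homologue", {
  expect_equal(homologous_heat(0.8, 10, "CAST"), 8)
  expect_equal(homologous_heat(0.8, 10, "B6"), 2)
  expect_equal(homologous_heat(0.5, 10, "B6"),
               homologous_heat(0.5, 10, "CAST"))
  expect_equal(average_homologous_heat(0.5, 10), 5)
  expect_equal(average_homologous_heat(1, 10), 0)
  # equals initiation-weighted mean of the two homologous heats
  x <- 0.3; h <- 7
  expect_equal(average_homologous_heat(x, h),
               x * homologous_heat(x, h, "B6") +
                 (1 - x) * homologous_heat(x, h, "CAST"))
  expect_error(homologous_heat(0.5, -1), "positive")
})

test_that("symmetry binning balances predicted event mass", {
  hs <- data.frame(id = 1:9, symmetry = seq(0.1, 0.9, 0.1))
  bins <- bin_by_symmetry(hs, enrichment = rep(1, 9), n_bins = 3)
  expect_equal(as.vector(table(bins)), c(3, 3, 3))
  expect_equal(bins[order(hs$symmetry)][c(1, 9)], c(1L, 3L))
  # one dominant hotspot can saturate a bin
  e2 <- c(10, rep(1, 8))
  bins2 <- bin_by_symmetry(hs, e2, n_bins = 3)
  expect_equal(bins2[1], 1L)
  expect_gt(sum(bins2 == 3), 3)
  expect_error(bin_by_symmetry(data.frame(id = 1:3, symmetry = 0.5),
                               rep(1, 3), 3), "degenerate")
})

test_that("observed vs expected detects a repair deficit and not a null", {
  set.seed(61)
  n <- 900
  hs <- data.frame(id = 1:n, symmetry = runif(n))
  enrich <- rexp(n) + 0.1
  bins <- bin_by_symmetry(hs, enrich, 3)
  draw_events <- function(w, n_ev = 800)
    sample(hs$id, n_ev, replace = TRUE, prob = w)
  # null: events proportional to enrichment regardless of symmetry
  ev_null <- draw_events(enrich)
  r0 <- observed_vs_expected(list(nco = ev_null), hs, bins, enrich)
  expect_gt(r0$chisq$nco["p"], 0.01)
  expect_equal(sum(r0$expected), 1)
  expect_equal(sum(r0$observed$nco$fraction), 1)
  # deficit: asymmetric hotspots repaired less
  ev_def <- draw_events(enrich * (0.25 + 0.75 * hs$symmetry))
  r1 <- observed_vs_expected(list(nco = ev_def), hs, bins, enrich)
  expect_lt(r1$chisq$nco["p"], 0.01)
  expect_lt(r1$observed$nco$fraction[1], r1$expected[1])
  expect_error(observed_vs_expected(list(n = ev_null), hs,
                                    rep(1L, n), enrich), "2 bins")
})

test_that("deficit-on generator depletes asymmetric bins end to end", {
  cfg <- sim_config(chrom_lengths = 10e6, n_hotspots = 2500,
                    dsb_per_meiosis_mean = 400, co_fraction = 0,
                    frac_asymmetric = 0.35, asym_repair_deficit = 0.8,
                    seed = 19)
  sm <- simulate_snp_map(cfg)
  hs <- simulate_hotspots(cfg, sm)
  f1 <- founder_genome(nrow(sm), "B6")
  f1$haps[, 2] <- 1L; f1$anc[, 2] <- 1L
  set.seed(23)
  hids <- integer()
  for (i in 1:4) {
    g <- simulate_meiosis(f1, sm, hs, cfg, "m", "maternal", "F1")
    hids <- c(hids, g$events$hotspot_id[g$events$kind == "NCO"])
  }
  cc <- simulate_chip_counts(hs, cfg, alpha = 100, beta = 100)
  bins <- bin_by_symmetry(cc, cc$dmc1_total, 3)
  res <- observed_vs_expected(list(nco = hids), cc, bins,
                              cc$dmc1_total)
  expect_lt(res$chisq$nco["p"], 0.01)
  expect_lt(res$observed$nco$fraction[1], res$expected[1])
})

test_that("initiation fractions sit near 0.5 at symmetric hotspots", {
  cfg <- sim_config(chrom_lengths = 10e6, n_hotspots = 2500,
                    frac_asymmetric = 0.4, seed = 33)
  sm <- simulate_snp_map(cfg)
  hs <- simulate_hotspots(cfg, sm)
  cc <- simulate_chip_counts(hs, cfg, alpha = 150, beta = 150)
  set.seed(4)
  # events initiating on each homologue proportional to binding
  n_ev <- 1500
  hid <- sample(cc$id, n_ev, replace = TRUE, prob = cc$heat)
  x <- cc$b6_binding_ratio[match(hid, cc$id)]
  ev <- data.frame(sample_id = "s", hotspot_id = hid,
                   recipient_bg = ifelse(runif(n_ev) < x, "B6", "CAST"))
  res <- initiation_fraction_less_bound(ev, cc, B = 200)
  symrow <- res[res$class == "symmetric", ]
  # the less-bound fraction is min(x, 1-x), so its mean sits just
  # below 0.5 at symmetric hotspots
  expect_gt(symrow$h3k4_frac, 0.4)
  expect_lte(symrow$h3k4_frac, 0.5)
  expect_gt(symrow$event_frac, 0.4)
  # the repair-delay shift moves DMC1 signal toward the more-bound
  # homologue, so its less-bound fraction sits below the H3K4me3 one
  expect_lt(symrow$dmc1_frac, symrow$h3k4_frac)
  asyrow <- res[res$class == "asymmetric", ]
  expect_lt(asyrow$h3k4_frac, 0.35)
  expect_error(initiation_fraction_less_bound(ev[0, ], cc), "no assigned")
})

test_that("motif disruption fraction is ~0.96 at extreme initiation bins", {
  cfg <- sim_config(chrom_lengths = c(12e6, 12e6), n_hotspots = 6000,
                    frac_asymmetric = 0.45, seed = 41)
  sm <- simulate_snp_map(cfg)
  hs <- simulate_hotspots(cfg, sm)
  cc <- simulate_chip_counts(hs, cfg, alpha = 120, beta = 120)
  md <- motif_disruption_fraction(cc, sm,
                                  breaks = c(0, 0.05, 0.5, 0.95, 1))
  extreme <- md[c(1, 4), ]
  expect_gt(sum(extreme$n), 100)
  pooled <- sum(extreme$fraction_disrupted * extreme$n) /
    sum(extreme$n)
  expect_equal(pooled, 0.96, tolerance = 0.05)
  # variant at the motif centre counts; 1 bp outside does not
  hs1 <- data.frame(id = 1L, chrom = 1L, center = 5000,
                    motif_start = 4990, motif_end = 5010,
                    motif_posterior = 1, dmc1_b6 = 30, dmc1_cast = 30)
  v_in <- data.frame(chrom = 1L, pos = 5000)
  v_out <- data.frame(chrom = 1L, pos = 5011)
  expect_equal(motif_disruption_fraction(hs1, v_in,
                 breaks = c(0, 1))$fraction_disrupted, 1)
  expect_equal(motif_disruption_fraction(hs1, v_out,
                 breaks = c(0, 1))$fraction_disrupted, 0)
})

test_that("the GLM attributes event rates to the true driver", {
  cfg <- sim_config(chrom_lengths = c(15e6, 15e6), n_hotspots = 5000,
                    frac_asymmetric = 0.4, seed = 55)
  sm <- simulate_snp_map(cfg)
  hs <- simulate_hotspots(cfg, sm)
  hs$h3k4_total <- rpois(nrow(hs), 50 * hs$heat)
  set.seed(66)
  # response driven by symmetry (plus heat), not SNP density
  eta <- -1.5 + 2 * hs$symmetry + 0.5 * log(hs$h3k4_total + 1e-4)
  y1 <- runif(nrow(hs)) < plogis(eta)
  co1 <- glm_symmetry_vs_density(y1, hs, sm)
  p_sym <- co1$p_value[co1$term == "symmetry"]
  p_dens <- co1$p_value[grepl("density", co1$term)]
  expect_lt(p_sym, 0.05)
  expect_true(all(p_dens > 0.05) || mean(p_dens > 0.05) >= 2 / 3)
  # response driven by SNP density only
  midx <- ncomap:::snp_index(sm)
  mcen <- (hs$motif_start + hs$motif_end) / 2
  dens <- vapply(seq_len(nrow(hs)), function(i)
    length(ncomap:::snp_range_idx(midx, hs$chrom[i], mcen[i] - 500,
                                  mcen[i] + 500)) / 1000, numeric(1))
  y2 <- runif(nrow(hs)) < plogis(-2.5 + 500 * dens)
  co2 <- glm_symmetry_vs_density(y2, hs, sm)
  expect_lt(co2$p_value[co2$term == "density_500"], 0.05)
  expect_gt(co2$p_value[co2$term == "symmetry"], 0.05)
  expect_error(glm_symmetry_vs_density(rep(TRUE, nrow(hs)), hs, sm),
               "constant")
})

test_that("event-motif distances implement both definitions", {
  hs <- data.frame(id = 1L, chrom = 1L, center = 1000,
                   motif_start = 982, motif_end = 1018,
                   motif_posterior = 1)
  sm <- data.frame(chrom = 1L, pos = c(900, 990, 1020, 1100),
                   allele_b6 = "A", allele_cast = "G",
                   class_b6 = "W", class_cast = "S")
  mk_ev <- function(idx) {
    ev <- data.frame(sample_id = "s", chrom = 1L,
                     min_start = min(sm$pos[idx]),
                     min_end = max(sm$pos[idx]), n_sites = length(idx),
                     recipient_bg = "B6", complex = FALSE,
                     inheritance = "unknown", parent = "unknown",
                     hotspot_id = 1L,
                     converted_idx = I(list(idx)),
                     converted_pos = I(list(sm$pos[idx])),
                     donor_allele = I(list(rep("CAST", length(idx)))))
    class(ev) <- c("nco_calls", "data.frame")
    ev
  }
  # converted marker inside the motif -> nearest-marker distance 0
  r1 <- event_motif_distance(mk_ev(2L), hs, sm)
  expect_equal(r1$distances$d_nearest_marker, 0)
  expect_equal(r1$distances$d_midpoint, 10)
  # minimal tract [980, 1020] centred on the motif -> midpoint 0
  ev2 <- mk_ev(c(2L, 3L)); ev2$min_start <- 980; ev2$min_end <- 1020
  r2 <- event_motif_distance(ev2, hs, sm)
  expect_equal(r2$distances$d_midpoint, 0)
  expect_error(event_motif_distance(mk_ev(1L), hs[0, ], sm),
               "no motifs")
})
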