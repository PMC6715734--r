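mk_records <- function(recip, donor, size = "single", dist = 200) {
  data.frame(event = seq_along(recip), pos = seq_along(recip) * 1000,
             recipient_base = recip, donor_base = donor,
             recipient_class = ifelse(recip %in% c("G", "C"), "S", "W"),
             donor_class = ifelse(donor %in% c("G", "C"), "S", "W"),
             type = ncomap:::strand_equiv_type(recip, donor),
             tract_size_class = size, nearest_snp_dist = dist,
             recipient_bg = "B6", stringsAsFactors = FALSE)
}

test_that("conversion classification collapses strand equivalents", {
  # C>A pools with G>T; A>G (W to S) pools with T>C
  expect_equal(ncomap:::strand_equiv_type("C", "A"),
               ncomap:::strand_equiv_type("G", "T"))
  expect_equal(ncomap:::strand_equiv_type("A", "G"),
               ncomap:::strand_equiv_type("T", "C"))
  sm <- data.frame(chrom = 1L, pos = c(100, 400, 2000),
                   allele_b6 = c("A", "C", "G"),
                   allele_cast = c("G", "A", "C"),
                   class_b6 = c("W", "S", "S"),
                   class_cast = c("S", "W", "S"))
  ev <- data.frame(sample_id = "s", chrom = 1L, min_start = 100,
                   min_end = 100, n_sites = 1L, recipient_bg = "B6",
                   complex = FALSE, inheritance = "unknown",
                   parent = "unknown", hotspot_id = NA_integer_,
                   converted_idx = I(list(1L)),
                   converted_pos = I(list(100)),
                   donor_allele = I(list("CAST")))
  class(ev) <- c("nco_calls", "data.frame")
  rec <- classify_conversions(ev, sm)
  # recipient A (B6 allele replaced), donor G: W -> S, single
  expect_equal(rec$recipient_class, "W")
  expect_equal(rec$donor_class, "S")
  expect_equal(rec$tract_size_class, "single")
  expect_equal(rec$nearest_snp_dist, 300)
})

test_that("GC-bias fraction, CI and test match constructed counts", {
  rec <- mk_records(c(rep("A", 68), rep("G", 32)),
                    c(rep("G", 68), rep("T", 32)))
  gb <- gc_bias_fraction(rec)
  expect_equal(gb$fraction, 0.68)
  expect_lt(gb$p_value, 0.001)
  rec2 <- mk_records(c(rep("A", 50), rep("G", 50)),
                     c(rep("G", 50), rep("T", 50)))
  gb2 <- gc_bias_fraction(rec2)
  expect_equal(gb2$fraction, 0.5)
  expect_equal(gb2$p_value, 1)
  # S>S conversions are uninformative and excluded
  rec3 <- mk_records(c("G", "A"), c("C", "G"))
  expect_equal(gc_bias_fraction(rec3)$n, 1)
  expect_error(gc_bias_fraction(rec3[1, ]), "informative")
})

test_that("single-vs-multi Fisher test matches enumeration", {
  rec <- rbind(mk_records(c(rep("A", 68), rep("G", 32)),
                          c(rep("G", 68), rep("T", 32)), "single"),
               mk_records(c(rep("A", 50), rep("G", 50)),
                          c(rep("G", 50), rep("T", 50)), "multi"))
  ft <- single_vs_multi_test(rec)
  expect_equal(ft$p_value, enum_fisher_p(68, 32, 50, 50),
               tolerance = 1e-9)
  expect_error(single_vs_multi_test(rec[rec$tract_size_class ==
                                          "single", ]), "both")
})

test_that("two-pathway model relations reproduce the printed values", {
  expect_equal(expected_observed_bias(0), 0.5)
  expect_equal(expected_observed_bias(1), 1)
  expect_equal(expected_observed_bias(0.53), 1 / 1.47)
  expect_equal(round(100 * expected_observed_bias(0.53)), 68)
  expect_equal(round(100 * cap_bias_single_base()), 67)
  expect_equal(cap_bias_single_base(), expected_observed_bias(0.5))
  # inverse composes to identity and is monotone
  p <- seq(0, 1, 0.05)
  # p = 0 maps to bias 0.5, where the inverse warns by design
  expect_equal(suppressWarnings(
    p_block_from_bias(expected_observed_bias(p))), p)
  expect_true(all(diff(expected_observed_bias(p)) > 0))
  expect_warning(p_block_from_bias(0.4), "p_block")
})

test_that("simulating the two-pathway model yields the 68% bias", {
  set.seed(500)
  n <- 1e5
  recip_S <- runif(n) < 0.5          # DSB equally on either homologue
  blocked <- recip_S & runif(n) < 0.53
  observed <- !blocked
  fr <- mean(!recip_S[observed])     # W-recipient => W-to-S conversion
  se <- sqrt(fr * (1 - fr) / sum(observed))
  expect_lt(abs(fr - 1 / 1.47), 3 * se)
})

test_that("blocked-marker tally reproduces the exact binomial p", {
  expect_equal(binom_two_sided(18, 19), enum_binom_p(18, 19),
               tolerance = 1e-12)
  expect_equal(binom_two_sided(18, 19), 7.63e-5, tolerance = 1e-2)
  expect_equal(binom_two_sided(1, 2), 1)
  expect_equal(binom_two_sided(19, 19), 2 / 2^19)
  # constructed complex event: inner S-recipient marker blocked
  sm <- data.frame(chrom = 1L, pos = c(100, 200, 300),
                   allele_b6 = c("A", "G", "T"),
                   allele_cast = c("G", "T", "C"),
                   class_b6 = c("W", "S", "W"),
                   class_cast = c("S", "W", "S"))
  ev <- data.frame(sample_id = "s", chrom = 1L, min_start = 100,
                   min_end = 300, n_sites = 2L, recipient_bg = "B6",
                   complex = TRUE, inheritance = "unknown",
                   parent = "unknown", hotspot_id = NA_integer_,
                   converted_idx = I(list(c(1L, 3L))),
                   converted_pos = I(list(c(100, 300))),
                   donor_allele = I(list(c("CAST", "CAST"))))
  class(ev) <- c("nco_calls", "data.frame")
  bt <- blocked_marker_tally(ev, sm)
  expect_equal(bt$n, 1)
  expect_equal(bt$k, 1)   # B6 recipient carries G at the blocked site
  expect_error(blocked_marker_tally(ev[ev$complex == FALSE, ], sm),
               "complex")
})

test_that("exact tests match enumeration across small sample spaces", {
  for (n in 1:25)
    for (k in unique(c(0, 1, floor(n / 2), n)))
      expect_equal(binom_two_sided(k, n), enum_binom_p(k, n),
                   tolerance = 1e-10)
  set.seed(9)
  for (rep in 1:60) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
      next
    p_r <- stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
    expect_equal(p_r, enum_fisher_p(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("distance-stratified bias approaches 68% at long distances", {
  set.seed(712)
  # two-pathway generative model: isolated SNPs (single-mismatch
  # tracts) experience blocking; clustered SNPs convert together
  n <- 4000
  iso <- runif(n) < 0.5
  dist <- ifelse(iso, runif(n, 150, 900), runif(n, 1, 25))
  recip_S <- runif(n) < 0.5
  blocked <- iso & recip_S & runif(n) < 0.53
  keep <- !blocked
  rec <- mk_records(ifelse(recip_S[keep], "G", "A"),
                    ifelse(recip_S[keep], "T", "G"),
                    size = ifelse(iso[keep], "single", "multi"),
                    dist = dist[keep])
  ds <- distance_stratified_bias(rec)
  near <- ds[ds$bin == "[0,10]", ]
  far <- ds[ds$bin == "(300,1e+03]", ]
  expect_equal(near$fraction, 0.5, tolerance = 0.06)
  expect_equal(far$fraction, 0.68, tolerance = 0.06)
  # monotone non-decreasing in expectation across informative bins
  ok <- ds$n > 100
  expect_true(all(diff(ds$fraction[ok]) > -0.08))
})

test_that("relative conversion proportions depress S-recipient types", {
  set.seed(81)
  types <- c("A>C|T>G", "A>G|T>C", "C>A|G>T", "C>G|G>C")
  ref <- data.frame(type = types, prop = rep(0.25, 4))
  # S-recipient types (C>*) converted at 0.47 of the rate
  w <- c(1, 1, 0.47, 0.47)
  draws <- sample(types, 3000, TRUE, prob = 0.25 * w)
  rec <- data.frame(type = draws)
  rp <- relative_conversion_proportions(rec, ref)
  ratio_W <- rp$ratio[rp$type %in% types[1:2]]
  ratio_S <- rp$ratio[rp$type %in% types[3:4]]
  expect_equal(mean(ratio_S) / mean(ratio_W), 0.47, tolerance = 0.1)
  # identical compositions give ratios 1
  rp2 <- relative_conversion_proportions(
    data.frame(type = rep(types, 25)), ref)
  expect_true(all(abs(rp2$ratio - 1) < 1e-9))
})

test_that("required DSB totals scale inversely with observability", {
  expect_equal(unname(required_dsb_ratio(1, 1, 300)), c(300, 300))
  r <- required_dsb_ratio(1, 300 / 465, 300)
  expect_equal(unname(r["strand_unaware"]), 465)
  expect_equal(unname(required_dsb_ratio(0.5, 0.25, 100)), c(200, 400))
  expect_error(required_dsb_ratio(0, 1, 10), "\\(0, 1\\]")
})
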