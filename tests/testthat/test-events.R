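toy_segments <- function(states, sample_id = "s") {
  n <- length(states)
  data.frame(sample_id = sample_id, chrom = 1L,
             first_idx = seq(1, by = 10, length.out = n),
             last_idx = seq(9, by = 10, length.out = n),
             first_pos = seq(1000, by = 10000, length.out = n),
             last_pos = seq(9000, by = 10000, length.out = n),
             state = states, mean_posterior = 1,
             stringsAsFactors = FALSE)
}

test_that("crossovers are called at state changes with the right interval", {
  seg <- toy_segments(c("BB", "BC"))
  cos <- call_crossovers(seg)
  expect_equal(nrow(cos), 1)
  expect_equal(cos$left_pos, 9000)
  expect_equal(cos$right_pos, 11000)
  expect_equal(cos$resolution, 2000)

  expect_equal(nrow(call_crossovers(toy_segments(c("BB", "BB")))), 0)
  expect_equal(nrow(call_crossovers(toy_segments("CC"))), 0)
})

test_that("short A-B-A excursions are flagged as NCO-like", {
  seg <- toy_segments(c("BB", "BC", "BB"))
  seg$first_idx <- c(1L, 10L, 12L)
  seg$last_idx <- c(9L, 11L, 30L)
  cos <- call_crossovers(seg, nco_like_max_snps = 2)
  expect_equal(nrow(cos), 2)
  expect_true(all(cos$nco_like))
  # a long excursion is two genuine calls
  seg$last_idx <- c(9L, 20L, 30L)
  seg$first_idx <- c(1L, 10L, 21L)
  cos2 <- call_crossovers(seg, nco_like_max_snps = 2)
  expect_false(any(cos2$nco_like))
})

test_that("NCO candidates carry the implied conversion direction", {
  sm <- data.frame(chrom = 1L, pos = c(100, 200, 300),
                   allele_b6 = c("A", "C", "T"),
                   allele_cast = c("G", "T", "C"),
                   class_b6 = c("W", "S", "W"),
                   class_cast = c("S", "W", "S"))
  gt <- structure(list(sample_id = "s", generation = "F2",
                       call = c(1L, 0L, 2L), dp = rep(20L, 3),
                       ad_b6 = c(10L, 20L, 0L),
                       ad_cast = c(10L, 0L, 20L)),
                  class = "sample_genotypes")
  # states: CC, BC, CC -> site1 het-in-CC, site2 homB6-in-BC,
  # site3 concordant
  bg <- list(state = c(2L, 1L, 2L), posterior = rep(1, 3),
             sample_id = "s")
  cand <- call_nco_candidates(gt, bg, sm)
  expect_equal(cand$snp_idx, c(1L, 2L))
  expect_equal(cand$recipient_bg, c("CAST", "unknown"))
  expect_equal(cand$donor_allele, c("B6", "B6"))
  expect_equal(cand$recipient_allele, c("CAST", "CAST"))

  # fully concordant sample: no candidates
  bg2 <- list(state = c(1L, 0L, 2L), posterior = rep(1, 3),
              sample_id = "s")
  expect_equal(nrow(call_nco_candidates(gt, bg2, sm)), 0)
})

test_that("the filter cascade removes the designed artifact modes", {
  sm <- data.frame(chrom = 1L, pos = seq(100, 2000, by = 100))
  sm$allele_b6 <- "A"; sm$allele_cast <- "G"
  sm$class_b6 <- "W"; sm$class_cast <- "S"
  base <- data.frame(sample_id = "s", chrom = 1L, snp_idx = 1L,
                     pos = 100, call = 1L, state = "BB",
                     recipient_bg = "B6", recipient_allele = "B6",
                     donor_allele = "CAST", dp = 21L, ad_b6 = 20L,
                     ad_cast = 1L, stringsAsFactors = FALSE)
  # (20, 1) het: allele-balance p ~ 2e-5 < 0.01 -> removed
  res <- apply_filters(base, NULL, sm, filter_config())
  expect_equal(nrow(res$events), 0)
  expect_equal(res$report$count[res$report$filter == "allele_balance"], 1)

  # balanced het at good depth survives and becomes one event
  good <- base; good$ad_b6 <- 10L; good$ad_cast <- 10L; good$dp <- 20L
  res2 <- apply_filters(good, NULL, sm, filter_config())
  expect_equal(nrow(res2$events), 1)
  expect_equal(res2$events$n_sites, 1L)

  # low-depth hom candidate removed
  hom <- base; hom$call <- 0L; hom$dp <- 3L
  hom$ad_b6 <- 3L; hom$ad_cast <- 0L; hom$state <- "BC"
  res3 <- apply_filters(hom, NULL, sm, filter_config())
  expect_equal(nrow(res3$events), 0)

  # candidate inside an excluded region is removed and counted
  excl <- filter_config(exclude = data.frame(chrom = 1, start = 50,
                                             end = 150))
  res4 <- apply_filters(good, NULL, sm, excl)
  expect_equal(res4$report$count[res4$report$filter ==
                                   "excluded_region"], 1)
  expect_equal(nrow(res4$events), 0)

  # founder-discordant site removed
  fb6 <- structure(list(sample_id = "b6", generation = "F0",
                        call = rep(1L, nrow(sm)), dp = rep(10L, nrow(sm)),
                        ad_b6 = rep(5L, nrow(sm)),
                        ad_cast = rep(5L, nrow(sm))),
                   class = "sample_genotypes")
  fca <- structure(list(sample_id = "cast", generation = "F0",
                        call = rep(2L, nrow(sm)), dp = rep(10L, nrow(sm)),
                        ad_b6 = rep(0L, nrow(sm)),
                        ad_cast = rep(10L, nrow(sm))),
                   class = "sample_genotypes")
  res5 <- apply_filters(good, list(b6 = fb6, cast = fca), sm,
                        filter_config())
  expect_equal(nrow(res5$events), 0)
})

test_that("filter report conserves counts: input = removed + surviving", {
  sim <- small_sim()
  id <- "F2.05"
  res <- call_sample_events(sim$calls[[id]], sim$snp_map,
                            list(b6 = sim$calls[["F0.B6"]],
                                 cast = sim$calls[["F0.CAST"]]))
  rep_ <- res$report
  input <- rep_$count[rep_$filter == "input"]
  surv <- rep_$count[rep_$filter == "surviving"]
  removed <- sum(rep_$count[!rep_$filter %in% c("input", "surviving")])
  expect_equal(input, removed + surv)
})

test_that("candidate merging builds minimal/maximal tracts and complexity", {
  sm <- data.frame(chrom = 1L, pos = c(100, 300, 500, 700, 900))
  sm$allele_b6 <- "A"; sm$allele_cast <- "G"
  sm$class_b6 <- "W"; sm$class_cast <- "S"
  mk <- function(idx) data.frame(
    sample_id = "s", chrom = 1L, snp_idx = idx,
    pos = sm$pos[idx], call = 1L, state = "BB",
    recipient_bg = "B6", recipient_allele = "B6",
    donor_allele = "CAST", dp = 20L, ad_b6 = 10L, ad_cast = 10L,
    stringsAsFactors = FALSE)
  # converted-unconverted-converted triple => complex
  cand <- mk(c(2L, 4L))
  res <- apply_filters(cand, NULL, sm, filter_config())
  expect_equal(nrow(res$events), 1)
  expect_true(res$events$complex)
  expect_equal(res$events$min_start, 300)
  expect_equal(res$events$min_end, 700)
  expect_equal(res$events$max_start, 100)
  expect_equal(res$events$max_end, 900)
  # contiguous pair is simple
  res2 <- apply_filters(mk(c(2L, 3L)), NULL, sm, filter_config())
  expect_false(res2$events$complex)
  # far-apart candidates split into two events
  sm2 <- data.frame(chrom = 1L, pos = c(100, 300, 9500, 9700))
  sm2$allele_b6 <- "A"; sm2$allele_cast <- "G"
  sm2$class_b6 <- "W"; sm2$class_cast <- "S"
  cand3 <- data.frame(sample_id = "s", chrom = 1L,
                      snp_idx = c(2L, 3L), pos = c(300, 9500),
                      call = 1L, state = "BB", recipient_bg = "B6",
                      recipient_allele = "B6", donor_allele = "CAST",
                      dp = 20L, ad_b6 = 10L, ad_cast = 10L,
                      stringsAsFactors = FALSE)
  res3 <- apply_filters(cand3, NULL, sm2, filter_config())
  expect_equal(nrow(res3$events), 2)
})

test_that("validated-fraction arithmetic matches its definition", {
  expect_equal(estimate_validated_fraction(0.842, 1.0, 0.44),
               0.91152, tolerance = 1e-10)
  expect_equal(estimate_validated_fraction(1.0, 1.0, 0.0), 1.0)
  expect_equal(estimate_validated_fraction(0.5, 0.8, 0.4), 0.6)
  expect_error(estimate_validated_fraction(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("de novo fraction reproduces the printed event ratios", {
  expect_equal(de_novo_fraction(821, 1384), 0.372, tolerance = 1e-3)
  expect_equal(de_novo_fraction(510, 882), 0.366, tolerance = 2e-3)
  expect_equal(de_novo_fraction(0, 50), 0)
  expect_equal(de_novo_fraction(0, 0), 0)
})
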