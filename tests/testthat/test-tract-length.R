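toy_map <- function(pos, chrom = 1L) {
  sm <- data.frame(chrom = chrom, pos = pos, allele_b6 = "A",
                   allele_cast = "G", class_b6 = "W", class_cast = "S")
  class(sm) <- c("snp_map", "data.frame")
  sm
}

toy_nco <- function(sm, idx) {
  ev <- data.frame(sample_id = "s", chrom = 1L,
                   min_start = min(sm$pos[idx]),
                   min_end = max(sm$pos[idx]),
                   n_sites = length(idx), recipient_bg = "B6",
                   complex = FALSE, inheritance = "unknown",
                   parent = "unknown", hotspot_id = NA_integer_,
                   converted_idx = I(list(idx)),
                   converted_pos = I(list(sm$pos[idx])),
                   donor_allele = I(list(rep("CAST", length(idx)))),
                   stringsAsFactors = FALSE)
  class(ev) <- c("nco_calls", "data.frame")
  ev
}

test_that("pair construction follows the focal/nearby definition", {
  sm <- toy_map(c(100, 130, 400))
  ev <- toy_nco(sm, c(1L, 2L))
  pairs <- build_pairs(ev, sm, window = 1000)
  # focal 100: (30, 1), (300, 0); focal 130: (30, 1), (270, 0)
  expect_equal(nrow(pairs), 4)
  expect_setequal(pairs$d[pairs$x == 1], c(30, 30))
  expect_setequal(pairs$d[pairs$x == 0], c(300, 270))
  # narrow window drops the distant pairs
  pairs2 <- build_pairs(ev, sm, window = 100)
  expect_equal(nrow(pairs2), 2)
  expect_true(all(pairs2$x == 1))
  expect_equal(nrow(build_pairs(ev[0, ], sm, 1000)), 0)
  expect_error(build_pairs(ev, sm, window = 0), "positive")
})

test_that("co-conversion probability is the exponential tail", {
  expect_equal(co_conversion_prob(1 / 30, 0), 1)
  expect_equal(co_conversion_prob(1 / 30, 30), exp(-1))
  expect_equal(co_conversion_prob(100, 10), exp(-1000))
  expect_error(co_conversion_prob(0, 5), "positive")
  expect_error(co_conversion_prob(1, -1), "non-negative")
})

test_that("composite log-likelihood matches closed forms", {
  expect_equal(composite_log_likelihood(1 / 30,
                                        data.frame(d = 30, x = 1L)), -1)
  p2 <- data.frame(d = c(50, 50), x = c(1L, 0L))
  expect_equal(composite_log_likelihood(log(2) / 50, p2),
               2 * log(0.5), tolerance = 1e-12)
  expect_error(composite_log_likelihood(0.1, p2[0, ]), "empty")
})

test_that("grid fit matches analytic and continuous maximisers", {
  p2 <- data.frame(d = c(50, 50), x = c(1L, 0L))
  fit <- fit_tract_length(p2)
  expect_equal(fit$mean_bp, 50 / log(2), tolerance = 0.05 / 50)
  expect_false(fit$at_boundary)

  set.seed(400)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    d <- sample(10:500, n, replace = TRUE)
    mu <- runif(1, 10, 200)
    x <- as.integer(runif(n) < exp(-d / mu))
    if (sum(x) == 0 || sum(x) == n) next
    pairs <- data.frame(d = d, x = x)
    fit <- fit_tract_length(pairs)
    cont <- optim_tract_mean(pairs)
    expect_lt(abs(fit$mean_bp - cont), 0.1 + 1e-8)
  }
})

test_that("degenerate pair sets hit the grid boundaries with warnings", {
  all1 <- data.frame(d = c(10, 20), x = c(1L, 1L))
  expect_warning(f1 <- fit_tract_length(all1), "co-converted")
  expect_equal(f1$mean_bp, 1000)
  expect_true(f1$at_boundary)
  all0 <- data.frame(d = c(10, 20), x = c(0L, 0L))
  expect_warning(f0 <- fit_tract_length(all0), "smallest")
  expect_equal(f0$mean_bp, 1)
  expect_true(f0$at_boundary)
})

test_that("estimator is SNP-density independent (conditioning property)", {
  set.seed(52)
  cfg <- sim_config(chrom_lengths = 20e6, seed = 5)
  sm_dense <- simulate_snp_map(cfg)
  cfg2 <- sim_config(chrom_lengths = 20e6, snp_spacing_mean = 340,
                     seed = 5)
  sm_sparse <- simulate_snp_map(cfg2)
  ev_d <- simulate_nco_events(500, sm_dense, 30, 20e6)
  ev_s <- simulate_nco_events(500, sm_sparse, 30, 20e6)
  f_d <- fit_tract_length(build_pairs(ev_d, sm_dense, 1000))
  f_s <- fit_tract_length(build_pairs(ev_s, sm_sparse, 1000))
  expect_equal(f_d$mean_bp, 30, tolerance = 0.2)
  expect_equal(f_s$mean_bp, 30, tolerance = 0.25)
})

test_that("block bootstrap produces sane intervals", {
  set.seed(9)
  cfg <- sim_config(chrom_lengths = 20e6, seed = 6)
  sm <- simulate_snp_map(cfg)
  ev <- simulate_nco_events(300, sm, 30, 20e6)
  expect_error(bootstrap_tract_ci(ev, sm, 20e6, B = 0), "positive")
  expect_warning(ci <- bootstrap_tract_ci(ev, sm, 20e6, B = 50),
                 "unstable")
  bb <- bootstrap_tract_ci(ev, sm, 20e6, B = 300)
  expect_lt(bb$ci[1], 30)
  expect_gt(bb$ci[2], 26)
  expect_lte(bb$ci[1], bb$ci[2])
  # degenerate: all events in one block -> interval collapses
  ev1 <- ev[(ev$min_start < 5e6), ]
  b1 <- bootstrap_tract_ci(ev1, sm, 20e6, B = 120, block_bp = 20e6)
  expect_equal(b1$ci[1], b1$ci[2])
})

test_that("tract-SNP probability matches the analytic uniform-grid value", {
  # SNPs exactly every 170 bp: tract of length L starting uniformly
  # covers a grid point with probability min(1, (L+1)/170);
  # for L ~ Exp(1/30) this integrates to (mean/spacing)(1 - exp(-spacing/mean))
  pos <- seq(170, 2e6, by = 170)
  sm <- toy_map(pos)
  centers <- data.frame(chrom = 1L,
                        center = runif(200, 1e5, 1.9e6))
  set.seed(31)
  res <- prob_tract_contains_snp(1 / 30, sm, centers, center_sd = 500,
                                 n_mc = 20000)
  analytic <- (30 / 170) * (1 - exp(-170 / 30))
  expect_lt(abs(res$prob - analytic), 3 * res$se + 0.01)
  expect_error(prob_tract_contains_snp(1 / 30, sm[0, ], centers),
               "empty")
})

test_that("DSB scaling identities hold", {
  e1 <- estimate_total_dsbs(270, 30, 1, power = 1, p_snp = 1,
                            co_detect_prob = 1, B = 100)
  expect_equal(e1$total_per_meiosis, 300)
  e2 <- estimate_total_dsbs(150, 0, 1, power = 0.5, p_snp = 1, B = 100)
  expect_equal(e2$total_per_meiosis, 300)
  expect_error(estimate_total_dsbs(10, 1, 1, power = 0, p_snp = 1),
               "\\(0, 1\\]")
  expect_error(estimate_total_dsbs(10, 1, 0, power = 1, p_snp = 1),
               "n_meioses")
})
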