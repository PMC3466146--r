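# Replichore / orientation / Ori-Ter categorization and the permutation KS test.

make_locations <- function(mid, L, strand = "+") {
  # point-like genes centered on the requested midpoints
  loc <- data.frame(gene_id = sprintf("g%04d", seq_along(mid)),
                    start = mid, end = mid,
                    strand = rep(strand, length.out = length(mid)),
                    stringsAsFactors = FALSE)
  attr(loc, "chromosome_length") <- L
  loc
}

test_that("replichore and orientation follow the circular definitions", {
  L <- 1e6
  cfg <- chromosome_config(L, ori = 2e5, ter = 7e5, window_n = 1L)
  loc <- make_locations(c(2e5 + 10, 2e5 - 10, 7e5 + 10, 6.9e5), L,
                        strand = c("+", "-", "+", "-"))
  cats <- assign_categories(loc, cfg)
  expect_equal(cats$replichore, c("Right", "Left", "Left", "Right"))
  expect_equal(cats$orientation, c("Forward", "Reverse", "Forward", "Reverse"))
  expect_equal(cats$proximity, c("Ori", "Ori", "Ter", "Ter"))
  # wrap-around: ori near the top of the coordinate system
  cfg2 <- chromosome_config(L, ori = L - 100, ter = 5e5, window_n = 1L)
  cats2 <- assign_categories(make_locations(c(50, L - 200, 4.9e5, 5.1e5), L),
                             cfg2)
  expect_equal(cats2$replichore, c("Right", "Left", "Right", "Left"))
})

test_that("gene midpoints respect circular wrap-around", {
  loc <- make_locations(c(250, 400, 600, 750), 1000)
  loc <- rbind(data.frame(gene_id = "w", start = 990, end = 10, strand = "+"),
               loc)
  cfg <- chromosome_config(1000, ori = 1, ter = 500, window_n = 1L)
  cats <- assign_categories(loc, cfg)
  # span 990..1000..10 has its midpoint at the origin of the circle
  expect_equal(cats$midpoint[cats$gene_id == "w"], 1000)
  expect_equal(cats$proximity[cats$gene_id == "w"], "Ori")
})

test_that("uniformly placed genes yield full Ori and Ter windows", {
  L <- 4e6
  mids <- seq(5000, L, by = 10000)  # 400 genes
  cfg <- chromosome_config(L, ori = 1e6, ter = 3e6, window_n = 100L)
  cats <- assign_categories(make_locations(mids, L), cfg)
  expect_equal(sum(cats$proximity == "Ori"), 200L)
  expect_equal(sum(cats$proximity == "Ter"), 200L)
  # brute-force nearest-midpoint check on each side of Ori
  d_circ <- pmin((mids - 1e6) %% L, (1e6 - mids) %% L)
  high <- (mids - 1e6) %% L <= (1e6 - mids) %% L
  expected_ori <- c(order(ifelse(high, d_circ, Inf))[1:100],
                    order(ifelse(!high, d_circ, Inf))[1:100])
  expect_setequal(which(cats$proximity == "Ori"), expected_ori)
})

test_that("window selection fails loudly when it cannot be honored", {
  L <- 1e5
  cfg <- chromosome_config(L, ori = 2.5e4, ter = 7.5e4, window_n = 100L)
  few <- make_locations(seq(1000, L, by = 1000), L)  # 100 genes in total
  expect_error(assign_categories(few, cfg), "side")
  # windows that would overlap are refused
  cfg2 <- chromosome_config(L, ori = 2.5e4, ter = 7.5e4, window_n = 30L)
  expect_error(assign_categories(make_locations(seq(1000, L, by = 1000), L),
                                 cfg2), "overlap")
  expect_error(chromosome_config(100, 5, 5), "differ")
})

test_that("mean profiles average per signal", {
  x <- c(0.5, 0.5, rep(0, 7))
  y <- c(0.25, 0.25, 0.5, rep(0, 6))
  expect_equal(unname(mean_profile(x)), x)
  expect_equal(unname(mean_profile(rbind(x, y))), (x + y) / 2)
  expect_error(mean_profile(matrix(numeric(0), 0, 9)), "empty")
})

test_that("simulated mean counts match the analytic expectation within 3 SE", {
  model <- codon_usage(length = 300L)
  genes <- simulate_genes(model, 200, seed = 91)
  cnt <- tss_count(genes)
  expected <- expected_tss_counts(model)
  se <- apply(cnt, 2, sd) / sqrt(nrow(cnt))
  # frame-1 columns can have zero variance; compare only where SE > 0
  ok <- se > 0
  expect_true(all(abs(colMeans(cnt)[ok] - expected[ok]) <= 3 * se[ok]))
  expect_true(all(abs(colMeans(cnt)[!ok] - expected[!ok]) < 1))
})

test_that("the 9-bin KS statistic is the maximum CDF gap", {
  u <- c(0.5, 0.5, rep(0, 7))
  expect_equal(ks_statistic(u, u), 0)
  expect_equal(ks_statistic(c(1, rep(0, 8)), c(rep(0, 8), 1)), 1)
  expect_equal(ks_statistic(u, c(0.25, 0.25, 0.5, rep(0, 6))), 0.5)
  # renormalization is applied internally
  expect_equal(ks_statistic(2 * u, 10 * u), 0)
})

test_that("comparing a group against itself gives D = 0 and p = 1", {
  set.seed(92)
  a <- matrix(runif(50 * 9), ncol = 9)
  a <- a / rowSums(a)
  res <- tssr_ks_test(a, a, M = 100, seed = 93)
  expect_equal(res$D, 0)
  expect_equal(res$p.value, 1)
  expect_equal(res$group_means[1, ], res$group_means[2, ])
  expect_equal(sum(res$group_means[1, ]), 1, tolerance = 1e-9)
})

test_that("the permutation KS result is reproducible and validated", {
  m <- codon_usage(length = 120L)
  a <- suppressWarnings(genic_tssr(tss_count(simulate_genes(m, 60, seed = 94))))
  b <- suppressWarnings(genic_tssr(tss_count(simulate_genes(m, 60, seed = 95))))
  r1 <- tssr_ks_test(a, b, M = 200, seed = 96)
  r2 <- tssr_ks_test(a, b, M = 200, seed = 96)
  expect_identical(r1, r2)
  expect_true(r1$p.value >= 0 && r1$p.value <= 1)
  # p is a multiple of 1/M
  expect_equal(r1$p.value * r1$M, round(r1$p.value * r1$M), tolerance = 1e-9)
  # relabeling A and B leaves D unchanged and p equal within resampling noise
  r3 <- tssr_ks_test(b, a, M = 200, seed = 96)
  expect_equal(r3$D, r1$D)
  expect_lt(abs(r3$p.value - r1$p.value),
            3 * sqrt(r1$p.value * (1 - r1$p.value) / r1$M) + 1 / r1$M)
  expect_error(tssr_ks_test(a, b[1:10, ]), "same size")
  expect_error(tssr_ks_test(a, b, M = 0), "at least 1")
})

test_that("sd_of_means summarizes the spread of each observed mean profile", {
  set.seed(97)
  a <- matrix(runif(30 * 9), ncol = 9); a <- a / rowSums(a)
  b <- matrix(runif(30 * 9), ncol = 9); b <- b / rowSums(b)
  res <- tssr_ks_test(a, b, M = 10, seed = 98)
  expect_equal(unname(res$sd_of_means["A"]), sd(colMeans(a)))
  expect_equal(unname(res$sd_of_means["B"]), sd(colMeans(b)))
})

test_that("pooled-count weighting is available as the alternative statistic", {
  set.seed(99)
  a <- matrix(rpois(40 * 9, 4) + 1, ncol = 9)
  b <- matrix(rpois(40 * 9, 4) + 1, ncol = 9)
  r <- tssr_ks_test(a, b, M = 50, seed = 100, profile = "pooled")
  expect_equal(unname(r$group_means[1, ]), unname(colSums(a) / sum(a)))
  # equal-weight and pooled statistics agree when every gene has equal totals
  an <- a / rowSums(a)
  bn <- b / rowSums(b)
  r_eq <- tssr_ks_test(an, bn, M = 1, seed = 1, profile = "mean")
  r_pl <- tssr_ks_test(an, bn, M = 1, seed = 1, profile = "pooled")
  expect_equal(r_eq$D, r_pl$D, tolerance = 1e-12)
})

test_that("the whole-chromosome screen contrasts three category pairs", {
  model <- codon_usage(length = 150L)
  sim <- simulate_genome(model, 400, seed = 102)
  L <- attr(sim$locations, "chromosome_length")
  cfg <- chromosome_config(L, ori = round(L * 0.1), ter = round(L * 0.6),
                           window_n = 100L)
  cnt <- tss_count(sim$genes)
  res <- tssr_bias_test(cnt, sim$locations, cfg, M = 50, seed = 103)
  expect_named(res[1:3], c("replichore", "orientation", "proximity"))
  expect_equal(res$proximity$n_per_group, 200L)
  for (nm in c("replichore", "orientation", "proximity")) {
    expect_true(res[[nm]]$p.value >= 0 && res[[nm]]$p.value <= 1)
    expect_true(all(abs(rowSums(res[[nm]]$group_means) - 1) < 1e-9))
  }
  # bit-reproducible under the same seed
  res2 <- tssr_bias_test(cnt, sim$locations, cfg, M = 50, seed = 103)
  expect_identical(res[1:3], res2[1:3])
})
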