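# Codon-usage gene simulation and its exact expected-count oracle.

degenerate_usage <- function(codon, stop = "TAA", n = 2L) {
  sense <- stats::setNames(rep(0, 61), setdiff(
    as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                    c("T", "C", "A", "G"), paste0)),
    c("TAA", "TAG", "TGA")))
  sense[codon] <- 1
  stp <- stats::setNames(rep(0, 3), c("TAA", "TAG", "TGA"))
  stp[stop] <- 1
  codon_usage(sense = sense, stop = stp, length = n)
}

test_that("a degenerate model generates its single possible gene", {
  m <- degenerate_usage("GGT", "TAA", n = 2L)
  g <- simulate_genes(m, 3, seed = 1)
  expect_equal(g$sequence, rep("GGTGGTTAA", 3))
  expect_identical(simulate_genes(m, 3, seed = 1), g)
})

test_that("frame-1 counts of simulated genes indicate the drawn stop", {
  m <- codon_usage(length = 30L)
  g <- simulate_genes(m, 50, seed = 2)
  cnt <- tss_count(g)
  stops <- substr(g$sequence, nchar(g$sequence) - 2L, nchar(g$sequence))
  expect_equal(unname(cnt[, "TAA.1"]), as.integer(stops == "TAA"))
  expect_equal(unname(cnt[, "TAG.1"]), as.integer(stops == "TAG"))
  expect_equal(unname(cnt[, "TGA.1"]), as.integer(stops == "TGA"))
})

test_that("expected counts are exact on hand-enumerable degenerate models", {
  # GGT body: junctions read TGG/GTG/GTT -- never a stop signal
  e <- expected_tss_counts(degenerate_usage("GGT", "TAA", n = 2L))
  expect_equal(unname(e), c(1, 0, 0, rep(0, 6)))
  # GTA body, n = 3: each of the 2 body junctions reads TA|G -> one TAG on
  # frame 2; the body->stop junction reads TA|T, no signal
  e2 <- expected_tss_counts(degenerate_usage("GTA", "TAA", n = 3L))
  expect_equal(unname(e2), c(1, 0, 0, 0, 2, 0, 0, 0, 0))
  expect_identical(tss_count(simulate_genes(degenerate_usage("GTA", "TAA", 3L),
                                            1, seed = 3))[1, ],
                   c(TAA.1 = 1L, TAG.1 = 0L, TGA.1 = 0L, TAA.2 = 0L,
                     TAG.2 = 2L, TGA.2 = 0L, TAA.3 = 0L, TAG.3 = 0L,
                     TGA.3 = 0L))
})

test_that("Monte-Carlo counts converge to the analytic expectation", {
  model <- codon_usage(length = 100L)
  genes <- simulate_genes(model, 20000, seed = 4)
  cnt <- tss_count(genes)
  expected <- expected_tss_counts(model)
  se <- apply(cnt, 2, sd) / sqrt(nrow(cnt))
  expect_true(all(abs(colMeans(cnt) - expected) <= 3 * pmax(se, 1e-12) +
                    1e-12))
  # pooled empirical TSSR converges to the normalized expectation
  expect_equal(unname(genomic_tssr(cnt, "pooled")),
               unname(expected_tssr(model)), tolerance = 0.02)
})

test_that("junction bias injects the advertised frame-specific effect", {
  base <- codon_usage(length = 200L)
  boosted <- codon_usage(length = 200L, junction_bias = c(TGA.2 = 2))
  e0 <- expected_tssr(base)
  e1 <- expected_tssr(boosted)
  expect_gt(e1["TGA.2"], e0["TGA.2"])
  # closed form at a single junction: doubling the TGA-forming pair weight
  # in a row that then renormalizes multiplies the match mass by
  # 2 / (1 + P(next codon starts with A))
  pA <- sum(base$sense[startsWith(names(base$sense), "A")])
  r2 <- expected_tss_counts(codon_usage(length = 2L,
                                        junction_bias = c(TGA.2 = 2)))
  r0 <- expected_tss_counts(codon_usage(length = 2L))
  expect_equal(unname(r2["TGA.2"] / r0["TGA.2"]), 2 / (1 + pA),
               tolerance = 1e-12)
  c1 <- expected_tss_counts(boosted)
  # the biased Markov simulator agrees with its own expectation
  cnt <- tss_count(simulate_genes(boosted, 2000, seed = 5))
  se <- apply(cnt, 2, sd) / sqrt(nrow(cnt))
  expect_true(all(abs(colMeans(cnt) - c1) <= 3 * pmax(se, 1e-12) + 1e-12))
  expect_error(codon_usage(junction_bias = c(bogus = 2)), "frame-2/3")
  expect_error(codon_usage(junction_bias = c(TAA.1 = 2)), "frame-2/3")
})

test_that("ratio sensitivity to a codon perturbation is smooth", {
  m0 <- codon_usage(length = 150L)
  eps <- 1e-3
  sense <- m0$sense
  sense["CTA"] <- sense["CTA"] + eps
  sense <- sense / sum(sense)
  m1 <- codon_usage(sense = sense, length = 150L)
  delta <- abs(expected_tssr(m1) - expected_tssr(m0))
  expect_true(all(delta < 50 * eps))
  expect_true(any(delta > 0))
})

test_that("simulated genomes have a consistent circular layout", {
  model <- codon_usage(length = c(20L, 60L))
  sim <- simulate_genome(model, 4, seed = 6, gap = 50L)
  len <- nchar(sim$genes$sequence)
  L <- attr(sim$locations, "chromosome_length")
  expect_equal(L, sum(len) + 4 * 50)
  expect_true(all(sim$locations$start >= 1 & sim$locations$end <= L))
  expect_equal(sim$locations$end - sim$locations$start + 1L, len)
  expect_true(all(sim$locations$strand %in% c("+", "-")))
  expect_identical(simulate_genome(model, 4, seed = 6, gap = 50L)$locations,
                   sim$locations)
})

test_that("three usage regimes are recovered as monophyletic clusters", {
  models <- list(lowGC = codon_usage(gc = 0.35, length = 200L),
                 midGC = codon_usage(gc = 0.50, length = 200L,
                                     stop = c(TAA = 0.4, TAG = 0.2, TGA = 0.4)),
                 highGC = codon_usage(gc = 0.65, length = 200L))
  rows <- list()
  for (k in seq_along(models)) {
    for (g in 1:3) {
      genes <- simulate_genes(models[[k]], 200, seed = 1000 * k + g)
      rows[[paste0(names(models)[k], "_", g)]] <-
        genomic_tssr(tss_count(genes), "pooled")
    }
  }
  m <- do.call(rbind, rows)
  tree <- tssr_cluster(m)
  for (k in names(models))
    expect_true(is_monophyletic(tree, grep(k, rownames(m), value = TRUE)))
})

test_that("codon usage models validate their inputs", {
  expect_error(codon_usage(stop = c(TAA = 0.5, TAG = 0.5, TGA = 0.5)),
               "summing to 1")
  expect_error(codon_usage(length = 0L), "positive")
  expect_error(codon_usage(sense = c(AAA = 1)), "61 sense codons")
  m <- codon_usage(gc = 0.5)
  expect_equal(sum(m$sense), 1, tolerance = 1e-12)
  expect_length(m$sense, 61)
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(m$sense)))
})

test_that("codon usage tables round-trip through the TSV reader", {
  m <- codon_usage(gc = 0.42)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(codon = c(names(m$sense), names(m$stop)),
                                probability = c(m$sense, m$stop) / 2),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_codon_usage(path, length = 99L)
  expect_equal(back$sense, m$sense, tolerance = 1e-12)
  expect_equal(back$stop, m$stop, tolerance = 1e-12)
  expect_equal(back$length, 99L)
})
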