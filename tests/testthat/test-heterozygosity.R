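test_that("allele frequencies and expected heterozygosity", {
  g <- make_genotypes(list(a = c(0L, 0L, 0L), b = c(1L, NA, 0L),
                           c = c(2L, 2L, 0L)))
  div <- allele_frequencies(g)
  # locus 1: calls 0,1,2 -> p = 0.5, E = 0.5
  expect_equal(div$alt_freq[1], 0.5)
  expect_equal(div$expected_het[1], 0.5)
  # locus 2: calls 0, NA, 2 -> missing excluded, p = 0.5
  expect_equal(div$alt_freq[2], 0.5)
  expect_equal(div$n_called[2], 2)
  # locus 3: all reference -> p = 0, E = 0
  expect_equal(div$alt_freq[3], 0)
  expect_equal(div$expected_het[3], 0)
})

test_that("all-missing loci are excluded with a warning", {
  g <- make_genotypes(list(a = c(0L, NA), b = c(1L, NA)))
  expect_warning(div <- allele_frequencies(g), "missing")
  expect_equal(div$locus_id, "snp01")
})

test_that("HL endpoints: all-heterozygous 0, all-homozygous 1", {
  set.seed(1)
  g <- make_genotypes(list(
    het = rep(1L, 10),
    hom = rep(c(0L, 2L), 5),
    mix1 = sample(0:2, 10, replace = TRUE),
    mix2 = sample(0:2, 10, replace = TRUE)
  ))
  hl <- hl_index(g)
  expect_equal(hl$hl[hl$individual_id == "het"], 0)
  expect_equal(hl$hl[hl$individual_id == "hom"], 1)
  expect_true(all(hl$hl >= 0 & hl$hl <= 1))
})

test_that("HL follows the E-weighted formula directly", {
  # two loci: E = 0.3 carried homozygous, E = 0.5 heterozygous
  # -> HL = 0.3 / (0.3 + 0.5) = 0.375
  g <- make_genotypes(list(ind = c(0L, 1L)))
  div <- structure(data.frame(locus_id = c("snp01", "snp02"),
                              alt_freq = c(NA, NA),
                              expected_het = c(0.3, 0.5),
                              n_called = c(1, 1)),
                   class = c("locus_diversity", "data.frame"))
  hl <- hl_index(g, div)
  expect_equal(hl$hl, 0.375)
  expect_equal(hl$n_loci_used, 2L)
})

test_that("missing calls contribute nowhere; undefined HL warns", {
  g <- make_genotypes(list(a = c(0L, NA, 1L), b = c(NA, NA, NA)))
  div <- structure(data.frame(locus_id = paste0("snp0", 1:3),
                              alt_freq = rep(NA_real_, 3),
                              expected_het = c(0.4, 0.5, 0.2),
                              n_called = rep(2, 3)),
                   class = c("locus_diversity", "data.frame"))
  expect_warning(hl <- hl_index(g, div), "undefined")
  expect_equal(hl$hl[1], 0.4 / (0.4 + 0.2))
  expect_true(is.na(hl$hl[2]))
  expect_equal(hl$n_loci_used, c(2L, 0L))
})

test_that("HL is invariant to REF/ALT relabeling", {
  set.seed(2)
  p <- sim_params(n_individuals = 60, n_loci = 12, seed = 2)
  g <- simulate_genotypes(p)
  flip <- c(2, 5, 9)
  calls <- unclass(g)
  calls[, flip] <- 2L - calls[, flip]
  g2 <- genotype_matrix(calls)
  expect_equal(hl_index(g)$hl, hl_index(g2)$hl, tolerance = 1e-12)
})

test_that("flipping a heterozygous call to homozygous raises HL", {
  set.seed(3)
  p <- sim_params(n_individuals = 40, n_loci = 10, seed = 3)
  g <- simulate_genotypes(p)
  div <- allele_frequencies(g)
  calls <- unclass(g)
  i <- which(apply(calls, 1, function(r) any(r == 1L)))[1]
  j <- which(calls[i, ] == 1L)[1]
  calls2 <- calls; calls2[i, j] <- 0L
  hl1 <- hl_index(g, div)$hl[i]
  hl2 <- hl_index(genotype_matrix(calls2), div)$hl[i]
  expect_gt(hl2, hl1)
})

test_that("mean HL under HWE matches an independent Monte-Carlo oracle", {
  set.seed(4)
  freqs <- runif(15, 0.15, 0.85)
  p <- sim_params(n_individuals = 4000, n_loci = 15, allele_freqs = freqs,
                  inbreeding_f = 0, seed = 4)
  g <- simulate_genotypes(p)
  hl <- hl_index(g, structure(
    data.frame(locus_id = colnames(g), alt_freq = freqs,
               expected_het = 2 * freqs * (1 - freqs),
               n_called = nrow(g)),
    class = c("locus_diversity", "data.frame")))
  # oracle: direct multinomial sampling and the definition applied by hand
  n_mc <- 100000
  e <- 2 * freqs * (1 - freqs)
  hom_draw <- matrix(rbinom(n_mc * 15, 1, rep(1 - e, each = n_mc)), n_mc, 15)
  hl_mc <- (hom_draw %*% e) / sum(e)
  se <- sd(hl$hl) / sqrt(nrow(g)) + sd(hl_mc) / sqrt(n_mc)
  expect_lt(abs(mean(hl$hl) - mean(hl_mc)), 3 * se)
})

test_that("population summaries: SE, medians and the interpolation rule", {
  hl <- structure(data.frame(individual_id = letters[1:9],
                             hl = (1:9) / 10, n_loci_used = 10L),
                  class = c("hl_scores", "data.frame"))
  s <- hl_summary(hl)
  expect_equal(s$p50, 0.5)

  hl2 <- structure(data.frame(individual_id = letters[1:10],
                              hl = (1:10) / 10, n_loci_used = 10L),
                   class = c("hl_scores", "data.frame"))
  s2 <- hl_summary(hl2)
  # hand-computed linear interpolation between order statistics:
  # h = (n-1)p + 1 = 1.9 -> 0.1 + 0.9 * (0.2 - 0.1) = 0.19
  expect_equal(s2$p10, 0.19)
  expect_equal(s2$p90, 0.91)

  hlc <- structure(data.frame(individual_id = letters[1:5], hl = 0.4,
                              n_loci_used = 10L),
                   class = c("hl_scores", "data.frame"))
  sc <- hl_summary(hlc)
  expect_equal(sc$se_hl, 0)
  expect_true(all(unlist(sc[paste0("p", seq(10, 90, 10))]) == 0.4))

  expect_warning(
    hl_summary(structure(data.frame(individual_id = c("a", "b"),
                                    hl = c(0.5, NA), n_loci_used = c(5L, 0L)),
                         class = c("hl_scores", "data.frame")),
               groups = c("g1", "g2")),
    "excluded")
})
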