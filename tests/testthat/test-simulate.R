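test_that("inbreeding F = 1 eliminates heterozygotes; p = 0 fixes hom-ref", {
  p <- sim_params(n_individuals = 500, n_loci = 4,
                  allele_freqs = c(0.5, 0.2, 0, 1), inbreeding_f = 1)
  set.seed(1)
  g <- simulate_genotypes(p)
  expect_equal(sum(unclass(g) == 1L), 0)
  expect_true(all(unclass(g)[, 3] == 0L))
  expect_true(all(unclass(g)[, 4] == 2L))
})

test_that("heterozygote fraction under HWE matches binomial sampling", {
  p <- sim_params(n_individuals = 100000L, n_loci = 1, allele_freqs = 0.5,
                  inbreeding_f = 0)
  set.seed(2)
  g <- simulate_genotypes(p)
  het <- mean(unclass(g) == 1L)
  half_width <- qnorm(0.9995) * sqrt(0.25 / 100000)  # 99.9% interval
  expect_lt(abs(het - 0.5), half_width)
})

test_that("genotype frequencies converge to the F-model probabilities", {
  pfreq <- 0.3; f <- 0.4
  p <- sim_params(n_individuals = 100000L, n_loci = 1, allele_freqs = pfreq,
                  inbreeding_f = f)
  set.seed(3)
  g <- simulate_genotypes(p)
  pq <- pfreq * (1 - pfreq)
  expected <- c((1 - pfreq)^2 + pq * f, 2 * pq * (1 - f), pfreq^2 + pq * f)
  obs <- tabulate(as.vector(unclass(g)) + 1L, 3)
  gof <- chisq.test(obs, p = expected)
  expect_gt(gof$p.value, 1e-4)
})

test_that("invalid allele frequencies and F are rejected", {
  expect_error(sim_params(n_loci = 2, allele_freqs = c(0.5, 1.2)), "0, 1")
  expect_error(sim_params(n_loci = 2, allele_freqs = c(0.5, NaN)), "finite")
  expect_error(sim_params(inbreeding_f = -0.1), "inbreeding")
})

test_that("mean HL increases strictly with the inbreeding coefficient", {
  set.seed(4)
  freqs <- runif(20, 0.2, 0.8)
  means <- sapply(c(0, 0.25, 0.5, 1), function(f) {
    p <- sim_params(n_individuals = 10000L, n_loci = 20, allele_freqs = freqs,
                    inbreeding_f = f, seed = 40 + round(100 * f))
    g <- simulate_genotypes(p)
    mean(hl_index(g)$hl, na.rm = TRUE)
  })
  expect_true(all(diff(means) > 0))
})

test_that("ages respect the truncation range and the analytic mean", {
  p <- sim_params(n_individuals = 50000L)
  set.seed(5)
  cv <- simulate_covariates(p)
  expect_true(all(cv$age >= 45 & cv$age <= 92))
  mu <- truncnorm_mean(59.5, 8, 45, 92)
  se <- sd(cv$age) / sqrt(nrow(cv))
  expect_lt(abs(mean(cv$age) - mu), 3 * se)
})

test_that("sex and cohort follow the configured proportions", {
  p <- sim_params(n_individuals = 200, male_fraction = 0)
  set.seed(6)
  cv <- simulate_covariates(p)
  expect_true(all(cv$sex == "female"))
  expect_setequal(levels(cv$cohort), c("RS1", "RS2"))
  expect_error(sim_params(age_range = c(60, 60)), "min < max")
})

test_that("an asymmetric template is rejected with an explanation", {
  tpl <- face_template()
  tpl[1, 2] <- tpl[1, 2] + 0.01   # break the mirror symmetry of a pair
  expect_error(sim_params(template = tpl), "not symmetric")
})

test_that("zero planted asymmetry yields near-zero TA downstream", {
  tpl <- face_template()
  bas <- asym_basis(tpl, face_scheme())
  p <- sim_params(n_individuals = 20, n_loci = 2,
                  da_vector = rep(0, 27), fa_sigma0 = 1e-12,
                  noise_sigma = 0, seed = 7)
  ch <- simulate_cohort(p)
  sc <- asymmetry_scores(ch$faces$landmarks)
  expect_true(all(sc$ta < 1e-8))
})

test_that("nuisance transforms are fully removed by the downstream GPA", {
  p <- sim_params(n_individuals = 40, n_loci = 2, noise_sigma = 0, seed = 8)
  c1 <- simulate_cohort(p, nuisance = TRUE)
  c2 <- simulate_cohort(p, nuisance = FALSE)
  expect_identical(c1$faces$planted$a, c2$faces$planted$a)
  s1 <- asymmetry_scores(c1$faces$landmarks)
  s2 <- asymmetry_scores(c2$faces$landmarks)
  expect_equal(s1$ta, s2$ta, tolerance = 1e-8)
  expect_equal(s1$fa, s2$fa, tolerance = 1e-8)
})

test_that("fixed seed gives bit-identical cohorts", {
  p <- sim_params(n_individuals = 30, n_loci = 5, seed = 9)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(unclass(c1$genotypes), unclass(c2$genotypes))
  expect_identical(unclass(c1$faces$landmarks), unclass(c2$faces$landmarks))
  expect_identical(c1$covariates$age, c2$covariates$age)
})

test_that("guard rails: HL effect needs HL; sigma must stay positive", {
  p <- sim_params(n_individuals = 10, n_loci = 2, beta_hl = 1e-4)
  set.seed(10)
  cv <- simulate_covariates(p)
  expect_error(simulate_faces(p, cv), "hl must be supplied")
  expect_error(sim_params(beta_hl = -1e-3), "> 0")
})

test_that("planted DA is recovered from a simulated cohort", {
  tpl <- face_template()
  bas <- asym_basis(tpl, face_scheme())
  u <- as.vector(bas$shape %*% rep(1, 9))
  da <- 0.4 * 5e-4 * u / sqrt(sum(u^2))
  ests <- sapply(1:6, function(s) {
    p <- sim_params(n_individuals = 800, n_loci = 2, da_vector = da,
                    noise_sigma = 0, seed = 400 + s)
    ch <- simulate_cohort(p)
    as.vector(asymmetry_scores(ch$faces$landmarks, orient_to = tpl)$da_vector)
  })
  m <- rowMeans(ests)
  se <- apply(ests, 1, sd) / sqrt(ncol(ests))
  expect_lt(sqrt(sum((m - da)^2)), 3 * sqrt(sum(se^2)))
})
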