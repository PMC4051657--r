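make_model_inputs <- function(n = 120, n_loci = 6, seed = 1, f = 0) {
  p <- sim_params(n_individuals = n, n_loci = n_loci, inbreeding_f = f,
                  seed = seed)
  set.seed(seed)
  g <- simulate_genotypes(p)
  cv <- simulate_covariates(p)
  list(g = g, cv = cv, hl = hl_index(g))
}

test_that("genotype columns are reference-coded against genotype 0", {
  cv <- structure(data.frame(individual_id = c("a", "b", "c"),
                             age = c(50, 60, 70),
                             sex = factor(c("female", "male", "female"),
                                          levels = c("female", "male")),
                             cohort = factor(c("RS1", "RS2", "RS1"))),
                  class = c("covariate_table", "data.frame"))
  g <- make_genotypes(list(a = c(0L, 1L), b = c(1L, 1L), c = c(2L, 1L)))
  hl <- structure(data.frame(individual_id = c("a", "b", "c"),
                             hl = c(0.5, 0.6, 0.7), n_loci_used = 2L),
                  class = c("hl_scores", "data.frame"))
  d <- build_design(cv, hl, g, snps = "snp01")
  # snp01 genotype column [0,1,2] -> indicator rows (0,0), (1,0), (0,1)
  expect_equal(unname(d$X[, "snp011"]), c(0, 1, 0))
  expect_equal(unname(d$X[, "snp012"]), c(0, 0, 1))
  expect_true("snp01 1 (ref. 0)" %in% d$labels)
})

test_that("constant sex or genotype columns are dropped with a warning", {
  inp <- make_model_inputs(seed = 2)
  cv <- inp$cv
  cv$sex <- factor(rep("female", nrow(cv)), levels = c("female", "male"))
  expect_warning(d <- build_design(cv, inp$hl, inp$g, snps = character(0)),
                 "sex")
  expect_false(any(grepl("sex", colnames(d$X))))
})

test_that("column count: intercept + sex + age + hl + cohort + 2 per SNP", {
  inp <- make_model_inputs(seed = 3)
  d <- build_design(inp$cv, inp$hl, inp$g, snps = 1:5)
  expect_equal(ncol(d$X), 1 + 1 + 1 + 1 + 1 + 2 * 5)
})

test_that("OLS reproduces exact and hand-computed fits", {
  x <- cbind("(Intercept)" = 1, x = c(0, 1, 2, 3))
  # suppressed: summary.lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(ols_fit(x, 1 + 2 * c(0, 1, 2, 3)))
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_lt(fit$sigma, 1e-12)

  # normal equations by hand: x = (0,1,2), y = (1,2,4)
  x2 <- cbind("(Intercept)" = 1, x = c(0, 1, 2))
  fit2 <- ols_fit(x2, c(1, 2, 4))
  expect_equal(unname(coef(fit2)), c(5 / 6, 3 / 2), tolerance = 1e-12)
})

test_that("row permutation leaves the fit unchanged", {
  set.seed(4)
  x <- cbind(1, matrix(rnorm(60), 30, 2))
  colnames(x) <- c("(Intercept)", "a", "b")
  y <- rnorm(30)
  perm <- sample(30)
  f1 <- ols_fit(x, y)
  f2 <- ols_fit(x[perm, ], y[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("rank deficiency errors naming the collinear term", {
  x <- cbind("(Intercept)" = 1, a = 1:10, dup = 1:10)
  expect_error(ols_fit(x, rnorm(10)), "dup")
  expect_error(ols_fit(cbind(a = 1:10), c(rnorm(9), NA)), "non-finite")
})

test_that("OLS matches an SVD pseudo-inverse oracle on random designs", {
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(15:40, 1); p <- sample(2:5, 1)
    x <- cbind(1, matrix(rnorm(n * p), n, p))
    colnames(x) <- c("(Intercept)", paste0("v", seq_len(p)))
    y <- rnorm(n)
    expect_equal(unname(coef(ols_fit(x, y))), pinv_coef(x, y),
                 tolerance = 1e-8)
  }
})

test_that("t statistics, p values and R^2 agree with summary.lm", {
  inp <- make_model_inputs(n = 150, seed = 6)
  d <- build_design(inp$cv, inp$hl, inp$g, snps = 1:2)
  set.seed(6)
  y <- rnorm(150)
  fit <- ols_fit(d, y[seq_along(d$ids)])
  ct <- fit$coefficients
  expect_equal(ct$t_value, ct$estimate / ct$std_error, tolerance = 1e-10)
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
})

test_that("alpha = 1 retains all three candidate interactions", {
  inp <- make_model_inputs(seed = 7)
  d <- build_design(inp$cv, inp$hl, inp$g, snps = character(0),
                    interactions = c("sex:age", "sex:hl", "age:hl"))
  set.seed(7)
  y <- rnorm(length(d$ids))
  pr <- prune_interactions(d, y, alpha = 1)
  expect_setequal(pr$kept, c("sex:age", "sex:hl", "age:hl"))
  expect_equal(nrow(pr$removed), 0)
})

test_that("stepwise pruning matches an independent formula-based oracle", {
  set.seed(8)
  for (rep in 1:40) {
    inp <- make_model_inputs(n = 120, n_loci = 4, seed = 800 + rep)
    d <- build_design(inp$cv, inp$hl, inp$g, snps = character(0),
                      interactions = c("sex:age", "sex:hl", "age:hl"))
    y <- rnorm(length(d$ids))
    pr <- prune_interactions(d, y, alpha = 0.05)
    df <- cbind(d$data, y = y)
    expect_setequal(pr$kept, oracle_stepwise(df, alpha = 0.05))
  }
})

test_that("a strong planted sex x HL interaction is retained", {
  retained <- logical(60)
  for (rep in seq_along(retained)) {
    inp <- make_model_inputs(n = 300, n_loci = 4, seed = 2000 + rep)
    d <- build_design(inp$cv, inp$hl, inp$g, snps = character(0),
                      interactions = c("sex:age", "sex:hl", "age:hl"))
    dat <- d$data
    y <- 0.001 * (dat$sex == "male") * dat$hl + rnorm(nrow(dat), 0, 1e-4)
    pr <- prune_interactions(d, y, alpha = 0.05)
    retained[rep] <- "sex:hl" %in% pr$kept
  }
  expect_gte(mean(retained), 0.99)
})

test_that("genome-wide flag thresholds are honored", {
  fit <- structure(list(coefficients = data.frame(
    term = c("a", "b", "c"), label = c("a", "b", "c"),
    estimate = 1, std_error = 1, t_value = 1,
    p_value = c(1e-9, 1e-7, 0.5))), class = "asym_lm")
  fl <- genomewide_flag(fit)
  expect_identical(unname(fl), c(TRUE, FALSE, FALSE))
  expect_identical(unname(genomewide_flag(fit, threshold = 1e-6)),
                   c(TRUE, TRUE, FALSE))
})
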