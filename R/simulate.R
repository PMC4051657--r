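#' Simulation parameters for a synthetic cohort
#'
#' Bundles and validates every knob of the cohort generator. The defaults
#' emulate a large two-cohort adult study: n = 3215 individuals aged 45--92
#' (truncated normal, mean 59.5, SD 8.0), cohorts RS1/RS2 in proportion
#' 2470:745, and 102 independent biallelic SNPs with allele frequencies drawn
#' Uniform(0.1, 0.9) under inbreeding coefficient `inbreeding_f = 0`.
#'
#' Landmark data are built from a bilaterally symmetric template (unit
#' centroid size): each face is template + symmetric individual deviation +
#' half of a planted antisymmetric asymmetry field, then an arbitrary
#' similarity transform (rotation/translation/scale) and coordinate
#' measurement noise are applied. The individual asymmetry field is
#' `a_i = da_vector + e_i` with `e_i` zero-mean Gaussian of scale
#' `sigma_i = fa_sigma0 + beta_hl * HL_i` (plus optional per-genotype, sex and
#' age shifts). Planted fields are projected onto the 9-dof asymmetric shape
#' subspace (the antisymmetric space minus the similarity-transform
#' directions that Procrustes alignment removes), so that planted values are
#' exactly recoverable by the object-symmetry pipeline.
#'
#' @param n_individuals cohort size.
#' @param n_loci number of biallelic loci.
#' @param allele_freqs optional per-locus ALT frequencies in \[0, 1\]; if
#'   NULL, drawn Uniform(0.1, 0.9) at simulation time (recorded in output).
#' @param inbreeding_f inbreeding coefficient F in \[0, 1\]; genotypes drawn
#'   with P(het) = 2p(1-p)(1-F) and the matching homozygote excess.
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param male_fraction proportion of males.
#' @param cohort_fractions named proportions summing to 1 (cohort labels).
#' @param template k x 3 bilaterally symmetric landmark template.
#' @param scheme the [symmetry_scheme()] the template satisfies.
#' @param da_vector planted directional asymmetry: `"auto"` (a fixed pattern
#'   of norm `0.05 * fa_sigma0`), a length-3k vector, or a k x 3 matrix.
#'   Always projected onto the recoverable asymmetric shape subspace.
#' @param fa_sigma0 baseline FA scale (shape units per dof).
#' @param beta_hl effect of HL on the FA scale (shape units per HL unit).
#' @param beta_snp optional list(locus =, shifts = c(s0, s1, s2)) adding
#'   per-genotype FA-scale shifts for one designated locus.
#' @param beta_male,beta_age optional additive shifts of the FA scale for
#'   males and per year of age (both 0 by default).
#' @param sym_sigma scale of the symmetric individual shape deviation.
#' @param noise_sigma landmark measurement noise SD (shape units, per
#'   coordinate).
#' @param seed RNG seed used by [simulate_cohort()].
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 3215L, n_loci = 102L,
                       allele_freqs = NULL, inbreeding_f = 0,
                       age_mean = 59.5, age_sd = 8.0, age_range = c(45, 92),
                       male_fraction = 0.5,
                       cohort_fractions = c(RS1 = 2470, RS2 = 745) / 3215,
                       template = face_template(), scheme = face_scheme(),
                       da_vector = "auto", fa_sigma0 = 5e-4,
                       beta_hl = 0, beta_snp = NULL,
                       beta_male = 0, beta_age = 0,
                       sym_sigma = 0.013, noise_sigma = 5e-5, seed = NULL) {
  stopifnot(is_count(n_individuals), is_count(n_loci))
  if (!is.null(allele_freqs)) {
    if (length(allele_freqs) != n_loci)
      stop_("allele_freqs must have one frequency per locus")
    if (!all(is.finite(allele_freqs)) || any(allele_freqs < 0 | allele_freqs > 1))
      stop_("allele frequencies must be finite and in [0, 1]")
  }
  if (!is.finite(inbreeding_f) || inbreeding_f < 0 || inbreeding_f > 1)
    stop_("inbreeding_f must be in [0, 1]")
  if (male_fraction < 0 || male_fraction > 1)
    stop_("male_fraction must be in [0, 1]")
  if (any(cohort_fractions < 0) || abs(sum(cohort_fractions) - 1) > 1e-8)
    stop_("cohort_fractions must be nonnegative and sum to 1")
  if (length(age_range) != 2L || !(age_range[1L] < age_range[2L]))
    stop_("age_range must satisfy min < max")
  if (!is.finite(fa_sigma0) || fa_sigma0 <= 0) stop_("fa_sigma0 must be > 0")
  # sigma_i must stay positive over the attainable HL range [0, 1]
  if (fa_sigma0 + min(0, beta_hl) <= 0)
    stop_("fa_sigma0 + beta_hl * HL must be > 0 for all HL in [0, 1]")
  if (symmetry_residual(template, scheme) > 1e-8)
    stop_("template is not symmetric under the scheme: midline landmarks must ",
          "lie on the reflection plane and paired landmarks must be exact ",
          "mirror images")
  if (!is.null(beta_snp))
    stopifnot(is.list(beta_snp), length(beta_snp$shifts) == 3L,
              is_count(beta_snp$locus), beta_snp$locus <= n_loci)
  if (is.null(names(cohort_fractions)))
    names(cohort_fractions) <- paste0("cohort", seq_along(cohort_fractions))
  structure(
    list(n_individuals = as.integer(n_individuals), n_loci = as.integer(n_loci),
         allele_freqs = allele_freqs, inbreeding_f = inbreeding_f,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         male_fraction = male_fraction, cohort_fractions = cohort_fractions,
         template = template, scheme = scheme, da_vector = da_vector,
         fa_sigma0 = fa_sigma0, beta_hl = beta_hl, beta_snp = beta_snp,
         beta_male = beta_male, beta_age = beta_age, sym_sigma = sym_sigma,
         noise_sigma = noise_sigma, seed = seed),
    class = "sim_params"
  )
}

#' Basis of the asymmetric and symmetric deviation subspaces
#'
#' For a symmetric template under a scheme, builds orthonormal bases of the
#' antisymmetric deviation subspace (3 dof per bilateral pair + 1 per midline
#' landmark), of its nuisance subspace (the translation along the reflection
#' axis and the two rotations about the in-plane axes, which Procrustes
#' alignment removes), of the resulting asymmetric *shape* subspace, and of
#' the symmetric deviation subspace. Fields are length-3k vectors in
#' column-major (landmark-fastest) order.
#'
#' @param template k x 3 symmetric configuration (defines the rotation
#'   fields).
#' @param scheme a [symmetry_scheme()].
#' @return List with `anti` (3k x d_a), `nuisance` (3k x 3), `shape`
#'   (3k x (d_a - 3)), `sym` (3k x d_s) orthonormal basis matrices.
#' @export
asym_basis <- function(template, scheme = face_scheme()) {
  k <- scheme$n_landmarks
  ax <- scheme$reflect_axis
  oth <- setdiff(1:3, ax)
  cell <- function(lm, axis) (axis - 1L) * k + lm
  anti <- list(); sym <- list()
  for (i in seq_len(nrow(scheme$pairs))) {
    l <- scheme$pairs[i, 1L]; r <- scheme$pairs[i, 2L]
    for (j in 1:3) {
      fa <- numeric(3L * k); fs <- numeric(3L * k)
      s <- if (j == ax) 1 else -1          # antisymmetric: delta_r = -reflect(delta_l)
      fa[cell(l, j)] <- 1; fa[cell(r, j)] <- s
      fs[cell(l, j)] <- 1; fs[cell(r, j)] <- -s
      anti[[length(anti) + 1L]] <- fa / sqrt(2)
      sym[[length(sym) + 1L]] <- fs / sqrt(2)
    }
  }
  for (m in scheme$midline) {
    fa <- numeric(3L * k); fa[cell(m, ax)] <- 1
    anti[[length(anti) + 1L]] <- fa
    for (j in oth) {
      fs <- numeric(3L * k); fs[cell(m, j)] <- 1
      sym[[length(sym) + 1L]] <- fs
    }
  }
  anti <- do.call(cbind, anti)
  sym <- do.call(cbind, sym)
  # nuisance: translation along reflection axis; rotations about the two
  # other axes (their infinitesimal fields are antisymmetric)
  tx <- numeric(3L * k); tx[cell(seq_len(k), ax)] <- 1
  rots <- lapply(oth, function(u) {
    w <- c(0, 0, 0); w[u] <- 1
    as.vector(t(apply(template, 1L, function(p) c(w[2] * p[3] - w[3] * p[2],
                                                  w[3] * p[1] - w[1] * p[3],
                                                  w[1] * p[2] - w[2] * p[1]))))
  })
  nuis <- cbind(tx, rots[[1L]], rots[[2L]])
  # express nuisance inside the antisymmetric subspace and orthonormalize
  nuis <- anti %*% crossprod(anti, nuis)
  nuis <- qr.Q(qr(nuis))
  # shape subspace: antisymmetric minus nuisance
  m <- anti - nuis %*% crossprod(nuis, anti)
  sv <- svd(m)
  shape <- sv$u[, sv$d > 1e-8, drop = FALSE]
  list(anti = anti, nuisance = nuis, shape = shape, sym = sym)
}

#' Simulate genotypes under an inbreeding coefficient
#'
#' Draws independent biallelic genotypes per locus with the inbreeding-
#' deformed Hardy-Weinberg probabilities: for ALT frequency p and inbreeding
#' coefficient F, P(hom-ref) = (1-p)^2 + p(1-p)F, P(het) = 2p(1-p)(1-F),
#' P(hom-alt) = p^2 + p(1-p)F.
#'
#' @param params a [sim_params()].
#' @return A [genotype_matrix()] with attribute `"allele_freqs"` recording
#'   the frequencies used.
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_individuals; l <- params$n_loci; f <- params$inbreeding_f
  p <- params$allele_freqs %||% stats::runif(l, 0.1, 0.9)
  if (!all(is.finite(p)) || any(p < 0 | p > 1))
    stop_("allele frequencies must be finite and in [0, 1]")
  calls <- matrix(NA_integer_, n, l)
  for (j in seq_len(l)) {
    pq <- p[j] * (1 - p[j])
    prob <- c((1 - p[j])^2 + pq * f, 2 * pq * (1 - f), p[j]^2 + pq * f)
    calls[, j] <- sample.int(3L, n, replace = TRUE, prob = prob) - 1L
  }
  g <- genotype_matrix(calls, sprintf("ind%04d", seq_len(n)),
                       sprintf("snp%03d", seq_len(l)))
  attr(g, "allele_freqs") <- p
  g
}

#' Simulate covariates (age, sex, cohort)
#'
#' Ages are drawn from a normal distribution truncated to `age_range` by
#' exact rejection sampling (clipping would distort the moments); sex is
#' Bernoulli(`male_fraction`); cohort labels are multinomial with
#' `cohort_fractions`.
#'
#' @param params a [sim_params()].
#' @return Data frame of class `covariate_table` with columns
#'   `individual_id`, `age`, `sex` (factor female/male), `cohort` (factor).
#' @export
simulate_covariates <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_individuals
  lo <- params$age_range[1L]; hi <- params$age_range[2L]
  if (!(lo < hi)) stop_("degenerate age range (min >= max)")
  age <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), params$age_mean, params$age_sd)
    ok <- draw >= lo & draw <= hi
    age[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  sex <- factor(ifelse(stats::runif(n) < params$male_fraction, "male", "female"),
                levels = c("female", "male"))
  cohort <- factor(sample(names(params$cohort_fractions), n, replace = TRUE,
                          prob = params$cohort_fractions),
                   levels = names(params$cohort_fractions))
  structure(
    data.frame(individual_id = sprintf("ind%04d", seq_len(n)), age = age,
               sex = sex, cohort = cohort, stringsAsFactors = FALSE),
    class = c("covariate_table", "data.frame")
  )
}

#' Simulate landmark configurations with planted asymmetry
#'
#' Builds each face as template + symmetric individual deviation + half of a
#' planted antisymmetric asymmetry field `a_i = da + e_i` (so the
#' original-minus-reflection difference recovers `a_i` exactly to first
#' order), with `e_i` isotropic Gaussian of scale `sigma_i` in the
#' 9-dof asymmetric shape subspace; an arbitrary similarity transform and
#' i.i.d. coordinate noise are then applied. The planted fields are returned
#' for truth-checking.
#'
#' @param params a [sim_params()].
#' @param covariates a `covariate_table` (defines n and the optional sex/age
#'   scale shifts).
#' @param hl optional per-individual HL values; required when
#'   `params$beta_hl != 0`.
#' @param snp_calls optional genotype vector (0/1/2) for the designated
#'   `beta_snp` locus.
#' @param nuisance apply the random similarity transforms? (TRUE; FALSE is
#'   useful to verify that alignment removes them).
#' @return List of class `sim_faces`: `landmarks` (a [landmark_array()]),
#'   `planted` (list with `a` = n x 3k matrix of planted asymmetry fields,
#'   `da` = planted DA field, `sigma` = per-individual FA scales).
#' @export
simulate_faces <- function(params, covariates, hl = NULL, snp_calls = NULL,
                           nuisance = TRUE) {
  stopifnot(inherits(params, "sim_params"),
            inherits(covariates, "covariate_table"))
  n <- nrow(covariates)
  tpl <- params$template
  scheme <- params$scheme
  if (symmetry_residual(tpl, scheme) > 1e-8)
    stop_("template is not symmetric under the scheme")
  if (params$beta_hl != 0 && is.null(hl))
    stop_("hl must be supplied when beta_hl != 0")
  bas <- asym_basis(tpl, scheme)
  s_dim <- ncol(bas$shape)
  sigma <- rep(params$fa_sigma0, n)
  if (!is.null(hl)) sigma <- sigma + params$beta_hl * hl
  if (!is.null(params$beta_snp)) {
    if (is.null(snp_calls)) stop_("snp_calls required when beta_snp is set")
    sigma <- sigma + params$beta_snp$shifts[snp_calls + 1L]
  }
  sigma <- sigma + params$beta_male * (covariates$sex == "male") +
    params$beta_age * (covariates$age - params$age_mean)
  if (any(!is.finite(sigma) | sigma <= 0))
    stop_("planted FA scale sigma_i must be positive for every individual")
  da <- params$da_vector
  if (identical(da, "auto")) {
    u <- bas$shape %*% rep(1, s_dim)
    da <- 0.05 * params$fa_sigma0 * as.vector(u) / sqrt(sum(u^2))
  } else {
    da <- as.vector(da)
    if (length(da) != nrow(tpl) * 3L)
      stop_("da_vector must have one entry per landmark coordinate")
    da <- as.vector(bas$shape %*% crossprod(bas$shape, da))
  }
  # draw order: symmetric deviations, asymmetry innovations, noise, nuisance
  # (so toggling the nuisance transforms does not change the signal draws)
  sym_coef <- matrix(stats::rnorm(n * ncol(bas$sym), 0, params$sym_sigma),
                     n, ncol(bas$sym))
  e_coef <- matrix(stats::rnorm(n * s_dim), n, s_dim) * sigma
  a <- sweep(e_coef %*% t(bas$shape), 2L, da, `+`)
  noise <- if (params$noise_sigma > 0)
    array(stats::rnorm(nrow(tpl) * 3L * n, 0, params$noise_sigma),
          dim = c(nrow(tpl), 3L, n)) else 0
  coords <- array(0, dim = c(nrow(tpl), 3L, n))
  for (i in seq_len(n)) {
    cfg <- tpl + matrix(sym_coef[i, ] %*% t(bas$sym), nrow(tpl), 3L) +
      matrix(a[i, ], nrow(tpl), 3L) / 2
    if (nuisance) {
      r <- qr_rotation(matrix(stats::rnorm(9), 3L, 3L))
      sc <- stats::runif(1L, 0.8, 1.25)
      tr <- stats::rnorm(3L, 0, 0.5)
      cfg <- sc * cfg %*% r + rep(tr, each = nrow(tpl))
    }
    coords[, , i] <- cfg
  }
  coords <- coords + noise
  structure(
    list(landmarks = landmark_array(coords, ids = covariates$individual_id,
                                    landmark_names = rownames(tpl)),
         planted = list(a = a, da = da, sigma = sigma)),
    class = "sim_faces"
  )
}

## uniform-ish random rotation: QR of a Gaussian matrix with sign and
## determinant fixes (deterministic given the input matrix)
qr_rotation <- function(m) {
  qrd <- qr(m)
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

#' Simulate a complete cohort
#'
#' Runs the full generator under one seed: genotypes, allele frequencies, HL
#' scores, covariates, and landmark data (with the HL or SNP effect on the FA
#' scale if planted).
#'
#' @param params a [sim_params()]; `params$seed`, if non-NULL, seeds the RNG.
#' @param nuisance apply random similarity transforms to the faces? Default
#'   TRUE.
#' @return List of class `sim_cohort` with elements `genotypes`, `diversity`,
#'   `hl`, `covariates`, `faces`, `params`.
#' @export
simulate_cohort <- function(params = sim_params(), nuisance = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  g <- simulate_genotypes(params)
  div <- allele_frequencies(g)
  hl <- hl_index(g, div)
  cov <- simulate_covariates(params)
  snp_calls <- if (!is.null(params$beta_snp))
    as.vector(unclass(g)[, params$beta_snp$locus]) else NULL
  faces <- simulate_faces(params, cov, hl = hl$hl, snp_calls = snp_calls,
                          nuisance = nuisance)
  structure(list(genotypes = g, diversity = div, hl = hl, covariates = cov,
                 faces = faces, params = params),
            class = "sim_cohort")
}
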