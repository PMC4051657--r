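# Independent oracles and small fixture builders used across the test files.
# Everything here is deliberately naive (loops, closed forms, brute force) and
# shares no code path with the package implementation it checks.

# least-squares coefficients via an SVD pseudo-inverse
pinv_coef <- function(x, y) {
  sv <- svd(x)
  pos <- sv$d > max(sv$d) * 1e-12
  as.vector(sv$v[, pos, drop = FALSE] %*%
              ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
}

# mean of a normal(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# random rotation via QR (only used to *generate* test cases / search points)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * k + (1 - cos(theta)) * k %*% k
}

# brute-force minimum of ||a %*% r - b|| over rotations: random search plus
# shrinking local axis-angle refinement (no SVD anywhere)
brute_min_dist <- function(a, b, n_random = 20000L) {
  best_r <- diag(3)
  best <- sqrt(sum((a - b)^2))
  for (i in seq_len(n_random)) {
    r <- random_rotation()
    d <- sqrt(sum((a %*% r - b)^2))
    if (d < best) { best <- d; best_r <- r }
  }
  step <- 0.2
  while (step > 1e-9) {
    improved <- FALSE
    for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      for (s in c(-step, step)) {
        r <- best_r %*% rotation_about(ax, s)
        d <- sqrt(sum((a %*% r - b)^2))
        if (d < best - 1e-15) { best <- d; best_r <- r; improved <- TRUE }
      }
    }
    if (!improved) step <- step / 2
  }
  list(dist = best, rotation = best_r)
}

# exhaustive best ANOVA split: loops over every locus and every
# single-class-vs-rest partition, missing calls to the majority branch
oracle_best_split <- function(g, y) {
  ss <- function(v) sum((v - mean(v))^2)
  best <- list(impr = -Inf)
  for (j in seq_len(ncol(g))) {
    gj <- g[, j]
    lev <- sort(unique(gj[!is.na(gj)]))
    if (length(lev) < 2) next
    cand <- if (length(lev) == 2) lev[1] else lev
    for (lv in cand) {
      obs_left <- !is.na(gj) & gj == lv
      na_left <- sum(obs_left) >= sum(!is.na(gj)) - sum(obs_left)
      left <- obs_left | (is.na(gj) & na_left)
      if (sum(left) == 0 || sum(!left) == 0) next
      impr <- ss(y) - ss(y[left]) - ss(y[!left])
      if (impr > best$impr + 1e-12)
        best <- list(impr = impr, locus = j, level = lv)
    }
  }
  best
}

# independent stepwise interaction pruning built on formula lm()
oracle_stepwise <- function(df, alpha = 0.05) {
  cand <- c("sex:age", "sex:hl", "age:hl")
  repeat {
    fml <- as.formula(paste("y ~ sex + age + hl + cohort",
                            if (length(cand)) paste("+", paste(cand, collapse = " + "))
                            else ""))
    fit <- lm(fml, data = df)
    if (!length(cand)) return(character())
    ct <- summary(fit)$coefficients
    p <- sapply(cand, function(ia) {
      parts <- strsplit(ia, ":")[[1]]
      rows <- grepl(":", rownames(ct)) &
        sapply(rownames(ct), function(r) all(sapply(parts, grepl, x = r)))
      max(ct[rows, 4])
    })
    if (max(p) <= alpha) return(cand)
    cand <- cand[-which.max(p)]
  }
}

# small asymmetric-ish landmark set: template plus controlled perturbations
make_faces <- function(n, asym_scale = 5e-4, sym_scale = 0.01, seed = 1,
                       nuisance = FALSE) {
  set.seed(seed)
  tpl <- face_template()
  bas <- asym_basis(tpl, face_scheme())
  coords <- array(0, dim = c(9, 3, n))
  for (i in seq_len(n)) {
    a <- as.vector(bas$shape %*% rnorm(ncol(bas$shape), 0, asym_scale))
    s <- as.vector(bas$sym %*% rnorm(ncol(bas$sym), 0, sym_scale))
    cfg <- tpl + matrix(s, 9, 3) + matrix(a, 9, 3) / 2
    if (nuisance)
      cfg <- runif(1, 0.8, 1.2) * cfg %*% random_rotation() +
        rep(rnorm(3, 0, 0.3), each = 9)
    coords[, , i] <- cfg
  }
  landmark_array(coords)
}

# genotype fixture with controllable values
make_genotypes <- function(calls_by_row, loci = NULL) {
  m <- do.call(rbind, calls_by_row)
  ids <- names(calls_by_row)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_along(calls_by_row))
  if (is.null(loci)) loci <- sprintf("snp%02d", seq_len(ncol(m)))
  genotype_matrix(m, individual_ids = ids, locus_ids = loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
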