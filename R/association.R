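#' Build the association design matrix
#'
#' Merges covariates, HL scores and genotype calls by individual id and
#' builds the ordinary-least-squares design: intercept; sex indicator (male
#' vs female reference); age; HL; cohort indicator (each later label vs the
#' first); and, per requested SNP, two treatment-coded genotype indicators
#' (genotype 1 vs 0 and genotype 2 vs 0). Optional pairwise interactions
#' among sex, age and HL can be included. Individuals with any missing
#' required field are dropped (count reported via a message); SNPs with a
#' single observed genotype class, and constant sex/cohort columns, are
#' dropped with a warning.
#'
#' @param covariates a `covariate_table`.
#' @param hl an `hl_scores` table.
#' @param genotypes a [genotype_matrix()].
#' @param snps locus ids (or indices) to include as genotype factors; NULL
#'   includes every locus in `genotypes`.
#' @param interactions character subset of
#'   `c("sex:age", "sex:hl", "age:hl")`.
#' @return Object of class `asym_design`: list with `X` (design matrix),
#'   `data` (merged model frame), `ids`, `vars`, `interactions`, `labels`
#'   (human-readable term names), `n_dropped`.
#' @export
build_design <- function(covariates, hl, genotypes, snps = NULL,
                         interactions = character()) {
  stopifnot(inherits(covariates, "covariate_table"),
            inherits(hl, "hl_scores"), inherits(genotypes, "genotype_matrix"))
  bad <- setdiff(interactions, c("sex:age", "sex:hl", "age:hl"))
  if (length(bad))
    stop_("unsupported interaction(s): ", paste(bad, collapse = ", "))
  if (is.null(snps)) snps <- colnames(genotypes)
  if (is.numeric(snps)) snps <- colnames(genotypes)[snps]
  miss <- setdiff(snps, colnames(genotypes))
  if (length(miss)) stop_("unknown loci: ", paste(miss, collapse = ", "))
  ids <- Reduce(intersect, list(covariates$individual_id, hl$individual_id,
                                rownames(genotypes)))
  if (!length(ids)) stop_("no shared individual ids across inputs")
  df <- data.frame(
    sex = covariates$sex[match(ids, covariates$individual_id)],
    age = covariates$age[match(ids, covariates$individual_id)],
    hl = hl$hl[match(ids, hl$individual_id)],
    cohort = covariates$cohort[match(ids, covariates$individual_id)],
    row.names = ids
  )
  for (s in snps) {
    calls <- unclass(genotypes)[match(ids, rownames(genotypes)), s]
    df[[s]] <- factor(calls, levels = sort(unique(calls[!is.na(calls)])))
  }
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  if (n_dropped)
    message(n_dropped, " individual(s) dropped for missing fields")
  df <- df[cc, , drop = FALSE]
  ids <- ids[cc]
  df <- droplevels(df)
  vars <- c("sex", "age", "hl", "cohort", snps)
  for (v in c("sex", "cohort", snps)) {
    if (nlevels(df[[v]]) < 2L) {
      warn_("term '", v, "' dropped: single observed level")
      vars <- setdiff(vars, v)
      interactions <- interactions[!grepl(paste0("\\b", v, "\\b"), interactions)]
    }
  }
  fml <- stats::as.formula(paste(
    "~", paste(c(vapply(vars, function(v) sprintf("`%s`", v), character(1L)),
                 interactions), collapse = " + ")))
  x <- stats::model.matrix(fml, data = df)
  colnames(x) <- gsub("`", "", colnames(x))
  structure(
    list(X = x, data = df, ids = ids, vars = vars,
         interactions = interactions, snps = intersect(snps, vars),
         labels = design_labels(colnames(x), df),
         n_dropped = n_dropped),
    class = "asym_design"
  )
}

## pretty term names: "sexmale" -> "sex male (ref. female)",
## "rs00011" -> "rs0001 1 (ref. 0)"
design_labels <- function(cols, df) {
  out <- cols
  for (v in names(df)) {
    if (!is.factor(df[[v]])) next
    lv <- levels(df[[v]])
    for (l in lv[-1L]) {
      hit <- out == paste0(v, l)
      out[hit] <- sprintf("%s %s (ref. %s)", v, l, lv[1L])
    }
  }
  out
}

## rebuild the design matrix for a subset of interactions (used by pruning)
design_with_interactions <- function(design, interactions) {
  fml <- stats::as.formula(paste(
    "~", paste(c(vapply(design$vars, function(v) sprintf("`%s`", v),
                        character(1L)), interactions), collapse = " + ")))
  x <- stats::model.matrix(fml, data = design$data)
  colnames(x) <- gsub("`", "", colnames(x))
  x
}

#' Ordinary least-squares fit with t-based inference
#'
#' Fits the response on a design matrix by ordinary least squares and reports
#' per-term estimates, standard errors (from the unbiased residual variance),
#' t values and two-sided p values referred to the t distribution with the
#' residual degrees of freedom. Rank-deficient designs are an error naming
#' the collinear columns.
#'
#' @param design an [build_design()] object or a plain design matrix
#'   (including the intercept column).
#' @param response numeric response vector, finite, one value per design row.
#' @return Object of class `asym_lm`: list with `coefficients` (data frame:
#'   term, label, estimate, std_error, t_value, p_value), `n`, `residual_df`,
#'   `r_squared`, `sigma`, `fitted`, `residuals`.
#' @export
ols_fit <- function(design, response) {
  x <- if (inherits(design, "asym_design")) design$X else design
  labels <- if (inherits(design, "asym_design")) design$labels else colnames(x)
  stopifnot(is.matrix(x), is.numeric(response))
  if (!all(is.finite(response))) stop_("non-finite response values")
  if (nrow(x) != length(response))
    stop_("response length does not match design rows")
  if (nrow(x) <= ncol(x))
    stop_("need more observations than design columns")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop_("rank-deficient design; collinear term(s): ",
          paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(response ~ 0 + x)
  sm <- summary(fit)
  ct <- sm$coefficients
  rownames(ct) <- sub("^x", "", rownames(ct))
  has_icpt <- "(Intercept)" %in% colnames(x)
  tss <- if (has_icpt) sum((response - mean(response))^2) else sum(response^2)
  structure(
    list(coefficients = data.frame(
           term = rownames(ct),
           label = labels[match(rownames(ct), colnames(x))],
           estimate = ct[, 1L], std_error = ct[, 2L],
           t_value = ct[, 3L], p_value = ct[, 4L],
           row.names = NULL, stringsAsFactors = FALSE),
         n = nrow(x), residual_df = fit$df.residual,
         r_squared = 1 - sum(stats::residuals(fit)^2) / tss,
         sigma = sm$sigma,
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit))),
    class = "asym_lm"
  )
}

#' @export
print.asym_lm <- function(x, digits = 4, ...) {
  cat("OLS fit: n =", x$n, " residual df =", x$residual_df,
      " R^2 =", signif(x$r_squared, 3), "\n")
  ct <- x$coefficients
  ct$estimate <- signif(ct$estimate, digits)
  ct$std_error <- signif(ct$std_error, digits)
  ct$t_value <- signif(ct$t_value, digits)
  ct$p_value <- signif(ct$p_value, digits)
  print(ct[, c("label", "estimate", "std_error", "t_value", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.asym_lm <- function(object, ...) object

#' @export
coef.asym_lm <- function(object, ...)
  stats::setNames(object$coefficients$estimate, object$coefficients$term)

#' @export
residuals.asym_lm <- function(object, ...) object$residuals

#' @export
predict.asym_lm <- function(object, newdesign = NULL, ...) {
  if (is.null(newdesign)) return(object$fitted)
  x <- if (inherits(newdesign, "asym_design")) newdesign$X else newdesign
  as.vector(x[, object$coefficients$term, drop = FALSE] %*%
              object$coefficients$estimate)
}

#' Stepwise removal of non-significant interactions
#'
#' Starts from the model with all requested pairwise interactions among sex,
#' age and HL, then iteratively refits, removing the interaction with the
#' largest p value whenever it exceeds `alpha`, until every remaining
#' interaction is significant or none remain. Base terms are always retained.
#'
#' @param design an [build_design()] object (built with the candidate
#'   interactions; if built without, all three are used as candidates).
#' @param response numeric response vector.
#' @param alpha retention threshold. Default 0.05.
#' @return List of class `pruned_fit`: `fit` (final [ols_fit()]),
#'   `removed` (data frame of removed terms with their p values, in removal
#'   order), `kept` (remaining interactions), `alpha`.
#' @export
prune_interactions <- function(design, response, alpha = 0.05) {
  stopifnot(inherits(design, "asym_design"))
  current <- design$interactions
  if (!length(current))
    current <- intersect(c("sex:age", "sex:hl", "age:hl"),
                         combn_interactions(design$vars))
  removed <- data.frame(term = character(), p_value = numeric(),
                        step = integer(), stringsAsFactors = FALSE)
  repeat {
    x <- design_with_interactions(design, current)
    fit <- ols_fit(structure(list(X = x, labels = design_labels(colnames(x),
                                                                design$data)),
                             class = "asym_design"), response)
    if (!length(current)) break
    ct <- fit$coefficients
    ia_rows <- grepl(":", ct$term, fixed = TRUE)
    # one design column per candidate (sex is 2-level, age/hl numeric)
    pvals <- vapply(current, function(ia) {
      parts <- strsplit(ia, ":", fixed = TRUE)[[1L]]
      hit <- ia_rows & vapply(ct$term, function(t)
        all(vapply(parts, function(p) grepl(p, t, fixed = TRUE), logical(1L))),
        logical(1L))
      max(ct$p_value[hit])
    }, numeric(1L))
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    removed <- rbind(removed, data.frame(term = current[worst],
                                         p_value = pvals[worst],
                                         step = nrow(removed) + 1L,
                                         stringsAsFactors = FALSE))
    current <- current[-worst]
  }
  structure(list(fit = fit, removed = removed, kept = current, alpha = alpha),
            class = "pruned_fit")
}

combn_interactions <- function(vars) {
  base <- intersect(c("sex", "age", "hl"), vars)
  if (length(base) < 2L) return(character())
  apply(utils::combn(base, 2L), 2L, paste, collapse = ":")
}

#' @export
print.pruned_fit <- function(x, ...) {
  cat("Stepwise interaction pruning (alpha =", x$alpha, ")\n")
  if (nrow(x$removed))
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  removed %s (p = %.4g)\n", x$removed$term[i],
                  x$removed$p_value[i]))
  else cat("  nothing removed\n")
  if (length(x$kept)) cat("  retained:", paste(x$kept, collapse = ", "), "\n")
  print(x$fit)
  invisible(x)
}

#' Flag terms reaching genome-wide significance
#'
#' @param fit an [ols_fit()] result.
#' @param threshold p-value threshold; default 1e-8.
#' @return Named logical vector (TRUE where `p <= threshold`).
#' @export
genomewide_flag <- function(fit, threshold = 1e-8) {
  stopifnot(inherits(fit, "asym_lm"))
  stats::setNames(fit$coefficients$p_value <= threshold, fit$coefficients$term)
}
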