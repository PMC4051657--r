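#' Genotype matrix constructor
#'
#' Individuals x biallelic loci, ALT-allele-count coded: 0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, NA = missing.
#'
#' @param calls n x L integer matrix with values in \{0, 1, 2, NA\}.
#' @param individual_ids,locus_ids row/column ids (default from dimnames or
#'   generated).
#' @return Integer matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individual_ids = NULL, locus_ids = NULL) {
  stopifnot(is.matrix(calls))
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stop_("genotype calls outside {0, 1, 2, NA}: e.g. value ",
          calls[which(bad)[1L]], " at position ", which(bad)[1L])
  individual_ids <- as.character(individual_ids %||% rownames(calls) %||%
                                   sprintf("ind%04d", seq_len(nrow(calls))))
  locus_ids <- as.character(locus_ids %||% colnames(calls) %||%
                              sprintf("snp%03d", seq_len(ncol(calls))))
  if (length(individual_ids) != nrow(calls) || length(locus_ids) != ncol(calls))
    stop_("id lengths do not match matrix dimensions")
  dimnames(calls) <- list(individual_ids, locus_ids)
  structure(calls, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x), "individuals x", ncol(x), "loci;",
      sum(is.na(x)), "missing calls\n")
  invisible(x)
}

#' Per-locus allele frequencies and expected heterozygosity
#'
#' Computes the ALT allele frequency of each biallelic locus from the
#' non-missing calls, `p = sum(calls) / (2 * n_called)`, and its expected
#' heterozygosity `E = 2 p (1 - p)` (optionally with the small-sample
#' correction `2n/(2n - 1)`). Loci with every call missing are excluded with
#' a warning.
#'
#' @param g a [genotype_matrix()].
#' @param unbiased apply the `2n/(2n-1)` small-sample correction to E?
#'   Default FALSE (plug-in estimator).
#' @return Object of class `locus_diversity`: data frame with columns
#'   `locus_id`, `alt_freq`, `expected_het`, `n_called`.
#' @export
allele_frequencies <- function(g, unbiased = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_called <- colSums(!is.na(g))
  if (any(n_called == 0L)) {
    warn_(sum(n_called == 0L), " locus/loci with all calls missing excluded: ",
          paste(colnames(g)[n_called == 0L], collapse = ", "))
    g <- g[, n_called > 0L, drop = FALSE]
    g <- genotype_matrix(unclass(g))
    n_called <- n_called[n_called > 0L]
  }
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)
  e <- 2 * p * (1 - p)
  if (unbiased) e <- e * (2 * n_called) / (2 * n_called - 1)
  structure(
    data.frame(locus_id = colnames(g), alt_freq = unname(p),
               expected_het = unname(e), n_called = unname(n_called),
               stringsAsFactors = FALSE),
    class = c("locus_diversity", "data.frame")
  )
}

#' Homozygosity-by-loci (HL) index
#'
#' Per-individual homozygosity weighted by locus variability:
#' `HL = sum(E_h) / (sum(E_h) + sum(E_j))`, where `E_h` are the expected
#' heterozygosities of the loci the individual carries in homozygosis and
#' `E_j` those carried in heterozygosis. HL ranges from 0 (all loci
#' heterozygous) to 1 (all loci homozygous); more variable loci weigh more.
#' Missing calls contribute to neither sum.
#'
#' @param g a [genotype_matrix()].
#' @param div a [locus_diversity] table supplying E per locus; defaults to
#'   frequencies estimated from `g` itself. Loci are matched by id.
#' @return Object of class `hl_scores`: data frame with columns
#'   `individual_id`, `hl`, `n_loci_used`.
#' @export
hl_index <- function(g, div = allele_frequencies(g)) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(div, "locus_diversity"))
  keep <- intersect(colnames(g), div$locus_id)
  if (length(keep) == 0L) stop_("no loci shared between genotypes and diversity table")
  gm <- unclass(g)[, keep, drop = FALSE]
  e <- div$expected_het[match(keep, div$locus_id)]
  hom <- !is.na(gm) & (gm == 0L | gm == 2L)
  het <- !is.na(gm) & gm == 1L
  num <- as.vector(hom %*% e)
  den <- num + as.vector(het %*% e)
  n_used <- rowSums(!is.na(gm))
  hl <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(hl))
    warn_(sum(is.na(hl)), " individual(s) with undefined HL ",
          "(no usable polymorphic loci)")
  structure(
    data.frame(individual_id = rownames(gm), hl = hl, n_loci_used = n_used,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("hl_scores", "data.frame")
  )
}

#' Population summaries of HL
#'
#' Per-group mean, standard error of the mean, and decile percentiles
#' (10th through 90th) of the HL distribution. Percentiles use linear
#' interpolation between closest order statistics.
#'
#' @param hl an [hl_scores] table.
#' @param groups optional vector of group labels (one per individual);
#'   default puts everyone in one group, `"all"`.
#' @return Data frame with one row per group: `group`, `n`, `mean_hl`,
#'   `se_hl`, `p10` ... `p90`.
#' @export
hl_summary <- function(hl, groups = NULL) {
  stopifnot(inherits(hl, "hl_scores"))
  groups <- as.character(groups %||% rep("all", nrow(hl)))
  stopifnot(length(groups) == nrow(hl))
  keep <- !is.na(hl$hl)
  empty <- setdiff(unique(groups), unique(groups[keep]))
  if (length(empty))
    warn_("group(s) with no usable HL values excluded: ",
          paste(empty, collapse = ", "))
  out <- lapply(split(hl$hl[keep], groups[keep]), function(v) {
    q <- stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1), type = 7,
                         names = FALSE)
    c(n = length(v), mean_hl = mean(v),
      se_hl = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      stats::setNames(q, paste0("p", seq(10, 90, 10))))
  })
  res <- data.frame(group = names(out), do.call(rbind, out),
                    stringsAsFactors = FALSE, row.names = NULL)
  res
}
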