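#' Run the full asymmetry--heterozygosity association pipeline
#'
#' Orchestrates every stage: obtain data (either read from files or simulate
#' a synthetic cohort), score asymmetry (TA/FA/DA) by the object-symmetry
#' Procrustes decomposition, compute allele frequencies and HL, fit the
#' FA and TA association models (OLS on sex, age, HL, cohort and the
#' configured SNPs, with stepwise interaction pruning), grow the ANOVA
#' regression trees over all loci, and write a report bundle.
#'
#' The configuration is a nested list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{simulate}{arguments for [sim_params()] -- mutually exclusive with
#'     `inputs`.}
#'   \item{inputs}{`landmarks`, `genotypes`, `covariates` paths plus
#'     `landmarks_format` ("long"/"tps") and `genotypes_format`
#'     ("table"/"vcf").}
#'   \item{model}{`snps` (loci for the OLS model; default the first five),
#'     `alpha` (interaction retention, default 0.05), `gw_threshold`
#'     (genome-wide significance, default 1e-8).}
#'   \item{tree}{`cp`, `minsplit`, `max_depth` for [anova_tree()].}
#'   \item{seed}{integer RNG seed, recorded in all outputs.}
#' }
#'
#' @param config list or path to a YAML config file.
#' @param out_dir optional output directory; when given, all artifact tables,
#'   tree dumps and the text report are written there.
#' @param seed overrides `config$seed`.
#' @return (Invisibly) a list bundle: `scores`, `diversity`, `hl`,
#'   `hl_summary`, `fit_fa`, `fit_ta`, `tree_fa`, `tree_ta`, `flags_fa`,
#'   `flags_ta`, `report` (character vector), `seed`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- seed %||% config$seed
  if (!is.null(config$simulate) && !is.null(config$inputs))
    stop_("config supplies both a simulation block and input paths; ",
          "use exactly one per data kind")
  if (is.null(config$simulate) && is.null(config$inputs))
    stop_("config must supply either a 'simulate' or an 'inputs' block")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg_hash <- config_hash(config)

  if (!is.null(config$simulate)) {
    params <- do.call(sim_params, config$simulate)
    cohort <- simulate_cohort(params)
    landmarks <- cohort$faces$landmarks
    genotypes <- cohort$genotypes
    covariates <- cohort$covariates
    scheme <- params$scheme
  } else {
    inp <- config$inputs
    for (need in c("landmarks", "genotypes", "covariates"))
      if (is.null(inp[[need]])) stop_("inputs block missing '", need, "'")
    landmarks <- read_landmarks(inp$landmarks,
                                format = inp$landmarks_format %||% "long")
    genotypes <- read_genotypes(inp$genotypes,
                                format = inp$genotypes_format %||% "table")
    covariates <- read_covariates(inp$covariates)
    scheme <- face_scheme()
  }

  ids <- list(landmarks = dimnames(landmarks)[[3L]],
              genotypes = rownames(genotypes),
              covariates = covariates$individual_id)
  shared <- Reduce(intersect, ids)
  orphans <- unlist(lapply(names(ids), function(k) {
    o <- setdiff(ids[[k]], shared)
    if (length(o)) paste0(k, ": ", paste(utils::head(o, 5L), collapse = ", "),
                          if (length(o) > 5L) ", ..." else "")
  }))
  if (length(orphans))
    stop_("individual ids do not match across inputs; orphans -- ",
          paste(orphans, collapse = "; "))

  scores <- asymmetry_scores(landmarks, scheme)
  div <- allele_frequencies(genotypes)
  n_monomorphic <- sum(div$expected_het == 0)
  hl <- hl_index(genotypes, div)
  hls <- hl_summary(hl, groups = as.character(covariates$cohort))

  model_cfg <- config$model %||% list()
  snps <- model_cfg$snps %||%
    colnames(genotypes)[seq_len(min(5L, ncol(genotypes)))]
  alpha <- model_cfg$alpha %||% 0.05
  gw <- model_cfg$gw_threshold %||% 1e-8
  design <- build_design(covariates, hl, genotypes, snps = snps,
                         interactions = c("sex:age", "sex:hl", "age:hl"))
  resp_fa <- scores$fa[design$ids]
  resp_ta <- scores$ta[design$ids]
  pr_fa <- prune_interactions(design, resp_fa, alpha = alpha)
  pr_ta <- prune_interactions(design, resp_ta, alpha = alpha)

  tree_cfg <- config$tree %||% list()
  tord <- match(design$ids, rownames(genotypes))
  tg <- genotype_matrix(unclass(genotypes)[tord, , drop = FALSE])
  tree_fa <- anova_tree(tg, resp_fa, cp = tree_cfg$cp %||% 0.01,
                        minsplit = tree_cfg$minsplit %||% 20L,
                        max_depth = tree_cfg$max_depth %||% 30L)
  tree_ta <- anova_tree(tg, resp_ta, cp = tree_cfg$cp %||% 0.01,
                        minsplit = tree_cfg$minsplit %||% 20L,
                        max_depth = tree_cfg$max_depth %||% 30L)
  flags_fa <- genomewide_flag(pr_fa$fit, threshold = gw)
  flags_ta <- genomewide_flag(pr_ta$fit, threshold = gw)

  report <- pipeline_report(seed, cfg_hash, length(shared), design, scores,
                            n_monomorphic, pr_fa, pr_ta, tree_fa, tree_ta,
                            flags_fa, flags_ta, alpha, gw, snps)
  bundle <- list(scores = scores, diversity = div, hl = hl, hl_summary = hls,
                 fit_fa = pr_fa, fit_ta = pr_ta,
                 tree_fa = tree_fa, tree_ta = tree_ta,
                 flags_fa = flags_fa, flags_ta = flags_ta,
                 report = report, seed = seed, config_hash = cfg_hash)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

## deterministic hash of the canonicalized config (md5 of its deparse)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config, control = c("all", "digits17")), f)
  unname(tools::md5sum(f))
}

snp_term_rows <- function(fit, snps) {
  vapply(fit$coefficients$term, function(t)
    any(vapply(snps, function(s) startsWith(t, s), logical(1L))), logical(1L))
}

pipeline_report <- function(seed, cfg_hash, n, design, scores, n_monomorphic,
                            pr_fa, pr_ta, tree_fa, tree_ta, flags_fa,
                            flags_ta, alpha, gw, snps) {
  fmt_fit <- function(pr, flags, label) {
    ct <- pr$fit$coefficients
    sig <- ct$label[ct$p_value <= alpha & ct$term != "(Intercept)"]
    snp_rows <- snp_term_rows(pr$fit, snps)
    gw_snps <- ct$label[flags & snp_rows]
    c(sprintf("%s model (n = %d, R^2 = %.4g):", label, pr$fit$n,
              pr$fit$r_squared),
      sprintf("  interactions removed: %s",
              if (nrow(pr$removed)) paste(pr$removed$term, collapse = ", ")
              else "none"),
      sprintf("  terms with p <= %g: %s", alpha,
              if (length(sig)) paste(sig, collapse = "; ") else "none"),
      sprintf("  SNP terms at genome-wide significance (p <= %g): %s", gw,
              if (length(gw_snps)) paste(gw_snps, collapse = "; ") else "none"))
  }
  fmt_tree <- function(tree, label)
    sprintf("%s ANOVA tree: %s", label,
            if (is_root_only(tree)) "root-only (no SNP identified)"
            else sprintf("%d node(s); first split on %s",
                         length(tree$nodes), tree$nodes[[1L]]$locus))
  c("facesym pipeline report",
    sprintf("seed: %s", seed %||% "none"),
    sprintf("config hash: %s", cfg_hash),
    sprintf("individuals analyzed: %d (%d dropped for missing fields)",
            n, design$n_dropped),
    sprintf("monomorphic loci: %d", n_monomorphic),
    sprintf("mean TA = %.6g, mean FA = %.6g, DA magnitude = %.6g",
            mean(scores$ta), mean(scores$fa), scores$da_magnitude),
    fmt_fit(pr_fa, flags_fa, "FA"),
    fmt_fit(pr_ta, flags_ta, "TA"),
    fmt_tree(tree_fa, "FA"),
    fmt_tree(tree_ta, "TA"))
}

write_fit_table <- function(pr, path) {
  ct <- pr$fit$coefficients
  utils::write.csv(
    data.frame(term = ct$label, estimate = ct$estimate,
               std_error = ct$std_error, t_value = ct$t_value,
               p_value = ct$p_value, stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_scores(bundle$scores, p("asymmetry_scores.csv"), p("da_vector.csv"))
  utils::write.csv(as.data.frame(bundle$hl), p("hl_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$hl_summary, p("hl_summary.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$diversity), p("locus_diversity.csv"),
                   row.names = FALSE)
  write_fit_table(bundle$fit_fa, p("model_fa.csv"))
  write_fit_table(bundle$fit_ta, p("model_ta.csv"))
  for (resp in c("fa", "ta")) {
    tree <- bundle[[paste0("tree_", resp)]]
    writeLines(utils::capture.output(print(tree)),
               p(sprintf("tree_%s.txt", resp)))
    jsonlite::write_json(tree_table(tree), p(sprintf("tree_%s.json", resp)),
                         dataframe = "rows", na = "null", digits = NA)
  }
  writeLines(bundle$report, p("report.txt"))
  invisible(out_dir)
}
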