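#' ANOVA regression tree over genotype predictors
#'
#' Recursive binary partitioning of a continuous response on many categorical
#' genotype predictors (CART with an ANOVA split criterion). At every node,
#' each locus contributes the nonredundant binary partitions of its observed
#' genotype classes \{0, 1, 2\} (each single class vs the rest); the (locus,
#' partition) pair maximizing the within-node sum-of-squares reduction is
#' chosen. A split is accepted only if its improvement is at least
#' `cp * SS(root)` and both children hold at least `minsplit / 3`
#' individuals. Individuals missing the split locus follow the majority
#' branch (no surrogate splits); the number routed this way is recorded per
#' node. A root-only tree is a valid result.
#'
#' @param genotypes a [genotype_matrix()] (or plain integer matrix).
#' @param response numeric vector, finite, one value per individual.
#' @param cp complexity parameter: minimum split improvement as a fraction
#'   of the root sum of squares. Default 0.01.
#' @param minsplit minimum node size to attempt a split. Default 20.
#' @param max_depth maximum tree depth. Default 30.
#' @return Object of class `anova_tree`: list with `nodes` (list of node
#'   records), `cp`, `minsplit`, `max_depth`, `ss_root`, `n`.
#' @export
anova_tree <- function(genotypes, response, cp = 0.01, minsplit = 20L,
                       max_depth = 30L) {
  g <- if (inherits(genotypes, "genotype_matrix")) unclass(genotypes)
       else as.matrix(genotypes)
  y <- as.numeric(response)
  if (!all(is.finite(y))) stop_("non-finite response values")
  if (nrow(g) != length(y)) stop_("response length does not match genotypes")
  if (length(y) < minsplit)
    stop_("need at least minsplit (", minsplit, ") individuals")
  loci <- colnames(g) %||% sprintf("locus%03d", seq_len(ncol(g)))
  node_ss <- function(v) sum(v^2) - sum(v)^2 / length(v)
  ss_root <- node_ss(y)
  nodes <- list()
  build <- function(rows, depth) {
    id <- length(nodes) + 1L
    yv <- y[rows]
    rec <- list(id = id, depth = depth, n = length(rows), mean = mean(yv),
                ss = node_ss(yv), leaf = TRUE, locus = NA_character_,
                left_level = NA_integer_, na_left = NA, improvement = NA_real_,
                n_missing_routed = NA_integer_, left_id = NA_integer_,
                right_id = NA_integer_)
    nodes[[id]] <<- rec
    if (length(rows) < minsplit || depth >= max_depth || rec$ss <= 0)
      return(id)
    best <- list(impr = -Inf)
    for (j in seq_len(ncol(g))) {
      gj <- g[rows, j]
      mis <- is.na(gj)
      lev <- sort(unique(gj[!mis]))
      if (length(lev) < 2L) next
      # single-class-vs-rest enumerates all nonredundant binary partitions
      # of <= 3 classes; with 2 classes the complement is redundant
      cand <- if (length(lev) == 2L) lev[1L] else lev
      for (lv in cand) {
        obs_left <- !mis & gj == lv
        na_left <- sum(obs_left) >= sum(!mis) - sum(obs_left)
        left <- obs_left | (mis & na_left)
        nl <- sum(left); nr <- length(rows) - nl
        if (nl == 0L || nr == 0L) next
        yl <- yv[left]; yr <- yv[!left]
        impr <- rec$ss - node_ss(yl) - node_ss(yr)
        if (impr > best$impr + 1e-12) {
          best <- list(impr = impr, j = j, lv = lv, na_left = na_left,
                       left = left, n_missing = sum(mis))
        }
      }
    }
    if (!is.finite(best$impr) || best$impr < cp * ss_root ||
        min(sum(best$left), length(rows) - sum(best$left)) < minsplit / 3)
      return(id)
    rec$leaf <- FALSE
    rec$locus <- loci[best$j]
    rec$locus_j <- best$j
    rec$left_level <- best$lv
    rec$na_left <- best$na_left
    rec$improvement <- best$impr
    rec$n_missing_routed <- best$n_missing
    nodes[[id]] <<- rec
    lid <- build(rows[best$left], depth + 1L)
    rid <- build(rows[!best$left], depth + 1L)
    nodes[[id]]$left_id <<- lid
    nodes[[id]]$right_id <<- rid
    id
  }
  build(seq_along(y), 0L)
  structure(list(nodes = nodes, cp = cp, minsplit = minsplit,
                 max_depth = max_depth, ss_root = ss_root, n = length(y)),
            class = "anova_tree")
}

#' @export
print.anova_tree <- function(x, digits = 4, ...) {
  cat("ANOVA regression tree: n =", x$n, " cp =", x$cp,
      " nodes =", length(x$nodes), "\n")
  show <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$leaf) {
      cat(sprintf("%s* leaf: n = %d, mean = %s\n", pad, nd$n,
                  signif(nd$mean, digits)))
    } else {
      cat(sprintf("%s%s = {%s} vs rest: n = %d, improvement = %s%s\n",
                  pad, nd$locus, nd$left_level, nd$n,
                  signif(nd$improvement, digits),
                  if (nd$n_missing_routed > 0)
                    sprintf(" (%d missing -> %s)", nd$n_missing_routed,
                            if (nd$na_left) "left" else "right") else ""))
      show(nd$left_id, indent + 1L)
      show(nd$right_id, indent + 1L)
    }
  }
  show(1L, 0L)
  invisible(x)
}

#' @export
predict.anova_tree <- function(object, genotypes, ...) {
  g <- if (inherits(genotypes, "genotype_matrix")) unclass(genotypes)
       else as.matrix(genotypes)
  vapply(seq_len(nrow(g)), function(i) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (nd$leaf) return(nd$mean)
      call <- if (!is.null(colnames(g)) && nd$locus %in% colnames(g))
        g[i, nd$locus] else g[i, nd$locus_j]
      left <- if (is.na(call)) nd$na_left else call == nd$left_level
      id <- if (left) nd$left_id else nd$right_id
    }
  }, numeric(1L))
}

#' Is a tree root-only (no accepted split)?
#'
#' @param tree an [anova_tree()].
#' @return TRUE if the tree consists of the root node alone.
#' @export
is_root_only <- function(tree) {
  stopifnot(inherits(tree, "anova_tree"))
  length(tree$nodes) == 1L
}

#' Tabulate tree nodes
#'
#' Flattens an [anova_tree()] into one row per node, suitable for writing to
#' a delimited file or JSON.
#'
#' @param tree an [anova_tree()].
#' @return Data frame with one row per node.
#' @export
tree_table <- function(tree) {
  stopifnot(inherits(tree, "anova_tree"))
  do.call(rbind, lapply(tree$nodes, function(nd)
    data.frame(id = nd$id, depth = nd$depth, n = nd$n, mean = nd$mean,
               ss = nd$ss, leaf = nd$leaf, locus = nd$locus,
               left_level = nd$left_level, na_left = nd$na_left,
               improvement = nd$improvement,
               n_missing_routed = nd$n_missing_routed,
               left_id = nd$left_id, right_id = nd$right_id,
               stringsAsFactors = FALSE)))
}
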