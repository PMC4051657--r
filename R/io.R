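#' Read landmark configurations
#'
#' Two formats are supported. `"long"` is a comma-delimited table with header
#' `individual_id, landmark, x, y, z` and one row per landmark. `"tps"` is
#' the morphometric TPS format with 3D points: records of the form
#' `LM3=<k>` followed by k lines of `x y z` and an `ID=<id>` line.
#'
#' Validation is strict: duplicate (individual, landmark) rows and unknown
#' landmark names are hard errors; individuals missing one or more of the
#' expected landmarks are excluded with a warning reporting the count. TPS
#' records with fewer coordinate lines than declared are a hard error
#' (truncated file).
#'
#' @param path file to read.
#' @param format `"long"` or `"tps"`.
#' @param landmark_names expected landmark set, in canonical order. For TPS
#'   (which stores no names) this supplies the names; rows must be in this
#'   order.
#' @return A [landmark_array()].
#' @export
read_landmarks <- function(path, format = c("long", "tps"),
                           landmark_names = face_landmarks()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: ", path)
  k <- length(landmark_names)
  if (format == "long") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("individual_id", "landmark", "x", "y", "z")
    if (!all(need %in% names(d)))
      stop_("long landmark table must have columns: ", paste(need, collapse = ", "))
    unknown <- setdiff(unique(d$landmark), landmark_names)
    if (length(unknown))
      stop_("unknown landmark name(s): ", paste(unknown, collapse = ", "),
            "; expected: ", paste(landmark_names, collapse = ", "))
    if (anyDuplicated(d[c("individual_id", "landmark")]))
      stop_("duplicate (individual, landmark) rows in ", path)
    ids <- unique(d$individual_id)
    cnt <- table(d$individual_id)
    complete <- names(cnt)[cnt == k]
    dropped <- setdiff(ids, complete)
    if (length(dropped))
      warn_(length(dropped), " individual(s) excluded for missing landmarks: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
    keep <- ids[ids %in% complete]           # preserve file order
    if (!length(keep)) stop_("no complete configurations in ", path)
    coords <- array(NA_real_, dim = c(k, 3L, length(keep)))
    row_i <- match(d$landmark, landmark_names)
    col_i <- match(d$individual_id, keep)
    ok <- !is.na(col_i)
    for (j in 1:3)
      coords[cbind(row_i[ok], j, col_i[ok])] <- d[[c("x", "y", "z")[j]]][ok]
    return(landmark_array(coords, ids = keep, landmark_names = landmark_names))
  }
  # TPS
  lines <- readLines(path)
  recs <- list(); ids <- character()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^LM3?=", ln, ignore.case = TRUE)) {
      m <- as.integer(sub("^LM3?=", "", ln, ignore.case = TRUE))
      if (i + m > length(lines))
        stop_("truncated TPS record at line ", i, ": ", m,
              " points declared but file ends early")
      block <- lines[(i + 1L):(i + m)]
      xyz <- t(vapply(strsplit(trimws(block), "\\s+"),
                      function(v) as.numeric(v[1:3]), numeric(3L)))
      if (anyNA(xyz))
        stop_("malformed or truncated coordinate line in TPS record at line ", i)
      i <- i + m + 1L
      id <- sprintf("tps%04d", length(recs) + 1L)
      while (i <= length(lines) && grepl("=", lines[i], fixed = TRUE) &&
             !grepl("^LM", trimws(lines[i]), ignore.case = TRUE)) {
        if (grepl("^ID=", trimws(lines[i]), ignore.case = TRUE))
          id <- sub("^ID=", "", trimws(lines[i]), ignore.case = TRUE)
        i <- i + 1L
      }
      if (nrow(xyz) != k) {
        warn_("TPS record ", id, " has ", nrow(xyz), " landmarks, expected ",
              k, "; excluded")
      } else {
        recs[[length(recs) + 1L]] <- xyz
        ids <- c(ids, id)
      }
    } else i <- i + 1L
  }
  if (!length(recs)) stop_("no usable TPS records in ", path)
  landmark_array(recs, ids = ids, landmark_names = landmark_names)
}

#' Write landmark configurations
#'
#' @param x a [landmark_array()].
#' @param path output file.
#' @param format `"long"` or `"tps"` (see [read_landmarks()]).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path, format = c("long", "tps")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "landmark_array"))
  n <- n_individuals(x); k <- dim(x)[1L]
  if (format == "long") {
    d <- data.frame(
      individual_id = rep(dimnames(x)[[3L]], each = k),
      landmark = rep(dimnames(x)[[1L]], n),
      x = as.vector(vapply(seq_len(n), function(i) unclass(x)[, 1L, i], numeric(k))),
      y = as.vector(vapply(seq_len(n), function(i) unclass(x)[, 2L, i], numeric(k))),
      z = as.vector(vapply(seq_len(n), function(i) unclass(x)[, 3L, i], numeric(k))),
      stringsAsFactors = FALSE)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(n)) {
      writeLines(sprintf("LM3=%d", k), con)
      m <- config_of(x, i)
      writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17),
                                                collapse = " ")), con)
      writeLines(sprintf("ID=%s", dimnames(x)[[3L]][i]), con)
    }
  }
  invisible(path)
}

#' Read a genotype matrix
#'
#' `"table"` format is a comma-delimited table: first column
#' `individual_id`, remaining columns one locus each, values in
#' \{0, 1, 2, NA\} (ALT allele counts). `"vcf"` reads a VCF v4.x file:
#' biallelic SNP records become loci (ALT allele count per diploid genotype);
#' `./.` and half-calls become missing; multi-allelic records are skipped
#' with a warning; non-diploid genotypes are a hard error naming the record.
#'
#' @param path file to read.
#' @param format `"table"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("table", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: ", path)
  if (format == "table") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(d)[1L] != "individual_id")
      stop_("genotype table must have 'individual_id' as its first column")
    calls <- as.matrix(d[-1L])
    bad <- !is.na(calls) & !(calls %in% 0:2)
    if (any(bad))
      stop_("genotype value outside {0, 1, 2, NA} at row ",
            which(bad, arr.ind = TRUE)[1L, 1L], ", locus ",
            colnames(calls)[which(bad, arr.ind = TRUE)[1L, 2L]])
    return(genotype_matrix(calls, individual_ids = d$individual_id,
                           locus_ids = colnames(calls)))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))          # single-record files drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warn_(sum(multi), " multi-allelic record(s) skipped: ",
          paste(utils::head(fix[multi, "ID"], 5L), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  keep <- which(!multi)
  calls <- matrix(NA_integer_, ncol(gt), length(keep),
                  dimnames = list(colnames(gt), ids[keep]))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    alleles <- strsplit(gt[j, ], "[/|]")
    nal <- lengths(alleles)
    nondip <- nal != 2L & !is.na(gt[j, ])
    if (any(nondip))
      stop_("non-diploid genotype in record ", ids[j], " (sample ",
            colnames(gt)[which(nondip)[1L]], ")")
    calls[, jj] <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".") || any(is.na(a))) NA_integer_
      else sum(a == "1")
    }, integer(1L))
  }
  genotype_matrix(calls)
}

#' Write a genotype matrix as a delimited table
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- data.frame(individual_id = rownames(g), unclass(g),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' Comma-delimited with header; required columns `individual_id`, `age`,
#' `sex` (female/male), `cohort`.
#'
#' @param path file to read.
#' @return Data frame of class `covariate_table`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "age", "sex", "cohort")
  if (!all(need %in% names(d)))
    stop_("covariate table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$individual_id)) stop_("duplicate individual ids")
  if (!all(is.finite(d$age)) || any(d$age <= 0))
    stop_("ages must be finite and positive")
  if (!all(d$sex %in% c("female", "male")))
    stop_("sex must be 'female' or 'male'")
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$cohort <- factor(d$cohort)
  structure(d, class = c("covariate_table", "data.frame"))
}

#' Write a covariate table
#'
#' @param x a `covariate_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write asymmetry scores and the DA vector
#'
#' Scores go to a comma-delimited table `individual_id, ta, fa`; the DA
#' vector (if `da_path` is given) to a k x 3 labeled table.
#'
#' @param scores an [asymmetry_scores()] object.
#' @param path scores output file.
#' @param da_path optional DA-vector output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, da_path = NULL) {
  stopifnot(inherits(scores, "asymmetry_scores"))
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  if (!is.null(da_path)) {
    da <- data.frame(landmark = rownames(scores$da_vector), scores$da_vector,
                     stringsAsFactors = FALSE)
    utils::write.csv(da, da_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
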