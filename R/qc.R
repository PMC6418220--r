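#' Merge strand-level counts into methylation proportions
#'
#' The methylation value at a CpG is the pooled (forward + reverse)
#' methylated read count over the pooled total read count — never the mean
#' of the two per-strand ratios. Entries where both strands are covered and
#' the per-strand methylation ratios disagree by more than
#' `max_strand_diff` are set to missing; the strand-concordance test is
#' skipped when either strand has zero coverage.
#'
#' @param counts a `strand_counts` object (see
#'   [simulate_methylation_counts()]) or a list with integer matrices
#'   `meth_fwd`, `total_fwd`, `meth_rev`, `total_rev` and a `cpgs` table.
#' @param max_strand_diff maximum tolerated absolute difference between
#'   per-strand methylation proportions (default 0.20).
#' @return object of class `meth_matrix`: list with `m` (proportions, NA
#'   where missing), `coverage` (total reads, NA where missing), `cpgs`,
#'   `samples`.
#' @export
merge_strands <- function(counts, max_strand_diff = 0.20) {
  for (f in c("meth_fwd", "total_fwd", "meth_rev", "total_rev")) {
    stop_if_not(!is.null(counts[[f]]), sprintf("counts lacks %s", f))
    stop_if_not(all(counts[[f]] >= 0, na.rm = TRUE),
                "negative read counts are invalid")
  }
  stop_if_not(all(counts$meth_fwd <= counts$total_fwd, na.rm = TRUE) &&
                all(counts$meth_rev <= counts$total_rev, na.rm = TRUE),
              "methylated reads exceed total reads on a strand")
  tot <- counts$total_fwd + counts$total_rev
  meth <- counts$meth_fwd + counts$meth_rev
  m <- meth / ifelse(tot > 0, tot, NA)
  both <- counts$total_fwd > 0 & counts$total_rev > 0
  pf <- counts$meth_fwd / ifelse(counts$total_fwd > 0, counts$total_fwd, NA)
  pr <- counts$meth_rev / ifelse(counts$total_rev > 0, counts$total_rev, NA)
  bad <- both & abs(pf - pr) > max_strand_diff
  bad[is.na(bad)] <- FALSE
  m[bad] <- NA
  cov <- tot
  cov[tot == 0 | bad] <- NA
  structure(
    list(m = m, coverage = cov, cpgs = counts$cpgs,
         samples = counts$samples %||% colnames(m)),
    class = "meth_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mask entries below a minimum read depth
#'
#' Entries with fewer than `min_reads` total reads become missing
#' (the boundary is inclusive: depth exactly `min_reads` is kept).
#'
#' @param mat a `meth_matrix`.
#' @param min_reads minimum total read count (default 5).
#' @return the filtered `meth_matrix`.
#' @export
apply_min_coverage <- function(mat, min_reads = 5) {
  stop_if_not(is_count(min_reads), "min_reads must be a count")
  drop <- !is.na(mat$coverage) & mat$coverage < min_reads
  mat$m[drop] <- NA
  mat$coverage[drop] <- NA
  mat
}

#' Site-level filters: coverage breadth and variability
#'
#' Keeps CpGs covered in at least `min_individuals` samples for which
#' strictly more than `min_variable_frac` of the covered samples have a
#' methylation proportion strictly between 0 and 1. Ties at the variable
#' fraction fail (the criterion is "more than").
#'
#' @param mat a `meth_matrix` (after entry-level filters).
#' @param min_individuals minimum number of covered samples (the
#'   discovery-style default is 100; use 50 for small cohorts).
#' @param min_variable_frac minimum fraction of covered samples with
#'   intermediate methylation (default 0.10, strict).
#' @return list with `mat` (rows restricted to kept CpGs) and `report`, a
#'   per-CpG `data.frame` with `cpg_id`, `n_covered`, `n_variable`,
#'   `pass_coverage`, `pass_variable`, `pass`, `reason`.
#' @export
filter_sites <- function(mat, min_individuals = 100, min_variable_frac = 0.10) {
  stop_if_not(min_individuals > 0 && min_variable_frac >= 0,
              "thresholds must be positive")
  n_samples <- ncol(mat$m)
  if (min_individuals > n_samples) {
    stop(sprintf(
      "min_individuals (%d) exceeds the number of samples (%d)",
      min_individuals, n_samples), call. = FALSE)
  }
  n_cov <- rowSums(!is.na(mat$m))
  n_var <- rowSums(mat$m > 0 & mat$m < 1, na.rm = TRUE)
  pass_cov <- n_cov >= min_individuals
  pass_var <- n_cov > 0 & n_var / pmax(n_cov, 1L) > min_variable_frac
  pass <- pass_cov & pass_var
  reason <- ifelse(pass, "",
            ifelse(!pass_cov, "coverage", "invariable"))
  report <- data.frame(
    cpg_id = mat$cpgs$cpg_id, n_covered = n_cov, n_variable = n_var,
    pass_coverage = pass_cov, pass_variable = pass_var, pass = pass,
    reason = reason, stringsAsFactors = FALSE
  )
  kept <- mat
  kept$m <- mat$m[pass, , drop = FALSE]
  kept$coverage <- mat$coverage[pass, , drop = FALSE]
  kept$cpgs <- mat$cpgs[pass, , drop = FALSE]
  rownames(kept$cpgs) <- NULL
  list(mat = kept, report = report)
}

#' Classify per-CpG baseline methylation state
#'
#' Labels each CpG by its mean methylation across covered samples:
#' `hypo` below 0.20, `hyper` above 0.80, `intermediate` otherwise.
#' CpGs with no covered samples get `NA`.
#'
#' @param mat a `meth_matrix`.
#' @return character vector of labels, one per CpG.
#' @export
classify_baseline_state <- function(mat) {
  mu <- rowMeans(mat$m, na.rm = TRUE)
  out <- ifelse(is.nan(mu), NA_character_,
         ifelse(mu < 0.20, "hypo",
         ifelse(mu > 0.80, "hyper", "intermediate")))
  names(out) <- mat$cpgs$cpg_id
  out
}

#' Drop CpGs overlapping an exclusion mask
#'
#' Removes CpGs falling inside user-supplied intervals (e.g. SNP or
#' blacklist masks), half-open semantics.
#'
#' @param mat a `meth_matrix`.
#' @param exclude `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return the restricted `meth_matrix`.
#' @export
apply_exclusion <- function(mat, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0) return(mat)
  drop <- in_any_interval(mat$cpgs$pos, exclude$start, exclude$end) &
    mat$cpgs$chrom %in% exclude$chrom
  mat$m <- mat$m[!drop, , drop = FALSE]
  mat$coverage <- mat$coverage[!drop, , drop = FALSE]
  mat$cpgs <- mat$cpgs[!drop, , drop = FALSE]
  rownames(mat$cpgs) <- NULL
  mat
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("Methylation matrix: %d CpGs x %d samples (%.1f%% missing)\n",
              nrow(x$m), ncol(x$m), 100 * mean(is.na(x$m))))
  invisible(x)
}
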