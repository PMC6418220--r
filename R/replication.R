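#' Region-level replication with direction-of-effect classes
#'
#' For each (region, trait) pair present in the discovery set, a region
#' replicates in the same direction if at least one replication CpG in the
#' region passes the per-trait Bonferroni cutoff with the same direction of
#' effect as the discovery region's top CpG (smallest p, ties broken by the
#' leftmost coordinate); the opposite-direction class is analogous. Regions
#' with zero testable replication CpGs are `untestable`.
#'
#' @param discovery `ewas_result`-like records with `element_id` column
#'   (from joining [annotate_cpgs()]), `trait`, `p`, `direction`, `pos`.
#'   Use the corrected p where available.
#' @param replication records of the replication cohort, same columns.
#' @param alpha family-wise level for the Bonferroni cutoff (default 0.05).
#' @param p_col which p-value column to use (default `"p_corrected"`, falls
#'   back to `"p_raw"`).
#' @param denominator `"all"`: the Bonferroni denominator is the number of
#'   replication tests for the trait across all candidate regions (default);
#'   `"per_region"`: the number of tests within the region.
#' @param direction_rule region direction from the `"top"` CpG (default) or
#'   a `"majority"` vote of its CpGs.
#' @return `data.frame` with one row per (region, trait): `element_id`,
#'   `trait`, `discovery_top_cpg`, `discovery_p`, `discovery_direction`,
#'   `replication_top_cpg`, `replication_p`, `n_testable`, `class`.
#' @export
replicate_regions <- function(discovery, replication, alpha = 0.05,
                              p_col = NULL, denominator = c("all", "per_region"),
                              direction_rule = c("top", "majority")) {
  denominator <- match.arg(denominator)
  direction_rule <- match.arg(direction_rule)
  pick_p <- function(d) {
    if (!is.null(p_col)) return(d[[p_col]])
    if ("p_corrected" %in% names(d) && any(!is.na(d$p_corrected))) {
      d$p_corrected
    } else d$p_raw
  }
  disc <- discovery[!is.na(discovery$element_id), , drop = FALSE]
  disc$p_use <- pick_p(disc)
  repl <- replication[!is.na(replication$element_id), , drop = FALSE]
  repl$p_use <- pick_p(repl)
  pairs <- unique(disc[, c("element_id", "trait")])
  stop_if_not(nrow(pairs) > 0, "no discovery region/trait pairs")
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    eid <- pairs$element_id[i]; tr <- pairs$trait[i]
    dd <- disc[disc$element_id == eid & disc$trait == tr, , drop = FALSE]
    if (nrow(dd) == 0 || all(is.na(dd$p_use))) {
      stop(sprintf("region %s has no discovery CpG for trait %s", eid, tr),
           call. = FALSE)
    }
    dd <- dd[order(dd$p_use, dd$pos), , drop = FALSE]
    top <- dd[1, ]
    dir_disc <- if (direction_rule == "top") top$direction else {
      s <- sum(sign(dd$direction), na.rm = TRUE)
      if (s == 0) top$direction else sign(s)
    }
    rr <- repl[repl$element_id == eid & repl$trait == tr &
                 !is.na(repl$p_use), , drop = FALSE]
    n_testable <- nrow(rr)
    if (n_testable == 0) {
      cls <- "untestable"
      rtop_id <- NA_character_; rtop_p <- NA_real_
    } else {
      n_tests <- if (denominator == "all") {
        sum(repl$trait == tr & !is.na(repl$p_use))
      } else n_testable
      cutoff <- bonferroni_threshold(n_tests, alpha)
      rr <- rr[order(rr$p_use, rr$pos), , drop = FALSE]
      rtop_id <- rr$cpg_id[1]; rtop_p <- rr$p_use[1]
      sig_same <- rr$p_use < cutoff & rr$direction == dir_disc
      sig_opp <- rr$p_use < cutoff & rr$direction == -dir_disc
      cls <- if (any(sig_same, na.rm = TRUE)) "replicated_same_direction"
        else if (any(sig_opp, na.rm = TRUE)) "replicated_opposite_direction"
        else "not_replicated"
    }
    out[[i]] <- data.frame(
      element_id = eid, trait = tr,
      discovery_top_cpg = top$cpg_id, discovery_p = top$p_use,
      discovery_direction = dir_disc,
      replication_top_cpg = rtop_id, replication_p = rtop_p,
      n_testable = n_testable, class = cls, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contrast replication rates between two region groups
#'
#' Rates are reported as nearest-integer percent and their ratio rounded
#' half-up to one decimal; the comparison p is an exact binomial test of the
#' group-B replication count under group A's rate.
#'
#' @param k_a,n_a replicated and total regions in group A.
#' @param k_b,n_b replicated and total regions in group B.
#' @return list with `rate_a_pct`, `rate_b_pct` (nearest-int percent),
#'   `rate_a`, `rate_b`, `ratio` (1-decimal), `ratio_raw`, `p_binomial`.
#' @export
replication_rate_contrast <- function(k_a, n_a, k_b, n_b) {
  stop_if_not(n_a > 0 && n_b > 0, "empty region group")
  stop_if_not(k_a <= n_a && k_b <= n_b, "replicated count exceeds group size")
  ra <- k_a / n_a; rb <- k_b / n_b
  ratio_raw <- if (rb > 0) ra / rb else Inf
  list(
    rate_a_pct = round_half_up(100 * ra), rate_b_pct = round_half_up(100 * rb),
    rate_a = ra, rate_b = rb,
    ratio = round_half_up(ratio_raw, 1), ratio_raw = ratio_raw,
    p_binomial = stats::binom.test(k_b, n_b, p = ra)$p.value
  )
}

#' Count replication outcomes per group
#'
#' Convenience tally of a [replicate_regions()] result: replicated (same or
#' opposite direction, per `directions`) over testable regions, optionally
#' within a subset of element ids.
#'
#' @param outcomes result of [replicate_regions()].
#' @param element_ids optional subset of regions.
#' @param directions classes counted as replicated.
#' @return list `k` (replicated regions) and `n` (testable regions),
#'   counting each region once (any trait).
#' @export
tally_replication <- function(outcomes, element_ids = NULL,
                              directions = "replicated_same_direction") {
  d <- outcomes
  if (!is.null(element_ids)) d <- d[d$element_id %in% element_ids, , drop = FALSE]
  testable <- unique(d$element_id[d$class != "untestable"])
  repl <- unique(d$element_id[d$class %in% directions])
  list(k = length(repl), n = length(testable))
}

#' Fine-mapping contrast of sequencing CpGs against array-tagged CpGs
#'
#' For regions with at least two discovery CpGs, one of which overlaps the
#' replication cohort's top CpG position, the region verdict is `refined`
#' iff some non-overlapping discovery CpG has a smaller p than the
#' overlapping one. Discovery CpG positions are additionally classified
#' into positional bands: the LMR midpoint band (`|pos_pct| <= 20`) and the
#' UMR bimodal band (`20 <= |pos_pct| <= 45`).
#'
#' @param discovery annotated discovery records (`element_id`, `cpg_id`,
#'   `pos`, `trait`, p column).
#' @param replication_top named numeric vector or `data.frame`
#'   (`element_id`, `pos`) giving the top replication CpG position per
#'   region.
#' @param elements element table (for positional bands).
#' @param p_col p-value column (default `"p_corrected"` falling back to
#'   `"p_raw"`).
#' @param overlap_tol bp tolerance for "overlapping" the array position
#'   (default 0 = exact).
#' @return `data.frame` per qualifying region: `element_id`, `overlap_cpg`,
#'   `overlap_p`, `best_other_cpg`, `best_other_p`, `refined`,
#'   `best_other_band`; regions failing the precondition are skipped.
#' @export
fine_map_contrast <- function(discovery, replication_top, elements,
                              p_col = NULL, overlap_tol = 0) {
  if (is.data.frame(replication_top)) {
    rt <- stats::setNames(replication_top$pos, replication_top$element_id)
  } else rt <- replication_top
  d <- discovery[!is.na(discovery$element_id), , drop = FALSE]
  d$p_use <- if (!is.null(p_col)) d[[p_col]] else {
    if ("p_corrected" %in% names(d) && any(!is.na(d$p_corrected)))
      d$p_corrected else d$p_raw
  }
  out <- list()
  for (eid in names(rt)) {
    dd <- d[d$element_id == eid & !is.na(d$p_use), , drop = FALSE]
    if (nrow(dd) < 2) next
    ov <- which(abs(dd$pos - rt[[eid]]) <= overlap_tol)
    if (length(ov) == 0) next
    ov <- ov[which.min(dd$p_use[ov])]
    others <- dd[-ov, , drop = FALSE]
    best <- others[order(others$p_use, others$pos), ][1, ]
    ei <- match(eid, elements$id)
    pct <- percent_distance(best$pos, elements$start[ei], elements$end[ei],
                            elements$tss_strand[ei], orient_by_tss = TRUE)
    band <- if (elements$class[ei] == "LMR") {
      if (abs(pct) <= 20) "midpoint" else "outside"
    } else {
      if (abs(pct) >= 20 && abs(pct) <= 45) "bimodal" else "outside"
    }
    out[[eid]] <- data.frame(
      element_id = eid, overlap_cpg = dd$cpg_id[ov], overlap_p = dd$p_use[ov],
      best_other_cpg = best$cpg_id, best_other_p = best$p_use,
      refined = best$p_use < dd$p_use[ov], best_other_band = band,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(element_id = character(), overlap_cpg = character(),
                      overlap_p = numeric(), best_other_cpg = character(),
                      best_other_p = numeric(), refined = logical(),
                      best_other_band = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
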