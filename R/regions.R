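#' Assign CpGs to regulatory elements
#'
#' Interval-overlap assignment under 0-based half-open semantics: a CpG at
#' `pos` belongs to `[start, end)` iff `start <= pos < end`. CpGs outside
#' all elements are labelled background (NA element id). Elements of the
#' same class must be disjoint; overlap raises an error.
#'
#' @param cpgs `data.frame` with `chrom`, `pos` (and optionally `cpg_id`).
#' @param elements element table (see [generate_elements()]).
#' @return `data.frame`: the CpG columns plus `element_id`, `element_class`,
#'   `specificity`.
#' @export
annotate_cpgs <- function(cpgs, elements) {
  o <- order(elements$start)
  el <- elements[o, , drop = FALSE]
  if (nrow(el) > 1) {
    same_class_overlap <- el$end[-nrow(el)] > el$start[-1] &
      el$class[-nrow(el)] == el$class[-1]
    if (any(same_class_overlap)) {
      stop("overlapping elements of the same class: assignment is ambiguous",
           call. = FALSE)
    }
  }
  i <- findInterval(cpgs$pos, el$start)
  hit <- i > 0 & cpgs$pos < el$end[pmax(i, 1L)]
  idx <- ifelse(hit, i, NA_integer_)
  out <- cpgs
  out$element_id <- el$id[idx]
  out$element_class <- el$class[idx]
  out$specificity <- el$specificity[idx]
  out
}

#' Percent distance of a CpG from its element midpoint
#'
#' `pos_pct = (pos - midpoint) / length * 100` with the midpoint taken as
#' the real-valued `(start + end) / 2` (no rounding, so the statistic is
#' exactly antisymmetric about the midpoint). When `orient_by_tss` is on
#' and the element's TSS strand is `-`, the sign is flipped so that
#' positive values always point into the gene body.
#'
#' @param pos CpG positions (bp).
#' @param start,end element bounds (0-based half-open); vectors recycled
#'   against `pos`.
#' @param tss_strand `"+"`/`"-"`/NA per element.
#' @param orient_by_tss flip signs on minus-strand elements.
#' @return numeric vector of signed percent distances; inside-element CpGs
#'   satisfy `|pos_pct| <= 50`.
#' @export
percent_distance <- function(pos, start, end, tss_strand = NA,
                             orient_by_tss = FALSE) {
  len <- end - start
  stop_if_not(all(len > 0), "zero-length element")
  mid <- (start + end) / 2
  pct <- (pos - mid) / len * 100
  if (orient_by_tss) {
    flip <- !is.na(tss_strand) & tss_strand == "-"
    pct <- ifelse(flip, -pct, pct)
  }
  pct
}

#' Positional profile of CpGs within elements
#'
#' Computes the signed percent distance from the element midpoint for every
#' (optionally subset) CpG assigned to an element. The LMR profile uses all
#' qualifying enhancers; the UMR profile is restricted to promoters whose
#' annotated TSS lies inside the element and within `umr_tss_window` bp of
#' the element midpoint, excluding bivalently oriented UMRs, with gene
#' orientation taken into account (minus-strand sign flip).
#'
#' @param annotated output of [annotate_cpgs()].
#' @param elements element table.
#' @param subset optional character vector of CpG ids to profile (e.g. the
#'   significant lipid-CpGs); default all.
#' @param umr_tss_window TSS window in bp (default 1500).
#' @return `data.frame` with `cpg_id`, `element_id`, `element_class`,
#'   `pos_pct`.
#' @export
positional_profile <- function(annotated, elements, subset = NULL,
                               umr_tss_window = 1500) {
  keep <- !is.na(annotated$element_id)
  if (!is.null(subset)) keep <- keep & annotated$cpg_id %in% subset
  d <- annotated[keep, , drop = FALSE]
  ei <- match(d$element_id, elements$id)
  el <- elements[ei, , drop = FALSE]
  umr_ok <- rep(TRUE, nrow(d))
  is_umr <- el$class == "UMR"
  mid <- (el$start + el$end) / 2
  umr_ok[is_umr] <- !is.na(el$tss[is_umr]) &
    el$tss[is_umr] >= el$start[is_umr] & el$tss[is_umr] < el$end[is_umr] &
    abs(el$tss[is_umr] - mid[is_umr]) <= umr_tss_window &
    !el$bivalent[is_umr]
  d <- d[umr_ok, , drop = FALSE]
  el <- el[umr_ok, , drop = FALSE]
  pct <- percent_distance(d$pos, el$start, el$end, el$tss_strand,
                          orient_by_tss = TRUE)
  data.frame(cpg_id = d$cpg_id, element_id = d$element_id,
             element_class = el$class, pos_pct = pct,
             stringsAsFactors = FALSE)
}

#' Plot positional densities of CpGs within elements
#'
#' Density of signed percent distances from the element midpoint, one panel
#' per element class, optionally overlaying a foreground subset (e.g.
#' lipid-CpGs) on the background of all CpGs.
#'
#' @param profile output of [positional_profile()] (background).
#' @param foreground optional second profile drawn on top.
#' @param main title.
#' @return invisibly, NULL. Draws on the active device.
#' @export
plot_positional_profile <- function(profile, foreground = NULL,
                                    main = "CpG positional profile") {
  classes <- intersect(c("LMR", "UMR"), unique(profile$element_class))
  old <- graphics::par(mfrow = c(1, max(length(classes), 1)))
  on.exit(graphics::par(old))
  for (cl in classes) {
    bg <- profile$pos_pct[profile$element_class == cl]
    dbg <- stats::density(bg, from = -50, to = 50)
    graphics::plot(dbg, main = sprintf("%s (%s)", main, cl),
                   xlab = "% distance from midpoint", col = "grey40")
    if (!is.null(foreground)) {
      fg <- foreground$pos_pct[foreground$element_class == cl]
      if (length(fg) > 1) {
        graphics::lines(stats::density(fg, from = -50, to = 50),
                        col = "firebrick")
      }
    }
  }
  invisible(NULL)
}

#' Fisher enrichment of a foreground proportion over a background
#'
#' Tests `a` of `b` foreground against `c` of `d` background with a
#' two-sided Fisher exact p computed by hypergeometric enumeration (the sum
#' of probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table). The fold change
#' `(a/b) / (c/d)` is reported rounded half-up to one decimal, the printed
#' precision used for such contrasts.
#'
#' @param a,b foreground successes and size (`a <= b`).
#' @param c,d background successes and size (`c <= d`).
#' @return list with `counts`, `proportion_fg`, `proportion_bg`, `fold`
#'   (1-decimal), `fold_raw`, `p` (two-sided Fisher), `flag`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  stop_if_not(all(vapply(list(a, b, c, d), is_count, logical(1))),
              "counts must be non-negative integers")
  stop_if_not(b > 0 && d > 0, "group sizes must be positive")
  stop_if_not(a <= b && c <= d, "successes cannot exceed group size")
  prop_fg <- a / b
  prop_bg <- c / d
  fold_raw <- if (c > 0) prop_fg / prop_bg else NA_real_
  fold <- if (is.na(fold_raw)) NA_real_ else round_half_up(fold_raw, 1)
  flag <- ""
  k <- a + c
  if (k == 0 || k == b + d || b == 0 || d == 0) {
    p <- 1
    flag <- "degenerate_margins"
  } else {
    p <- fisher_p_twosided(a, b, c, d)
  }
  list(counts = c(a = a, b = b, c = c, d = d),
       proportion_fg = prop_fg, proportion_bg = prop_bg,
       fold = fold, fold_raw = fold_raw, p = p, flag = flag)
}

## Two-sided Fisher exact p for the 2x2 table [[a, b-a], [c, d-c]] by full
## enumeration of the hypergeometric support at fixed margins.
fisher_p_twosided <- function(a, b, c, d) {
  k <- a + c                       # total successes
  lo <- max(0L, k - d)
  hi <- min(k, b)
  support <- lo:hi
  logp <- stats::dhyper(support, b, d, k, log = TRUE)
  obs <- logp[support == a]
  # tolerance guards ties against floating-point noise (fisher.test uses
  # a relative epsilon of 1e-7 for the same reason)
  sum(exp(logp[logp <= obs + 1e-7 * abs(obs) + 1e-12]))
}

#' Array capture fractions of element CpGs
#'
#' For each element class, the fraction of element-resident catalog CpGs
#' present in an array-like mask, plus the positional profile of the masked
#' CpGs (to expose design bias of sparse arrays).
#'
#' @param annotated output of [annotate_cpgs()] on the full catalog.
#' @param mask character vector of CpG ids captured by the array.
#' @param elements element table.
#' @return list with `fractions` (named by class) and `masked_profile`.
#' @export
array_mask_comparison <- function(annotated, mask, elements) {
  resident <- annotated[!is.na(annotated$element_id), , drop = FALSE]
  fr <- vapply(c(LMR = "LMR", UMR = "UMR"), function(cl) {
    ids <- resident$cpg_id[resident$element_class == cl]
    if (length(ids) == 0) return(NA_real_)
    mean(ids %in% mask)
  }, numeric(1))
  prof <- positional_profile(annotated, elements, subset = mask)
  list(fractions = fr, masked_profile = prof)
}
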