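#' Cis methylation QTL scan
#'
#' For every CpG x SNP pair within the cis window (boundary inclusive),
#' fits a linear model of the methylation proportion on allele dosage
#' (plus optional covariates) and reports the slope (methylation per
#' allele), its t-test p, and Storey q-values over the whole scan.
#' Monomorphic SNPs are skipped.
#'
#' @param mat a `meth_matrix` (proportion scale).
#' @param genotypes list with `dosage` (samples x SNPs) and `snp_info`.
#' @param covariates optional numeric matrix of covariates (samples x k).
#' @param window cis window in bp (default 250000).
#' @param fdr FDR level used for the `significant` flag (default 0.10).
#' @return `data.frame`: `cpg_id`, `snp_id`, `distance`, `slope`, `se`,
#'   `p`, `q`, `significant`.
#' @export
cis_met_qtl <- function(mat, genotypes, covariates = NULL,
                        window = 250000, fdr = 0.10) {
  n <- ncol(mat$m)
  stop_if_not(n >= 30, "need at least 30 shared samples for the QTL scan")
  stop_if_not(nrow(genotypes$dosage) == n,
              "genotype and methylation sample counts disagree")
  info <- genotypes$snp_info
  poly <- apply(genotypes$dosage, 2L, function(d) length(unique(d)) > 1L)
  out <- list()
  for (i in seq_len(nrow(mat$m))) {
    cpos <- mat$cpgs$pos[i]
    near <- which(abs(info$pos - cpos) <= window & poly)
    if (!length(near)) next
    y <- mat$m[i, ]
    ok <- !is.na(y)
    if (sum(ok) < 30) next
    for (j in near) {
      d <- genotypes$dosage[, j]
      if (length(unique(d[ok])) < 2) next
      X <- cbind(1, d)
      if (!is.null(covariates)) X <- cbind(X, covariates)
      ft <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
      rdf <- ft$df.residual
      if (rdf <= 0) next
      s2 <- sum(ft$residuals^2) / rdf
      XtXi <- chol2inv(qr.R(ft$qr))
      se <- sqrt(s2 * XtXi[2, 2])
      slope <- ft$coefficients[2]
      p <- 2 * stats::pt(-abs(slope / se), rdf)
      out[[length(out) + 1L]] <- data.frame(
        cpg_id = mat$cpgs$cpg_id[i], snp_id = info$snp_id[j],
        distance = info$pos[j] - cpos, slope = unname(slope), se = se, p = p,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(cpg_id = character(), snp_id = character(),
                      distance = numeric(), slope = numeric(), se = numeric(),
                      p = numeric(), q = numeric(), significant = logical()))
  }
  qv <- storey_qvalues(pmax(res$p, .Machine$double.xmin))
  res$q <- qv$q
  res$significant <- res$q < fdr
  rownames(res) <- NULL
  res
}

#' Classify elements as under genetic regulation
#'
#' An element is "under genetic regulation" iff at least one of its resident
#' CpGs has a significant cis metQTL. Also produces a report in the shape of
#' a genetic-regulation enrichment table: per element group, the proportion
#' of genetically regulated elements and the Fisher fold over a background
#' proportion.
#'
#' @param qtls result of [cis_met_qtl()].
#' @param annotated CpG annotation from [annotate_cpgs()].
#' @param elements element table.
#' @param groups named list of element-id vectors to report on (default one
#'   group per specificity plus "all").
#' @param background optional `c(successes, size)` background counts; the
#'   default uses all elements in `elements`.
#' @return list with `regulated` (named logical per element) and `report`
#'   (`data.frame`: group, k, n, proportion, fold, p).
#' @export
classify_genetic_regulation <- function(qtls, annotated, elements,
                                        groups = NULL, background = NULL) {
  sig_cpgs <- unique(qtls$cpg_id[qtls$significant])
  cpg_el <- annotated$element_id[match(sig_cpgs, annotated$cpg_id)]
  regulated <- stats::setNames(elements$id %in% cpg_el, elements$id)
  if (is.null(groups)) {
    groups <- list(
      all = elements$id,
      shared = elements$id[elements$specificity == "shared"],
      adipose_specific = elements$id[elements$specificity == "adipose_specific"]
    )
  }
  if (is.null(background)) {
    background <- c(sum(regulated), length(regulated))
  }
  report <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    k <- sum(regulated[ids]); nn <- length(ids)
    if (nn == 0) {
      return(data.frame(group = g, k = 0L, n = 0L, proportion = NA_real_,
                        fold = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    fe <- fisher_enrichment(k, nn, background[1], background[2])
    fold <- if (k == 0) 0.0 else fe$fold
    data.frame(group = g, k = k, n = nn, proportion = k / nn,
               fold = fold, p = fe$p, stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  list(regulated = regulated, report = report)
}

#' Conditional EWAS on a SNP genotype
#'
#' Refits the coverage-weighted binomial lipid model for the given CpGs with
#' the SNP dosage appended as a covariate, one SNP at a time, and reports
#' the conditioned test together with the attenuation ratio
#' `p_conditional / p_marginal`.
#'
#' @param mat a `meth_matrix`.
#' @param phenotypes phenotype table.
#' @param trait trait column name.
#' @param dosage numeric dosage vector (one SNP, one value per sample).
#' @param cpg_ids CpGs to refit (default all rows of `mat`).
#' @param transform trait transform.
#' @param use_cells include cell proportions.
#' @return `data.frame`: `cpg_id`, marginal `beta/z/p`, conditional
#'   `beta_cond/z_cond/p_cond`, `attenuation`, `flag`.
#' @export
conditional_ewas <- function(mat, phenotypes, trait, dosage,
                             cpg_ids = NULL, transform = "identity",
                             use_cells = TRUE) {
  stop_if_not(length(unique(dosage[!is.na(dosage)])) > 1,
              "dosage is constant; conditioning is undefined")
  X0 <- build_design(phenotypes, use_cells = use_cells)
  tv <- prepare_trait(phenotypes[[trait]], transform)
  X0[, "trait"] <- tv$values
  Xc <- cbind(X0, dosage = dosage)
  rows <- if (is.null(cpg_ids)) seq_len(nrow(mat$m)) else
    match(cpg_ids, mat$cpgs$cpg_id)
  out <- lapply(rows, function(i) {
    marg <- fit_weighted_binomial(mat$m[i, ], mat$coverage[i, ], X0, "trait")
    cond <- fit_weighted_binomial(mat$m[i, ], mat$coverage[i, ], Xc, "trait")
    flag <- if (nzchar(cond$flag)) cond$flag else marg$flag
    data.frame(
      cpg_id = mat$cpgs$cpg_id[i],
      beta = marg$beta, z = marg$z, p = marg$p_raw,
      beta_cond = cond$beta, z_cond = cond$z, p_cond = cond$p_raw,
      attenuation = cond$p_raw / marg$p_raw,
      flag = flag, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cis methylation-expression association
#'
#' For every CpG x gene pair whose transcribed region lies within the cis
#' window of the CpG (distance to the nearest gene edge, boundary
#' inclusive), fits a fixed-effects linear model of methylation on
#' expression plus covariates and tests the expression effect by a
#' likelihood-ratio test against the covariate-only null;
#' `-2 log(likelihood ratio)` is referred to a chi-square with 1 df.
#'
#' @param mat a `meth_matrix`.
#' @param expression genes x samples matrix.
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @param covariates optional numeric covariate matrix (samples x k).
#' @param window cis window in bp (default 1e6).
#' @param fdr FDR level for the `significant` flag (default 0.10).
#' @return `data.frame`: `cpg_id`, `gene_id`, `distance`, `slope`, `lrt`,
#'   `p`, `q`, `significant`.
#' @export
cis_expression_association <- function(mat, expression, genes,
                                       covariates = NULL, window = 1e6,
                                       fdr = 0.10) {
  n <- ncol(mat$m)
  stop_if_not(n >= 30, "need at least 30 shared samples")
  stop_if_not(ncol(expression) == n,
              "expression and methylation sample counts disagree")
  out <- list()
  for (i in seq_len(nrow(mat$m))) {
    cpos <- mat$cpgs$pos[i]
    dist <- gene_edge_distance(cpos, genes$start, genes$end)
    near <- which(dist <= window)
    if (!length(near)) next
    y <- mat$m[i, ]
    for (j in near) {
      e <- expression[genes$gene_id[j], ]
      ok <- !is.na(y) & !is.na(e)
      if (sum(ok) < 30) next
      if (stats::var(e[ok]) == 0) next
      lr <- lrt_linear(y[ok], e[ok],
                       if (is.null(covariates)) NULL else
                         covariates[ok, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        cpg_id = mat$cpgs$cpg_id[i], gene_id = genes$gene_id[j],
        distance = dist[j], slope = lr$slope, lrt = lr$lrt, p = lr$p,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(cpg_id = character(), gene_id = character(),
                      distance = numeric(), slope = numeric(),
                      lrt = numeric(), p = numeric(), q = numeric(),
                      significant = logical()))
  }
  qv <- storey_qvalues(pmax(res$p, .Machine$double.xmin))
  res$q <- qv$q
  res$significant <- res$q < fdr
  rownames(res) <- NULL
  res
}

## distance from a point to the nearest edge of [start, end); 0 if inside
gene_edge_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos < end, 0,
         pmin(abs(pos - start), abs(pos - (end - 1))))
}

## Gaussian ML likelihood-ratio test of `x` in y ~ x (+ covars): the LRT is
## 2 * (loglik_full - loglik_null) = n * log(RSS0 / RSS1), chi-square 1 df.
lrt_linear <- function(y, x, covars = NULL) {
  n <- length(y)
  X1 <- cbind(1, x)
  X0 <- matrix(1, n, 1)
  if (!is.null(covars)) {
    X1 <- cbind(X1, covars)
    X0 <- cbind(X0, covars)
  }
  f1 <- stats::lm.fit(X1, y)
  f0 <- stats::lm.fit(X0, y)
  rss1 <- sum(f1$residuals^2)
  rss0 <- sum(f0$residuals^2)
  lrt <- max(0, n * log(rss0 / max(rss1, 1e-300)))
  list(slope = unname(f1$coefficients[2]), lrt = lrt,
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Expression-lipid association
#'
#' Per gene, fixed-effects linear model of expression on the prepared trait
#' (plus covariates), tested by the same 1-df likelihood-ratio statistic;
#' direction of effect is recorded for expected-direction checks.
#'
#' @param expression genes x samples matrix.
#' @param trait numeric trait vector (already prepared/standardized).
#' @param covariates optional covariate matrix.
#' @return `data.frame`: `gene_id`, `slope`, `direction`, `lrt`, `p`, `q`.
#' @export
expression_trait_association <- function(expression, trait,
                                         covariates = NULL) {
  stop_if_not(stats::var(trait, na.rm = TRUE) > 0, "trait is constant")
  out <- lapply(rownames(expression), function(g) {
    e <- expression[g, ]
    ok <- !is.na(e) & !is.na(trait)
    lr <- lrt_linear(e[ok], trait[ok],
                     if (is.null(covariates)) NULL else
                       covariates[ok, , drop = FALSE])
    data.frame(gene_id = g, slope = lr$slope, direction = sign(lr$slope),
               lrt = lr$lrt, p = lr$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$q <- storey_qvalues(pmax(res$p, .Machine$double.xmin))$q
  rownames(res) <- NULL
  res
}

#' Distance summaries of methylation-expression links
#'
#' Per element with at least one significant expression association: the
#' distance from the associated CpG to its most-correlated gene (smallest
#' p) and to its most-proximal gene (nearest transcribed-region edge over
#' all genes), plus cohort means and the fraction of elements correlated
#' with more than one gene.
#'
#' @param expr_assocs result of [cis_expression_association()] with an
#'   `element_id` column joined on (via [annotate_cpgs()]).
#' @param genes gene table.
#' @param cpg_pos named vector of CpG positions (by cpg_id).
#' @return list with `per_element` table, `mean_correlated_distance`,
#'   `mean_proximal_distance`, `frac_multi_gene`.
#' @export
distance_summaries <- function(expr_assocs, genes, cpg_pos) {
  sig <- expr_assocs[expr_assocs$significant & !is.na(expr_assocs$element_id), ,
                     drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(per_element = NULL, mean_correlated_distance = NA_real_,
                mean_proximal_distance = NA_real_, frac_multi_gene = NA_real_))
  }
  per <- do.call(rbind, lapply(split(sig, sig$element_id), function(d) {
    best <- d[which.min(d$p), ]
    pos <- cpg_pos[[best$cpg_id]]
    prox <- min(gene_edge_distance(pos, genes$start, genes$end))
    data.frame(
      element_id = best$element_id,
      correlated_gene = best$gene_id,
      correlated_distance = abs(best$distance),
      proximal_distance = prox,
      n_genes = length(unique(d$gene_id)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  list(per_element = per,
       mean_correlated_distance = mean(per$correlated_distance),
       mean_proximal_distance = mean(per$proximal_distance),
       frac_multi_gene = mean(per$n_genes > 1))
}

#' Gene-set overlap enrichment
#'
#' Fisher 2x2 of annotated genes among a hit set against a catalog
#' background (e.g. trait-annotated genes in a GWAS gene catalog).
#'
#' @param hit_annotated,hit_total annotated and total genes in the hit set.
#' @param catalog_annotated,catalog_total annotated and total genes in the
#'   catalog universe.
#' @return an [fisher_enrichment()] result.
#' @export
set_overlap_enrichment <- function(hit_annotated, hit_total,
                                   catalog_annotated, catalog_total) {
  stop_if_not(hit_total > 0 && catalog_total > 0, "empty gene set")
  fisher_enrichment(hit_annotated, hit_total, catalog_annotated,
                    catalog_total)
}
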