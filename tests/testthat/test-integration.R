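mat_from <- function(M, pos = NULL) {
  n_cpg <- nrow(M)
  if (is.null(pos)) pos <- seq_len(n_cpg) * 1000L
  structure(list(
    m = M, coverage = matrix(30, n_cpg, ncol(M)),
    cpgs = data.frame(chrom = "chrS", pos = pos,
                      cpg_id = sprintf("cpg_%07d", pos),
                      stringsAsFactors = FALSE),
    samples = sprintf("S%03d", seq_len(ncol(M)))
  ), class = "meth_matrix")
}

test_that("cis window boundaries are inclusive and monomorphic SNPs skipped", {
  set.seed(31)
  n <- 50
  M <- matrix(runif(n, 0.2, 0.8), 1, n)
  mat <- mat_from(M, pos = 500000L)
  dos <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.3),
               c = rbinom(n, 2, 0.4), mono = rep(1L, n))
  geno <- list(dosage = dos, snp_info = data.frame(
    snp_id = colnames(dos), chrom = "chrS",
    pos = c(250000L,        # exactly window away: included
            249999L,        # outside by 1 bp: excluded
            500010L,        # inside
            500020L),       # monomorphic: skipped
    maf = rep(0.3, 4), stringsAsFactors = FALSE))
  res <- cis_met_qtl(mat, geno, window = 250000)
  expect_setequal(res$snp_id, c("a", "c"))
  expect_true(all(abs(res$distance) <= 250000))
})

test_that("planted SNP effects are recovered in slope sign and rough magnitude", {
  set.seed(32)
  n <- 500
  dos <- rbinom(n, 2, 0.3)
  # methylation proportion rises 0.08 per allele around 0.3
  M <- matrix(pmin(pmax(0.3 + 0.08 * dos + rnorm(n, 0, 0.05), 0.01), 0.99),
              1, n)
  mat <- mat_from(M, pos = 1000L)
  geno <- list(dosage = cbind(s1 = dos), snp_info = data.frame(
    snp_id = "s1", chrom = "chrS", pos = 1500L, maf = 0.3,
    stringsAsFactors = FALSE))
  res <- cis_met_qtl(mat, geno)
  expect_gt(res$slope, 0)
  expect_lt(abs(res$slope - 0.08), 0.02)
  expect_lt(res$p, 1e-10)
})

test_that("QTL slope is unbiased across seeds at n = 500", {
  slopes <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 500
    dos <- rbinom(n, 2, 0.4)
    M <- matrix(pmin(pmax(0.4 + 0.05 * dos + rnorm(n, 0, 0.08), 0.01), 0.99),
                1, n)
    geno <- list(dosage = cbind(s1 = dos), snp_info = data.frame(
      snp_id = "s1", chrom = "chrS", pos = 1500L, maf = 0.4,
      stringsAsFactors = FALSE))
    cis_met_qtl(mat_from(M, 1000L), geno)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.05), 0.1 * 0.05)
})

test_that("genetic-regulation classification reproduces the printed fold-change table", {
  # printed group counts against the printed background 22101/50759
  bg <- c(22101, 50759)
  groups <- list(all = c(362, 567), adipose_specific = c(111, 226),
                 shared = c(251, 341), blood1 = c(63, 68), blood2 = c(21, 22))
  folds <- vapply(groups, function(g)
    fisher_enrichment(g[1], g[2], bg[1], bg[2])$fold, numeric(1))
  expect_equal(unname(folds), c(1.5, 1.1, 1.7, 2.1, 2.2))
})

test_that("element-level genetic regulation flags elements via their resident CpGs", {
  coh <- simulate_cohort(sim_config(
    n_samples = 150, n_elements_lmr = 60, n_elements_umr = 30,
    frac_metqtl_cpgs = 0.15, snp_effect_logit = 0.8, frac_lipid_cpgs = 0,
    n_snps = 300, seed = 33))
  mat <- qc_matrix(coh, 100)
  qtls <- cis_met_qtl(mat, coh$genotypes)
  ann <- annotate_cpgs(coh$cpgs, coh$elements)
  gr <- classify_genetic_regulation(qtls, ann, coh$elements)
  # elements with a planted metQTL CpG should be called at a higher rate
  planted_el <- unique(ann$element_id[match(coh$truth$metqtl$cpg_id,
                                            ann$cpg_id)])
  planted_el <- planted_el[!is.na(planted_el)]
  rate_planted <- mean(gr$regulated[planted_el])
  rate_other <- mean(gr$regulated[setdiff(coh$elements$id, planted_el)])
  expect_gt(rate_planted, rate_other + 0.2)
  # empty group reports zero proportion and fold 0
  rep0 <- classify_genetic_regulation(
    qtls[0, ], ann, coh$elements,
    groups = list(none = coh$elements$id))$report
  expect_equal(rep0$proportion, 0)
  expect_equal(rep0$fold, 0)
})

test_that("conditioning on an unrelated SNP barely moves the statistic", {
  set.seed(34)
  coh <- simulate_cohort(sim_config(
    n_samples = 500, n_elements_lmr = 10, n_elements_umr = 4,
    frac_lipid_cpgs = 0, frac_metqtl_cpgs = 0, seed = 35))
  mat <- qc_matrix(coh, 100)
  keep <- sample(nrow(mat$m), 40)
  mat$m <- mat$m[keep, , drop = FALSE]
  mat$coverage <- mat$coverage[keep, , drop = FALSE]
  mat$cpgs <- mat$cpgs[keep, , drop = FALSE]
  dosage <- rbinom(500, 2, 0.3)     # independent of everything
  res <- conditional_ewas(mat, coh$phenotypes, "HDL", dosage)
  dz <- abs(res$z_cond - res$z)
  expect_lt(median(dz, na.rm = TRUE), 0.2)
})

test_that("conditioning on the causal SNP nulls out a SNP-mediated association", {
  set.seed(36)
  n <- 400
  dos <- rbinom(n, 2, 0.4)
  # trait driven by the SNP; methylation driven by the SNP: association
  # between methylation and trait is purely SNP-mediated
  trait <- dos + rnorm(n, 0, 0.8)
  pi <- plogis(-1 + 0.8 * dos)
  T <- matrix(rpois(n, 40) + 5, 1, n)
  M <- matrix(rbinom(n, T, pi) / T, 1, n)
  mat <- mat_from(M, 1000L)
  ph <- data.frame(sample_id = sprintf("S%03d", 1:n), HDL = trait,
                   age = rnorm(n, 45, 8), sex = sample(c("M", "F"), n, TRUE),
                   BMI = rnorm(n, 45, 4), batch = "MetV1",
                   stringsAsFactors = FALSE)
  mat$coverage <- T
  res <- conditional_ewas(mat, ph, "HDL", dos, use_cells = FALSE)
  expect_lt(res$p, 1e-4)            # marginal association is strong
  expect_gt(res$p_cond, 0.01)       # conditioning removes it
  expect_gt(res$attenuation, 10)
  expect_error(conditional_ewas(mat, ph, "HDL", rep(1, n)), "constant")
})

test_that("methylation-expression LRT equals the two-fit oracle and respects the window", {
  set.seed(37)
  n <- 60
  M <- matrix(runif(n, 0.2, 0.8), 1, n)
  mat <- mat_from(M, pos = 1000000L)
  genes <- data.frame(
    gene_id = c("g_in", "g_edge", "g_out", "g_flat"),
    chrom = "chrS",
    start = c(1005000, 2000000, 2000001, 1020000),
    end = c(1015000, 2010000, 2010001, 1030000),
    stringsAsFactors = FALSE
  )
  expr <- rbind(
    g_in = 5 + 3 * M[1, ] + rnorm(n, 0, 0.5),
    g_edge = rnorm(n, 8, 1),
    g_out = rnorm(n, 8, 1),
    g_flat = rep(2, n)                 # zero variance: skipped
  )
  colnames(expr) <- mat$samples
  res <- cis_expression_association(mat, expr, genes, window = 1e6)
  expect_setequal(res$gene_id, c("g_in", "g_edge"))  # g_out 1 bp too far
  expect_true(res$significant[res$gene_id == "g_in"])
  # oracle: two explicit lm fits, ML loglik difference
  y <- M[1, ]; x <- expr["g_in", ]
  ll_full <- logLik(lm(y ~ x)); ll_null <- logLik(lm(y ~ 1))
  lrt_oracle <- as.numeric(2 * (ll_full - ll_null))
  expect_lt(abs(res$lrt[res$gene_id == "g_in"] - lrt_oracle), 1e-8)
  # identical fit and null -> LRT 0, p 1
  lr0 <- lipidews:::lrt_linear(y, rep(0, n))
  expect_equal(lr0$lrt, 0)
  expect_equal(lr0$p, 1)
})

test_that("expression-trait association recovers planted links with direction", {
  set.seed(38)
  n <- 200
  trait <- rnorm(n)
  expr <- rbind(
    gene_up = 5 + 0.8 * trait + rnorm(n),
    gene_null = rnorm(n, 5)
  )
  colnames(expr) <- sprintf("S%03d", 1:n)
  res <- expression_trait_association(expr, trait)
  expect_lt(res$p[res$gene_id == "gene_up"], 1e-6)
  expect_equal(res$direction[res$gene_id == "gene_up"], 1)
  expect_gt(res$p[res$gene_id == "gene_null"], 0.001)
  expect_error(expression_trait_association(expr, rep(1, n)), "constant")
})

test_that("null expression-trait p-values are uniform across seeds", {
  ps <- vapply(1:200, function(s) {
    set.seed(400 + s)
    n <- 60
    expr <- matrix(rnorm(n, 8), 1, dimnames = list("g", sprintf("S%02d", 1:n)))
    expression_trait_association(expr, rnorm(n))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("distance summaries pick most-correlated and most-proximal genes", {
  # single gene at 10 kb: both distances 10 kb
  genes1 <- data.frame(gene_id = "g1", chrom = "chrS",
                       start = 110000, end = 130000, stringsAsFactors = FALSE)
  ea1 <- data.frame(cpg_id = "c1", gene_id = "g1", distance = 10000,
                    slope = 1, lrt = 30, p = 1e-7, q = 1e-6,
                    significant = TRUE, element_id = "E1",
                    stringsAsFactors = FALSE)
  ds1 <- distance_summaries(ea1, genes1, c(c1 = 100000))
  expect_equal(ds1$mean_correlated_distance, 10000)
  expect_equal(ds1$mean_proximal_distance, 10000)
  expect_equal(ds1$frac_multi_gene, 0)
  # a stronger long-range gene dominates the correlated distance
  genes2 <- rbind(genes1, data.frame(gene_id = "g2", chrom = "chrS",
                                     start = 600000, end = 620000,
                                     stringsAsFactors = FALSE))
  ea2 <- rbind(ea1, data.frame(cpg_id = "c1", gene_id = "g2",
                               distance = 500000, slope = 2, lrt = 60,
                               p = 1e-12, q = 1e-11, significant = TRUE,
                               element_id = "E1", stringsAsFactors = FALSE))
  ds2 <- distance_summaries(ea2, genes2, c(c1 = 100000))
  expect_equal(ds2$per_element$correlated_gene, "g2")
  expect_gt(ds2$mean_correlated_distance, ds2$mean_proximal_distance)
  expect_equal(ds2$frac_multi_gene, 1)
  # elements without significant genes are excluded
  ea3 <- ea1; ea3$significant <- FALSE
  ds3 <- distance_summaries(ea3, genes1, c(c1 = 100000))
  expect_true(is.na(ds3$mean_correlated_distance))
})

test_that("significant QTLs concentrate near their CpGs when effects decay with distance", {
  set.seed(39)
  n <- 200; n_cpg <- 40
  cpg_pos <- seq(1e5, 4e6, length.out = n_cpg)
  snp_pos <- cpg_pos + rep(c(5e3, 1e5, 2.4e5), length.out = n_cpg)
  dos <- vapply(seq_len(n_cpg), function(j) rbinom(n, 2, 0.3), integer(n))
  colnames(dos) <- sprintf("s%02d", seq_len(n_cpg))
  # effect shrinks with SNP-CpG distance
  eff <- 0.1 * exp(-abs(snp_pos - cpg_pos) / 5e4)
  M <- t(vapply(seq_len(n_cpg), function(i)
    pmin(pmax(0.4 + eff[i] * dos[, i] + rnorm(n, 0, 0.06), 0.01), 0.99),
    numeric(n)))
  mat <- mat_from(M, pos = as.integer(cpg_pos))
  geno <- list(dosage = dos, snp_info = data.frame(
    snp_id = colnames(dos), chrom = "chrS", pos = as.integer(snp_pos),
    maf = 0.3, stringsAsFactors = FALSE))
  res <- cis_met_qtl(mat, geno)
  expect_lt(median(abs(res$distance[res$significant])),
            median(abs(res$distance)))
})

test_that("gene-set overlap enrichment matches the catalog example and edge cases", {
  fe <- set_overlap_enrichment(6, 20, 692, 15815)
  expect_equal(fe$fold, 6.9)
  expect_equal(fe$p, fisher.test(matrix(c(6, 14, 692, 15123), 2,
                                        byrow = TRUE))$p.value,
               tolerance = 1e-9)
  same <- set_overlap_enrichment(692, 15815, 692, 15815)
  expect_equal(same$fold, 1.0)
  expect_error(set_overlap_enrichment(0, 0, 692, 15815), "empty")
})
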