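#' Configuration for the synthetic methylation cohort
#'
#' Bundles every knob of the synthetic-study generator. Defaults emulate the
#' discovery design the package targets: ~200 severely obese donors, targeted
#' bisulfite sequencing of regulatory elements at ~33x mean coverage, CpG
#' densities of ~7 per low-methylated region (LMR, putative enhancer) and ~37
#' per unmethylated region (UMR, putative promoter), mildly overdispersed
#' (beta-binomial) read counts, and sparse planted CpG-lipid, SNP-CpG and
#' CpG-expression effects.
#'
#' @param n_samples number of donors.
#' @param n_elements_lmr,n_elements_umr numbers of LMR/UMR elements placed on
#'   the toy chromosome.
#' @param mean_cpgs_per_lmr,mean_cpgs_per_umr Poisson mean CpG count per
#'   element class.
#' @param lmr_length_mean,umr_length_mean mean element lengths in bp
#'   (enhancers shorter than promoters).
#' @param chrom_length length of the single toy chromosome in bp
#'   (0-based half-open coordinates throughout).
#' @param coverage_mean mean total read depth per CpG per sample.
#' @param coverage_dispersion negative-binomial size parameter of the depth
#'   distribution (larger = closer to Poisson).
#' @param beta_dispersion beta-binomial overdispersion rho in [0, 1); 0 gives
#'   pure binomial counts.
#' @param frac_lipid_cpgs fraction of element-resident CpGs carrying a planted
#'   lipid association.
#' @param effect_size_logit planted CpG-lipid effect, logit units per SD of
#'   the (analysis-scale) trait.
#' @param frac_metqtl_cpgs fraction of element-resident CpGs with a planted
#'   cis-SNP effect.
#' @param snp_effect_logit planted SNP effect, logit units per allele dosage.
#' @param n_snps number of simulated biallelic SNPs.
#' @param maf_range range of minor-allele frequencies.
#' @param frac_expr_linked fraction of elements whose methylation drives the
#'   expression of a linked gene.
#' @param expr_effect_size expression change per unit methylation proportion
#'   at the linked CpG (expression is on an arbitrary log-intensity scale).
#' @param background_cpg_frac fraction of the CpG catalog falling outside any
#'   element.
#' @param array_mask_frac_lmr,array_mask_frac_umr fractions of LMR/UMR CpGs
#'   captured by the emulated array design (anchored to the ~6% / ~19%
#'   capture of enhancer/promoter CpGs by sparse arrays).
#' @param frac_adipose_specific fraction of elements labelled tissue-specific
#'   rather than shared.
#' @param frac_bivalent_umr fraction of UMRs flagged as bivalently oriented
#'   (excluded from positional TSS profiles).
#' @param female_frac Bernoulli probability of female sex.
#' @param trait_cor 4x4 correlation matrix of the latent lipid traits, order
#'   TG, HDL, LDL, TC.
#' @param seed integer root seed; all stage randomness derives from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 200,
                       n_elements_lmr = 600,
                       n_elements_umr = 400,
                       mean_cpgs_per_lmr = 7,
                       mean_cpgs_per_umr = 37,
                       lmr_length_mean = 1000,
                       umr_length_mean = 2700,
                       chrom_length = 1e7,
                       coverage_mean = 33,
                       coverage_dispersion = 8,
                       beta_dispersion = 0.02,
                       frac_lipid_cpgs = 0.01,
                       effect_size_logit = 0.3,
                       frac_metqtl_cpgs = 0.05,
                       snp_effect_logit = 0.5,
                       n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       frac_expr_linked = 0.3,
                       expr_effect_size = 4,
                       background_cpg_frac = 0.05,
                       array_mask_frac_lmr = 0.06,
                       array_mask_frac_umr = 0.19,
                       frac_adipose_specific = 0.4,
                       frac_bivalent_umr = 0.05,
                       female_frac = 0.6,
                       trait_cor = NULL,
                       seed = 1L) {
  if (is.null(trait_cor)) {
    trait_cor <- matrix(c(
      1.0, -0.4, 0.2, 0.3,
      -0.4, 1.0, 0.0, 0.2,
      0.2, 0.0, 1.0, 0.9,
      0.3, 0.2, 0.9, 1.0
    ), 4, 4, dimnames = list(TRAITS, TRAITS))
  }
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_elements_lmr = as.integer(n_elements_lmr),
    n_elements_umr = as.integer(n_elements_umr),
    mean_cpgs_per_lmr = mean_cpgs_per_lmr,
    mean_cpgs_per_umr = mean_cpgs_per_umr,
    lmr_length_mean = lmr_length_mean,
    umr_length_mean = umr_length_mean,
    chrom_length = chrom_length,
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    beta_dispersion = beta_dispersion,
    frac_lipid_cpgs = frac_lipid_cpgs,
    effect_size_logit = effect_size_logit,
    frac_metqtl_cpgs = frac_metqtl_cpgs,
    snp_effect_logit = snp_effect_logit,
    n_snps = as.integer(n_snps),
    maf_range = maf_range,
    frac_expr_linked = frac_expr_linked,
    expr_effect_size = expr_effect_size,
    background_cpg_frac = background_cpg_frac,
    array_mask_frac_lmr = array_mask_frac_lmr,
    array_mask_frac_umr = array_mask_frac_umr,
    frac_adipose_specific = frac_adipose_specific,
    frac_bivalent_umr = frac_bivalent_umr,
    female_frac = female_frac,
    trait_cor = trait_cor,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

TRAITS <- c("TG", "HDL", "LDL", "TC")

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$n_samples >= 2, "n_samples must be >= 2")
  stop_if_not(cfg$n_elements_lmr >= 0 && cfg$n_elements_umr >= 0,
              "element counts must be non-negative")
  stop_if_not(cfg$coverage_mean >= 5, "coverage_mean must be >= 5")
  stop_if_not(is_prop(cfg$beta_dispersion) && cfg$beta_dispersion < 1,
              "beta_dispersion must lie in [0, 1)")
  for (f in c("frac_lipid_cpgs", "frac_metqtl_cpgs", "frac_expr_linked",
              "background_cpg_frac", "array_mask_frac_lmr",
              "array_mask_frac_umr", "frac_adipose_specific",
              "frac_bivalent_umr", "female_frac")) {
    stop_if_not(is_prop(cfg[[f]]), sprintf("%s must lie in [0, 1]", f))
  }
  stop_if_not(all(dim(cfg$trait_cor) == c(4, 4)) &&
                all(abs(cfg$trait_cor - t(cfg$trait_cor)) < 1e-12),
              "trait_cor must be a symmetric 4x4 matrix")
  invisible(cfg)
}

#' Place disjoint regulatory elements on the toy chromosome
#'
#' Elements are laid out non-overlapping in 0-based half-open coordinates.
#' Each UMR carries a transcription start site (TSS) inside the element with
#' a random strand; elements are labelled shared or tissue-specific, and a
#' small fraction of UMRs is flagged bivalent.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `id`,
#'   `class` ("LMR"/"UMR"), `specificity` ("shared"/"adipose_specific"),
#'   `tss`, `tss_strand` (NA for LMRs), `bivalent`.
#' @export
generate_elements <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "elements"))
  n_lmr <- config$n_elements_lmr
  n_umr <- config$n_elements_umr
  n <- n_lmr + n_umr
  cls <- sample(c(rep("LMR", n_lmr), rep("UMR", n_umr)))
  mean_len <- ifelse(cls == "LMR", config$lmr_length_mean,
                     config$umr_length_mean)
  len <- pmax(100, round(stats::rgamma(n, shape = 6, scale = mean_len / 6)))
  free <- config$chrom_length - sum(len)
  if (free <= n) {
    stop("chromosome too short to place all elements without overlap",
         call. = FALSE)
  }
  # stick-breaking gaps: n+1 gaps of at least 1 bp summing to the free space
  cuts <- sort(sample.int(free - 1L, n))
  gaps <- diff(c(0L, cuts, free))
  start <- cumsum(gaps)[seq_len(n)] + cumsum(c(0, len[-n]))
  end <- start + len
  tss <- ifelse(cls == "UMR",
                start + floor(stats::runif(n) * len),
                NA_real_)
  tss_strand <- ifelse(cls == "UMR",
                       sample(c("+", "-"), n, replace = TRUE),
                       NA_character_)
  spec <- ifelse(stats::runif(n) < config$frac_adipose_specific,
                 "adipose_specific", "shared")
  bivalent <- cls == "UMR" & stats::runif(n) < config$frac_bivalent_umr
  idx <- stats::ave(seq_len(n), cls, FUN = seq_along)
  data.frame(
    chrom = "chrS", start = start, end = end,
    id = sprintf("%s_%04d", cls, idx),
    class = cls, specificity = spec,
    tss = tss, tss_strand = tss_strand, bivalent = bivalent,
    stringsAsFactors = FALSE
  )
}

#' Sample a CpG catalog within (and around) elements
#'
#' CpG counts per element are Poisson around the configured class densities;
#' a configured fraction of the catalog is background (outside all elements).
#' Positions are unique and strictly increasing.
#'
#' @param elements output of [generate_elements()].
#' @param config a [sim_config()].
#' @return `data.frame` with columns `chrom`, `pos`, `cpg_id`.
#' @export
generate_cpgs <- function(elements, config) {
  set.seed(stage_seed(config$seed, "cpgs"))
  lam <- ifelse(elements$class == "LMR", config$mean_cpgs_per_lmr,
                config$mean_cpgs_per_umr)
  counts <- stats::rpois(nrow(elements), lam)
  pos <- unlist(lapply(seq_len(nrow(elements)), function(i) {
    if (counts[i] == 0) return(integer(0))
    unique(elements$start[i] +
             floor(stats::runif(counts[i]) * (elements$end[i] - elements$start[i])))
  }))
  f <- config$background_cpg_frac
  if (f > 0 && length(pos) > 0) {
    n_bg <- round(length(pos) * f / (1 - f))
    got <- integer(0)
    while (length(got) < n_bg) {
      cand <- floor(stats::runif(2L * n_bg) * config$chrom_length)
      inside <- in_any_interval(cand, elements$start, elements$end)
      got <- unique(c(got, cand[!inside]))
    }
    pos <- c(pos, got[seq_len(n_bg)])
  }
  pos <- sort(unique(pos))
  data.frame(chrom = "chrS", pos = pos,
             cpg_id = sprintf("cpg_%07d", pos),
             stringsAsFactors = FALSE)
}

## Half-open membership of points in a set of disjoint sorted-by-start
## intervals; returns logical.
in_any_interval <- function(pos, start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  i <- findInterval(pos, start)
  i > 0 & pos < end[pmax(i, 1L)]
}

#' Simulate donor phenotypes and covariates
#'
#' Draws four correlated lipid traits (TG log-normal; HDL-C, LDL-C and TC
#' normal), age, sex (Bernoulli, cohort-style 60% female), BMI (severely
#' obese range), a two-level capture-panel batch, and five-part cell
#' proportions on the simplex (Dirichlet(5,3,2,1,1)).
#'
#' @param config a [sim_config()].
#' @param n number of samples (defaults to `config$n_samples`).
#' @return `data.frame` with columns `sample_id`, `TG`, `HDL`, `LDL`, `TC`,
#'   `age`, `sex`, `BMI`, `batch`, `cell1`..`cell5`.
#' @export
simulate_phenotypes <- function(config, n = config$n_samples) {
  stop_if_not(n >= 2, "need at least 2 samples")
  set.seed(stage_seed(config$seed, "phenotypes"))
  L <- chol(config$trait_cor)
  z <- matrix(stats::rnorm(n * 4), n, 4) %*% L
  tg <- exp(log(1.6) + 0.45 * z[, 1])          # mmol/L, right-skewed
  hdl <- pmax(0.4, 1.15 + 0.28 * z[, 2])
  ldl <- pmax(0.8, 2.9 + 0.75 * z[, 3])
  tc <- pmax(1.5, 4.9 + 0.9 * z[, 4])
  cells <- rdirichlet(n, c(5, 3, 2, 1, 1))
  colnames(cells) <- paste0("cell", 1:5)
  out <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    TG = tg, HDL = hdl, LDL = ldl, TC = tc,
    age = round(pmin(70, pmax(20, stats::rnorm(n, 45, 9)))),
    sex = ifelse(stats::runif(n) < config$female_frac, "F", "M"),
    BMI = round(40 + stats::rgamma(n, shape = 4, scale = 2.2), 1),
    batch = sample(c("MetV1", "MetV2"), n, replace = TRUE,
                   prob = c(0.55, 0.45)),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(cells))
}

#' Simulate biallelic SNP dosages
#'
#' Allele frequencies are uniform over the configured MAF range and genotypes
#' are Hardy-Weinberg binomial draws. SNPs that come out monomorphic in the
#' sample are excluded.
#'
#' @param config a [sim_config()].
#' @param n number of samples.
#' @param panel optional `snp_info` table from a previous call: reuses that
#'   SNP panel (positions and allele frequencies) with fresh
#'   Hardy-Weinberg draws, as when two cohorts are typed on one design.
#' @return list with `dosage` (samples x SNPs integer matrix) and `snp_info`
#'   (`data.frame` with `snp_id`, `chrom`, `pos`, `maf`).
#' @export
simulate_genotypes <- function(config, n = config$n_samples, panel = NULL) {
  set.seed(stage_seed(config$seed, "genotypes"))
  if (is.null(panel)) {
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    pos <- sort(sample.int(config$chrom_length, config$n_snps))
  } else {
    maf <- panel$maf
    pos <- panel$pos
  }
  dos <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
  keep <- if (is.null(panel)) {
    apply(dos, 2L, function(d) length(unique(d)) > 1L)
  } else rep(TRUE, ncol(dos))
  dos <- dos[, keep, drop = FALSE]
  info <- data.frame(
    snp_id = sprintf("snp_%07d", pos[keep]),
    chrom = "chrS", pos = pos[keep], maf = maf[keep],
    stringsAsFactors = FALSE
  )
  colnames(dos) <- info$snp_id
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  list(dosage = dos, snp_info = info)
}

## Registry of planted effects. Lipid effects are restricted to
## element-resident CpGs; each metQTL CpG is paired with the nearest SNP
## within the cis window. `tissue` marks where a lipid effect is active
## ("both" for shared elements, "adipose" for tissue-specific ones).
plant_truth <- function(catalog, elements, genotypes, config,
                        cis_window = 250000) {
  set.seed(stage_seed(config$seed, "simulate"))
  ann <- annotate_cpgs(catalog, elements)
  resident <- which(!is.na(ann$element_id))
  n_lip <- round(length(resident) * config$frac_lipid_cpgs)
  lip_idx <- sort(sample(resident, n_lip))
  lipid <- data.frame(
    cpg_id = catalog$cpg_id[lip_idx],
    trait = sample(TRAITS, n_lip, replace = TRUE),
    effect = config$effect_size_logit * sample(c(-1, 1), n_lip, replace = TRUE),
    element_id = ann$element_id[lip_idx],
    tissue = ifelse(
      ann$specificity[lip_idx] == "shared", "both", "adipose"),
    stringsAsFactors = FALSE
  )
  n_qtl <- round(length(resident) * config$frac_metqtl_cpgs)
  qtl_idx <- sort(sample(resident, n_qtl))
  snp_pos <- genotypes$snp_info$pos
  nearest <- vapply(catalog$pos[qtl_idx], function(p) {
    d <- abs(snp_pos - p)
    j <- which.min(d)
    if (d[j] <= cis_window) j else NA_integer_
  }, integer(1))
  ok <- !is.na(nearest)
  metqtl <- data.frame(
    cpg_id = catalog$cpg_id[qtl_idx][ok],
    snp_id = genotypes$snp_info$snp_id[nearest[ok]],
    effect = config$snp_effect_logit *
      sample(c(-1, 1), sum(ok), replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(lipid = lipid, metqtl = metqtl, expr = NULL)
}

#' Simulate per-strand methylated/total read counts
#'
#' Per CpG i and sample j the latent methylation proportion is
#' `logit(pi_ij) = alpha_i + beta_i * trait_j + gamma_i * dosage_ij`, with
#' baseline levels `alpha_i` drawn from a hypo/intermediate/hyper mixture
#' (55/35/10). Total depth is negative-binomial around the configured mean,
#' split binomially between strands; methylated reads are beta-binomial with
#' overdispersion `beta_dispersion` (both strands share one latent draw).
#' Zero-depth entries are legal and represent missing data.
#'
#' @param catalog CpG catalog from [generate_cpgs()].
#' @param phenotypes table from [simulate_phenotypes()].
#' @param genotypes list from [simulate_genotypes()].
#' @param truth planted-effect registry (internal; built by
#'   [simulate_cohort()]). Effects with `tissue == "adipose"` are only
#'   expressed when `tissue = "adipose"`.
#' @param config a [sim_config()].
#' @param tissue which tissue's counts to draw ("adipose" or "blood").
#' @param seed_stage internal substream label.
#' @return an object of class `strand_counts`: list of CpG x sample integer
#'   matrices `meth_fwd`, `total_fwd`, `meth_rev`, `total_rev`, plus `cpgs`
#'   and `samples`.
#' @export
simulate_methylation_counts <- function(catalog, phenotypes, genotypes,
                                        truth, config,
                                        tissue = "adipose",
                                        seed_stage = "counts") {
  set.seed(stage_seed(config$seed, seed_stage))
  n_cpg <- nrow(catalog)
  n <- nrow(phenotypes)
  state <- sample(c("hypo", "mid", "hyper"), n_cpg, replace = TRUE,
                  prob = c(0.55, 0.35, 0.10))
  base_m <- ifelse(state == "hypo", stats::runif(n_cpg, 0.02, 0.20),
            ifelse(state == "mid", stats::runif(n_cpg, 0.20, 0.80),
                   stats::runif(n_cpg, 0.80, 0.98)))
  alpha <- stats::qlogis(base_m)
  eta <- matrix(alpha, n_cpg, n)
  # planted lipid effects on the standardized analysis-scale trait
  if (nrow(truth$lipid) > 0) {
    tr_std <- scale_traits(phenotypes)
    act <- truth$lipid$tissue == "both" | tissue == "adipose"
    li <- truth$lipid[act, , drop = FALSE]
    ridx <- match(li$cpg_id, catalog$cpg_id)
    for (k in seq_len(nrow(li))) {
      eta[ridx[k], ] <- eta[ridx[k], ] + li$effect[k] * tr_std[, li$trait[k]]
    }
  }
  if (nrow(truth$metqtl) > 0) {
    ridx <- match(truth$metqtl$cpg_id, catalog$cpg_id)
    cidx <- match(truth$metqtl$snp_id, colnames(genotypes$dosage))
    stop_if_not(!anyNA(ridx) && !anyNA(cidx),
                "truth registry references CpGs/SNPs absent from the inputs")
    for (k in seq_len(nrow(truth$metqtl))) {
      eta[ridx[k], ] <- eta[ridx[k], ] +
        truth$metqtl$effect[k] * genotypes$dosage[, cidx[k]]
    }
  }
  pi_mean <- stats::plogis(eta)
  total <- matrix(stats::rnbinom(n_cpg * n, mu = config$coverage_mean,
                                 size = config$coverage_dispersion),
                  n_cpg, n)
  rho <- config$beta_dispersion
  if (rho > 0) {
    s <- (1 - rho) / rho
    pm <- pmin(pmax(pi_mean, 1e-6), 1 - 1e-6)
    pi_real <- matrix(stats::rbeta(n_cpg * n, pm * s, (1 - pm) * s),
                      n_cpg, n)
  } else {
    pi_real <- pi_mean
  }
  total_fwd <- matrix(stats::rbinom(n_cpg * n, total, 0.5), n_cpg, n)
  total_rev <- total - total_fwd
  meth_fwd <- matrix(stats::rbinom(n_cpg * n, total_fwd, pi_real), n_cpg, n)
  meth_rev <- matrix(stats::rbinom(n_cpg * n, total_rev, pi_real), n_cpg, n)
  dn <- list(catalog$cpg_id, phenotypes$sample_id)
  for (m in c("meth_fwd", "total_fwd", "meth_rev", "total_rev")) {
    x <- get(m)
    dimnames(x) <- dn
    assign(m, x)
  }
  structure(
    list(meth_fwd = meth_fwd, total_fwd = total_fwd,
         meth_rev = meth_rev, total_rev = total_rev,
         cpgs = catalog, samples = phenotypes$sample_id),
    class = "strand_counts"
  )
}

## Analysis-scale standardized traits (log TG), used for planting effects.
scale_traits <- function(phenotypes) {
  out <- cbind(
    TG = as.numeric(scale(log(phenotypes$TG))),
    HDL = as.numeric(scale(phenotypes$HDL)),
    LDL = as.numeric(scale(phenotypes$LDL)),
    TC = as.numeric(scale(phenotypes$TC))
  )
  rownames(out) <- phenotypes$sample_id
  out
}

#' Simulate a cis-linked expression matrix
#'
#' A configured fraction of elements drives the expression of a gene placed
#' at a mixture of short (~tens of kb) and long-range (200-900 kb) distances
#' from the linked CpG, echoing the observation that regulatory elements can
#' show their strongest expression effects at non-adjacent genes. An equal
#' number of unlinked null genes is added.
#'
#' @param catalog CpG catalog.
#' @param truth planted-effect registry (gains an `expr` component).
#' @param phenotypes phenotype table (defines sample ids).
#' @param counts `strand_counts` used to compute realized methylation at the
#'   linked CpGs.
#' @param elements element table.
#' @param config a [sim_config()].
#' @return list with `expr` (genes x samples matrix), `genes` (`data.frame`
#'   with `gene_id`, `chrom`, `start`, `end`) and the updated `truth`.
#' @export
simulate_expression <- function(catalog, truth, phenotypes, counts,
                                elements, config) {
  set.seed(stage_seed(config$seed, "expression"))
  n <- nrow(phenotypes)
  ann <- annotate_cpgs(catalog, elements)
  linked_el <- elements$id[stats::runif(nrow(elements)) < config$frac_expr_linked]
  linked_el <- linked_el[linked_el %in% ann$element_id]
  m <- with_merged_proportion(counts)
  rows <- list(); genes <- list(); expr <- list()
  gi <- 0L
  for (el in linked_el) {
    cands <- which(ann$element_id == el)
    ci <- cands[which.min(abs(catalog$pos[cands] -
                                mean(catalog$pos[cands])))]
    cpg_pos <- catalog$pos[ci]
    long <- stats::runif(1) < 0.4
    d <- if (long) stats::runif(1, 2e5, 9e5) else 5e3 + stats::rexp(1, 1 / 3.3e4)
    d <- round(d) * sample(c(-1L, 1L), 1)
    glen <- round(stats::runif(1, 5e3, 3e4))
    if (d > 0) { gstart <- cpg_pos + d; gend <- gstart + glen }
    else { gend <- cpg_pos + d; gstart <- gend - glen }
    gstart <- max(0, gstart); gend <- max(gstart + 1000, min(gend, config$chrom_length))
    gi <- gi + 1L
    gid <- sprintf("gene_%04d", gi)
    mv <- m[ci, ]
    mv[is.na(mv)] <- mean(mv, na.rm = TRUE)
    expr[[gid]] <- stats::rnorm(n, 8, 1) + config$expr_effect_size * mv
    genes[[gid]] <- data.frame(gene_id = gid, chrom = "chrS",
                               start = gstart, end = gend,
                               stringsAsFactors = FALSE)
    rows[[gid]] <- data.frame(
      cpg_id = catalog$cpg_id[ci], gene_id = gid,
      element_id = el, effect = config$expr_effect_size,
      distance = abs(d), stringsAsFactors = FALSE
    )
  }
  n_null <- max(1L, length(linked_el))
  for (k in seq_len(n_null)) {
    gi <- gi + 1L
    gid <- sprintf("gene_%04d", gi)
    gstart <- sample.int(config$chrom_length - 4e4, 1)
    genes[[gid]] <- data.frame(gene_id = gid, chrom = "chrS",
                               start = gstart,
                               end = gstart + round(stats::runif(1, 5e3, 3e4)),
                               stringsAsFactors = FALSE)
    expr[[gid]] <- stats::rnorm(n, 8, 1)
  }
  expr <- do.call(rbind, expr)
  colnames(expr) <- phenotypes$sample_id
  truth$expr <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(cpg_id = character(), gene_id = character(),
               element_id = character(), effect = numeric(),
               distance = numeric())
  list(expr = expr, genes = do.call(rbind, c(genes, make.row.names = FALSE)),
       truth = truth)
}

## merged methylation proportion with no QC, NA where depth 0
with_merged_proportion <- function(counts) {
  tot <- counts$total_fwd + counts$total_rev
  m <- (counts$meth_fwd + counts$meth_rev) / ifelse(tot > 0, tot, NA)
  m
}

#' Generate one complete synthetic study
#'
#' Runs every generator stage in order (elements, CpGs, phenotypes,
#' genotypes, planted truth, counts, expression, array mask) from a single
#' root seed and returns all pieces plus the ground-truth registry.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_cohort`: list with `config`,
#'   `elements`, `cpgs`, `phenotypes`, `genotypes`, `counts`, `expression`,
#'   `genes`, `truth`, `array_mask` (character vector of CpG ids).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  elements <- generate_elements(config)
  cpgs <- generate_cpgs(elements, config)
  phenotypes <- simulate_phenotypes(config)
  genotypes <- simulate_genotypes(config)
  truth <- plant_truth(cpgs, elements, genotypes, config)
  counts <- simulate_methylation_counts(cpgs, phenotypes, genotypes,
                                        truth, config)
  ex <- simulate_expression(cpgs, truth, phenotypes, counts, elements, config)
  truth <- ex$truth
  set.seed(stage_seed(config$seed, "mask"))
  ann <- annotate_cpgs(cpgs, elements)
  mask <- character(0)
  for (cl in c("LMR", "UMR")) {
    frac <- if (cl == "LMR") config$array_mask_frac_lmr else
      config$array_mask_frac_umr
    ids <- cpgs$cpg_id[!is.na(ann$element_class) & ann$element_class == cl]
    mask <- c(mask, sample(ids, round(length(ids) * frac)))
  }
  structure(
    list(config = config, elements = elements, cpgs = cpgs,
         phenotypes = phenotypes, genotypes = genotypes, counts = counts,
         expression = ex$expr, genes = ex$genes, truth = truth,
         array_mask = sort(mask)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort\n")
  cat(sprintf("  samples:  %d\n", nrow(x$phenotypes)))
  cat(sprintf("  elements: %d (%d LMR / %d UMR)\n", nrow(x$elements),
              sum(x$elements$class == "LMR"), sum(x$elements$class == "UMR")))
  cat(sprintf("  CpGs:     %d (planted lipid: %d, metQTL: %d)\n",
              nrow(x$cpgs), nrow(x$truth$lipid), nrow(x$truth$metqtl)))
  cat(sprintf("  SNPs:     %d; genes: %d\n", ncol(x$genotypes$dosage),
              nrow(x$genes)))
  invisible(x)
}

#' Simulate a matched two-tissue study for replication analyses
#'
#' Generates a discovery ("adipose") and a replication ("blood") cohort over
#' the same element/CpG catalog and planted-truth registry. Lipid effects at
#' shared elements are expressed in both tissues; effects at tissue-specific
#' elements only in the discovery tissue.
#'
#' @param config a [sim_config()] (the replication cohort reuses it with an
#'   independent sample draw).
#' @param n_replication sample size of the replication cohort.
#' @return list with `discovery` and `replication` (each a
#'   `synthetic_cohort`-like list with `counts` and `phenotypes`) plus the
#'   shared `elements`, `cpgs`, `truth`.
#' @export
simulate_tissue_pair <- function(config = sim_config(),
                                 n_replication = config$n_samples) {
  base <- simulate_cohort(config)
  cfg2 <- config
  cfg2$seed <- config$seed + 77711L
  pheno2 <- simulate_phenotypes(cfg2, n_replication)
  geno2 <- simulate_genotypes(cfg2, n_replication,
                              panel = base$genotypes$snp_info)
  counts2 <- simulate_methylation_counts(base$cpgs, pheno2, geno2,
                                         base$truth, cfg2,
                                         tissue = "blood",
                                         seed_stage = "counts")
  list(
    discovery = base,
    replication = list(config = cfg2, phenotypes = pheno2,
                       genotypes = geno2, counts = counts2),
    elements = base$elements, cpgs = base$cpgs, truth = base$truth
  )
}
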