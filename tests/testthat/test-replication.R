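mk_records <- function(df) {
  defaults <- data.frame(chrom = "chrS", flag = "", stringsAsFactors = FALSE)
  cbind(df, defaults[rep(1, nrow(df)), , drop = FALSE], row.names = NULL)
}

disc_one_region <- function() {
  mk_records(data.frame(
    cpg_id = c("c1", "c2"), pos = c(100, 150), element_id = "E1",
    trait = "TG", p_raw = c(1e-6, 1e-3), direction = c(1, 1),
    stringsAsFactors = FALSE
  ))
}

test_that("a strong same-direction replication CpG replicates the region", {
  # 10 candidate replication tests for the trait -> cutoff 0.05/10 = 5e-3;
  # the example's cutoff regime: one CpG at p = 1e-6 clears any cutoff
  repl <- mk_records(data.frame(
    cpg_id = sprintf("r%02d", 1:10), pos = 1:10 * 10,
    element_id = c("E1", rep("EX", 9)), trait = "TG",
    p_raw = c(1e-6, runif(9, 0.2, 1)), direction = 1,
    stringsAsFactors = FALSE
  ))
  out <- replicate_regions(disc_one_region(), repl)
  e1 <- out[out$element_id == "E1", ]
  expect_equal(e1$class, "replicated_same_direction")
  expect_equal(e1$discovery_top_cpg, "c1")
  # flip the sign: opposite-direction class
  repl$direction[1] <- -1
  out2 <- replicate_regions(disc_one_region(), repl)
  expect_equal(out2$class[out2$element_id == "E1"],
               "replicated_opposite_direction")
})

test_that("regions without replication CpGs are untestable; weak ones not replicated", {
  repl <- mk_records(data.frame(
    cpg_id = "r1", pos = 10, element_id = "EX", trait = "TG",
    p_raw = 0.5, direction = 1, stringsAsFactors = FALSE
  ))
  out <- replicate_regions(disc_one_region(), repl)
  expect_equal(out$class[out$element_id == "E1"], "untestable")
  repl2 <- mk_records(data.frame(
    cpg_id = "r1", pos = 10, element_id = "E1", trait = "TG",
    p_raw = 0.3, direction = 1, stringsAsFactors = FALSE
  ))
  out2 <- replicate_regions(disc_one_region(), repl2)
  expect_equal(out2$class[out2$element_id == "E1"], "not_replicated")
})

test_that("replication classes partition testable regions and tighten monotonically", {
  set.seed(21)
  n_reg <- 30
  disc <- mk_records(data.frame(
    cpg_id = sprintf("d%02d", 1:n_reg), pos = 1:n_reg * 100,
    element_id = sprintf("E%02d", 1:n_reg), trait = "TG",
    p_raw = runif(n_reg, 1e-8, 1e-4), direction = sample(c(-1, 1), n_reg, TRUE),
    stringsAsFactors = FALSE
  ))
  has_repl <- rbinom(n_reg, 1, 0.8) == 1
  repl <- mk_records(data.frame(
    cpg_id = sprintf("r%02d", 1:n_reg), pos = 1:n_reg * 100 + 5,
    element_id = sprintf("E%02d", 1:n_reg), trait = "TG",
    p_raw = 10^runif(n_reg, -9, -0.1), direction = sample(c(-1, 1), n_reg, TRUE),
    stringsAsFactors = FALSE
  ))[has_repl, ]
  out <- replicate_regions(disc, repl, alpha = 0.05)
  tab <- table(factor(out$class, levels = c(
    "replicated_same_direction", "replicated_opposite_direction",
    "not_replicated", "untestable")))
  expect_equal(sum(tab[1:3]), sum(has_repl))
  expect_equal(unname(tab[["untestable"]]), sum(!has_repl))
  # tightening alpha never creates replications
  out_tight <- replicate_regions(disc, repl, alpha = 0.005)
  gained <- out_tight$class %in% c("replicated_same_direction",
                                   "replicated_opposite_direction") &
    out$class == "not_replicated"
  expect_false(any(gained))
})

test_that("per-region Bonferroni denominators are laxer than scan-wide ones", {
  disc <- disc_one_region()
  repl <- mk_records(data.frame(
    cpg_id = sprintf("r%02d", 1:40), pos = 1:40 * 10,
    element_id = c("E1", rep("EX", 39)), trait = "TG",
    p_raw = c(0.03, runif(39, 0.5, 1)), direction = 1,
    stringsAsFactors = FALSE
  ))
  # p = 0.03 fails 0.05/40 but passes 0.05/1 (single in-region test)
  wide <- replicate_regions(disc, repl, denominator = "all")
  local <- replicate_regions(disc, repl, denominator = "per_region")
  expect_equal(wide$class[wide$element_id == "E1"], "not_replicated")
  expect_equal(local$class[local$element_id == "E1"],
               "replicated_same_direction")
})

test_that("rate contrasts reproduce the printed cross-tissue replication rates", {
  rc <- replication_rate_contrast(46, 340, 12, 225)
  expect_equal(rc$rate_a_pct, 14)
  expect_equal(rc$rate_b_pct, 5)
  expect_lt(rc$p_binomial, 0.01)
  rc2 <- replication_rate_contrast(17, 46, 5, 28)
  expect_gte(rc2$ratio, 2)
  rc3 <- replication_rate_contrast(10, 50, 10, 50)
  expect_equal(rc3$ratio, 1.0)
  expect_error(replication_rate_contrast(0, 0, 1, 10), "empty")
})

test_that("fine-mapping verdicts compare non-overlapping CpGs against the array CpG", {
  el <- data.frame(chrom = "chrS", start = 0, end = 1000, id = "E1",
                   class = "LMR", specificity = "shared", tss = NA,
                   tss_strand = NA, bivalent = FALSE,
                   stringsAsFactors = FALSE)
  disc <- mk_records(data.frame(
    cpg_id = c("c1", "c2"), pos = c(400, 500), element_id = "E1",
    trait = "TG", p_raw = c(1e-4, 1e-6), direction = 1,
    stringsAsFactors = FALSE
  ))
  # array CpG overlaps c1 (p = 1e-4); c2 is stronger -> refined
  out <- fine_map_contrast(disc, c(E1 = 400), el)
  expect_true(out$refined)
  expect_equal(out$best_other_cpg, "c2")
  expect_equal(out$best_other_band, "midpoint")  # pos 500 = midpoint
  # overlapping CpG is itself the strongest -> not refined
  out2 <- fine_map_contrast(disc, c(E1 = 500), el)
  expect_false(out2$refined)
  # single-CpG regions are skipped
  out3 <- fine_map_contrast(disc[1, ], c(E1 = 400), el)
  expect_equal(nrow(out3), 0)
})

test_that("positional bands split LMR midpoints from UMR bimodal flanks", {
  el <- data.frame(chrom = "chrS", start = 0, end = 1000, id = "U1",
                   class = "UMR", specificity = "shared", tss = 500,
                   tss_strand = "+", bivalent = FALSE,
                   stringsAsFactors = FALSE)
  disc <- mk_records(data.frame(
    cpg_id = c("c1", "c2"), pos = c(500, 200), element_id = "U1",
    trait = "TG", p_raw = c(1e-3, 1e-7), direction = 1,
    stringsAsFactors = FALSE
  ))
  out <- fine_map_contrast(disc, c(U1 = 500), el)
  # pos 200 -> pos_pct = -30: inside the UMR bimodal band
  expect_equal(out$best_other_band, "bimodal")
})

test_that("planted shared-tissue effects replicate at a higher rate than specific ones", {
  cfg <- sim_config(n_samples = 150, n_elements_lmr = 150,
                    n_elements_umr = 100, frac_lipid_cpgs = 0.04,
                    effect_size_logit = 0.6, frac_metqtl_cpgs = 0,
                    frac_adipose_specific = 0.5, seed = 77)
  pair <- simulate_tissue_pair(cfg)
  qc_d <- qc_matrix(list(counts = pair$discovery$counts), 100)
  qc_r <- qc_matrix(list(counts = pair$replication$counts), 100)
  ann <- annotate_cpgs(pair$cpgs, pair$elements)
  join <- function(ew) {
    ew$element_id <- ann$element_id[match(ew$cpg_id, ann$cpg_id)]
    ew
  }
  ew_d <- join(run_ewas(qc_d, pair$discovery$phenotypes))
  ew_r <- join(run_ewas(qc_r, pair$replication$phenotypes))
  li <- pair$truth$lipid
  cand <- unique(li[, c("element_id", "trait", "tissue")])
  disc <- ew_d[!is.na(ew_d$element_id) &
                 paste(ew_d$element_id, ew_d$trait) %in%
                 paste(cand$element_id, cand$trait), ]
  out <- replicate_regions(disc, ew_r)
  shared_ids <- cand$element_id[cand$tissue == "both"]
  spec_ids <- cand$element_id[cand$tissue == "adipose"]
  ts <- tally_replication(out, shared_ids)
  tp <- tally_replication(out, spec_ids)
  expect_gt(ts$k / ts$n, tp$k / tp$n)
})
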