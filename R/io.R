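write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the standard file set: `cpg_counts.tsv` (long per-strand counts,
#' zero-depth entries omitted), `elements.bed` (BED6 plus class,
#' specificity, tss, tss_strand, bivalent), `phenotypes.tsv`,
#' `genotypes.tsv` (dosage matrix with SNP metadata), `expression.tsv`,
#' `genes.bed`, `array_mask.txt` and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cts <- cohort$counts
  long <- function(strand, meth, total) {
    idx <- which(total > 0, arr.ind = TRUE)
    data.frame(
      chrom = cts$cpgs$chrom[idx[, 1]],
      pos = cts$cpgs$pos[idx[, 1]],
      sample = cts$samples[idx[, 2]],
      strand = strand,
      meth_reads = meth[idx],
      total_reads = total[idx],
      stringsAsFactors = FALSE
    )
  }
  counts_long <- rbind(long("+", cts$meth_fwd, cts$total_fwd),
                       long("-", cts$meth_rev, cts$total_rev))
  counts_long <- counts_long[order(counts_long$pos, counts_long$sample,
                                   counts_long$strand), ]
  paths <- c(
    counts = file.path(outdir, "cpg_counts.tsv"),
    elements = file.path(outdir, "elements.bed"),
    phenotypes = file.path(outdir, "phenotypes.tsv"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    genes = file.path(outdir, "genes.bed"),
    mask = file.path(outdir, "array_mask.txt"),
    truth = file.path(outdir, "truth.json")
  )
  write_tsv(counts_long, paths["counts"])
  el <- cohort$elements
  bed <- data.frame(chrom = el$chrom, start = el$start, end = el$end,
                    name = el$id, score = 0,
                    strand = ifelse(is.na(el$tss_strand), ".", el$tss_strand),
                    class = el$class, specificity = el$specificity,
                    tss = ifelse(is.na(el$tss), ".", el$tss),
                    tss_strand = ifelse(is.na(el$tss_strand), ".",
                                        el$tss_strand),
                    bivalent = as.integer(el$bivalent),
                    stringsAsFactors = FALSE)
  write_tsv(bed, paths["elements"])
  write_tsv(cohort$phenotypes, paths["phenotypes"])
  geno <- cbind(cohort$genotypes$snp_info,
                as.data.frame(t(cohort$genotypes$dosage)))
  write_tsv(geno, paths["genotypes"])
  expr <- data.frame(gene_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, paths["expression"])
  write_tsv(cohort$genes, paths["genes"])
  writeLines(cohort$array_mask, paths["mask"])
  jsonlite::write_json(
    list(lipid = cohort$truth$lipid, metqtl = cohort$truth$metqtl,
         expr = cohort$truth$expr),
    paths["truth"], dataframe = "columns", digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Read a cohort back from [write_cohort()] output
#'
#' @param dir directory holding the cohort files.
#' @return list with the same components as a `synthetic_cohort` (minus the
#'   config): `counts` (`strand_counts`), `elements`, `phenotypes`,
#'   `genotypes`, `expression`, `genes`, `array_mask`, `truth`.
#' @export
read_cohort <- function(dir) {
  counts_long <- read_tsv(file.path(dir, "cpg_counts.tsv"))
  pheno <- read_tsv(file.path(dir, "phenotypes.tsv"))
  pos <- sort(unique(counts_long$pos))
  samples <- pheno$sample_id
  cpgs <- data.frame(chrom = "chrS", pos = pos,
                     cpg_id = sprintf("cpg_%07d", pos),
                     stringsAsFactors = FALSE)
  mk <- function(strand, col) {
    m <- matrix(0L, length(pos), length(samples),
                dimnames = list(cpgs$cpg_id, samples))
    d <- counts_long[counts_long$strand == strand, ]
    m[cbind(match(d$pos, pos), match(d$sample, samples))] <- d[[col]]
    m
  }
  counts <- structure(
    list(meth_fwd = mk("+", "meth_reads"), total_fwd = mk("+", "total_reads"),
         meth_rev = mk("-", "meth_reads"), total_rev = mk("-", "total_reads"),
         cpgs = cpgs, samples = samples),
    class = "strand_counts"
  )
  bed <- read_tsv(file.path(dir, "elements.bed"))
  elements <- data.frame(
    chrom = bed$chrom, start = bed$start, end = bed$end, id = bed$name,
    class = bed$class, specificity = bed$specificity,
    tss = suppressWarnings(as.numeric(ifelse(bed$tss == ".", NA, bed$tss))),
    tss_strand = ifelse(bed$tss_strand == ".", NA, bed$tss_strand),
    bivalent = as.logical(bed$bivalent), stringsAsFactors = FALSE
  )
  geno_raw <- read_tsv(file.path(dir, "genotypes.tsv"), check.names = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "maf")
  dosage <- t(as.matrix(geno_raw[, setdiff(names(geno_raw), meta_cols)]))
  colnames(dosage) <- geno_raw$snp_id
  expr_raw <- read_tsv(file.path(dir, "expression.tsv"), check.names = FALSE)
  expression <- as.matrix(expr_raw[, -1])
  rownames(expression) <- expr_raw$gene_id
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(
    counts = counts, elements = elements, phenotypes = pheno,
    genotypes = list(dosage = dosage,
                     snp_info = geno_raw[, meta_cols]),
    expression = expression, genes = read_tsv(file.path(dir, "genes.bed")),
    array_mask = readLines(file.path(dir, "array_mask.txt")),
    truth = truth
  )
}
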