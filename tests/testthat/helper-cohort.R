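# Small study configurations used across tests. Sizes are scaled down from
# the default study design to keep unit tests fast; the acceptance suite
# uses the full default design where a criterion requires it.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_samples = 60, n_elements_lmr = 40, n_elements_umr = 25,
             n_snps = 80, seed = seed, ...)
}

# ~2000-CpG single-purpose null cohort: no planted effects, pure binomial
null_config <- function(seed = 1, n_samples = 200, rho = 0) {
  sim_config(n_samples = n_samples, n_elements_lmr = 65, n_elements_umr = 42,
             beta_dispersion = rho, frac_lipid_cpgs = 0, frac_metqtl_cpgs = 0,
             frac_expr_linked = 0, background_cpg_frac = 0, n_snps = 50,
             seed = seed)
}

qc_matrix <- function(cohort, min_individuals = 40) {
  m <- apply_min_coverage(merge_strands(cohort$counts), 5)
  filter_sites(m, min_individuals = min_individuals)$mat
}

# strand_counts object from explicit per-strand count matrices
make_counts <- function(meth_fwd, total_fwd, meth_rev, total_rev,
                        pos = NULL) {
  n_cpg <- nrow(meth_fwd)
  if (is.null(pos)) pos <- seq_len(n_cpg) * 100L
  cpgs <- data.frame(chrom = "chrS", pos = pos,
                     cpg_id = sprintf("cpg_%07d", pos),
                     stringsAsFactors = FALSE)
  samples <- sprintf("S%03d", seq_len(ncol(meth_fwd)))
  for (m in list(meth_fwd, total_fwd, meth_rev, total_rev)) {
    stopifnot(all(dim(m) == dim(meth_fwd)))
  }
  structure(
    list(meth_fwd = meth_fwd, total_fwd = total_fwd,
         meth_rev = meth_rev, total_rev = total_rev,
         cpgs = cpgs, samples = samples),
    class = "strand_counts"
  )
}

# independent maximum-likelihood oracle for the coverage-weighted binomial
# fit: direct optimization of the weighted log-likelihood with numerical
# derivatives, no IRLS anywhere
ml_binomial_oracle <- function(y, w, X) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  gr <- function(b) {
    mu <- plogis(drop(X %*% b))
    -drop(crossprod(X, w * (y - mu)))
  }
  fit <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  fit$par
}

# brute-force two-sided Fisher oracle: log-binomial-coefficient arithmetic,
# no dhyper
fisher_oracle <- function(a, b, c, d) {
  k <- a + c
  lo <- max(0, k - d); hi <- min(k, b)
  xs <- lo:hi
  logp <- lchoose(b, xs) + lchoose(d, k - xs) - lchoose(b + d, k)
  obs <- logp[xs == a]
  sum(exp(logp[logp <= obs + 1e-7 * abs(obs) + 1e-12]))
}
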