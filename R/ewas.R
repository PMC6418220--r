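#' Prepare a lipid trait for association testing
#'
#' Applies the configured transform (log for right-skewed traits such as
#' triglycerides), removes outliers beyond mean +/- 3 SD of the transformed
#' vector (computed once, never re-applied to the trimmed set), and
#' standardizes the surviving values to mean 0, SD 1.
#'
#' @param raw numeric trait values (may contain NA).
#' @param transform `"identity"` or `"log"`.
#' @return object of class `trait_vector`: list with `values` (standardized,
#'   NA where missing or trimmed), `outlier_mask` (TRUE = kept),
#'   `transform`, `n_used`.
#' @export
prepare_trait <- function(raw, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  stop_if_not(sum(!is.na(raw)) >= 10,
              "need at least 10 non-missing trait values")
  x <- raw
  if (transform == "log") {
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop(sprintf("log transform undefined for non-positive values at: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    x <- log(x)
  }
  mu <- mean(x, na.rm = TRUE)
  sdv <- stats::sd(x, na.rm = TRUE)
  keep <- !is.na(x) & abs(x - mu) <= 3 * sdv
  v <- ifelse(keep, x, NA)
  v <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  structure(
    list(values = v, outlier_mask = keep & !is.na(raw),
         transform = transform, n_used = sum(keep)),
    class = "trait_vector"
  )
}

#' Coverage-weighted binomial regression for one CpG
#'
#' Fits a binomial GLM with logit link to methylation proportions, weighted
#' by the total read coverage at the site, by iteratively reweighted least
#' squares (gradient tolerance 1e-8, at most 50 iterations), and reports the
#' Wald two-sided p-value for the trait coefficient. Degenerate inputs
#' (constant methylation, too few samples, non-convergence/separation) give
#' a flagged record with missing z rather than an error.
#'
#' @param m methylation proportions (one CpG, one value per sample; NA =
#'   missing).
#' @param coverage total reads per sample (the binomial weights).
#' @param X design matrix including an intercept and the trait column.
#' @param trait_col name or index of the trait column in `X`.
#' @param min_n minimum usable samples; defaults to `ncol(X) + 5`. Pass a
#'   smaller value only for closed-form checks on pooled count groups.
#' @return one-row `data.frame`: `beta`, `se`, `z`, `p_raw`, `n_used`,
#'   `direction`, `flag` ("" if clean).
#' @export
fit_weighted_binomial <- function(m, coverage, X, trait_col = "trait",
                                  min_n = NULL) {
  use <- !is.na(m) & !is.na(coverage) & coverage > 0 &
    stats::complete.cases(X)
  rec <- function(beta = NA_real_, se = NA_real_, z = NA_real_,
                  p = NA_real_, n = sum(use), flag = "") {
    data.frame(beta = beta, se = se, z = z, p_raw = p, n_used = n,
               direction = ifelse(is.na(beta), NA_real_, sign(beta)),
               flag = flag, stringsAsFactors = FALSE)
  }
  Xu <- X[use, , drop = FALSE]
  mu_ <- m[use]; wu <- coverage[use]
  p_cols <- ncol(X)
  if (is.null(min_n)) min_n <- p_cols + 5
  if (sum(use) < max(min_n, p_cols)) return(rec(flag = "too_few_samples"))
  tc <- if (is.character(trait_col)) match(trait_col, colnames(X)) else trait_col
  if (p_cols > 1 && length(unique(Xu[, tc])) < 2) {
    return(rec(flag = "constant_trait"))
  }
  if (all(mu_ == 0) || all(mu_ == 1)) return(rec(flag = "degenerate"))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      x = Xu, y = mu_, weights = wu, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 50)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || any(is.na(fit$coefficients))) {
    return(rec(flag = "non_converged"))
  }
  W <- fit$weights                       # IRLS working weights at optimum
  XtWX <- crossprod(Xu * sqrt(W))
  cov_beta <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov_beta)) return(rec(flag = "singular"))
  beta <- fit$coefficients[tc]
  se <- sqrt(cov_beta[tc, tc])
  if (!is.finite(se) || se <= 0 || abs(beta) > 15 ||
      abs(beta) / max(se, 1e-12) > 1e3) {
    return(rec(flag = "separation"))
  }
  z <- beta / se
  rec(beta = unname(beta), se = se, z = unname(z),
      p = 2 * stats::pnorm(-abs(z)))
}

## Build the covariate design matrix: age, sex, BMI, batch, cell
## proportions with one column dropped (simplex collinearity).
build_design <- function(phenotypes, use_cells = TRUE) {
  df <- data.frame(
    age = phenotypes$age,
    sex = as.integer(phenotypes$sex == "F"),
    BMI = phenotypes$BMI,
    batch = as.integer(phenotypes$batch == levels(factor(phenotypes$batch))[1])
  )
  if (use_cells && all(paste0("cell", 1:5) %in% names(phenotypes))) {
    df <- cbind(df, phenotypes[, paste0("cell", 2:5)])
  }
  keep <- vapply(df, function(x) stats::var(x, na.rm = TRUE) > 0, logical(1))
  X <- cbind(`(Intercept)` = 1, trait = NA_real_,
             as.matrix(df[, keep, drop = FALSE]))
  X
}

#' Epigenome-wide association of methylation with lipid traits
#'
#' Runs the coverage-weighted binomial regression at every kept CpG for each
#' requested lipid trait, restricting each fit to the samples covered at
#' that CpG. Results are ordered deterministically by (chrom, pos, trait).
#'
#' @param mat a QC'd `meth_matrix`.
#' @param phenotypes phenotype table with trait and covariate columns.
#' @param traits character vector of trait columns to test (default the four
#'   lipids TG, HDL, LDL, TC).
#' @param transforms named list/character of per-trait transforms; traits not
#'   named use `"identity"` (TG defaults to `"log"`).
#' @param use_cells include cell-proportion covariates if present.
#' @param min_samples minimum covered samples per fit (on top of the
#'   rank + 5 rule).
#' @return object of class `ewas_result`: `data.frame` with one row per
#'   (CpG, trait): `cpg_id`, `chrom`, `pos`, `trait`, `beta`, `se`, `z`,
#'   `p_raw`, `n_used`, `direction`, `flag`.
#' @export
run_ewas <- function(mat, phenotypes, traits = TRAITS,
                     transforms = c(TG = "log"),
                     use_cells = TRUE, min_samples = 20) {
  if (nrow(mat$m) == 0) {
    warning("no CpGs passed QC; returning empty result")
    return(structure(empty_ewas(), class = c("ewas_result", "data.frame")))
  }
  stop_if_not(all(mat$samples == phenotypes$sample_id),
              "sample ids of matrix and phenotypes disagree")
  X0 <- build_design(phenotypes, use_cells = use_cells)
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    tf <- if (tr %in% names(transforms)) transforms[[tr]] else "identity"
    tv <- prepare_trait(phenotypes[[tr]], tf)
    X <- X0
    X[, "trait"] <- tv$values
    recs <- fit_cpg_block(mat$m, mat$coverage, X, 2L, min_samples)
    out[[ti]] <- cbind(
      data.frame(cpg_id = mat$cpgs$cpg_id, chrom = mat$cpgs$chrom,
                 pos = mat$cpgs$pos, trait = tr, stringsAsFactors = FALSE),
      recs
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$trait), ]
  rownames(res) <- NULL
  structure(res, class = c("ewas_result", "data.frame"))
}

## Binomial-logit IRLS with prior (coverage) weights. Newton scoring on the
## working response, deviance-change tolerance 1e-8, at most 50 sweeps —
## the same optimum glm.fit reaches (cross-checked in the tests), with the
## per-fit overhead stripped for the epigenome-wide loop.
irls_binomial <- function(Xu, y, w, tol = 1e-8, maxit = 50L) {
  eta <- rep(stats::qlogis((sum(w * y) + 0.5) / (sum(w) + 1)), length(y))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    varmu <- mu * (1 - mu)
    varmu[varmu < 1e-10] <- 1e-10
    wk <- w * varmu
    zv <- eta + (y - mu) / varmu
    sw <- sqrt(wk)
    fit <- .lm.fit(Xu * sw, zv * sw)
    if (anyNA(fit$coefficients) || fit$rank < ncol(Xu)) {
      return(list(flag = "singular"))
    }
    beta <- fit$coefficients[order(fit$pivot)]
    eta <- drop(Xu %*% beta)
    # binomial deviance up to a beta-free constant
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (is.finite(dev_old) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) return(list(flag = "non_converged"))
  varmu <- pmax(mu * (1 - mu), 1e-10)
  cov_beta <- tryCatch(chol2inv(chol(crossprod(Xu * sqrt(w * varmu)))),
                       error = function(e) NULL)
  if (is.null(cov_beta)) return(list(flag = "singular"))
  list(beta = beta, se = sqrt(diag(cov_beta)), flag = NULL)
}

## IRLS sweep over the rows of a methylation matrix. Same model and flags
## as fit_weighted_binomial (which remains the single-CpG reference path);
## assembles plain vectors instead of per-CpG data.frames.
fit_cpg_block <- function(M, Cov, X, trait_idx, min_samples) {
  n_cpg <- nrow(M)
  okX <- stats::complete.cases(X)
  beta <- se <- z <- p <- rep(NA_real_, n_cpg)
  n_used <- integer(n_cpg)
  flag <- character(n_cpg)
  p_cols <- ncol(X)
  for (i in seq_len(n_cpg)) {
    mi <- M[i, ]; ci <- Cov[i, ]
    use <- okX & !is.na(mi) & !is.na(ci) & ci > 0
    nu <- sum(use)
    n_used[i] <- nu
    if (nu < max(p_cols + 5, min_samples)) { flag[i] <- "too_few_samples"; next }
    yu <- mi[use]
    if (all(yu == 0) || all(yu == 1)) { flag[i] <- "degenerate"; next }
    Xu <- X[use, , drop = FALSE]
    if (length(unique(Xu[, trait_idx])) < 2) { flag[i] <- "constant_trait"; next }
    fit <- irls_binomial(Xu, yu, ci[use])
    if (!is.null(fit$flag)) { flag[i] <- fit$flag; next }
    b <- fit$beta[trait_idx]
    s <- fit$se[trait_idx]
    if (!is.finite(s) || s <= 0 || abs(b) > 15 ||
        abs(b) / max(s, 1e-12) > 1e3) {
      flag[i] <- "separation"; next
    }
    beta[i] <- b; se[i] <- s; z[i] <- b / s
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(beta = beta, se = se, z = z, p_raw = p, n_used = n_used,
             direction = ifelse(is.na(beta), NA_real_, sign(beta)),
             flag = flag, stringsAsFactors = FALSE)
}

empty_ewas <- function() {
  data.frame(cpg_id = character(), chrom = character(), pos = numeric(),
             trait = character(), beta = numeric(), se = numeric(),
             z = numeric(), p_raw = numeric(), n_used = integer(),
             direction = numeric(), flag = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.ewas_result <- function(x, ...) {
  fitted <- sum(x$flag == "")
  cat(sprintf("EWAS result: %d records (%d fitted, %d flagged) over %d traits\n",
              nrow(x), fitted, nrow(x) - fitted,
              length(unique(x$trait))))
  if ("q" %in% names(x)) {
    cat(sprintf("  significant at FDR 10%%: %d\n", sum(x$q < 0.10, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.ewas_result <- function(object, ...) {
  by_trait <- split(object, object$trait)
  out <- do.call(rbind, lapply(names(by_trait), function(tr) {
    d <- by_trait[[tr]]
    data.frame(
      trait = tr, n_records = nrow(d), n_fitted = sum(d$flag == ""),
      lambda_raw = if (any(d$flag == ""))
        genomic_inflation_lambda(d$z[d$flag == ""]) else NA_real_,
      n_fdr10 = if ("q" %in% names(d)) sum(d$q < 0.10, na.rm = TRUE) else NA_integer_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
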