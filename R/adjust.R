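#' Estimate the empirical null of a z-score vector
#'
#' Fits a three-component Gaussian mixture
#' `w0 N(mu0, sigma0^2) + w1 N(mu1, sigma1^2) + w2 N(mu2, sigma2^2)`
#' by constrained EM, where the null component is the dominant, central one
#' (`mu1 < mu0 < mu2`, `w0` maximal). `mu0` is the bias and `sigma0` the
#' inflation of the test statistics; the two flanking components absorb true
#' signal. Initialization is deterministic (median/MAD for the null,
#' quantile-anchored tails), so the fit carries no hidden randomness. On
#' non-convergence after `max_iter` sweeps the estimator falls back to the
#' median/MAD of the input with a warning flag.
#'
#' @param z finite z-scores (at least 500).
#' @param max_iter maximum EM sweeps (default 500).
#' @param tol convergence tolerance on the mean log-likelihood.
#' @return object of class `empirical_null`: list with `mu0`, `sigma0`,
#'   `w0`, `components` (3x3 matrix of w/mu/sigma), `loglik`, `n_iter`,
#'   `converged`, `fallback`.
#' @export
estimate_empirical_null <- function(z, max_iter = 500, tol = 1e-8) {
  z <- z[is.finite(z)]
  stop_if_not(length(z) >= 500,
              "need at least 500 finite z-scores to estimate the null")
  med <- stats::median(z)
  madv <- stats::mad(z)
  if (madv <= 0) madv <- stats::sd(z)
  w <- c(0.90, 0.05, 0.05)
  mu <- c(med, med - 3 * madv, med + 3 * madv)
  sg <- c(madv, madv, madv)
  n <- length(z)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  # fixed identifiability bounds: the flanking (signal) components may not
  # move inside median +/- 3 MAD of the input, nor collapse to spikes.
  # Without these bounds a flank can sit on top of the null and the
  # likelihood develops a flat ridge the EM crawls along forever; with
  # bounds fixed in advance the projected EM has a fixed constraint set
  # and converges like ordinary EM.
  lo <- med - 3 * madv
  hi <- med + 3 * madv
  for (iter in seq_len(max_iter)) {
    par_old <- c(w, mu, sg)
    dens <- vapply(1:3, function(k) w[k] * stats::dnorm(z, mu[k], sg[k]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- mean(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    for (k in 1:3) {
      if (nk[k] < 1e-8) next
      mu[k] <- sum(r[, k] * z) / nk[k]
      sg[k] <- sqrt(sum(r[, k] * (z - mu[k])^2) / nk[k])
      sg[k] <- max(sg[k], 1e-3)
    }
    mu[2] <- min(mu[2], lo)
    mu[3] <- max(mu[3], hi)
    sg[2] <- max(sg[2], 0.5 * madv)
    sg[3] <- max(sg[3], 0.5 * madv)
    if (abs(ll - ll_old) < tol ||
        max(abs(c(w, mu, sg) - par_old)) < 1e-7) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  fallback <- FALSE
  if (!converged) {
    warning("empirical-null EM did not converge; falling back to median/MAD")
    mu[1] <- med; sg[1] <- madv; w <- c(1, 0, 0)
    fallback <- TRUE
  } else if (w[1] < max(w[2], w[3])) {
    # enforce the dominance constraint: the null is the heaviest component,
    # flanks relabelled by mean around it
    k <- which.max(w)
    ordk <- c(k, setdiff(1:3, k))
    w <- w[ordk]; mu <- mu[ordk]; sg <- sg[ordk]
    if (mu[2] > mu[3]) {
      w[2:3] <- w[3:2]; mu[2:3] <- mu[3:2]; sg[2:3] <- sg[3:2]
    }
  }
  comp <- rbind(w = w, mu = mu, sigma = sg)
  colnames(comp) <- c("null", "lower", "upper")
  structure(
    list(mu0 = mu[1], sigma0 = sg[1], w0 = w[1], components = comp,
         loglik = ll_old, n_iter = iter, converged = converged,
         fallback = fallback),
    class = "empirical_null"
  )
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf(
    "Empirical null: bias mu0 = %.4f, inflation sigma0 = %.4f (w0 = %.3f)%s\n",
    x$mu0, x$sigma0, x$w0,
    if (x$fallback) " [median/MAD fallback]" else ""))
  invisible(x)
}

#' Recalibrate z-scores against an empirical null
#'
#' `z' = (z - mu0) / sigma0`, with two-sided normal-tail p-values of the
#' corrected statistics.
#'
#' @param z raw z-scores (NA passed through).
#' @param null an `empirical_null`.
#' @return list with `z` (corrected) and `p` (corrected two-sided p).
#' @export
correct_statistics <- function(z, null) {
  stop_if_not(is.finite(null$sigma0) && null$sigma0 > 0,
              "null inflation sigma0 must be positive")
  zc <- (z - null$mu0) / null$sigma0
  list(z = zc, p = 2 * stats::pnorm(-abs(zc)))
}

#' Genomic inflation factor
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)`; 1.0 indicates calibrated
#' statistics.
#'
#' @param z z-scores (NA dropped).
#' @return the inflation factor, a single number.
#' @export
genomic_inflation_lambda <- function(z) {
  z <- z[is.finite(z)]
  stop_if_not(length(z) > 0, "cannot compute lambda of an empty vector")
  stats::median(z^2) / stats::qchisq(0.5, df = 1)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 with a cubic smoother evaluated at 0.95, then computes
#' `q_i = pi0 * min_{p_j >= p_i} (p_j * m / rank_j)`. pi0 falls back to 1
#' when the estimate exceeds 1 or fewer than 100 p-values are supplied
#' (in which case q-values coincide with Benjamini-Hochberg).
#'
#' @param p p-values in (0, 1].
#' @param pi0 optionally pin pi0 (e.g. `pi0 = 1` for plain BH).
#' @return list with `q` (same order as `p`), `pi0`, and `fdr_cutoffs`
#'   (largest p called significant at FDR 5% and 10%, NA if none).
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  stop_if_not(all(is.finite(p)) && all(p > 0) && all(p <= 1),
              "p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = 0.95)$y
      if (!is.finite(pi0) || pi0 > 1) pi0 <- 1
      pi0 <- max(pi0, 1 / m)
    }
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * p[o] * m / rank(p, ties.method = "max")[o]
  q <- cummin(q)
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  cut5 <- suppressWarnings(max(p[out < 0.05]))
  cut10 <- suppressWarnings(max(p[out < 0.10]))
  list(q = out, pi0 = pi0,
       fdr_cutoffs = c(fdr5 = if (is.finite(cut5)) cut5 else NA_real_,
                       fdr10 = if (is.finite(cut10)) cut10 else NA_real_))
}

#' Per-trait Bonferroni threshold
#'
#' @param n_tests number of tests for one trait.
#' @param alpha family-wise error level (default 0.05).
#' @return the p-value cutoff `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stop_if_not(is_count(n_tests) && n_tests > 0, "n_tests must be positive")
  alpha / n_tests
}

#' Empirical-null correction and FDR for a full EWAS result
#'
#' Per trait: estimates the empirical null from the fitted z-scores, adds
#' corrected z and p columns, and computes Storey q-values over the clean
#' (non-flagged) records. Flagged records are excluded from the FDR
#' denominator and carry NA q.
#'
#' @param ewas an `ewas_result`.
#' @return the `ewas_result` with added columns `z_corrected`,
#'   `p_corrected`, `q`, and attributes `null_fits` (per-trait
#'   `empirical_null`) and `lambdas` (per-trait raw/corrected inflation).
#' @export
adjust_ewas <- function(ewas) {
  traits <- unique(ewas$trait)
  ewas$z_corrected <- NA_real_
  ewas$p_corrected <- NA_real_
  ewas$q <- NA_real_
  nulls <- list()
  lambdas <- list()
  for (tr in traits) {
    sel <- ewas$trait == tr & ewas$flag == "" & is.finite(ewas$z)
    z <- ewas$z[sel]
    nf <- estimate_empirical_null(z)
    cs <- correct_statistics(z, nf)
    ewas$z_corrected[sel] <- cs$z
    ewas$p_corrected[sel] <- cs$p
    qv <- storey_qvalues(cs$p)
    ewas$q[sel] <- qv$q
    nulls[[tr]] <- nf
    lambdas[[tr]] <- c(raw = genomic_inflation_lambda(z),
                       corrected = genomic_inflation_lambda(cs$z))
  }
  attr(ewas, "null_fits") <- nulls
  attr(ewas, "lambdas") <- lambdas
  ewas
}
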