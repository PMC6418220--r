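#' @keywords internal
"_PACKAGE"

## Half-up decimal rounding, used wherever fold changes and rates are
## reported at a fixed printed precision (R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prop <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

## Deterministic per-stage seed derived from one root seed: offsets keep
## every substream below 2^31 and distinct across stage names.
stage_seed <- function(root_seed, stage) {
  offs <- c(
    simulate = 101L, phenotypes = 211L, genotypes = 307L, elements = 401L,
    cpgs = 503L, counts = 601L, expression = 701L, mask = 809L,
    qc = 907L, ewas = 1009L, adjust = 1103L, annotate = 1201L,
    replicate = 1301L, integrate = 1409L, report = 1511L
  )
  o <- offs[[stage]]
  if (is.null(o)) o <- sum(utf8ToInt(stage)) %% 1000L
  (as.integer(root_seed) %% 2000000000L) + o
}

## Dirichlet draws via independent gammas; rows sum to one exactly.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
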