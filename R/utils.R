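## Internal helpers shared across modules.

#' Evaluate an expression under a local, restored RNG state
#'
#' All stochastic operations in mloykit take an explicit `seed` argument and
#' are evaluated through this helper, so the caller's global random state is
#' never consumed or disturbed.
#'
#' @param seed integer seed; must be a finite scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## derive a stream-specific child seed (kept well below .Machine$integer.max)
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream)) %% 2147483L + stream
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single finite value in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Used by [dge_loy_vs_wt()].  For small groups (both arms of size
#' `exact_max` or less) the permutation null of the rank-sum statistic is
#' enumerated in full (midranks, so ties are handled exactly); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.  The two-sided p-value is defined as the permutation probability of
#' a rank sum at least as far from its null mean as observed.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max use full enumeration when `length(x)` and `length(y)` are
#'   both at most this value.
#' @return list with `statistic` (rank sum of `x`) and `p_value`.
#' @export
ranksum_test <- function(x, y, exact_max = 10L) {
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (m + n + 1) / 2
  if (m <= exact_max && n <= exact_max) {
    idx <- combn(m + n, m)
    Wperm <- colSums(matrix(r[idx], nrow = m))
    p <- mean(abs(Wperm - mu) >= abs(W - mu) - 1e-9)
  } else {
    N <- m + n
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = W, p_value = 1))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = W, p_value = p)
}

## Vectorized per-group median (groups as integer codes 1..ng); NA for
## empty groups.  Even-length groups: mean of the two middle order stats.
grouped_median <- function(x, g, ng) {
  cnt <- tabulate(g, nbins = ng)
  o <- order(g, x, method = "radix")
  xs <- x[o]
  ends <- cumsum(cnt)
  starts <- ends - cnt + 1L
  lo <- starts + (cnt - 1L) %/% 2L
  hi <- starts + cnt %/% 2L
  out <- rep(NA_real_, ng)
  nz <- cnt > 0L
  out[nz] <- (xs[lo[nz]] + xs[hi[nz]]) / 2
  out
}

## Vectorized per-group DLRS: sd of successive differences (in input order
## within group) divided by sqrt(2); NA for groups with < 3 points.
grouped_dlrs <- function(x, g, ng) {
  o <- order(g, method = "radix")      # stable: preserves probe order
  xs <- x[o]; gs <- g[o]
  n <- length(xs)
  if (n < 2L) return(rep(NA_real_, ng))
  d <- xs[-1L] - xs[-n]
  keep <- gs[-1L] == gs[-n]
  d <- d[keep]; gd <- gs[-1L][keep]
  m <- tabulate(gd, nbins = ng)
  s1 <- rep(0, ng); s2 <- rep(0, ng)
  agg <- rowsum(cbind(d, d * d), gd)
  idx <- as.integer(rownames(agg))
  s1[idx] <- agg[, 1]; s2[idx] <- agg[, 2]
  out <- rep(NA_real_, ng)
  ok <- m >= 2L                         # >= 3 probes -> >= 2 differences
  out[ok] <- sqrt(pmax(0, (s2[ok] - s1[ok]^2 / m[ok]) / (m[ok] - 1)) / 2)
  out
}

## Woolf (log-OR) interval with Haldane-Anscombe 0.5 correction on zero cells
woolf_or_ci <- function(a, b, c, d, conf = 0.95) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  lo <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  c(or = exp(lo), lo = exp(lo - z * se), hi = exp(lo + z * se))
}

## Benjamini-Hochberg adjustment (thin wrapper kept for a stable name)
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

star_marks <- function(p, cuts = c(0.05, 0.01, 0.001, 0.0001)) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    strrep("*", sum(pp < cuts))
  }, character(1))
}
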