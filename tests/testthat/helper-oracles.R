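# Independent oracles used to check package implementations.
# These deliberately avoid the code paths they validate.

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (the standard "sum of probabilities not larger
# than the observed table" definition, with the usual relative tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c                 # first-column margin
  n <- b + d
  k <- a + b                 # first-row margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Two-sided rank-sum p by brute-force enumeration of group assignments,
# computed through the Mann-Whitney U statistic (pairwise comparisons)
# rather than rank sums.
oracle_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  v <- c(x, y)
  u_stat <- function(ix) {
    xs <- v[ix]; ys <- v[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(m))
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, u_stat)
  centre <- m * n / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

# Logistic regression by hand-rolled IRLS (Newton-Raphson) for y ~ X.
oracle_logistic <- function(X, y, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  dev <- -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  list(beta = beta, deviance = dev)
}

# Cox partial log-likelihood (Breslow form; no ties in the fixtures that
# use it) for a single covariate, maximized by optimize().
oracle_cox_beta <- function(time, event, x, interval = c(-10, 10)) {
  pl <- function(beta) {
    ll <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(pl, interval, maximum = TRUE)$maximum
}

# Build a CellDataset directly from a dense matrix with given gene names.
toy_dataset <- function(counts, msy_genes = character(0), cells = NULL) {
  cell_dataset(counts, cells = cells, msy_genes = msy_genes)
}
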