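# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain cumulative products, series summation and
# adjacency-matrix reachability.

# normalized stationary law from the recurrence P_n = P_{n-1} h_n / n,
# evaluated bluntly at a fixed truncation
oracle_stationary <- function(h_fun, n_max = 1e4) {
  n <- seq_len(n_max)
  h <- h_fun(n)
  logp <- c(0, cumsum(log(h) - log(n)))
  logp[is.nan(logp)] <- -Inf
  p <- exp(logp - max(logp[is.finite(logp)]))
  p / sum(p)
}

oracle_moments <- function(p) {
  n <- seq_along(p) - 1
  m <- sum(n * p)
  v <- sum(n^2 * p) - m^2
  c(mean = m, variance = v, vmr = v / m)
}

# direct series evaluation of the two-arm stationary law:
# pi(k, 2) = 2 pi / k!, pi(2, m) = 2 pi / m!, state (2,2) counted once
oracle_example2 <- function(kmax = 60) {
  arm <- 2 / factorial(0:kmax)
  total <- 2 * sum(arm) - arm[3]
  vals <- c(0:kmax, 2)                       # gene-1 value: k on arm 1, 2 on arm 2
  probs <- c(arm - ifelse(0:kmax == 2, arm[3], 0), sum(arm)) / total
  m <- sum(vals * probs)
  v <- sum(vals^2 * probs) - m^2
  list(mean = m, vmr = v / m, p22 = arm[3] / total, p_gene1_eq_2 = sum(arm) / total)
}

# brute-force ancestor sets by boolean adjacency-matrix powers
oracle_ancestors <- function(edges, genes, gene) {
  n <- length(genes)
  A <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  for (r in seq_len(nrow(edges))) A[edges$regulator[r], edges$target[r]] <- TRUE
  reach <- A
  P <- A
  for (k in seq_len(n)) {
    P <- (P %*% A) > 0
    reach <- reach | P
  }
  sort(genes[reach[, gene]])
}

oracle_in_cycle <- function(edges, genes, gene) {
  gene %in% oracle_ancestors(edges, genes, gene)
}

# random strictly monotone h schedule on a bounded support
random_monotone_h <- function(len, increasing, h0 = NULL) {
  h0 <- h0 %||% stats::runif(1, 0.5, 4)
  inc <- stats::runif(len - 1, 0.05, 0.6)
  h <- if (increasing) h0 + cumsum(c(0, inc)) else pmax(h0 - cumsum(c(0, inc)), 1e-3)
  h
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# bounded-support model from an explicit h schedule (g = 1 so f = h)
model_from_h <- function(h) {
  birth_death_model(f = c(h, 0), g = rep(1, length(h) + 1))
}

# model whose h follows `h_head` and then stays constant (h bounded, so the
# chain is positive recurrent and the monotonicity is global, not truncated)
model_from_monotone_h <- function(h_head) {
  L <- length(h_head)
  hl <- h_head[L]
  birth_death_model(
    f = function(n) ifelse(n <= L, h_head[pmin(n, L)], hl),
    g = function(n) rep(1, length(n))
  )
}
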