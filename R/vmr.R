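#' Sample variance-to-mean ratio (Fano factor)
#'
#' Computes the sample VMR of a vector of non-negative integer counts:
#' unbiased sample variance (denominator `n - 1`) divided by the sample
#' mean. Under a Poisson null the population VMR is 1 and the sample VMR is
#' asymptotically Gamma-distributed (see [vmr_gamma_interval()]). A sample
#' with mean 0 has an undefined VMR, reported as `NA` with
#' `vmr_defined = FALSE` rather than as 0.
#'
#' @param counts Non-negative numeric vector, `length >= 2`.
#' @return One-row tibble: `n`, `mean`, `variance`, `vmr`, `vmr_defined`.
#' @examples
#' sample_vmr(c(0, 1, 2, 3, 4))  # vmr = 2.5 / 2 = 1.25
#' @export
sample_vmr <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("need at least 2 samples to estimate a variance", call. = FALSE)
  if (anyNA(counts)) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  m <- mean(counts)
  v <- stats::var(counts)
  defined <- m > 0
  tibble::tibble(
    n = length(counts), mean = m, variance = v,
    vmr = if (defined) v / m else NA_real_,
    vmr_defined = defined
  )
}

#' Null acceptance interval for the sample VMR under a Poisson model
#'
#' For `n` i.i.d. Poisson samples the sample VMR asymptotically follows a
#' Gamma distribution with shape `(n - 1) / 2` and scale `2 / (n - 1)`
#' (mean exactly 1 for every `n`). The equal-tail `alpha/2`, `1 - alpha/2`
#' quantiles of that law give a two-sided acceptance interval that always
#' brackets 1 and shrinks towards it as `n` grows. The approximation is
#' asymptotic; a warning (not an error) is raised below `n = 30`.
#'
#' @param n Sample size, `>= 2`.
#' @param alpha Two-sided level in (0, 1); default 0.05.
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' vmr_gamma_interval(101)  # about (0.742, 1.296)
#' @export
vmr_gamma_interval <- function(n, alpha = 0.05) {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("`n` must be a single sample size >= 2", call. = FALSE)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (n < 30)
    warning("the Gamma null for the sample VMR is asymptotic; n = ", n,
            " is small and the interval may be inaccurate", call. = FALSE)
  shape <- (n - 1) / 2
  scale <- 2 / (n - 1)
  c(lo = stats::qgamma(alpha / 2, shape = shape, scale = scale),
    hi = stats::qgamma(1 - alpha / 2, shape = shape, scale = scale))
}

#' Test a sample VMR against the Poisson null
#'
#' Computes the sample VMR and compares it with the two-sided Gamma null
#' interval: verdict `"below"` if the VMR falls under the lower quantile
#' (candidate negative autoregulation), `"above"` if over the upper quantile
#' (candidate positive autoregulation), `"consistent"` otherwise. Also
#' reports the two-sided p-value `2 * min(F(vmr), 1 - F(vmr))` under the
#' Gamma null, used when multiple-testing correction is requested upstream.
#'
#' @inheritParams sample_vmr
#' @param alpha Two-sided level; default 0.05.
#' @return One-row tibble: `n`, `mean`, `variance`, `vmr`, `vmr_defined`,
#'   `ci_lo`, `ci_hi`, `p_value`, `verdict`.
#' @examples
#' set.seed(1)
#' vmr_test(rpois(1000, 5))$verdict  # "consistent" with high probability
#' @export
vmr_test <- function(counts, alpha = 0.05) {
  res <- sample_vmr(counts)
  ci <- vmr_gamma_interval(res$n, alpha)
  res$ci_lo <- ci[["lo"]]
  res$ci_hi <- ci[["hi"]]
  if (!res$vmr_defined) {
    res$p_value <- NA_real_
    res$verdict <- NA_character_
    return(res)
  }
  shape <- (res$n - 1) / 2
  scale <- 2 / (res$n - 1)
  F_v <- stats::pgamma(res$vmr, shape = shape, scale = scale)
  res$p_value <- min(1, 2 * min(F_v, 1 - F_v))
  res$verdict <- if (res$vmr < res$ci_lo) "below"
                 else if (res$vmr > res$ci_hi) "above"
                 else "consistent"
  res
}

#' VMR of a mixture of cell types
#'
#' Law of total variance for a mixed population: with component weights
#' `w_i`, means `mu_i` and variances `s2_i`, the mixture has mean
#' `sum(w mu)`, variance `sum(w s2) + sum(w (mu - mean)^2)` and VMR
#' variance/mean. If every component is at least Poisson-dispersed
#' (`s2_i >= mu_i`), the mixture VMR is `>= 1`: cell-type heterogeneity
#' cannot push a super-Poissonian population below the Poisson line, which
#' is what makes a population VMR below 1 informative even for heterogeneous
#' samples.
#'
#' @param components Data frame with columns `weight`, `mean`, `variance`;
#'   weights must sum to 1 (within 1e-9).
#' @return One-row tibble: `mean`, `variance`, `vmr`.
#' @examples
#' mixture_vmr(tibble::tibble(weight = c(.5, .5), mean = c(5, 15),
#'                            variance = c(5, 15)))  # vmr = 3.5
#' @export
mixture_vmr <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("weight", "mean", "variance") %in% names(components)))
  w <- components$weight; mu <- components$mean; s2 <- components$variance
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-9)
    stop("component weights must be positive and sum to 1", call. = FALSE)
  if (any(mu < 0) || any(s2 < 0))
    stop("component means and variances must be non-negative", call. = FALSE)
  m <- sum(w * mu)
  v <- sum(w * s2) + sum(w * (mu - m)^2)
  tibble::tibble(mean = m, variance = v,
                 vmr = if (m > 0) v / m else NA_real_)
}

#' Intrinsic/extrinsic decomposition of the VMR
#'
#' Splits the pooled VMR of samples observed under labelled environments
#' into an intrinsic part (size-weighted mean of within-environment
#' variances over the overall mean) and an extrinsic part (size-weighted
#' variance of the environment means over the overall mean). Population
#' (`1/n`) variances are used throughout so the two parts sum exactly to the
#' pooled population VMR (law of total variance); this is the standard
#' intrinsic/extrinsic noise convention.
#'
#' @param data Data frame of samples.
#' @param value Column of counts (tidy-eval).
#' @param group Column of environment labels (tidy-eval).
#' @return One-row tibble: `vmr_intrinsic`, `vmr_extrinsic`, `vmr_total`,
#'   `n_groups`.
#' @examples
#' d <- tibble::tibble(env = rep(c("a", "b"), each = 4),
#'                     x = c(1, 2, 3, 2, 7, 8, 9, 8))
#' vmr_decomposition(d, x, env)
#' @export
vmr_decomposition <- function(data, value, group) {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("degenerate grouping: need >= 2 groups with >= 2 samples each",
         call. = FALSE)
  mu <- mean(x)
  if (mu <= 0) stop("overall mean must be positive", call. = FALSE)
  pop_var <- function(v) mean((v - mean(v))^2)
  by_g <- tapply(x, g, function(v) c(n = length(v), m = mean(v), v = pop_var(v)))
  tab <- do.call(rbind, by_g)
  w <- tab[, "n"] / sum(tab[, "n"])
  within <- sum(w * tab[, "v"])
  between <- sum(w * (tab[, "m"] - mu)^2)
  tibble::tibble(
    vmr_intrinsic = within / mu,
    vmr_extrinsic = between / mu,
    vmr_total = (within + between) / mu,
    n_groups = length(sizes)
  )
}

#' Compare an inference result with a random classifier
#'
#' Given a standard that marks `standard_positives` of `population` genes as
#' autoregulated, a classifier that picks `picked` genes at random hits a
#' hypergeometric number of them. With an observed overlap of `overlap`
#' genes, this returns the probabilities that the random classifier does
#' worse, ties, or does better.
#'
#' @param population Total number of genes `N`.
#' @param standard_positives Number the standard calls positive, `K <= N`.
#' @param picked Number of genes the classifier picks, `n <= N`.
#' @param overlap Observed overlap `k`, `0 <= k <= min(K, n)`.
#' @return One-row tibble: `p_worse`, `p_tie`, `p_better` (summing to 1).
#' @examples
#' random_classifier_comparison(39, 17, 5, 3)  # p_worse 0.6255, p_better 0.1017
#' @export
random_classifier_comparison <- function(population, standard_positives,
                                         picked, overlap) {
  N <- population; K <- standard_positives; n <- picked; k <- overlap
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent arguments: need 0 <= k <= min(K, n) <= N", call. = FALSE)
  tibble::tibble(
    p_worse = if (k == 0) 0 else stats::phyper(k - 1, K, N - K, n),
    p_tie = stats::dhyper(k, K, N - K, n),
    p_better = stats::phyper(k, K, N - K, n, lower.tail = FALSE)
  )
}
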