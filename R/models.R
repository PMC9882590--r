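#' Linear feedback model of a single autoregulated gene
#'
#' The worked linear model: synthesis `f_n = k + b (n - 1)` and constant
#' per-molecule degradation `g_n = c`. The slope `b` is the strength of
#' autoregulation (`b > 0` positive, `b < 0` negative, `b = 0` none) and the
#' stationary Fano factor is `VMR = 1 + b / (c - b)`, so the model gives an
#' exact target for every solver and simulator in the package. Validity
#' requires `c > 0` and `c - b > 0`; with `b < 0` the synthesis schedule
#' would go negative at large `n` and is clipped at zero there, with a
#' warning at construction time (the clip truncates the support, it does not
#' change the distribution below the clip point).
#'
#' @param k Basal synthesis rate at `n = 1` (events per unit time), `k > 0`.
#' @param b Feedback slope per molecule (can be negative).
#' @param c Constant per-molecule degradation rate, `c > 0`, `c - b > 0`.
#' @return A [birth_death_model()] carrying `family = "linear_feedback"` and
#'   a `true_autoregulation` attribute (`"positive"`, `"negative"` or
#'   `"none"`) used as ground truth by the synthetic-data generator.
#' @examples
#' glance(solve_stationary(linear_feedback_model(k = 1, b = 0.5, c = 1)))$vmr  # 2
#' @export
linear_feedback_model <- function(k, b, c) {
  if (!(c > 0) || !(c - b > 0))
    stop("invalid parameters: need c > 0 and c - b > 0", call. = FALSE)
  if (!(k > 0)) stop("invalid parameters: need k > 0", call. = FALSE)
  force(k); force(b); force(c)
  if (b < 0)
    rlang::warn(paste0("b < 0: synthesis schedule is clipped at 0 from n = ",
                       ceiling(1 - k / b) + 1, " upward"),
                class = "fanoreg_clip_warning")
  m <- birth_death_model(
    f = function(n) pmax(0, k + b * (n - 1)),
    g = function(n) rep(c, length(n))
  )
  attr(m, "family") <- "linear_feedback"
  attr(m, "params") <- list(k = k, b = b, c = c)
  attr(m, "true_vmr") <- 1 + b / (c - b)
  attr(m, "true_autoregulation") <-
    if (b > 0) "positive" else if (b < 0) "negative" else "none"
  m
}

#' Poisson (no autoregulation) gene model
#'
#' Constant synthesis rate `lambda` and unit per-molecule degradation: the
#' relative growth rate is the constant `lambda`, so the stationary law is
#' Poisson(`lambda`) with VMR exactly 1. The null model of the whole
#' inference workflow.
#'
#' @param lambda Mean stationary copy number, `lambda > 0`.
#' @return A [birth_death_model()] with `true_autoregulation = "none"`.
#' @export
poisson_gene_model <- function(lambda) {
  stopifnot(lambda > 0)
  force(lambda)
  m <- birth_death_model(
    f = function(n) rep(lambda, length(n)),
    g = function(n) rep(1, length(n))
  )
  attr(m, "family") <- "poisson"
  attr(m, "params") <- list(lambda = lambda)
  attr(m, "true_vmr") <- 1
  attr(m, "true_autoregulation") <- "none"
  m
}

#' Two-gene frozen-arm model with VMR below 1
#'
#' The worked two-gene counterexample to degradation-independence: each gene
#' is only synthesised *and only degraded* when the other gene's count equals
#' 2 (`f_1 = g_1 = 1` iff `n_2 = 2`, `f_2 = g_2 = 1` iff `n_1 = 2`), started
#' from state (2, 2). The reachable states form two "arms"
#' `{(k, 2)} U {(2, m)}`; the stationary law puts mass proportional to
#' `2 / k!` on each arm state, giving marginal `VMR = 2e / (4e - 1) ~ 0.55`
#' for both genes even though neither gene has autoregulation in the
#' `h`-schedule sense — degradation here *is* regulated, which is exactly the
#' assumption the below-1 theory needs.
#'
#' @param box Per-arm truncation bound (states `0..box` per coordinate).
#' @return A [coupled_model()] with species `gene1`, `gene2`.
#' @examples
#' glance(solve_stationary(example2_model()))
#' @export
example2_model <- function(box = 30) {
  m <- coupled_model(
    synth = list(
      function(n) if (n[2] == 2L) 1 else 0,
      function(n) if (n[1] == 2L) 1 else 0
    ),
    deg = list(
      function(n) if (n[2] == 2L) 1 else 0,
      function(n) if (n[1] == 2L) 1 else 0
    ),
    box = c(box, box),
    initial_state = c(2, 2)
  )
  attr(m, "family") <- "example2_pair"
  attr(m, "true_vmr") <- 2 * exp(1) / (4 * exp(1) - 1)
  attr(m, "true_autoregulation") <- "negative"
  m
}

#' Environment-driven gene without autoregulation
#'
#' A gene W whose synthesis rate depends only on a finite upstream
#' environment Y (a continuous-time chain with rate matrix `q`), with
#' constant per-molecule degradation `G` and no feedback from W to Y. This
#' is the setting in which "no autoregulation implies VMR >= 1" holds: W is
#' conditionally Poisson given Y, and switching of Y can only add variance.
#'
#' @param q Square rate matrix of the environment chain (off-diagonal
#'   entries are transition rates; the diagonal is ignored).
#' @param synth Numeric vector `F_i` of synthesis rates, one per environment
#'   state.
#' @param deg Constant per-molecule degradation rate `G > 0`.
#' @param w_max Truncation bound for the W coordinate; defaults to a
#'   generous Poisson-style bound above `max(synth) / deg`.
#' @return A [coupled_model()] with species `Y` (environment state,
#'   `1..nrow(q)`) and `W` (copy number), `true_autoregulation = "none"`.
#' @export
environment_driven_model <- function(q, synth, deg, w_max = NULL) {
  q <- as.matrix(q)
  S <- nrow(q)
  stopifnot(ncol(q) == S, length(synth) == S, deg > 0, all(synth >= 0))
  if (any(q[row(q) != col(q)] < 0))
    stop("off-diagonal environment rates must be non-negative", call. = FALSE)
  mu_max <- max(synth) / deg
  if (is.null(w_max)) w_max <- ceiling(mu_max + 12 * sqrt(mu_max + 1) + 25)
  reactions <- list()
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j || q[i, j] <= 0) next
    local({
      ii <- i; jj <- j; rij <- q[i, j]
      reactions[[length(reactions) + 1L]] <<- list(
        delta = c(jj - ii, 0L),
        rate = function(state) if (state[1] == ii) rij else 0
      )
    })
  }
  reactions[[length(reactions) + 1L]] <- list(
    delta = c(0L, 1L), rate = function(state) synth[state[1]]
  )
  reactions[[length(reactions) + 1L]] <- list(
    delta = c(0L, -1L), rate = function(state) deg * state[2]
  )
  m <- new_coupled_model(reactions, lower = c(1L, 0L), box = c(S, w_max),
                         initial_state = c(1L, 0L), species = c("Y", "W"))
  attr(m, "family") <- "environment_driven"
  attr(m, "params") <- list(q = q, synth = synth, deg = deg)
  attr(m, "true_autoregulation") <- "none"
  m
}

#' Multistep gene-cycle counterexample
#'
#' The k-stage promoter cycle `G1 -> G2 -> ... -> Gk -> G1 + M`, `M -> 0`:
#' each stage advances at rate `k_stages` so a full cycle takes mean time 1,
#' the final step simultaneously resets the stage *and* produces one mRNA (a
#' deliberate multistep event), and each mRNA degrades at per-molecule rate
#' `deg_rate`. With many stages the cycle time is nearly deterministic, so
#' for `k_stages = 100`, `deg_rate = 0.01` the mRNA count concentrates near
#' 100 with VMR close to 0.5 — sub-Poissonian *without* autoregulation,
#' which is why the below-1 inference branch explicitly assumes one-step
#' dynamics. [solve_stationary()] refuses this model; use
#' [simulate_cells()].
#'
#' @param k_stages Number of promoter stages, `>= 1`. With `k_stages = 1`
#'   the cycle degenerates to a single exponential step and the model
#'   reduces to Poisson production (VMR 1).
#' @param deg_rate Per-molecule mRNA degradation rate.
#' @param m_max Truncation bound on the mRNA count used by the lattice
#'   representation (the dedicated simulator is not truncated below it).
#' @return A `multistep_cycle_model`, a [coupled_model()] whose final
#'   reaction changes two coordinates at once.
#' @export
multistep_cycle_model <- function(k_stages, deg_rate, m_max = NULL) {
  k_stages <- as.integer(k_stages)
  stopifnot(k_stages >= 1L, deg_rate > 0)
  mu <- 1 / deg_rate  # production rate is 1 cycle per unit time
  if (is.null(m_max)) m_max <- ceiling(mu + 12 * sqrt(mu + 1) + 25)
  force(deg_rate)
  reactions <- list(
    list(delta = c(1L, 0L),
         rate = function(state) if (state[1] < k_stages) k_stages else 0),
    list(delta = c(1L - k_stages, 1L),  # Gk -> G1 + M: the multistep event
         rate = function(state) if (state[1] == k_stages) k_stages else 0),
    list(delta = c(0L, -1L), rate = function(state) deg_rate * state[2])
  )
  m <- new_coupled_model(reactions, lower = c(1L, 0L), box = c(k_stages, m_max),
                         initial_state = c(1L, 0L), species = c("stage", "mRNA"),
                         class = "multistep_cycle_model")
  attr(m, "family") <- "multistep_cycle"
  attr(m, "params") <- list(k_stages = k_stages, deg_rate = deg_rate)
  attr(m, "true_autoregulation") <- "none"
  m
}
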