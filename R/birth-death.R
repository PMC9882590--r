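#' Single-gene birth-death expression model
#'
#' Builds the continuous-time Markov chain model of the copy number of a
#' single, autonomously expressed gene. The chain lives on the non-negative
#' integers with transition rate `f_n` from state `n - 1` up to `n`
#' (synthesis, indexed by the *target* state) and total rate `n * g_n` from
#' state `n` down to `n - 1` (each of the `n` molecules degrades at
#' per-molecule rate `g_n`).
#'
#' Schedules can be given as plain numeric vectors (`f[n]` is the rate into
#' state `n`, so `f[1]` is the 0 to 1 rate) or as vectorised functions of the
#' state index `n = 1, 2, ...`, which is what the automatic truncation of
#' [solve_stationary()] needs when the support is not known in advance.
#'
#' @param f Synthesis schedule: numeric vector or function of `n >= 1`.
#'   All values must be non-negative.
#' @param g Per-molecule degradation schedule: numeric vector or function of
#'   `n >= 1`. All values must be strictly positive.
#' @param max_state Truncation bound for the stationary solver: a positive
#'   integer, or `"auto"` (the default) to extend the support until the
#'   stationary recurrence has certifiably converged. Vector schedules cap
#'   `"auto"` at their own length.
#' @return An object of class `birth_death_model`.
#' @examples
#' # constant relative growth rate h = 2: stationary law is Poisson(2)
#' m <- birth_death_model(f = function(n) 2, g = function(n) 1)
#' glance(solve_stationary(m))
#' @seealso [linear_feedback_model()], [relative_growth()], [solve_stationary()]
#' @export
birth_death_model <- function(f, g, max_state = "auto") {
  f_sched <- as_schedule(f, "f")
  g_sched <- as_schedule(g, "g")
  if (!identical(max_state, "auto")) {
    max_state <- as.integer(max_state)
    if (length(max_state) != 1L || is.na(max_state) || max_state < 1L)
      stop("`max_state` must be \"auto\" or a single positive integer", call. = FALSE)
  }
  len <- min(f_sched$length, g_sched$length)
  structure(
    list(f = f_sched$fun, g = g_sched$fun, max_state = max_state,
         schedule_length = len),
    class = "birth_death_model"
  )
}

# Normalise a schedule (vector or function) to a vectorised function of n,
# with the finite length it is defined on (Inf for functions).
as_schedule <- function(x, name) {
  if (is.function(x)) {
    fun <- function(n) {
      v <- as.numeric(x(n))
      if (length(v) == 1L && length(n) > 1L) v <- rep(v, length(n))
      if (length(v) != length(n))
        stop(sprintf("schedule `%s` must be vectorised over n", name), call. = FALSE)
      v
    }
    return(list(fun = fun, length = Inf))
  }
  if (is.numeric(x)) {
    if (length(x) < 1L)
      stop(sprintf("schedule `%s` is empty", name), call. = FALSE)
    if (anyNA(x)) stop(sprintf("schedule `%s` contains NA", name), call. = FALSE)
    xx <- as.numeric(x)
    fun <- function(n) {
      if (any(n > length(xx)))
        stop(sprintf("schedule `%s` is only defined up to n = %d", name, length(xx)),
             call. = FALSE)
      xx[n]
    }
    return(list(fun = fun, length = length(xx)))
  }
  stop(sprintf("schedule `%s` must be a numeric vector or a function", name),
       call. = FALSE)
}

#' @export
print.birth_death_model <- function(x, ...) {
  len <- if (is.finite(x$schedule_length)) x$schedule_length else "unbounded"
  cat("<birth_death_model>\n")
  cat("  schedule length:", len, "\n")
  cat("  truncation:", if (identical(x$max_state, "auto")) "auto" else x$max_state, "\n")
  fam <- attr(x, "family")
  if (!is.null(fam))
    cat("  family:", fam, paste0("(", paste(names(attr(x, "params")), unlist(attr(x, "params")),
                                            sep = " = ", collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Relative growth rate schedule
#'
#' Computes `h_n = f_n / g_n`, the ratio of synthesis to per-molecule
#' degradation rate at copy number `n`. A constant `h` means no
#' autoregulation (and a Poisson stationary law); `h` rising anywhere means
#' positive autoregulation, falling anywhere means negative autoregulation.
#'
#' @param model A [birth_death_model()].
#' @param n_max Largest state to evaluate. Defaults to the vector schedule
#'   length; required for function schedules.
#' @return A tibble with columns `n`, `f`, `g`, `h`.
#' @examples
#' m <- linear_feedback_model(k = 1, b = 0.5, c = 1)
#' relative_growth(m, n_max = 3)
#' @export
relative_growth <- function(model, n_max = NULL) {
  stopifnot(inherits(model, "birth_death_model"))
  if (is.null(n_max)) {
    n_max <- if (is.finite(model$schedule_length)) model$schedule_length
             else if (!identical(model$max_state, "auto")) model$max_state
             else stop("`n_max` is required for unbounded function schedules", call. = FALSE)
  }
  n <- seq_len(n_max)
  f <- model$f(n)
  g <- model$g(n)
  if (any(f < 0))
    stop("negative synthesis rate at n = ", n[which(f < 0)[1]], call. = FALSE)
  bad <- which(g <= 0)
  if (length(bad) > 0)
    stop("degenerate model: degradation rate g_n is not positive at n = ", n[bad[1]],
         call. = FALSE)
  tibble::tibble(n = n, f = f, g = g, h = f / g)
}

#' Classify autoregulation signs from a relative growth rate schedule
#'
#' A gene has positive autoregulation if `h_n > h_{n-1}` for some `n` and
#' negative autoregulation if `h_n < h_{n-1}` for some `n`; both can hold at
#' different expression levels, and a constant schedule has neither.
#'
#' @param h Either the tibble returned by [relative_growth()] or a numeric
#'   vector of `h` values on a contiguous index range.
#' @param tol Relative tolerance under which two consecutive values count as
#'   equal (guards against float noise in user-supplied schedules).
#' @return A character vector: a subset of `c("positive", "negative")`,
#'   empty when `h` is constant.
#' @examples
#' classify_rates(c(1, 1.5, 2))   # "positive"
#' classify_rates(c(1, 3, 2))     # both signs
#' classify_rates(c(2, 2, 2, 2))  # character(0)
#' @export
classify_rates <- function(h, tol = 1e-9) {
  if (is.data.frame(h)) {
    if (!"h" %in% names(h)) stop("data frame input must have a column `h`", call. = FALSE)
    h <- h$h
  }
  h <- as.numeric(h)
  if (length(h) < 2L)
    stop("insufficient range: need at least 2 consecutive h values", call. = FALSE)
  if (anyNA(h)) stop("h contains NA", call. = FALSE)
  d <- diff(h)
  scale <- pmax(abs(h[-1]), abs(h[-length(h)]), 1)
  out <- character(0)
  if (any(d > tol * scale)) out <- c(out, "positive")
  if (any(d < -tol * scale)) out <- c(out, "negative")
  out
}

#' Exact stationary distribution of an expression model
#'
#' For a single-gene birth-death model the stationary law satisfies the
#' recurrence `P_n = P_{n-1} * h_n / n` with `h_n = f_n / g_n`; this is
#' evaluated in log space with automatic truncation: the support is extended
#' until the unnormalised term stays below `tail_tol` times the running
#' normaliser for 10 consecutive states, and the excluded mass is certified
#' by a geometric tail bound. For coupled multi-gene models see
#' [solve_stationary.coupled_model()].
#'
#' @param model A model object.
#' @param tail_tol Requested bound on the probability mass lost to
#'   truncation.
#' @param ... Passed to methods.
#' @return A `stationary_dist` object: a tibble of states and probabilities
#'   with attributes `tail_mass` (certified truncation bound) and `species`.
#'   Use [tidy()] for the table, [glance()] or [distribution_moments()] for
#'   mean/variance/VMR.
#' @examples
#' d <- solve_stationary(birth_death_model(function(n) 2, function(n) 1))
#' head(tidy(d))          # Poisson(2) probabilities
#' glance(d)$vmr          # 1
#' @export
solve_stationary <- function(model, tail_tol = 1e-12, ...) {
  UseMethod("solve_stationary")
}

#' @rdname solve_stationary
#' @param max_states Hard cap on the number of support states explored
#'   before the model is declared non-normalizable (stationarity needs the
#'   recurrence terms to decay, e.g. a finite upper bound on `h_n`).
#' @export
solve_stationary.birth_death_model <- function(model, tail_tol = 1e-12,
                                               max_states = 1e6, ...) {
  cap <- if (identical(model$max_state, "auto")) {
    min(max_states, model$schedule_length)
  } else {
    min(model$max_state, model$schedule_length)
  }
  auto <- identical(model$max_state, "auto")

  # log unnormalised terms: log u_n = log u_{n-1} + log h_n - log n, u_0 = 0
  logu <- 0
  logs <- 0          # running log normaliser (log-sum-exp of terms so far)
  quiet <- 0L        # consecutive states with term < tail_tol * normaliser
  terms <- numeric(256); terms[1] <- 0
  n_kept <- 1L
  chunk <- 512L
  n <- 0L
  last_ratio <- NA_real_
  done <- FALSE

  while (!done && n < cap) {
    ns <- seq.int(n + 1L, min(n + chunk, cap))
    g <- model$g(ns)
    bad <- which(g <= 0)
    if (length(bad) > 0)
      stop("degenerate model: g_n is not positive at n = ", ns[bad[1]], call. = FALSE)
    f <- model$f(ns)
    if (any(f < 0))
      stop("negative synthesis rate at n = ", ns[which(f < 0)[1]], call. = FALSE)
    h <- f / g
    lt <- logu + cumsum(log(h) - log(ns))
    for (i in seq_along(ns)) {
      t_i <- lt[i]
      if (!is.finite(t_i) && is.na(t_i)) stop("schedule produced NaN rates", call. = FALSE)
      if (t_i == -Inf) { # synthesis hit zero: support ends here
        done <- TRUE
        last_ratio <- 0
        break
      }
      if (n_kept + 1L > length(terms)) terms <- c(terms, numeric(length(terms)))
      n_kept <- n_kept + 1L
      terms[n_kept] <- t_i
      logs <- max(logs, t_i) + log1p(exp(min(logs, t_i) - max(logs, t_i)))
      last_ratio <- if (n_kept >= 3L) exp(terms[n_kept] - terms[n_kept - 1L]) else NA_real_
      if (auto) {
        quiet <- if (t_i < logs + log(tail_tol)) quiet + 1L else 0L
        if (quiet >= 10L) { done <- TRUE; break }
      }
    }
    logu <- lt[length(ns)]
    n <- ns[length(ns)]
  }

  lt_last <- terms[n_kept]
  if (auto && !done) {
    # still growing (or not yet certifiably decaying) at the cap
    if (is.na(last_ratio) || last_ratio >= 1 || lt_last >= logs + log(tail_tol))
      stop("stationary recurrence did not converge within ", cap,
           " states; the chain appears non-normalizable (h_n must eventually be bounded)",
           call. = FALSE)
  }

  probs <- exp(terms[seq_len(n_kept)] - logs)
  probs <- probs / sum(probs)
  tail_mass <- if (!is.na(last_ratio) && last_ratio < 1) {
    exp(lt_last - logs) * last_ratio / (1 - last_ratio)
  } else if (identical(last_ratio, 0)) 0 else NA_real_

  new_stationary_dist(
    tibble::tibble(n = 0:(n_kept - 1L), prob = probs),
    species = "n", tail_mass = tail_mass
  )
}

new_stationary_dist <- function(tbl, species, tail_mass) {
  structure(tbl, species = species, tail_mass = tail_mass,
            class = c("stationary_dist", class(tibble::tibble())))
}

#' @export
print.stationary_dist <- function(x, ...) {
  sp <- attr(x, "species")
  cat("<stationary_dist> over", paste(sp, collapse = " x "),
      "(", nrow(x), "states, certified tail mass",
      format(attr(x, "tail_mass"), digits = 3), ")\n")
  NextMethod()
}

#' Moments of a discrete stationary distribution
#'
#' Mean, variance and variance-to-mean ratio (Fano factor) of one species of
#' a solved distribution. A distribution degenerate at zero has an undefined
#' VMR (a 0/0 ratio); it is reported as `NA` with `vmr_defined = FALSE`,
#' never silently as 0.
#'
#' @param dist A `stationary_dist` (1-dimensional, or use [marginal()] first)
#'   or a data frame with columns `n` and `prob`.
#' @return A one-row tibble: `mean`, `variance`, `vmr`, `vmr_defined`.
#' @examples
#' distribution_moments(solve_stationary(linear_feedback_model(1, 0.5, 1)))
#' @export
distribution_moments <- function(dist) {
  stopifnot(is.data.frame(dist))
  value_cols <- setdiff(names(dist), "prob")
  if (length(value_cols) != 1L)
    stop("distribution is multi-dimensional; take a marginal() first", call. = FALSE)
  n <- dist[[value_cols]]
  p <- dist$prob
  mu <- sum(n * p)
  v <- sum(n^2 * p) - mu^2
  v <- max(v, 0)
  defined <- mu > 0
  tibble::tibble(
    mean = mu, variance = v,
    vmr = if (defined) v / mu else NA_real_,
    vmr_defined = defined
  )
}

#' @export
glance.stationary_dist <- function(x, ...) {
  sp <- attr(x, "species")
  if (length(sp) == 1L) {
    out <- distribution_moments(x)
    out$tail_mass <- attr(x, "tail_mass")
    return(out)
  }
  purrr::map_dfr(sp, function(s) {
    out <- distribution_moments(marginal(x, s))
    out$species <- s
    out$tail_mass <- attr(x, "tail_mass")
    out[, c("species", setdiff(names(out), "species"))]
  })
}

#' @export
tidy.stationary_dist <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Marginal distribution of one species
#'
#' Sums a multi-dimensional stationary distribution over all other
#' coordinates. The certified tail mass of the joint solve is carried
#' through unchanged.
#'
#' @param dist A `stationary_dist`.
#' @param species Species name or integer index.
#' @return A 1-dimensional `stationary_dist` with columns `n` and `prob`.
#' @export
marginal <- function(dist, species) {
  stopifnot(inherits(dist, "stationary_dist"))
  sp <- attr(dist, "species")
  if (is.numeric(species)) {
    if (species < 1 || species > length(sp)) stop("species index out of range", call. = FALSE)
    species <- sp[species]
  }
  if (!species %in% sp) stop("unknown species: ", species, call. = FALSE)
  if (length(sp) == 1L) return(dist)
  tbl <- tidy(dist) |>
    dplyr::group_by(n = .data[[species]]) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop") |>
    dplyr::arrange(.data$n)
  new_stationary_dist(tbl, species = "n", tail_mass = attr(dist, "tail_mass"))
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.stationary_dist <- function(object, ...) {
  sp <- attr(object, "species")
  if (length(sp) == 1L) {
    ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n, y = .data$prob)) +
      ggplot2::geom_col(width = 0.9) +
      ggplot2::labs(x = "copy number", y = "stationary probability")
  } else if (length(sp) == 2L) {
    ggplot2::ggplot(tidy(object),
                    ggplot2::aes(x = .data[[sp[1]]], y = .data[[sp[2]]],
                                 fill = .data$prob)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = sp[1], y = sp[2], fill = "probability")
  } else {
    stop("autoplot supports 1- and 2-dimensional distributions; take marginals first",
         call. = FALSE)
  }
}
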