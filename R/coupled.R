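#' Coupled multi-gene expression model
#'
#' Builds a continuous-time Markov chain for `m` genes that regulate each
#' other. The state is the vector of copy numbers `n = (n_1, ..., n_m)`; for
#' gene `i` the transition `n_i - 1 -> n_i` occurs at rate `f_i(n)` (synthesis,
#' evaluated at the target state) and `n_i -> n_i - 1` at total rate
#' `n_i * g_i(n)` (per-molecule degradation). Only one-step events exist:
#' every transition changes exactly one coordinate by one.
#'
#' @param synth List of `m` synthesis rate functions; each takes the full
#'   integer state vector (the *target* state of the birth) and returns a
#'   non-negative rate.
#' @param deg List of `m` per-molecule degradation rate functions of the
#'   state vector. Zero is allowed where a coordinate is frozen (as in the
#'   two-arm worked example); the reachable chain must still be positive
#'   recurrent.
#' @param box Integer vector of per-species truncation bounds (counts range
#'   over `0..box[i]`).
#' @param initial_state Integer state vector. Needed to pick the closed
#'   communicating class when the truncated chain is reducible.
#' @param species Optional character vector of species names (defaults to
#'   `gene1, gene2, ...`).
#' @return An object of class `coupled_model`.
#' @examples
#' # two independent Poisson genes
#' m <- coupled_model(
#'   synth = list(\(n) 2, \(n) 3),
#'   deg   = list(\(n) 1, \(n) 1),
#'   box = c(25, 25), initial_state = c(0, 0)
#' )
#' glance(solve_stationary(m))
#' @seealso [example2_model()], [environment_driven_model()],
#'   [multistep_cycle_model()], [solve_stationary()]
#' @export
coupled_model <- function(synth, deg, box, initial_state, species = NULL) {
  m <- length(synth)
  stopifnot(length(deg) == m, length(box) == m, length(initial_state) == m)
  if (!all(vapply(c(synth, deg), is.function, logical(1))))
    stop("`synth` and `deg` must be lists of functions of the state vector", call. = FALSE)
  box <- as.integer(box)
  initial_state <- as.integer(initial_state)
  if (any(initial_state < 0) || any(initial_state > box))
    stop("`initial_state` must lie inside the truncation box", call. = FALSE)
  if (is.null(species)) species <- paste0("gene", seq_len(m))
  reactions <- list()
  for (i in seq_len(m)) {
    local({
      ii <- i
      e_i <- integer(m); e_i[ii] <- 1L
      reactions[[length(reactions) + 1L]] <<- list(
        delta = e_i,
        rate = function(state) synth[[ii]](state + e_i)  # target-indexed
      )
      reactions[[length(reactions) + 1L]] <<- list(
        delta = -e_i,
        rate = function(state) if (state[ii] > 0L) state[ii] * deg[[ii]](state) else 0
      )
    })
  }
  new_coupled_model(reactions, lower = integer(m), box = box,
                    initial_state = initial_state, species = species)
}

new_coupled_model <- function(reactions, lower, box, initial_state, species,
                              class = character()) {
  structure(
    list(reactions = reactions, lower = as.integer(lower), box = as.integer(box),
         initial_state = as.integer(initial_state), species = species,
         n_species = length(species)),
    class = c(class, "coupled_model")
  )
}

#' @export
print.coupled_model <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$n_species, " species (",
      paste(x$species, collapse = ", "), "), ",
      length(x$reactions), " reaction channels\n", sep = "")
  cat("  box:", paste(x$lower, x$box, sep = "..", collapse = " x "),
      " initial state: (", paste(x$initial_state, collapse = ", "), ")\n")
  invisible(x)
}

is_one_step <- function(model) {
  all(vapply(model$reactions, function(r) sum(r$delta != 0L) == 1L, logical(1)))
}

# Enumerate states reachable from the initial state inside the box.
# Returns a matrix of states (rows) in discovery order.
reachable_states <- function(model) {
  m <- model$n_species
  key <- function(s) paste(s, collapse = ",")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  queue <- list(model$initial_state)
  assign(key(model$initial_state), TRUE, envir = seen)
  out <- list(model$initial_state)
  while (length(queue) > 0) {
    s <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (r in model$reactions) {
      if (r$rate(s) <= 0) next
      t_ <- s + r$delta
      if (any(t_ < model$lower) || any(t_ > model$box)) next
      k <- key(t_)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- t_
        out[[length(out) + 1L]] <- t_
      }
    }
  }
  do.call(rbind, out)
}

#' @describeIn solve_stationary Stationary law of a coupled one-step chain:
#'   enumerates the states reachable from `initial_state` inside the
#'   truncation box, restricts to the closed communicating class, and solves
#'   the sparse stationary linear system (one row replaced by the
#'   normalisation constraint, with a power-iteration fallback on the
#'   uniformised chain). The reported `tail_mass` is the stationary
#'   probability flux blocked at the box boundary; expanding the box must
#'   leave every probability within `tail_tol`.
#' @export
solve_stationary.coupled_model <- function(model, tail_tol = 1e-9, ...) {
  if (!is_one_step(model))
    stop(paste("model contains multistep events (a reaction changes more than one",
               "species at once); the one-step stationary theory does not apply.",
               "Use simulate_cells() instead."), call. = FALSE)

  states <- reachable_states(model)
  n_states <- nrow(states)
  key <- function(s) paste(s, collapse = ",")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n_states)) assign(key(states[i, ]), i, envir = idx)

  # transition triplets + blocked boundary rate per state
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  blocked <- numeric(n_states)
  for (i in seq_len(n_states)) {
    s <- states[i, ]
    for (r in model$reactions) {
      a <- r$rate(s)
      if (a <= 0) next
      t_ <- s + r$delta
      if (any(t_ < model$lower) || any(t_ > model$box)) {
        blocked[i] <- blocked[i] + a
        next
      }
      j <- get(key(t_), envir = idx)
      from <- c(from, i); to <- c(to, j); rate <- c(rate, a)
    }
  }

  # closed communicating classes of the reachable truncated chain
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = TRUE, vertices = data.frame(name = seq_len(n_states))
  )
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership[as.character(seq_len(n_states))]
  edge_cross <- memb[from] != memb[to]
  open_classes <- unique(memb[from][edge_cross])
  closed <- setdiff(unique(memb), open_classes)
  if (length(closed) > 1L)
    stop("the truncated chain is reducible with multiple closed classes; ",
         "set `initial_state` to pick one", call. = FALSE)
  if (length(closed) == 0L)
    stop("no closed communicating class found inside the box; enlarge the box",
         call. = FALSE)
  keep <- which(memb == closed)
  remap <- integer(n_states); remap[keep] <- seq_along(keep)
  in_cc <- from %in% keep & to %in% keep
  fi <- remap[from[in_cc]]; ti <- remap[to[in_cc]]; ri <- rate[in_cc]
  nc <- length(keep)

  # generator Q on the closed class; solve t(Q) pi = 0 with normalisation
  exit <- numeric(nc)
  for (k in seq_along(fi)) exit[fi[k]] <- exit[fi[k]] + ri[k]
  Qt <- Matrix::sparseMatrix(i = ti, j = fi, x = ri, dims = c(nc, nc)) +
    Matrix::sparseMatrix(i = seq_len(nc), j = seq_len(nc), x = -exit, dims = c(nc, nc))
  A <- Qt
  A[nc, ] <- 1
  b <- c(rep(0, nc - 1L), 1)
  pi_hat <- tryCatch({
    sol <- as.numeric(Matrix::solve(A, b))
    if (any(!is.finite(sol)) || min(sol) < -1e-10) stop("singular")
    sol
  }, error = function(e) {
    # power iteration on the uniformised chain P = I + Q / lambda
    lambda <- max(exit) * 1.05 + 1e-12
    P <- Matrix::t(Qt) / lambda + Matrix::Diagonal(nc)
    p <- rep(1 / nc, nc)
    for (it in seq_len(200000L)) {
      p_new <- as.numeric(p %*% P)
      p_new <- p_new / sum(p_new)
      if (max(abs(p_new - p)) < 1e-14) { p <- p_new; break }
      p <- p_new
    }
    p
  })
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)

  # certificate: stationary probability flux blocked at the box boundary,
  # converted to a mass scale by the slowest per-state exit rate
  flux <- sum(pi_hat * blocked[keep])
  tail_mass <- if (flux == 0) 0 else flux / min(exit[exit > 0])

  tbl <- tibble::as_tibble(as.data.frame(states[keep, , drop = FALSE]))
  names(tbl) <- model$species
  tbl$prob <- pi_hat
  ord <- do.call(order, lapply(rev(model$species), function(s) tbl[[s]]))
  new_stationary_dist(tbl[ord, ], species = model$species, tail_mass = tail_mass)
}
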