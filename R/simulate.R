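#' Simulation plan for snapshot data
#'
#' Describes how single-cell snapshot data are generated: `n_cells`
#' independent replicate chains are each advanced by the exact stochastic
#' simulation algorithm (Gillespie) to time `t_end`, and the state at
#' `t_end` is the one snapshot per cell. Independent replicate chains (not a
#' thinned single trajectory) is what makes the snapshots i.i.d., which the
#' downstream VMR test assumes. Each cell draws from its own
#' counter-derived random substream, so enlarging `n_cells` never changes
#' the cells already simulated.
#'
#' @param n_cells Number of cells (independent chains), `>= 1`.
#' @param t_end Simulation horizon per chain, in the time units of the rate
#'   constants. `NULL` picks `100 / min(g)` at simulation time, a generous
#'   mixing heuristic for chains whose relaxation rate is set by
#'   degradation.
#' @param burn_in Time that must have elapsed before the snapshot; only
#'   validated against `t_end` (the snapshot is always taken at `t_end`).
#' @param seed Integer root seed.
#' @return A `simulation_plan` object.
#' @export
simulation_plan <- function(n_cells, t_end = NULL, burn_in = 0, seed = 1) {
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 1L, burn_in >= 0)
  if (!is.null(t_end) && t_end <= burn_in)
    stop("need t_end > burn_in", call. = FALSE)
  structure(list(n_cells = n_cells, t_end = t_end, burn_in = burn_in,
                 seed = as.integer(seed)),
            class = "simulation_plan")
}

#' Simulate single-cell snapshot counts from an expression model
#'
#' Runs one exact-SSA chain per cell and returns the snapshot expression
#' matrix in tidy form: one row per cell, one integer count column per gene.
#'
#' @param model A [birth_death_model()], [coupled_model()] or
#'   [multistep_cycle_model()].
#' @param plan A [simulation_plan()].
#' @param ... Passed to methods.
#' @return A tibble with a `cell` column and one column per gene, carrying
#'   attribute `truth` (per-gene `true_autoregulation` label) when the model
#'   declares one.
#' @examples
#' m <- poisson_gene_model(5)
#' sim <- simulate_cells(m, simulation_plan(n_cells = 200, t_end = 20, seed = 7))
#' sample_vmr(sim$gene1)
#' @export
simulate_cells <- function(model, plan, ...) {
  UseMethod("simulate_cells")
}

# tabulate a coupled model's reactions over its full lattice, with
# propensities forced to 0 where the jump would leave the lattice
compile_lattice <- function(model) {
  dims <- model$box - model$lower + 1L
  m <- model$n_species
  grid <- as.matrix(expand.grid(lapply(seq_len(m), function(i)
    seq.int(model$lower[i], model$box[i])), KEEP.OUT.ATTRS = FALSE))
  n_states <- nrow(grid)
  n_r <- length(model$reactions)
  prop <- matrix(0, n_states, n_r)
  deltas <- matrix(0L, n_r, m)
  for (r in seq_len(n_r)) {
    rx <- model$reactions[[r]]
    deltas[r, ] <- rx$delta
    for (s in seq_len(n_states)) {
      st <- grid[s, ]
      tg <- st + rx$delta
      if (any(tg < model$lower) || any(tg > model$box)) next
      a <- rx$rate(st)
      if (a > 0) prop[s, r] <- a
    }
  }
  list(dims = dims, deltas = deltas, prop = prop)
}

resolve_t_end <- function(plan, g_min) {
  if (!is.null(plan$t_end)) return(plan$t_end)
  if (!is.finite(g_min) || g_min <= 0)
    stop("cannot derive a default t_end (no positive degradation rate); set t_end",
         call. = FALSE)
  100 / g_min
}

as_expression_tbl <- function(counts, genes, truth = NULL) {
  counts <- matrix(as.integer(counts), nrow = NROW(counts))
  colnames(counts) <- genes
  out <- dplyr::bind_cols(
    tibble::tibble(cell = paste0("cell_", seq_len(nrow(counts)))),
    tibble::as_tibble(counts)
  )
  attr(out, "truth") <- truth
  out
}

#' @describeIn simulate_cells Single gene: the birth-death chain is embedded
#'   in a one-dimensional lattice sized from its solved stationary support.
#' @param gene Column name for the simulated gene.
#' @param init Initial copy number (default 0).
#' @param event_cap Per-cell safety cap on simulated events.
#' @export
simulate_cells.birth_death_model <- function(model, plan, gene = "gene1",
                                             init = 0L, event_cap = 1e8, ...) {
  sol <- solve_stationary(model, tail_tol = 1e-12)
  n_sup <- max(sol$n)
  n_max <- max(2L * n_sup + 10L, n_sup + 30L, init + 10L)
  ns <- seq_len(n_max)
  f <- model$f(pmin(ns, model$schedule_length))
  g <- model$g(pmin(ns, model$schedule_length))
  if (any(f < 0) || any(g < 0)) stop("negative rate in schedule", call. = FALSE)
  t_end <- resolve_t_end(plan, min(g[g > 0]))
  # 2 reactions on the 0..n_max lattice; birth is target-indexed: rate f[n+1]
  prop <- cbind(c(f, 0), 0:n_max * c(1, g))  # birth blocked at n_max
  snaps <- ssa_lattice_cpp(
    dims = n_max + 1L, deltas = rbind(1L, -1L), prop = prop,
    init = as.integer(init), n_cells = plan$n_cells, t_end = t_end,
    seed = plan$seed, event_cap = event_cap
  )
  as_expression_tbl(snaps, gene,
                    truth = truth_tbl(gene, attr(model, "true_autoregulation")))
}

#' @describeIn simulate_cells Coupled chains: reactions are tabulated over
#'   the truncation box and simulated with one-step (or, for the multistep
#'   cycle, joint) events.
#' @param genes Column names for the simulated species (defaults to the
#'   model's species names).
#' @export
simulate_cells.coupled_model <- function(model, plan, genes = model$species,
                                         init = model$initial_state,
                                         event_cap = 1e8, ...) {
  lat <- compile_lattice(model)
  g_rates <- lat$prop[, vapply(model$reactions, function(r)
    sum(r$delta) < 0 && sum(r$delta != 0L) == 1L, logical(1)), drop = FALSE]
  t_end <- resolve_t_end(plan, if (any(g_rates > 0)) min(g_rates[g_rates > 0]) else NA)
  snaps <- ssa_lattice_cpp(
    dims = lat$dims, deltas = lat$deltas, prop = lat$prop,
    init = as.integer(init - model$lower), n_cells = plan$n_cells,
    t_end = t_end, seed = plan$seed, event_cap = event_cap
  )
  snaps <- sweep(snaps, 2L, -model$lower)
  lab <- attr(model, "true_autoregulation")
  as_expression_tbl(snaps, genes,
                    truth = truth_tbl(genes, rep_len(lab %||% NA_character_, length(genes))))
}

#' @describeIn simulate_cells Multistep gene cycle: a dedicated O(1)-per-event
#'   simulator (stage advance, cycle completion producing one mRNA, mRNA
#'   degradation); returns the mRNA count as the single gene column.
#' @export
simulate_cells.multistep_cycle_model <- function(model, plan, gene = "mRNA",
                                                 event_cap = 1e8, ...) {
  p <- attr(model, "params")
  t_end <- resolve_t_end(plan, p$deg_rate)
  snaps <- ssa_cycle_cpp(
    k_stages = p$k_stages, stage_rate = p$k_stages, deg = p$deg_rate,
    n_cells = plan$n_cells, t_end = t_end, seed = plan$seed,
    event_cap = event_cap
  )
  as_expression_tbl(snaps[, 2L, drop = FALSE], gene,
                    truth = truth_tbl(gene, "none"))
}

truth_tbl <- function(genes, labels) {
  if (is.null(labels) || all(is.na(labels))) return(NULL)
  tibble::tibble(gene = genes, true_autoregulation = labels)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Synthetic expression matrix with ground-truth autoregulation labels
#'
#' Samples a cells-by-genes count matrix from per-gene generating models and
#' attaches the generating truth as metadata, so the inference workflow can
#' be scored end to end. Supported families (one row of `gene_configs` per
#' gene, a `params` list-column holding the family's parameters):
#'
#' * `poisson`: no autoregulation, `params = list(lambda = )`.
#' * `linear_feedback`: `params = list(k = , b = , c = )`; truth is the sign
#'   of `b`.
#' * `environment_driven`: `params = list(q = , synth = , deg = , parents = )`;
#'   `parents` must name the gene's regulators in `network` (the upstream
#'   environment the model abstracts). Truth `"none"`.
#' * `example2_pair`: `params = list(partner = )`; the two genes of the pair
#'   are simulated jointly from [example2_model()] and both carry truth
#'   `"negative"` (sub-Poissonian dynamics generated by regulated
#'   degradation). List the pair once, naming the partner gene.
#'
#' @param network A [grn_network()]; every configured gene that declares
#'   `parents` must have exactly those regulators in the network.
#' @param gene_configs Tibble with columns `gene` (character), `family`
#'   (character) and `params` (list of named lists).
#' @param plan A [simulation_plan()]; each gene consumes an independent seed
#'   derived from `plan$seed` and its column position, so the matrix is
#'   reproducible gene by gene.
#' @return Expression tibble (cell column + one integer column per gene)
#'   with attribute `truth`: a tibble of `gene`, `true_autoregulation`.
#' @export
synthetic_expression <- function(network, gene_configs, plan) {
  stopifnot(is.data.frame(gene_configs),
            all(c("gene", "family", "params") %in% names(gene_configs)))
  if (anyDuplicated(gene_configs$gene))
    stop("duplicate gene in gene_configs", call. = FALSE)
  cfgs <- gene_configs

  cols <- list()
  truths <- list()
  done <- character(0)
  for (i in seq_len(nrow(cfgs))) {
    gene <- cfgs$gene[i]
    if (gene %in% done) next
    fam <- cfgs$family[i]
    p <- cfgs$params[[i]]
    seed_i <- derive_seed(plan$seed, i)
    plan_i <- simulation_plan(plan$n_cells, plan$t_end, plan$burn_in, seed_i)
    sim <- switch(
      fam,
      poisson = simulate_cells(poisson_gene_model(p$lambda), plan_i, gene = gene),
      linear_feedback = withCallingHandlers(
        simulate_cells(linear_feedback_model(p$k, p$b, p$c), plan_i, gene = gene),
        fanoreg_clip_warning = function(w) invokeRestart("muffleWarning")
      ),
      environment_driven = {
        parents <- p$parents %||% character(0)
        missing_edge <- parents[!vapply(parents, function(pg)
          any(network$edges$regulator == pg & network$edges$target == gene),
          logical(1))]
        if (length(missing_edge) > 0)
          stop("config/topology mismatch: ", gene, " lists parent(s) ",
               paste(missing_edge, collapse = ", "),
               " with no matching edge in the network", call. = FALSE)
        joint <- simulate_cells(
          environment_driven_model(p$q, p$synth, p$deg), plan_i,
          genes = c(".env", gene)
        )
        out <- joint[, c("cell", gene)]
        attr(out, "truth") <- truth_tbl(gene, "none")
        out
      },
      example2_pair = {
        partner <- p$partner
        if (is.null(partner) || !partner %in% cfgs$gene)
          stop("example2_pair gene ", gene, " must name a configured `partner`",
               call. = FALSE)
        joint <- simulate_cells(example2_model(), plan_i, genes = c(gene, partner))
        done <- c(done, partner)
        joint
      },
      stop("unknown model family: ", fam, call. = FALSE)
    )
    cols[[length(cols) + 1L]] <- sim[, setdiff(names(sim), "cell"), drop = FALSE]
    truths[[length(truths) + 1L]] <- attr(sim, "truth")
    done <- c(done, gene)
  }
  counts <- dplyr::bind_cols(cols)
  counts <- counts[, intersect(cfgs$gene, names(counts)), drop = FALSE]
  out <- dplyr::bind_cols(tibble::tibble(cell = paste0("cell_", seq_len(plan$n_cells))),
                          counts)
  attr(out, "truth") <- dplyr::bind_rows(truths) |> dplyr::distinct()
  out
}

# independent per-gene seed derived from the root seed; kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + k * 40503) %% 2147483647) + 1L
}

#' Ten-gene benchmark fixture for the inference workflow
#'
#' A fixed study design used throughout the package's evaluation: two
#' acyclic in-network genes with strong negative feedback (`linear_feedback`
#' with `b = -3`, true VMR 0.25), two root genes with positive feedback
#' (`b = 0.5`, true VMR 2) and six Poisson null genes, wired into a small
#' acyclic network. Returns everything needed to score
#' [infer_autoregulation()] against ground truth.
#'
#' @param plan A [simulation_plan()]; `n_cells = 10000` reproduces the
#'   calibration regime the per-gene test is designed for.
#' @return A list with elements `matrix` (expression tibble), `network`
#'   ([grn_network()]) and `truth` (tibble of gene, true_autoregulation).
#' @export
benchmark_fixture <- function(plan) {
  configs <- tibble::tibble(
    gene = c("neg1", "neg2", "pos1", "pos2", paste0("null", 1:6)),
    family = c("linear_feedback", "linear_feedback",
               "linear_feedback", "linear_feedback", rep("poisson", 6)),
    params = list(
      list(k = 8, b = -3, c = 1), list(k = 8, b = -3, c = 1),
      list(k = 1, b = 0.5, c = 1), list(k = 1, b = 0.5, c = 1),
      list(lambda = 10), list(lambda = 10), list(lambda = 10),
      list(lambda = 10), list(lambda = 10), list(lambda = 10)
    )
  )
  # acyclic wiring: the negative-feedback genes have upstream regulators but
  # sit in no directed cycle; the positive-feedback genes are roots
  edges <- tibble::tribble(
    ~regulator, ~target,
    "null1", "neg1",
    "null2", "neg2",
    "pos1",  "null3",
    "pos2",  "null4",
    "null3", "null5",
    "null4", "null6"
  )
  network <- grn_network(edges)
  mat <- synthetic_expression(network, configs, plan)
  list(matrix = mat, network = network, truth = attr(mat, "truth"))
}
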