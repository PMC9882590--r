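test_that("snapshots are reproducible and cell substreams are counter-based", {
  plan <- simulation_plan(60, t_end = 10, seed = 5)
  a <- simulate_cells(poisson_gene_model(2), plan)
  b <- simulate_cells(poisson_gene_model(2), plan)
  expect_identical(a, b)
  # growing n_cells must not reshuffle earlier cells
  bigger <- simulate_cells(poisson_gene_model(2), simulation_plan(100, t_end = 10, seed = 5))
  expect_identical(a$gene1, bigger$gene1[1:60])
  # a different seed gives different data
  other <- simulate_cells(poisson_gene_model(2), simulation_plan(60, t_end = 10, seed = 6))
  expect_false(identical(a$gene1, other$gene1))
})

test_that("plans validate their fields", {
  expect_error(simulation_plan(0), "n_cells")
  expect_error(simulation_plan(10, t_end = 5, burn_in = 5), "t_end > burn_in")
})

test_that("SSA snapshots match the analytic stationary law in total variation", {
  plan <- simulation_plan(20000, t_end = 50, seed = 11)
  for (m in list(poisson_gene_model(2), linear_feedback_model(1, 0.5, 1))) {
    sim <- simulate_cells(m, plan)
    sol <- solve_stationary(m)
    emp <- tabulate(sim$gene1 + 1L, nbins = max(sol$n, max(sim$gene1)) + 1L) / nrow(sim)
    ana <- numeric(length(emp))
    ana[sol$n + 1L] <- sol$prob
    expect_lt(0.5 * sum(abs(emp - ana)), 0.02)
  }
})

test_that("linear feedback simulation recovers VMR = 1 + b/(c - b)", {
  sim <- simulate_cells(linear_feedback_model(1, 0.5, 1),
                        simulation_plan(20000, t_end = 50, seed = 12))
  v <- sample_vmr(sim$gene1)
  mc_se <- sqrt(2 / (v$n - 1)) * 2   # null-scale Monte-Carlo yardstick
  expect_lt(abs(v$vmr - 2), 10 * mc_se)
})

test_that("zero-synthesis chains stay absorbed at zero", {
  m <- birth_death_model(f = function(n) 0, g = function(n) 1)
  sim <- simulate_cells(m, simulation_plan(50, t_end = 5, seed = 1))
  expect_true(all(sim$gene1 == 0L))
})

test_that("coupled two-arm simulation agrees with its exact marginal VMR", {
  sim <- simulate_cells(example2_model(), simulation_plan(20000, t_end = 200, seed = 13))
  truth <- 2 * exp(1) / (4 * exp(1) - 1)
  for (g in c("gene1", "gene2"))
    expect_lt(abs(sample_vmr(sim[[g]])$vmr - truth), 0.05)
  truth_tbl <- attr(sim, "truth")
  expect_equal(truth_tbl$true_autoregulation, c("negative", "negative"))
})

test_that("environment-driven genes without autoregulation stay at VMR >= 1", {
  q <- matrix(c(0, 0.5, 0.8, 0), 2, 2, byrow = TRUE)
  m <- environment_driven_model(q, synth = c(2, 12), deg = 1)
  sol_vmr <- distribution_moments(marginal(solve_stationary(m), "W"))$vmr
  expect_gte(sol_vmr, 1)
  sim <- simulate_cells(m, simulation_plan(20000, t_end = 40, seed = 17))
  v <- sample_vmr(sim$W)
  expect_gt(v$vmr, 1 - 3 * sqrt(2 / (v$n - 1)) * sol_vmr)
  expect_lt(abs(v$vmr - sol_vmr), 0.3)
})

test_that("doubling the horizon leaves the empirical VMR at stationarity", {
  m <- linear_feedback_model(1, 0.5, 1)
  v1 <- sample_vmr(simulate_cells(m, simulation_plan(20000, t_end = 30, seed = 9))$gene1)
  v2 <- sample_vmr(simulate_cells(m, simulation_plan(20000, t_end = 60, seed = 9))$gene1)
  mc_se <- sqrt(2 / (v1$n - 1)) * 2   # VMR ~ 2 scales the null SE roughly 2x
  expect_lt(abs(v1$vmr - v2$vmr), 3 * mc_se)
})

test_that("multistep cycle: solver refuses, simulator concentrates the count", {
  m <- multistep_cycle_model(100, 0.01)
  expect_error(solve_stationary(m), "multistep")
  sim <- simulate_cells(m, simulation_plan(800, t_end = 600, seed = 21))
  v <- sample_vmr(sim$mRNA)
  expect_lt(abs(v$mean - 100), 5)
  expect_lt(v$vmr, 0.7)  # clearly sub-Poissonian despite no autoregulation
  # degenerate single-stage cycle is one-step and Poissonian
  m1 <- multistep_cycle_model(1, 0.01)
  sol <- glance(solve_stationary(m1))
  expect_equal(sol$vmr[sol$species == "mRNA"], 1, tolerance = 1e-6)
  expect_equal(sol$mean[sol$species == "mRNA"], 100, tolerance = 1e-3)
})

test_that("synthetic matrices carry per-gene truth and honour topology checks", {
  net <- grn_network(tibble::tibble(regulator = "A", target = "B"))
  cfg <- tibble::tibble(
    gene = c("A", "B", "C"),
    family = c("poisson", "linear_feedback", "poisson"),
    params = list(list(lambda = 5), list(k = 8, b = -3, c = 1), list(lambda = 3))
  )
  mat <- synthetic_expression(net, cfg, simulation_plan(500, t_end = 20, seed = 3))
  expect_equal(names(mat), c("cell", "A", "B", "C"))
  truth <- attr(mat, "truth")
  expect_equal(truth$true_autoregulation[match(c("A", "B", "C"), truth$gene)],
               c("none", "negative", "none"))
  expect_true(all(vapply(mat[-1], is.integer, logical(1))))

  # an environment-driven gene must name real regulators
  cfg_bad <- tibble::tibble(
    gene = "B", family = "environment_driven",
    params = list(list(q = matrix(c(0, 1, 1, 0), 2), synth = c(1, 5), deg = 1,
                       parents = "Z"))
  )
  expect_error(synthetic_expression(net, cfg_bad, simulation_plan(10, t_end = 5, seed = 1)),
               "topology mismatch")

  # paired two-arm genes are simulated jointly
  cfg_pair <- tibble::tibble(
    gene = c("P1", "P2"), family = "example2_pair",
    params = list(list(partner = "P2"), list(partner = "P1"))
  )
  mp <- synthetic_expression(net, cfg_pair, simulation_plan(200, t_end = 50, seed = 8))
  expect_equal(names(mp), c("cell", "P1", "P2"))
})

test_that("the ten-gene benchmark fixture has the planted structure", {
  fx <- benchmark_fixture(simulation_plan(300, t_end = 20, seed = 2))
  expect_equal(ncol(fx$matrix), 11L)
  expect_equal(sort(fx$truth$true_autoregulation),
               sort(c(rep("negative", 2), rep("positive", 2), rep("none", 6))))
  expect_equal(length(ancestors(fx$network, "pos1")), 0L)
  expect_gt(length(ancestors(fx$network, "neg1")), 0L)
  expect_false(in_directed_cycle(fx$network, "neg1"))
})
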