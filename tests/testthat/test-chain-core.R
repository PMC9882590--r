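test_that("relative growth rate is the elementwise f/g ratio", {
  m <- birth_death_model(f = function(n) rep(2, length(n)),
                         g = function(n) rep(1, length(n)))
  expect_equal(relative_growth(m, n_max = 5)$h, rep(2, 5))

  lin <- linear_feedback_model(k = 1, b = 0.5, c = 1)
  expect_equal(relative_growth(lin, n_max = 3)$h, c(1, 1.5, 2))

  z <- birth_death_model(f = rep(0, 4), g = rep(1, 4))
  expect_equal(relative_growth(z)$h, rep(0, 4))

  bad <- birth_death_model(f = c(1, 1), g = c(1, 1))
  bad$g <- function(n) c(1, 0)[n]
  expect_error(relative_growth(bad, 2), "n = 2")
})

test_that("rate classification finds rises and falls beyond tolerance", {
  expect_equal(classify_rates(c(2, 2, 2, 2)), character(0))
  expect_equal(classify_rates(c(1, 1.5, 2)), "positive")
  expect_setequal(classify_rates(c(1, 3, 2)), c("positive", "negative"))
  # float noise below the relative tolerance is not a signal
  expect_equal(classify_rates(c(1, 1 + 1e-13, 1)), character(0))
  expect_error(classify_rates(2), "insufficient")
  # accepts the relative_growth tibble directly
  expect_equal(classify_rates(relative_growth(linear_feedback_model(1, 0.5, 1), 10)),
               "positive")
})

test_that("constant h gives the Poisson stationary law", {
  d <- solve_stationary(birth_death_model(function(n) 2, function(n) 1))
  expect_equal(d$prob[1], exp(-2), tolerance = 1e-12)
  expect_equal(d$prob, dpois(d$n, 2) / sum(dpois(d$n, 2)), tolerance = 1e-12)
  g <- glance(d)
  expect_equal(g$mean, 2, tolerance = 1e-9)
  expect_equal(g$vmr, 1, tolerance = 1e-9)
  expect_lt(attr(d, "tail_mass"), 1e-12)
})

test_that("linear feedback model reproduces VMR = 1 + b/(c - b)", {
  expect_equal(glance(solve_stationary(linear_feedback_model(1, 0.5, 1)))$vmr,
               2, tolerance = 1e-9)
  expect_equal(glance(solve_stationary(linear_feedback_model(5, 0, 1)))$vmr,
               1, tolerance = 1e-9)
  expect_warning(m <- linear_feedback_model(2, -0.5, 1), "clipped")
  expect_equal(glance(solve_stationary(m))$vmr, 2 / 3, tolerance = 1e-9)
  expect_error(linear_feedback_model(1, 2, 1), "c - b > 0")
  expect_error(linear_feedback_model(1, 0.5, 0), "c > 0")
  # cross-check one solve against the blunt truncated recurrence
  ora <- oracle_moments(oracle_stationary(function(n) (1 + 0.5 * (n - 1)) / 1))
  expect_equal(glance(solve_stationary(linear_feedback_model(1, 0.5, 1)))$vmr,
               unname(ora["vmr"]), tolerance = 1e-9)
})

test_that("zero synthesis gives a point mass at zero with undefined VMR", {
  d <- solve_stationary(birth_death_model(f = function(n) 0, g = function(n) 1))
  expect_equal(nrow(d), 1L)
  expect_equal(d$prob, 1)
  mom <- distribution_moments(d)
  expect_true(is.na(mom$vmr))
  expect_false(mom$vmr_defined)
})

test_that("non-normalizable models are refused", {
  # h_n = n grows without bound: no stationary law
  expect_error(
    solve_stationary(birth_death_model(f = function(n) n^2, g = function(n) 1),
                     max_states = 5000),
    "non-normalizable"
  )
})

test_that("solved single-gene laws satisfy detailed balance state by state", {
  models <- list(
    linear_feedback_model(1, 0.5, 1),
    poisson_gene_model(7),
    birth_death_model(f = function(n) 3 / n, g = function(n) 0.5 + 0.1 * n)
  )
  for (m in models) {
    d <- solve_stationary(m)
    n <- d$n[-1]
    lhs <- d$prob[-1] * n * m$g(n)
    rhs <- d$prob[-nrow(d)] * m$f(n)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("monotone h schedules bound the VMR on the right side of 1", {
  set.seed(401)
  for (i in 1:30) {
    h_up <- random_monotone_h(sample(4:12, 1), increasing = TRUE)
    expect_gt(glance(solve_stationary(model_from_monotone_h(h_up)))$vmr, 1)
    h_dn <- random_monotone_h(sample(4:12, 1), increasing = FALSE, h0 = runif(1, 2, 6))
    expect_lt(glance(solve_stationary(model_from_monotone_h(h_dn)))$vmr, 1)
  }
  expect_equal(glance(solve_stationary(poisson_gene_model(3)))$vmr, 1,
               tolerance = 1e-9)
})

test_that("auto truncation is certified: explicit deeper truncation agrees", {
  m_auto <- linear_feedback_model(1, 0.5, 1)
  v_auto <- glance(solve_stationary(m_auto, tail_tol = 1e-10))$vmr
  m_deep <- linear_feedback_model(1, 0.5, 1)
  m_deep$max_state <- 500L
  v_deep <- glance(solve_stationary(m_deep))$vmr
  expect_lt(abs(v_auto - v_deep), 10 * 1e-10)
})

test_that("two-arm coupled model matches the arm-summation series exactly", {
  d <- solve_stationary(example2_model())
  ora <- oracle_example2()
  for (sp in c("gene1", "gene2")) {
    mom <- distribution_moments(marginal(d, sp))
    expect_equal(mom$mean, ora$mean, tolerance = 1e-9)
    expect_equal(mom$vmr, ora$vmr, tolerance = 1e-9)
    expect_equal(mom$mean, (6 * exp(1) - 2) / (4 * exp(1) - 1), tolerance = 1e-9)
  }
  expect_equal(d$prob[d$gene1 == 2 & d$gene2 == 2], 1 / (4 * exp(1) - 1),
               tolerance = 1e-9)
  m1 <- marginal(d, 1)
  expect_equal(m1$prob[m1$n == 2], ora$p_gene1_eq_2, tolerance = 1e-9)
  # symmetry under coordinate swap
  expect_equal(marginal(d, 1)$prob, marginal(d, 2)$prob, tolerance = 1e-12)
})

test_that("coupled solver factorises independent genes and embeds the single solver", {
  m <- coupled_model(
    synth = list(function(n) 2, function(n) 3),
    deg = list(function(n) 1, function(n) 1),
    box = c(25, 30), initial_state = c(0, 0)
  )
  d <- solve_stationary(m)
  m2 <- marginal(d, 2)
  expect_lt(sum(abs(m2$prob - dpois(m2$n, 3) / sum(dpois(m2$n, 3)))), 1e-9)
  expect_equal(distribution_moments(marginal(d, 1))$vmr, 1, tolerance = 1e-8)

  # 1-species coupled chain vs the recurrence solver: same law to 1e-9 TV
  single <- solve_stationary(poisson_gene_model(2))
  emb <- solve_stationary(coupled_model(
    synth = list(function(n) 2), deg = list(function(n) 1),
    box = 40, initial_state = 0
  ))
  common <- seq_len(min(nrow(single), nrow(emb)))
  expect_lt(sum(abs(single$prob[common] - emb$prob[common])), 1e-9)
})

test_that("expanding the truncation box does not move the two-arm law", {
  d30 <- solve_stationary(example2_model(box = 30), tail_tol = 1e-9)
  d60 <- solve_stationary(example2_model(box = 60), tail_tol = 1e-9)
  key30 <- paste(d30$gene1, d30$gene2)
  key60 <- paste(d60$gene1, d60$gene2)
  shared <- intersect(key30, key60)
  expect_lt(max(abs(d30$prob[match(shared, key30)] - d60$prob[match(shared, key60)])),
            1e-9)
})

test_that("marginals are identities in 1-D and carry tail mass through", {
  d <- solve_stationary(poisson_gene_model(4))
  expect_identical(marginal(d, 1), d)
  e2 <- solve_stationary(example2_model())
  expect_equal(attr(marginal(e2, "gene1"), "tail_mass"), attr(e2, "tail_mass"))
  expect_error(marginal(e2, 3), "out of range")
  expect_error(marginal(e2, "geneX"), "unknown species")
})

test_that("reducible boxes without a reachable closed class are diagnosed", {
  # both species frozen unless the other is at 2, but started off both arms:
  # nothing can ever move, the single absorbing state is its own closed class
  m <- coupled_model(
    synth = list(function(n) if (n[2] == 2) 1 else 0,
                 function(n) if (n[1] == 2) 1 else 0),
    deg = list(function(n) if (n[2] == 2) 1 else 0,
               function(n) if (n[1] == 2) 1 else 0),
    box = c(10, 10), initial_state = c(5, 5)
  )
  d <- solve_stationary(m)
  expect_equal(nrow(d), 1L)
  expect_equal(d$gene1, 5L)
})
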