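# deterministic toy counts with a prescribed VMR verdict at n = 400:
# interval at n = 400 is roughly (0.87, 1.14)
counts_below <- rep(c(3, 3, 3, 3), 100)              # vmr 0
counts_above <- rep(c(0, 0, 0, 12), 100)             # vmr = 9
set.seed(123)
counts_pois  <- rpois(400, 8)

mk_matrix <- function(...) {
  cols <- list(...)
  dplyr::bind_cols(tibble::tibble(cell = paste0("c", seq_along(cols[[1]]))),
                   tibble::as_tibble(cols))
}

test_that("branch order: below-1 on acyclic in-network genes wins first", {
  net <- grn_network(tibble::tibble(regulator = "up", target = "root_like"))
  # root_like has no ancestor? it has ancestor "up". give a true root too:
  net2 <- grn_network(tibble::tibble(regulator = "a", target = "b"))
  m <- mk_matrix(a = counts_below, b = counts_pois)
  calls <- infer_autoregulation(m, net2)
  a_row <- calls[calls$gene == "a", ]
  # "a" is a root *and* acyclic with VMR below: the below-1 branch must win
  expect_equal(a_row$verdict, "negative_autoregulation")
  expect_equal(a_row$proposition, "prop2")
  expect_true(all(c("one_step_assumed", "degradation_constant_assumed") %in%
                    a_row$caveats[[1]]))
  expect_false("in_cycle" %in% a_row$caveats[[1]])
})

test_that("positive calls need a root gene and carry the autonomy caveat", {
  net <- grn_network(tibble::tibble(regulator = "root", target = "child"))
  m <- mk_matrix(root = counts_above, child = counts_above)
  calls <- infer_autoregulation(m, net)
  r <- calls[calls$gene == "root", ]
  expect_equal(r$verdict, "positive_autoregulation")
  expect_equal(r$proposition, "prop1")
  expect_true("autonomy_assumed" %in% r$caveats[[1]])
  expect_false("has_ancestor" %in% r$caveats[[1]])
  # the child is over-dispersed but has an ancestor: undetermined
  ch <- calls[calls$gene == "child", ]
  expect_equal(ch$verdict, "undetermined")
  expect_true("has_ancestor" %in% ch$caveats[[1]])
})

test_that("cycle members and out-of-network genes are undetermined", {
  net <- grn_network(tibble::tibble(regulator = c("p", "q"), target = c("q", "p")))
  m <- mk_matrix(p = counts_below, q = counts_pois, stray = counts_below)
  calls <- infer_autoregulation(m, net)
  p_row <- calls[calls$gene == "p", ]
  expect_equal(p_row$verdict, "undetermined")   # below 1 but inside a feedback loop
  expect_true("in_cycle" %in% p_row$caveats[[1]])
  s_row <- calls[calls$gene == "stray", ]
  expect_equal(s_row$verdict, "undetermined")
  expect_true("not_in_network" %in% s_row$caveats[[1]])
})

test_that("undefined VMR and zero-variance genes are handled, not fatal", {
  net <- grn_network(tibble::tibble(regulator = "a", target = "b"))
  m <- mk_matrix(a = rep(0, 400), b = counts_below)
  expect_message(calls <- infer_autoregulation(m, net), "zero variance")
  a_row <- calls[calls$gene == "a", ]
  expect_equal(a_row$verdict, "undetermined")
  expect_true("vmr_undefined" %in% a_row$caveats[[1]])
  b_row <- calls[calls$gene == "b", ]
  expect_equal(b_row$verdict, "negative_autoregulation")
})

test_that("no-autoregulation is never a verdict; every gene gets exactly one", {
  fx <- benchmark_fixture(simulation_plan(500, t_end = 20, seed = 77))
  calls <- infer_autoregulation(fx$matrix, fx$network)
  expect_equal(nrow(calls), 10L)
  expect_true(all(calls$verdict %in%
    c("negative_autoregulation", "positive_autoregulation", "undetermined")))
  expect_false(any(grepl("no_autoregulation|none", calls$verdict)))
  expect_true(all((calls$verdict == "undetermined") == (calls$proposition == "none")))
})

test_that("count policy: non-integer data error unless explicitly rounded", {
  net <- grn_network(tibble::tibble(regulator = "a", target = "b"))
  m <- mk_matrix(a = counts_pois + 0.5, b = counts_pois)
  expect_error(infer_autoregulation(m, net), "molecule counts")
  expect_warning(calls <- infer_autoregulation(m, net, allow_noninteger = TRUE),
                 "rounded")
  expect_equal(nrow(calls), 2L)
  m_neg <- mk_matrix(a = c(-1, rep(1, 399)), b = counts_pois)
  expect_error(infer_autoregulation(m_neg, net), "negative")
})

test_that("gene matching is case-sensitive unless explicitly folded", {
  net <- grn_network(tibble::tibble(regulator = "UP", target = "TGT"))
  m <- mk_matrix(tgt = counts_below)
  strict <- infer_autoregulation(m, net)
  expect_true("not_in_network" %in% strict$caveats[[1]])
  expect_equal(strict$verdict, "undetermined")
  folded <- infer_autoregulation(m, net, case_insensitive = TRUE)
  expect_equal(folded$verdict, "negative_autoregulation")
  expect_equal(folded$gene, "tgt")
})

test_that("optional BH correction only makes calls more conservative", {
  fx <- benchmark_fixture(simulation_plan(2000, t_end = 20, seed = 31))
  plain <- infer_autoregulation(fx$matrix, fx$network)
  bh <- infer_autoregulation(fx$matrix, fx$network, p_adjust = "BH")
  det <- function(x) sum(x$verdict != "undetermined")
  expect_lte(det(bh), det(plain) + 0L)
  expect_true(all(bh$p_value >= plain$p_value, na.rm = TRUE))
})

test_that("summaries count verdicts and score against truth", {
  fx <- benchmark_fixture(simulation_plan(2000, t_end = 20, seed = 52))
  calls <- infer_autoregulation(fx$matrix, fx$network)
  s <- summarize_calls(calls)
  expect_equal(sum(s$n_genes), 10L)
  conf <- summarize_calls(calls, truth = fx$truth)
  expect_equal(sum(conf$n_genes), 10L)
  expect_true(all(c("verdict", "true_autoregulation") %in% names(conf)))
  # empty input
  empty <- calls[0, ]
  expect_equal(nrow(summarize_calls(empty)), 0L)
  g <- glance(calls)
  expect_equal(g$n_genes, 10L)
  expect_equal(g$n_negative + g$n_positive + g$n_undetermined, 10L)
})

test_that("tidy and autoplot produce flat tables and a ggplot", {
  fx <- benchmark_fixture(simulation_plan(300, t_end = 20, seed = 5))
  calls <- infer_autoregulation(fx$matrix, fx$network)
  flat <- tidy(calls)
  expect_true(is.character(flat$caveats))
  p <- autoplot(calls)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(solve_stationary(poisson_gene_model(3))), "ggplot")
  expect_s3_class(autoplot(solve_stationary(example2_model())), "ggplot")
})
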