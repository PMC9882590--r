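#' Infer gene autoregulation from snapshot counts and a known GRN
#'
#' Combines the per-gene Fano-factor test with the structure of a known gene
#' regulatory network. For each measured gene, in this order:
#'
#' 1. If the gene is in the network, **not** in a directed cycle, and its
#'    sample VMR is significantly *below* 1: call
#'    `negative_autoregulation` (the below-1 result for one-step chains with
#'    unregulated degradation; caveats `one_step_assumed`,
#'    `degradation_constant_assumed`).
#' 2. Otherwise, if the gene has **no ancestor** in the network and its VMR
#'    is significantly *above* 1: call `positive_autoregulation` (the
#'    autonomous single-gene result; caveat `autonomy_assumed`, because
#'    autonomy cannot be verified from snapshot data and this branch is the
#'    less reliable of the two).
#' 3. Otherwise `undetermined`.
#'
#' The below-1 branch is evaluated first: when a gene qualifies for both, the
#' below-1 result is the more reliable call because it does not assume
#' autonomous expression. Genes absent from the network are `undetermined`
#' with caveat `not_in_network`; genes with undefined VMR (all-zero counts)
#' are `undetermined` with caveat `vmr_undefined`. The workflow never emits
#' a "no autoregulation" verdict — a VMR consistent with 1 is uninformative,
#' not evidence of absence.
#'
#' @param matrix Expression tibble: `cell` column (or row identifiers in the
#'   first column) plus one non-negative integer count column per gene, as
#'   produced by [simulate_cells()], [synthetic_expression()] or
#'   [read_expression()].
#' @param net A [grn_network()].
#' @param alpha Per-gene two-sided test level (default 0.05, applied per
#'   gene with no multiplicity correction, the workflow's reference
#'   behaviour).
#' @param p_adjust `"none"` (default) or `"BH"`: Benjamini-Hochberg
#'   adjustment of the per-gene Gamma-test p-values, an optional deviation
#'   from the reference behaviour.
#' @param allow_noninteger If `FALSE` (default), non-integer counts are an
#'   error — the method is defined on molecule counts. If `TRUE`, counts
#'   are rounded with a warning.
#' @param case_insensitive Match matrix gene names to network gene names
#'   case-insensitively. Off by default: silent case-folding corrupts symbol
#'   namespaces (mouse vs human conventions), so it must be asked for.
#' @return An `autoreg_calls` tibble: `gene`, `verdict`, `proposition`
#'   (`"prop2"` for the below-1 branch, `"prop1"` for the above-1 branch,
#'   `"none"`), `n`, `mean`, `variance`, `vmr`, `ci_lo`, `ci_hi`,
#'   `p_value`, `caveats` (list-column of flags).
#' @examples
#' plan <- simulation_plan(n_cells = 2000, seed = 42)
#' fx <- benchmark_fixture(plan)
#' calls <- infer_autoregulation(fx$matrix, fx$network)
#' summarize_calls(calls, truth = fx$truth)
#' @export
infer_autoregulation <- function(matrix, net, alpha = 0.05,
                                 p_adjust = c("none", "BH"),
                                 allow_noninteger = FALSE,
                                 case_insensitive = FALSE) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(matrix), inherits(net, "grn_network"))
  counts <- validate_counts(matrix, allow_noninteger)
  genes <- colnames(counts)
  if (length(genes) == 0) stop("expression matrix has no gene columns", call. = FALSE)

  tests <- purrr::map_dfr(genes, function(g) {
    out <- vmr_test(counts[, g], alpha)
    out$gene <- g
    out
  })

  if (p_adjust == "BH") {
    adj <- stats::p.adjust(tests$p_value, method = "BH")
    # rescore verdicts from adjusted p-values, keeping the direction
    tests$verdict <- dplyr::case_when(
      is.na(adj) ~ NA_character_,
      adj <= alpha & tests$vmr < 1 ~ "below",
      adj <= alpha & tests$vmr > 1 ~ "above",
      TRUE ~ "consistent"
    )
    tests$p_value <- adj
  }

  if (case_insensitive) {
    folded <- net$edges
    folded$regulator <- toupper(folded$regulator)
    folded$target <- toupper(folded$target)
    net <- suppressMessages(grn_network(folded, genes = toupper(net$genes)))
    struct <- structural_report(net, toupper(genes))
    struct$gene <- genes[match(struct$gene, toupper(genes))]
    struct <- struct[!is.na(struct$gene), ]
  } else {
    struct <- structural_report(net, genes)
  }

  joined <- dplyr::left_join(tests, struct, by = "gene")
  decided <- purrr::pmap_dfr(
    joined[, c("verdict", "vmr_defined", "in_network", "in_cycle",
               "has_ancestor", "self_loop")],
    function(verdict, vmr_defined, in_network, in_cycle, has_ancestor, self_loop) {
      res <- branch_call(verdict, vmr_defined, in_network, in_cycle,
                         has_ancestor, self_loop)
      tibble::tibble(final_verdict = res$final_verdict,
                     proposition = res$proposition, caveats = res$caveats)
    })
  calls <- dplyr::bind_cols(joined, decided)

  zero_var <- calls$variance == 0 & calls$mean > 0
  if (any(zero_var))
    message("gene(s) with zero variance and positive mean (VMR = 0): ",
            paste(calls$gene[zero_var], collapse = ", "),
            " - often a data problem, called by the usual branch logic")

  out <- calls |>
    dplyr::select("gene", verdict = "final_verdict", "proposition", "n", "mean",
                  "variance", "vmr", "ci_lo", "ci_hi", "p_value", "caveats")
  class(out) <- c("autoreg_calls", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  out
}

# one gene's branch decision; `verdict` is the VMR test verdict
branch_call <- function(verdict, vmr_defined, in_network, in_cycle,
                        has_ancestor, self_loop) {
  caveats <- character(0)
  if (!in_network) caveats <- c(caveats, "not_in_network")
  if (in_cycle) caveats <- c(caveats, "in_cycle")
  if (has_ancestor) caveats <- c(caveats, "has_ancestor")
  if (self_loop) caveats <- c(caveats, "self_loop_in_grn")
  if (!vmr_defined) {
    return(list(final_verdict = "undetermined", proposition = "none",
                caveats = list(c(caveats, "vmr_undefined"))))
  }
  if (in_network && !in_cycle && identical(verdict, "below")) {
    return(list(final_verdict = "negative_autoregulation", proposition = "prop2",
                caveats = list(c(setdiff(caveats, "in_cycle"),
                                 "one_step_assumed", "degradation_constant_assumed"))))
  }
  if (in_network && !has_ancestor && identical(verdict, "above")) {
    return(list(final_verdict = "positive_autoregulation", proposition = "prop1",
                caveats = list(c(setdiff(caveats, "has_ancestor"), "autonomy_assumed"))))
  }
  list(final_verdict = "undetermined", proposition = "none",
       caveats = list(caveats))
}

validate_counts <- function(matrix, allow_noninteger) {
  first <- matrix[[1]]
  gene_cols <- if (is.character(first) || is.factor(first))
    setdiff(names(matrix), names(matrix)[1]) else names(matrix)
  if (length(gene_cols) == 0 || nrow(matrix) == 0)
    stop("empty expression matrix", call. = FALSE)
  if (anyDuplicated(gene_cols))
    stop("duplicate gene names in expression matrix", call. = FALSE)
  counts <- as.matrix(matrix[, gene_cols, drop = FALSE])
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("expression matrix contains missing values", call. = FALSE)
  if (any(counts < 0)) stop("expression matrix contains negative values", call. = FALSE)
  nonint <- abs(counts - round(counts)) > 1e-8
  if (any(nonint)) {
    if (!allow_noninteger)
      stop("expression matrix contains non-integer values; the method is defined ",
           "on molecule counts (set allow_noninteger = TRUE to round, at your own risk)",
           call. = FALSE)
    warning("rounded ", sum(nonint), " non-integer count(s)", call. = FALSE)
    counts <- round(counts)
  }
  colnames(counts) <- gene_cols
  counts
}

#' Summarise autoregulation calls
#'
#' Counts calls per verdict and proposition; with ground-truth labels
#' (e.g. from [synthetic_expression()]), cross-tabulates verdicts against
#' the truth instead, which is how the synthetic benchmarks are scored.
#'
#' @param calls An `autoreg_calls` tibble from [infer_autoregulation()].
#' @param truth Optional tibble with columns `gene`, `true_autoregulation`
#'   (`"positive"`, `"negative"`, `"none"`).
#' @return A tibble of counts: `verdict`, `proposition`, `n_genes` — or,
#'   with truth, `verdict`, `true_autoregulation`, `n_genes`.
#' @export
summarize_calls <- function(calls, truth = NULL) {
  stopifnot(is.data.frame(calls))
  if (is.null(truth)) {
    return(dplyr::count(tibble::as_tibble(calls), .data$verdict,
                        .data$proposition, name = "n_genes"))
  }
  stopifnot(all(c("gene", "true_autoregulation") %in% names(truth)))
  tibble::as_tibble(calls) |>
    dplyr::left_join(truth, by = "gene") |>
    dplyr::count(.data$verdict, .data$true_autoregulation, name = "n_genes")
}

#' @export
tidy.autoreg_calls <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$caveats <- vapply(out$caveats, paste, character(1), collapse = ";")
  out
}

#' @export
glance.autoreg_calls <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_negative = sum(x$verdict == "negative_autoregulation"),
    n_positive = sum(x$verdict == "positive_autoregulation"),
    n_undetermined = sum(x$verdict == "undetermined"),
    alpha = attr(x, "alpha"),
    p_adjust = attr(x, "p_adjust")
  )
}

#' @export
autoplot.autoreg_calls <- function(object, ...) {
  d <- tidy(object)
  d$gene <- stats::reorder(d$gene, d$vmr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$vmr,
                                  colour = .data$verdict)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sample VMR (bars: Poisson-null interval)",
                  colour = "verdict")
}
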