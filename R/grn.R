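#' Gene regulatory network
#'
#' A directed graph of genes: each edge `regulator -> target` is a known
#' regulatory relationship. The inference workflow needs two structural
#' queries from it: the ancestor set of a gene (all genes with a directed
#' path into it) and whether a gene sits in a directed cycle (feedback
#' loop). Self-loops are accepted in the input but reported: a self-loop is
#' itself an autoregulation annotation, so a self-looped gene is treated as
#' already annotated rather than eligible for inference.
#'
#' @param edges Data frame whose first two columns are regulator and target
#'   gene identifiers (extra columns are ignored).
#' @param genes Optional character vector of additional isolated genes.
#' @return An object of class `grn_network` with elements `genes`, `edges`
#'   (tibble `regulator`, `target`) and `self_loops`.
#' @examples
#' net <- grn_network(tibble::tibble(regulator = c("A", "B"), target = c("B", "C")))
#' ancestors(net, "C")
#' @export
grn_network <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && ncol(edges) < 2)
    stop("`edges` needs two columns: regulator, target", call. = FALSE)
  e <- tibble::tibble(regulator = as.character(edges[[1]]),
                      target = as.character(edges[[2]]))
  dup <- nrow(e) - nrow(dplyr::distinct(e))
  if (dup > 0) {
    message("dropped ", dup, " duplicate edge(s)")
    e <- dplyr::distinct(e)
  }
  self <- e$regulator[e$regulator == e$target]
  if (length(self) > 0)
    message("input contains self-loop(s) on: ", paste(unique(self), collapse = ", "),
            " (treated as declared autoregulation)")
  all_genes <- unique(c(e$regulator, e$target, as.character(genes)))
  g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                     vertices = data.frame(name = all_genes))
  structure(list(genes = all_genes, edges = e, self_loops = unique(self),
                 graph = g),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network>", length(x$genes), "genes,", nrow(x$edges), "edges")
  if (length(x$self_loops) > 0)
    cat(",", length(x$self_loops), "self-loop(s)")
  cat("\n")
  invisible(x)
}

#' Read a gene regulatory network from a two-column edge list
#'
#' Parses a TSV of `regulator <TAB> target` rows. Lines starting with `#`
#' are comments; a leading header row is detected when both fields match
#' common column-name vocabulary (`regulator`, `target`, `from`, `to`,
#' `source`, `tf`, `gene`). Duplicate edges are dropped with a message; a
#' row without exactly two fields is a parse error naming the line.
#'
#' @param path Path to the edge-list file.
#' @param sep Field separator (default tab; use "," for CSV edge lists).
#' @return A [grn_network()].
#' @export
read_grn <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) return(grn_network(tibble::tibble(regulator = character(0),
                                                           target = character(0))))
  parts <- strsplit(lines[keep], sep, fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0)
    stop("parse error at line ", keep[bad[1]], ": expected 2 tab-separated fields, got ",
         lengths(parts)[bad[1]], call. = FALSE)
  mat <- do.call(rbind, parts)
  header_vocab <- c("regulator", "target", "from", "to", "source", "tf", "gene",
                    "gene1", "gene2", "parent", "child")
  first <- tolower(trimws(mat[1, ]))
  if (all(first %in% header_vocab)) mat <- mat[-1, , drop = FALSE]
  grn_network(tibble::tibble(regulator = trimws(mat[, 1]),
                             target = trimws(mat[, 2])))
}

#' Ancestors of a gene in the network
#'
#' All genes with a directed path of length at least 1 into `gene`. The gene
#' itself is included only when it lies on a directed cycle through itself
#' (including a self-loop). A gene with no ancestors is a network root — the
#' "no upstream regulator" condition of the positive-autoregulation branch.
#'
#' @param net A [grn_network()].
#' @param gene Gene identifier.
#' @return Character vector of ancestor genes (possibly empty).
#' @export
ancestors <- function(net, gene) {
  stopifnot(inherits(net, "grn_network"))
  if (!gene %in% net$genes) stop("unknown gene: ", gene, call. = FALSE)
  anc <- names(igraph::subcomponent(net$graph, gene, mode = "in"))
  anc <- setdiff(anc, gene)
  if (in_directed_cycle(net, gene)) anc <- c(gene, anc)
  sort(anc)
}

#' Is a gene in a directed cycle?
#'
#' True iff the gene belongs to a strongly connected component of size at
#' least 2, or carries a self-loop. Genes in a feedback loop cannot be
#' classified by the below-1 branch of the inference workflow, because a
#' loop can push the VMR below 1 without autoregulation.
#'
#' @inheritParams ancestors
#' @return Logical scalar.
#' @export
in_directed_cycle <- function(net, gene) {
  stopifnot(inherits(net, "grn_network"))
  if (!gene %in% net$genes) stop("unknown gene: ", gene, call. = FALSE)
  if (gene %in% net$self_loops) return(TRUE)
  comp <- igraph::components(net$graph, mode = "strong")
  sum(comp$membership == comp$membership[[gene]]) >= 2L
}

#' Structural eligibility report for a set of measured genes
#'
#' For every gene in the network and/or the expression matrix, reports the
#' flags the inference workflow branches on: network membership, presence of
#' ancestors, directed-cycle membership, and whether the gene was measured.
#' Measured genes absent from the network cannot be classified at all and
#' are flagged here.
#'
#' @param net A [grn_network()] (may be empty).
#' @param genes_in_matrix Character vector of measured gene names.
#' @return Tibble: `gene`, `in_network`, `has_ancestor`, `in_cycle`,
#'   `in_matrix`, `self_loop`.
#' @export
structural_report <- function(net, genes_in_matrix = character(0)) {
  stopifnot(inherits(net, "grn_network"))
  all_genes <- union(net$genes, genes_in_matrix)
  purrr::map_dfr(all_genes, function(g) {
    in_net <- g %in% net$genes
    tibble::tibble(
      gene = g,
      in_network = in_net,
      has_ancestor = in_net && length(ancestors(net, g)) > 0,
      in_cycle = in_net && in_directed_cycle(net, g),
      in_matrix = g %in% genes_in_matrix,
      self_loop = g %in% net$self_loops
    )
  })
}
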