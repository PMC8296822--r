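#' Read a scored PPI edge list (STRING dialect)
#'
#' Expects a TSV with header `protein1  protein2  combined_score`, scores
#' being integers in `[0, 999]`.  Self-loops are dropped and duplicate
#' unordered pairs collapsed to their maximum score, each with a warning.
#'
#' @param path path to the PPI TSV.
#' @return a data.frame with columns `gene_a`, `gene_b`, `combined_score`
#'   (unordered pairs stored with `gene_a <= gene_b`), of class
#'   `c("dcnet_ppi", "data.frame")`.
#' @export
read_ppi <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "numeric"))
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(tab)))
    stop("PPI file must have columns ", paste(need, collapse = ", "),
         ": ", path)
  ppi_network(tab$protein1, tab$protein2, tab$combined_score)
}

#' Construct a scored PPI network from vectors
#'
#' @param gene_a,gene_b endpoint gene identifiers.
#' @param combined_score integer confidence scores in `[0, 999]`.
#' @return a `dcnet_ppi` data.frame (see [read_ppi()]).
#' @export
ppi_network <- function(gene_a, gene_b, combined_score) {
  if (any(combined_score %% 1 != 0) ||
      any(combined_score < 0 | combined_score > 999))
    stop("combined_score must be integers in [0, 999]")
  p <- order_pairs(gene_a, gene_b)
  p$combined_score <- as.integer(combined_score)
  loops <- p$gene_a == p$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    p <- p[!loops, , drop = FALSE]
  }
  key <- paste(p$gene_a, p$gene_b)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate edge(s) collapsed to maximum score")
    p <- p[order(key, -p$combined_score), , drop = FALSE]
    p <- p[!duplicated(paste(p$gene_a, p$gene_b)), , drop = FALSE]
  }
  p <- p[order(p$gene_a, p$gene_b), , drop = FALSE]
  rownames(p) <- NULL
  class(p) <- c("dcnet_ppi", "data.frame")
  p
}

#' Filter a PPI network by combined score
#'
#' Retains high-confidence interactions.  With `strict = TRUE` (the
#' default) an edge is kept when its score is strictly greater than
#' `min_score`; with `strict = FALSE` the comparison is `>=`.  The
#' operation is idempotent.
#'
#' @param ppi a `dcnet_ppi` data.frame.
#' @param min_score score threshold (default 900).
#' @param strict logical; strictly-greater comparison (default `TRUE`).
#' @return the filtered `dcnet_ppi` data.frame.
#' @export
filter_ppi <- function(ppi, min_score = 900, strict = TRUE) {
  keep <- if (strict) ppi$combined_score > min_score
          else ppi$combined_score >= min_score
  out <- ppi[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the wild-type disease-related network (WDRN)
#'
#' The WDRN is the subgraph of the (score-filtered) PPI made of every edge
#' with at least one differentially expressed endpoint.  Its node set is
#' the union of retained edge endpoints; DEGs with no retained incident
#' edge therefore do not appear.
#'
#' @param filtered_ppi a `dcnet_ppi` data.frame, typically from
#'   [filter_ppi()].
#' @param deg_set character vector of DEG gene ids (may be empty).
#' @param tissue tissue label recorded as provenance.
#' @return an object of class `"dcnet_wdrn"`: list with `edges`
#'   (`gene_a`, `gene_b`, `combined_score`), `nodes` (`gene_id`, `is_deg`)
#'   and `tissue`.
#' @export
build_wdrn <- function(filtered_ppi, deg_set, tissue = "tissue") {
  deg_set <- unique(normalize_gene_id(deg_set))
  keep <- filtered_ppi$gene_a %in% deg_set | filtered_ppi$gene_b %in% deg_set
  edges <- filtered_ppi[keep, c("gene_a", "gene_b", "combined_score"),
                        drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- data.frame(gene_id = ids, is_deg = ids %in% deg_set,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, tissue = tissue),
            class = "dcnet_wdrn")
}

#' @export
print.dcnet_wdrn <- function(x, ...) {
  cs <- coverage_stats(x$nodes, x$edges)
  cat("WDRN [", x$tissue, "]: ", cs$n_edges, " edges, ", cs$n_nodes,
      " nodes, ", cs$n_deg_nodes, " DEGs (",
      formatC(cs$deg_coverage_pct, format = "f", digits = 2), "%)\n",
      sep = "")
  invisible(x)
}

#' Network coverage statistics
#'
#' Counts edges, nodes and DEG nodes, and reports the DEG share of the
#' node set as a percentage truncated (not rounded) to two decimals.
#'
#' @param nodes data.frame with columns `gene_id` and logical `is_deg`.
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @return list with `n_edges`, `n_nodes`, `n_deg_nodes`,
#'   `deg_coverage_pct` (`NA` when the network has no nodes).
#' @export
coverage_stats <- function(nodes, edges) {
  n_nodes <- nrow(nodes)
  n_deg <- sum(nodes$is_deg)
  list(n_edges = nrow(edges), n_nodes = n_nodes, n_deg_nodes = n_deg,
       deg_coverage_pct = truncate_pct(n_deg, n_nodes))
}

#' Write a WDRN (or DN) to edge/node TSVs and GraphML
#'
#' @param net a `dcnet_wdrn` or `dcnet_dn` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default the class-specific network name.
#' @return invisibly, a named vector of file paths.
#' @export
write_network <- function(net, dir,
                          prefix = if (inherits(net, "dcnet_dn")) "dn"
                                   else "wdrn") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  p_nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  p_gml <- file.path(dir, paste0(prefix, ".graphml"))
  utils::write.table(net$edges, p_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, p_nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- edges_to_igraph(net$edges, vertices = net$nodes$gene_id)
  igraph::V(g)$is_deg <- net$nodes$is_deg[match(igraph::V(g)$name,
                                                net$nodes$gene_id)]
  igraph::write_graph(g, p_gml, format = "graphml")
  invisible(c(edges = p_edges, nodes = p_nodes, graphml = p_gml))
}
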