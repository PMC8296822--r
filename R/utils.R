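# Internal helpers shared across modules.

# Canonical unordered edge representation: gene_a <= gene_b lexicographically.
order_pairs <- function(a, b) {
  a <- normalize_gene_id(a)
  b <- normalize_gene_id(b)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

edge_key <- function(a, b) {
  p <- order_pairs(a, b)
  paste(p$gene_a, p$gene_b, sep = "\t")
}

# Edge data.frame -> igraph, keeping extra edge columns as attributes.
edges_to_igraph <- function(edges, vertices = NULL) {
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (!is.null(vertices) && length(vertices))
      g <- igraph::add_vertices(g, length(vertices), name = vertices)
    return(g)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

# Density of a simple undirected graph with nv vertices and ne edges.
graph_density <- function(nv, ne) {
  if (nv < 2L) return(0)
  2 * ne / (nv * (nv - 1))
}

# Truncate (floor) a percentage to two decimals, computed so that ratios of
# integer counts never suffer a floating-point boundary error.
truncate_pct <- function(numerator, denominator) {
  if (denominator == 0) return(NA_real_)
  (10000 * numerator) %/% denominator / 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a
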