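#' Differential co-expression network analysis for one tissue
#'
#' Runs the full per-tissue chain: DEG calling, score filtering of the
#' PPI, wild-type disease-related network (WDRN) construction,
#' condition-specific Spearman classification of every WDRN edge,
#' differential network (DN) assembly, MCODE-style module detection on
#' the DN, and hub selection.
#'
#' @param expr a `dcnet_expr` object (see [expression_set()],
#'   [read_expression()]).
#' @param ppi a `dcnet_ppi` scored edge list (see [read_ppi()]).
#' @param tissue tissue label carried through all results.
#' @param p_threshold,lfc_threshold,deg_method,adjust DEG-calling
#'   parameters, see [call_degs()].
#' @param min_score,strict PPI score filter, see [filter_ppi()].
#' @param alpha,cor_method edge-classification parameters, see
#'   [classify_edges()].
#' @param vwp,haircut,fluff,min_module_score module-detection parameters,
#'   see [find_modules()].
#' @param hub_threshold hub selection threshold, see [select_hubs()].
#' @return object of class `"dcnet"`: list with components `tissue`,
#'   `degs`, `deg_set`, `ppi_filtered`, `wdrn`, `edge_correlations`,
#'   `dn`, `modules`, `hubs`, `coverage` (WDRN and DN coverage stats) and
#'   `params`.
#' @examples
#' tis <- simulate_tissue(sim_config(n_genes = 60, n_ppi_edges = 120,
#'                                   seed = 7))
#' fit <- dcnet(tis$expr, tis$ppi, tissue = "demo")
#' fit
#' @export
dcnet <- function(expr, ppi, tissue = "tissue",
                  p_threshold = 0.05, lfc_threshold = 0.5,
                  deg_method = c("moderated", "welch"),
                  adjust = c("none", "BH"),
                  min_score = 900, strict = TRUE,
                  alpha = 0.05,
                  cor_method = c("auto", "exact", "t_approx"),
                  vwp = 0.2, haircut = TRUE, fluff = FALSE,
                  min_module_score = 3, hub_threshold = 10) {
  deg_method <- match.arg(deg_method)
  adjust <- match.arg(adjust)
  cor_method <- match.arg(cor_method)
  degs <- call_degs(expr, p_threshold, lfc_threshold, deg_method, adjust)
  deg_set <- degs$gene_id[degs$is_deg]
  filtered <- filter_ppi(ppi, min_score, strict)
  wdrn <- build_wdrn(filtered, deg_set, tissue)
  cors <- classify_edges(wdrn, expr, alpha, cor_method)
  dn <- build_dn(cors, wdrn)
  modules <- find_modules(dn$edges, vwp = vwp, haircut = haircut,
                          fluff = fluff,
                          min_component_score = min_module_score)
  hubs <- select_hubs(dn$edges, modules, hub_threshold)
  structure(list(
    tissue = tissue,
    degs = degs,
    deg_set = deg_set,
    ppi_filtered = filtered,
    wdrn = wdrn,
    edge_correlations = cors,
    dn = dn,
    modules = modules,
    hubs = hubs,
    coverage = list(wdrn = coverage_stats(wdrn$nodes, wdrn$edges),
                    dn = coverage_stats(dn$nodes, dn$edges)),
    params = list(p_threshold = p_threshold,
                  lfc_threshold = lfc_threshold,
                  deg_method = deg_method, adjust = adjust,
                  min_score = min_score, strict = strict, alpha = alpha,
                  cor_method = cor_method, vwp = vwp, haircut = haircut,
                  fluff = fluff, min_module_score = min_module_score,
                  hub_threshold = hub_threshold)),
    class = "dcnet")
}

#' @export
print.dcnet <- function(x, ...) {
  cat("dcnet analysis [", x$tissue, "]\n", sep = "")
  cat("  DEGs: ", length(x$deg_set), " of ", nrow(x$degs),
      " genes (p < ", x$params$p_threshold, ", |log2FC| > ",
      x$params$lfc_threshold, ", ", x$params$deg_method, ")\n", sep = "")
  print(x$wdrn)
  print(x$dn)
  cat("  modules: ", nrow(x$modules), " with score > ",
      x$params$min_module_score, "; hubs: ", nrow(x$hubs), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dcnet <- function(object, ...) {
  cw <- object$coverage$wdrn
  cd <- object$coverage$dn
  out <- list(
    tissue = object$tissue,
    n_genes = nrow(object$degs),
    n_degs = length(object$deg_set),
    wdrn_edges = cw$n_edges, wdrn_nodes = cw$n_nodes,
    wdrn_deg_nodes = cw$n_deg_nodes,
    wdrn_deg_coverage_pct = cw$deg_coverage_pct,
    dn_edges = cd$n_edges, dn_nodes = cd$n_nodes,
    dn_deg_nodes = cd$n_deg_nodes,
    dn_deg_coverage_pct = cd$deg_coverage_pct,
    n_gained = sum(object$dn$edges$status == "gained"),
    n_lost = sum(object$dn$edges$status == "lost"),
    n_modules = nrow(object$modules),
    top_module_score = if (nrow(object$modules)) object$modules$score[1]
                       else NA_real_,
    hubs = object$hubs)
  class(out) <- "summary.dcnet"
  out
}

#' @export
print.summary.dcnet <- function(x, ...) {
  cat("dcnet analysis [", x$tissue, "]\n", sep = "")
  cat("  genes tested:      ", x$n_genes, "\n", sep = "")
  cat("  DEGs:              ", x$n_degs, "\n", sep = "")
  cat("  WDRN:              ", x$wdrn_edges, " edges, ", x$wdrn_nodes,
      " nodes, ", x$wdrn_deg_nodes, " DEGs (",
      formatC(x$wdrn_deg_coverage_pct, format = "f", digits = 2),
      "%)\n", sep = "")
  cat("  DN:                ", x$dn_edges, " edges (", x$n_gained,
      " gained, ", x$n_lost, " lost), ", x$dn_nodes, " nodes, ",
      x$dn_deg_nodes, " DEGs (",
      formatC(x$dn_deg_coverage_pct, format = "f", digits = 2),
      "%)\n", sep = "")
  cat("  modules retained:  ", x$n_modules,
      if (!is.na(x$top_module_score))
        paste0(" (top score ", format(x$top_module_score, digits = 3), ")"),
      "\n", sep = "")
  if (nrow(x$hubs)) {
    cat("  hub genes:\n")
    print(x$hubs, row.names = FALSE)
  } else cat("  hub genes:         none\n")
  invisible(x)
}

#' Plot a differential network
#'
#' Draws the DN with the conventions of differential-network figures:
#' gained edges (activated in disease) red, lost edges green, edge width
#' proportional to the perturbation magnitude, DEG nodes filled.
#'
#' @param x a `dcnet` fit or a `dcnet_dn` object.
#' @param ... passed to [igraph::plot.igraph()].
#' @return invisibly, the igraph object drawn.
#' @export
plot.dcnet <- function(x, ...) plot(x$dn, ...)

#' @rdname plot.dcnet
#' @export
plot.dcnet_dn <- function(x, ...) {
  if (nrow(x$edges) == 0L) {
    warning("empty differential network; nothing to plot")
    return(invisible(NULL))
  }
  g <- edges_to_igraph(x$edges[, c("gene_a", "gene_b")],
                       vertices = x$nodes$gene_id)
  st <- x$edges$status
  igraph::E(g)$color <- ifelse(st == "gained", "red3", "green4")
  igraph::E(g)$width <- 1 + 3 * x$edges$magnitude /
    max(x$edges$magnitude, 1e-9)
  isdeg <- x$nodes$is_deg[match(igraph::V(g)$name, x$nodes$gene_id)]
  igraph::V(g)$color <- ifelse(isdeg, "grey30", "grey85")
  igraph::V(g)$label.cex <- 0.6
  plot(g, ...)
  invisible(g)
}
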