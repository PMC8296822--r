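# MCODE-style dense-region detection: vertex weighting by the
# core-clustering coefficient, greedy seeded expansion, haircut
# post-processing and density x size scoring.

# adjacency list (named list of character vectors) from an edge data.frame
adjacency_list <- function(edges, vertices = NULL) {
  verts <- sort(unique(c(edges$gene_a, edges$gene_b, vertices)))
  adj <- lapply(stats::setNames(vector("list", length(verts)), verts),
                function(x) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]
    b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# highest k-core of the subgraph induced on `members`; returns
# list(k, vertices) -- k = 0 with all vertices when the subgraph is empty
# of edges, k = NULL when members is empty.
highest_core <- function(adj, members) {
  deg_in <- function(keep)
    vapply(keep, function(v) sum(adj[[v]] %in% keep), integer(1L))
  keep <- members
  best <- list(k = 0L, vertices = members)
  k <- 1L
  repeat {
    # peel to the k-core
    repeat {
      dg <- deg_in(keep)
      drop <- names(dg)[dg < k]
      if (!length(drop) || !length(keep)) break
      keep <- setdiff(keep, drop)
    }
    if (!length(keep)) break
    best <- list(k = k, vertices = keep)
    k <- k + 1L
  }
  best
}

count_edges_within <- function(adj, members) {
  sum(vapply(members, function(v) sum(adj[[v]] %in% members),
             integer(1L))) / 2
}

#' MCODE vertex weights (core-clustering coefficient)
#'
#' For each vertex `v`, the highest k-core of the closed neighborhood
#' `N[v]` is found; the weight is `k` times the density of that core.
#' Isolated vertices have weight 0.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` describing a
#'   simple undirected graph.
#' @param vertices optional character vector of vertex names (to include
#'   isolated vertices).
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(edges, vertices = NULL) {
  adj <- adjacency_list(edges, vertices)
  w <- vapply(names(adj), function(v) {
    nb <- adj[[v]]
    if (!length(nb)) return(0)
    closed <- c(v, nb)
    core <- highest_core(adj, closed)
    if (core$k == 0L) return(0)
    nv <- length(core$vertices)
    ne <- count_edges_within(adj, core$vertices)
    core$k * graph_density(nv, ne)
  }, numeric(1L))
  w
}

#' Find dense modules (MCODE-style)
#'
#' Vertices are seeded in decreasing weight order (ties broken by
#' lexicographic vertex name).  From each unused seed, expansion
#' recursively admits unused neighbors whose weight exceeds
#' `seed_weight * (1 - vwp)`.  Each vertex belongs to at most one
#' candidate module.  With `haircut = TRUE` the candidate is reduced to
#' its 2-core (iterative removal of degree-1 members); with
#' `fluff = TRUE` unused neighbors whose closed-neighborhood density
#' exceeds `fluff_density` are appended afterwards.  Candidates with
#' fewer than 2 members are dropped; retained modules must have
#' `score = density * n_members` strictly greater than
#' `min_component_score`.
#'
#' @param edges graph edge data.frame (`gene_a`, `gene_b`).
#' @param vwp vertex weight percentage in `[0, 1)`, default 0.2.
#' @param haircut drop degree-1 members (default `TRUE`).
#' @param fluff append dense boundary vertices (default `FALSE`).
#' @param fluff_density closed-neighborhood density cutoff used when
#'   `fluff = TRUE` (default 0.1).
#' @param min_component_score strict lower bound on the module score
#'   (default 3).
#' @return object of class `"dcnet_modules"`: data.frame with columns
#'   `module_id`, `seed`, `n_members`, `density`, `score`, `members`
#'   (semicolon-separated, sorted), ordered by decreasing score.
#' @export
find_modules <- function(edges, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1, min_component_score = 3) {
  if (!is.finite(vwp) || vwp < 0 || vwp >= 1)
    stop("'vwp' must be in [0, 1)")
  adj <- adjacency_list(edges)
  w <- vertex_weights(edges)
  ord <- names(w)[order(-w, names(w))]
  used <- character()
  records <- list()
  for (seed in ord) {
    if (seed %in% used) next
    cutoff <- w[[seed]] * (1 - vwp)
    members <- seed
    frontier <- seed
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        cand <- setdiff(adj[[v]], c(members, used))
        cand <- cand[w[cand] > cutoff]
        nxt <- c(nxt, cand)
      }
      nxt <- unique(nxt)
      members <- c(members, nxt)
      frontier <- nxt
    }
    # every touched member is consumed, kept module or not
    used <- c(used, members)
    if (haircut) {
      repeat {
        dg <- vapply(members, function(v) sum(adj[[v]] %in% members),
                     integer(1L))
        drop <- members[dg < 2L]
        if (!length(drop)) break
        members <- setdiff(members, drop)
      }
    }
    if (fluff && length(members)) {
      boundary <- setdiff(unique(unlist(adj[members])), c(members, used))
      dens <- vapply(boundary, function(v) {
        closed <- c(v, adj[[v]])
        graph_density(length(closed), count_edges_within(adj, closed))
      }, numeric(1L))
      add <- boundary[dens > fluff_density]
      members <- c(members, add)
      used <- c(used, add)
    }
    if (length(members) < 2L) next
    nv <- length(members)
    ne <- count_edges_within(adj, members)
    dens <- graph_density(nv, ne)
    score <- dens * nv
    if (score > min_component_score)
      records[[length(records) + 1L]] <-
        data.frame(seed = seed, n_members = nv, density = dens,
                   score = score,
                   members = paste(sort(members), collapse = ";"),
                   stringsAsFactors = FALSE)
  }
  if (!length(records)) {
    out <- data.frame(module_id = integer(), seed = character(),
                      n_members = integer(), density = numeric(),
                      score = numeric(), members = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, records)
    out <- out[order(-out$score, out$seed), , drop = FALSE]
    out <- cbind(module_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  }
  class(out) <- c("dcnet_modules", "data.frame")
  out
}

module_members <- function(modules, i) {
  strsplit(modules$members[i], ";", fixed = TRUE)[[1L]]
}

#' Select hub genes from modules
#'
#' A gene's hub score is its degree in the tissue network restricted to
#' the members of its module.  Genes with a score strictly greater than
#' `hub_threshold` are hubs.  When no module gene passes the threshold,
#' the single maximum-score gene is returned with
#' `rule = "fallback_max"` (lexicographic tie-break), so a best candidate
#' is always reported for a non-empty module list.
#'
#' @param edges the tissue network edge data.frame the modules were
#'   derived from.
#' @param modules a `dcnet_modules` data.frame.
#' @param hub_threshold strict score threshold, default 10.
#' @return data.frame with columns `gene_id`, `hub_score`, `module_id`,
#'   `rule` (`"threshold"` or `"fallback_max"`); empty for an empty
#'   module list.
#' @export
select_hubs <- function(edges, modules, hub_threshold = 10) {
  empty <- data.frame(gene_id = character(), hub_score = integer(),
                      module_id = integer(), rule = character(),
                      stringsAsFactors = FALSE)
  if (nrow(modules) == 0L) return(empty)
  adj <- adjacency_list(edges)
  cand <- do.call(rbind, lapply(seq_len(nrow(modules)), function(i) {
    mem <- module_members(modules, i)
    data.frame(gene_id = mem,
               hub_score = vapply(mem, function(v)
                 sum(adj[[v]] %in% mem), integer(1L)),
               module_id = modules$module_id[i],
               stringsAsFactors = FALSE)
  }))
  hubs <- cand[cand$hub_score > hub_threshold, , drop = FALSE]
  if (nrow(hubs)) {
    hubs$rule <- "threshold"
  } else {
    best <- cand[order(-cand$hub_score, cand$gene_id), , drop = FALSE][1L, ]
    best$rule <- "fallback_max"
    hubs <- best
  }
  hubs <- hubs[order(-hubs$hub_score, hubs$gene_id), , drop = FALSE]
  rownames(hubs) <- NULL
  hubs
}

#' Merge per-tissue networks into one annotated graph
#'
#' Takes a named list of networks (`dcnet_wdrn` or `dcnet_dn` objects, or
#' plain edge data.frames) over the same identifier space and returns
#' their node/edge union, with every node and edge annotated with the set
#' of contributing tissues; DEG flags are kept tissue-resolved.
#'
#' @param networks named list (names are tissue labels), length >= 2.
#' @return list of class `"dcnet_merged"` with `edges` (`gene_a`,
#'   `gene_b`, `tissues` semicolon-joined) and `nodes` (`gene_id`,
#'   `tissues`, `deg_in` tissues where the gene is a DEG).
#' @export
merge_networks <- function(networks) {
  if (length(networks) < 2L) stop("need at least two networks")
  labels <- names(networks)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == ""))
    stop("'networks' must be a named list with unique tissue labels")
  edge_tissues <- list()
  node_tissues <- list()
  node_deg <- list()
  for (lab in labels) {
    net <- networks[[lab]]
    edges <- if (is.data.frame(net)) net else net$edges
    nodes <- if (is.data.frame(net)) NULL else net$nodes
    keys <- edge_key(edges$gene_a, edges$gene_b)
    for (k in keys) edge_tissues[[k]] <- c(edge_tissues[[k]], lab)
    ids <- if (!is.null(nodes)) nodes$gene_id
           else unique(c(edges$gene_a, edges$gene_b))
    for (id in ids) node_tissues[[id]] <- c(node_tissues[[id]], lab)
    if (!is.null(nodes))
      for (id in nodes$gene_id[nodes$is_deg])
        node_deg[[id]] <- c(node_deg[[id]], lab)
  }
  keys <- sort(names(edge_tissues) %||% character(0))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(parts, `[`, "", 1L),
    gene_b = vapply(parts, `[`, "", 2L),
    tissues = vapply(keys, function(k)
      paste(sort(unique(edge_tissues[[k]])), collapse = ";"),
      "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  ids <- sort(names(node_tissues) %||% character(0))
  nodes <- data.frame(
    gene_id = ids,
    tissues = vapply(ids, function(i)
      paste(sort(unique(node_tissues[[i]])), collapse = ";"), ""),
    deg_in = vapply(ids, function(i)
      paste(sort(unique(node_deg[[i]])), collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(edges = edges, nodes = nodes, tissues = labels),
            class = "dcnet_merged")
}

#' @export
print.dcnet_merged <- function(x, ...) {
  cat("merged network over {", paste(x$tissues, collapse = ", "), "}: ",
      nrow(x$edges), " edges, ", nrow(x$nodes), " nodes\n", sep = "")
  invisible(x)
}
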