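# Independent oracles used by the tests.  These deliberately do not share
# code with the package internals they check.

# all permutations of 1..n, one per row (plain recursive construction)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  unname(out)
}

# brute-force two-sided exact Spearman p: enumerate every ordering of y
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  P <- oracle_perms(n)
  u <- rank(x)
  v <- rank(y)
  obs <- cor(u, v)
  vperm <- matrix(v[t(P)], n, nrow(P))
  rhos <- as.vector(cor(u, vperm))
  mean(abs(rhos) >= abs(obs) - 1e-9)
}

# brute-force core-clustering coefficient: for vertex v, scan every
# subset of its closed neighborhood for the highest attainable minimum
# induced degree; the highest core is the union of all subsets attaining
# it.  A is a symmetric 0/1 adjacency matrix with dimnames.
oracle_vertex_weight <- function(A, v) {
  nb <- which(A[v, ] > 0)
  if (!length(nb)) return(0)
  closed <- sort(unique(c(which(rownames(A) == v), nb)))
  m <- length(closed)
  kmax <- 0L
  core <- integer()
  for (mask in seq_len(2^m - 1L)) {
    S <- closed[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0]
    if (length(S) < 2L) next
    mind <- min(rowSums(A[S, S, drop = FALSE]))
    if (mind > kmax) {
      kmax <- mind
      core <- S
    } else if (mind == kmax && kmax > 0L) {
      core <- sort(unique(c(core, S)))
    }
  }
  if (kmax == 0L) return(0)
  nv <- length(core)
  ne <- sum(A[core, core]) / 2
  kmax * (2 * ne / (nv * (nv - 1)))
}

# random simple graph as an edge data.frame plus adjacency matrix
random_graph <- function(n, p, labels = sprintf("V%02d", seq_len(n))) {
  A <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1L
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  edges <- data.frame(gene_a = labels[idx[, 1]], gene_b = labels[idx[, 2]],
                      stringsAsFactors = FALSE)
  list(A = A, edges = edges)
}

# unordered-pair keys for comparing edge sets
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# edge data.frame of the complete graph over the given vertices
clique_edges <- function(genes, score = NULL) {
  cmb <- t(combn(genes, 2L))
  out <- data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(score)) out$combined_score <- score
  out
}

# small deterministic expression fixture: g genes, nh + nd samples
tiny_expr <- function(g = 4, nh = 3, nd = 3, seed = 1) {
  set.seed(seed)
  genes <- paste0("G", seq_len(g))
  m <- matrix(rnorm(g * (nh + nd), mean = 8, sd = 1), g, nh + nd,
              dimnames = list(genes,
                              c(paste0("H", seq_len(nh)),
                                paste0("D", seq_len(nd)))))
  expression_set(m, setNames(rep(c("healthy", "disease"), c(nh, nd)),
                             colnames(m)))
}
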