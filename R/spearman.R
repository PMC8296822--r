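# Spearman correlation with exact permutation p-values.
#
# At the sample sizes this pipeline targets (3-6 per condition) the
# t approximation to the Spearman null is anticonservative, so the exact
# permutation null is used by default whenever it is enumerable.

# cache of permutation matrices and no-tie null |rho| tables, keyed by n
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  if (n > 8L) stop("exact enumeration supported only for n <= 8")
  perm_rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perm_rec(v[-i]), deparse.level = 0)
    }))
  }
  m <- perm_rec(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

# sorted |rho| values over all permutations of untied ranks 1..n
null_abs_rho <- function(n) {
  key <- paste0("null", n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  u <- seq_len(n)
  v <- sort(abs(perm_rho_dist(u, u)))
  .perm_cache[[key]] <- v
  v
}

# rho between ranks u and every permutation of ranks v
perm_rho_dist <- function(u, v) {
  n <- length(u)
  P <- all_permutations(n)
  uc <- u - mean(u)
  vperm <- matrix(v[P], nrow(P), n)
  num <- as.vector(vperm %*% uc)
  den <- sqrt(sum(uc^2) * sum((v - mean(v))^2))
  if (den == 0) return(rep(NA_real_, nrow(P)))
  num / den
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of the average-ranked values:
#' `rho = S_uv / sqrt(S_u^2 * S_v^2)` with `S_uv` the sample covariance of
#' the rank vectors and `S_u^2`, `S_v^2` their sample variances.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return the coefficient in `[-1, 1]`, or `NA` if either vector is
#'   constant (undefined correlation).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  u <- rank(x)
  v <- rank(y)
  su2 <- stats::var(u)
  sv2 <- stats::var(v)
  if (su2 == 0 || sv2 == 0) return(NA_real_)
  suv <- stats::cov(u, v)
  suv / sqrt(su2 * sv2)
}

#' P-value for a Spearman correlation
#'
#' `method = "exact"` enumerates the permutation null: all `n!` orderings
#' of one rank vector, two-sided, with the observed ordering included in
#' the count (so `p > 0`).  With tied ranks the enumeration conditions on
#' the observed tie pattern, which requires the rank vectors themselves
#' (`ranks_x`, `ranks_y`).  `method = "t_approx"` uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df; at `|rho| = 1`
#' the p-value is set to the smallest representable positive value.
#' `method = "auto"` (default) picks exact when `n <= 8` and the ranks are
#' untied (or unavailable, assumed untied), otherwise the t approximation.
#'
#' @param rho observed Spearman coefficient, `|rho| <= 1`.
#' @param n number of paired observations, `n >= 3`.
#' @param method `"auto"`, `"exact"` or `"t_approx"`.
#' @param ranks_x,ranks_y optional rank vectors (needed for exact
#'   enumeration under ties).
#' @return two-sided p-value in `(0, 1]`.
#' @export
spearman_pvalue <- function(rho, n, method = c("auto", "exact", "t_approx"),
                            ranks_x = NULL, ranks_y = NULL) {
  method <- match.arg(method)
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) > 1 + 1e-8) stop("|rho| must be <= 1")
  if (n < 3L) stop("need n >= 3")
  has_ties <- !is.null(ranks_x) &&
    (anyDuplicated(ranks_x) > 0L || anyDuplicated(ranks_y) > 0L)
  if (method == "auto")
    method <- if (n <= 8L && !has_ties) "exact" else "t_approx"
  if (method == "exact") {
    if (has_ties) {
      dist <- abs(perm_rho_dist(ranks_x, ranks_y))
      return(mean(dist >= abs(rho) - 1e-9))
    }
    tab <- null_abs_rho(n)
    # count of permutations with |rho_perm| >= |rho_obs|
    idx <- findInterval(abs(rho) - 1e-9, tab)
    return((length(tab) - idx) / length(tab))
  }
  if (abs(rho) >= 1) return(.Machine$double.xmin)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Classify WDRN edges by condition-specific correlation
#'
#' For every WDRN edge, computes the Spearman correlation and its p-value
#' separately in healthy and disease samples and labels the edge
#' `"gained"` (significant only in disease), `"lost"` (significant only in
#' health) or `"none"`.  Edges whose genes are missing from the expression
#' set are skipped with a warning; edges with a constant expression vector
#' in either condition get status `"none"` with `NA` correlations.
#'
#' @param wdrn a `dcnet_wdrn` object.
#' @param expr a `dcnet_expr` object covering both conditions.
#' @param alpha per-test significance level in (0, 1), default 0.05.
#' @param method p-value method passed to [spearman_pvalue()].
#' @param adjust `"none"` (default, per-test alpha) or `"BH"` across edges
#'   within each condition.
#' @return data.frame of class `c("dcnet_edge_cor", "data.frame")` with
#'   columns `gene_a`, `gene_b`, `rho_healthy`, `p_healthy`,
#'   `rho_disease`, `p_disease`, `n_healthy`, `n_disease`, `status`,
#'   `perturbation` (`rho_disease - rho_healthy`) and `magnitude`.
#' @export
classify_edges <- function(wdrn, expr, alpha = 0.05,
                           method = c("auto", "exact", "t_approx"),
                           adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  edges <- wdrn$edges
  h <- condition_matrix(expr, "healthy")
  d <- condition_matrix(expr, "disease")
  present <- edges$gene_a %in% rownames(expr$values) &
    edges$gene_b %in% rownames(expr$values)
  if (any(!present)) {
    warning(sum(!present),
            " edge(s) skipped: gene(s) absent from the expression set")
    edges <- edges[present, , drop = FALSE]
  }
  n <- nrow(edges)
  rho_h <- rho_d <- p_h <- p_d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- edges$gene_a[i]
    b <- edges$gene_b[i]
    rho_h[i] <- spearman_rho(h[a, ], h[b, ])
    rho_d[i] <- spearman_rho(d[a, ], d[b, ])
    if (!is.na(rho_h[i]))
      p_h[i] <- spearman_pvalue(rho_h[i], ncol(h), method,
                                rank(h[a, ]), rank(h[b, ]))
    if (!is.na(rho_d[i]))
      p_d[i] <- spearman_pvalue(rho_d[i], ncol(d), method,
                                rank(d[a, ]), rank(d[b, ]))
  }
  ph_flag <- p_h
  pd_flag <- p_d
  if (adjust == "BH") {
    ph_flag <- stats::p.adjust(p_h, method = "BH")
    pd_flag <- stats::p.adjust(p_d, method = "BH")
  }
  sig_h <- !is.na(ph_flag) & ph_flag < alpha
  sig_d <- !is.na(pd_flag) & pd_flag < alpha
  status <- rep("none", n)
  status[sig_d & !sig_h] <- "gained"
  status[sig_h & !sig_d] <- "lost"
  out <- data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                    rho_healthy = rho_h, p_healthy = p_h,
                    rho_disease = rho_d, p_disease = p_d,
                    n_healthy = rep(ncol(h), n),
                    n_disease = rep(ncol(d), n),
                    status = status,
                    perturbation = rho_d - rho_h,
                    stringsAsFactors = FALSE)
  out$magnitude <- abs(out$perturbation)
  class(out) <- c("dcnet_edge_cor", "data.frame")
  out
}

#' Assemble the differential network (DN)
#'
#' The DN keeps exactly the WDRN edges classified as differentially
#' correlated (`status != "none"`).  Each edge carries its direction
#' (`gained` = activated in disease, `lost` = inactivated in disease) and
#' `magnitude = |rho_disease - rho_healthy|`, the perturbation weight used
#' for edge widths in plots.
#'
#' @param edge_correlations output of [classify_edges()].
#' @param wdrn the `dcnet_wdrn` the correlations were computed on.
#' @return an object of class `"dcnet_dn"`: list with `edges` (the DCG
#'   rows), `nodes` (`gene_id`, `is_deg`) and `tissue`.
#' @export
build_dn <- function(edge_correlations, wdrn) {
  edges <- edge_correlations[edge_correlations$status != "none", ,
                             drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- data.frame(
    gene_id = ids,
    is_deg = ids %in% wdrn$nodes$gene_id[wdrn$nodes$is_deg],
    stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, tissue = wdrn$tissue),
            class = "dcnet_dn")
}

#' @export
print.dcnet_dn <- function(x, ...) {
  cs <- coverage_stats(x$nodes, x$edges)
  cat("differential network [", x$tissue, "]: ", cs$n_edges,
      " DCG edges (", sum(x$edges$status == "gained"), " gained, ",
      sum(x$edges$status == "lost"), " lost), ", cs$n_nodes, " nodes, ",
      cs$n_deg_nodes, " DEGs (",
      formatC(cs$deg_coverage_pct, format = "f", digits = 2), "%)\n",
      sep = "")
  invisible(x)
}

#' Export a differential network in SIF format
#'
#' One line per edge: `gene_a dcg gene_b`.
#'
#' @param dn a `dcnet_dn` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sif <- function(dn, path) {
  lines <- paste(dn$edges$gene_a, "dcg", dn$edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}
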