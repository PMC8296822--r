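#' Simulation configuration
#'
#' Parameters for the synthetic-data generator.  Defaults describe a
#' small two-condition study with six samples per group (a
#' three-per-group preset mirrors small public microarray series:
#' set `n_healthy = n_disease = 3`), log2-scale intensities with
#' Gaussian noise, a planted fraction of differentially expressed genes,
#' and condition-specific correlated gene pairs confined to
#' high-confidence PPI edges.
#'
#' @param n_genes number of genes (default 300).
#' @param n_ppi_edges number of PPI edges (default 900); must not exceed
#'   `n_genes * (n_genes - 1) / 2`.
#' @param score_range integer interval for combined scores, within
#'   `[150, 999]` (default `c(150, 999)`).
#' @param fraction_above_900 fraction of edges drawn with score > 900
#'   (default 0.5; forced to 0 or 1 when `score_range` lies entirely on
#'   one side of 900).
#' @param n_healthy,n_disease samples per condition (defaults 6 and 6).
#' @param baseline_mean_range interval for per-gene baseline means, log2
#'   units (default `c(4, 12)`).
#' @param noise_sd residual standard deviation, log2 units (default 0.5).
#' @param deg_fraction fraction of genes planted as DEGs (default 0.25).
#' @param deg_shift absolute log2 shift of planted DEGs in disease,
#'   random sign (default 1.0).
#' @param dcg_fraction_of_edges fraction of PPI edges planted as
#'   differentially correlated pairs (default 0.04; kept low enough that planted pairs can stay vertex-disjoint).
#' @param target_rho model correlation of planted pairs in their active
#'   condition, strictly in (0, 1) (default 0.95).
#' @param dcg_min_score planted pairs are drawn only from edges with
#'   combined score strictly above this (default 900), so the default
#'   score filter of the downstream network cannot remove them.
#' @param seed integer RNG seed.
#' @return list of class `"dcnet_sim_config"`.
#' @export
sim_config <- function(n_genes = 300, n_ppi_edges = 900,
                       score_range = c(150, 999),
                       fraction_above_900 = 0.5,
                       n_healthy = 6, n_disease = 6,
                       baseline_mean_range = c(4, 12),
                       noise_sd = 0.5,
                       deg_fraction = 0.25, deg_shift = 1.0,
                       dcg_fraction_of_edges = 0.04,
                       target_rho = 0.95,
                       dcg_min_score = 900,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_ppi_edges = as.integer(n_ppi_edges),
              score_range = as.integer(score_range),
              fraction_above_900 = fraction_above_900,
              n_healthy = as.integer(n_healthy),
              n_disease = as.integer(n_disease),
              baseline_mean_range = baseline_mean_range,
              noise_sd = noise_sd,
              deg_fraction = deg_fraction, deg_shift = deg_shift,
              dcg_fraction_of_edges = dcg_fraction_of_edges,
              target_rho = target_rho,
              dcg_min_score = dcg_min_score,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 2L || n_ppi_edges < 1L || n_healthy < 1L || n_disease < 1L)
      stop("counts must be positive")
    if (n_ppi_edges > n_genes * (n_genes - 1) / 2)
      stop("n_ppi_edges exceeds the maximum for ", n_genes, " genes")
    if (length(score_range) != 2L || score_range[1] > score_range[2] ||
        score_range[1] < 150L || score_range[2] > 999L)
      stop("score_range must be an interval within [150, 999]")
    if (deg_fraction < 0 || deg_fraction > 1 ||
        dcg_fraction_of_edges < 0 || dcg_fraction_of_edges > 1 ||
        fraction_above_900 < 0 || fraction_above_900 > 1)
      stop("fractions must lie in [0, 1]")
    if (target_rho <= 0 || target_rho >= 1)
      stop("target_rho must be strictly inside (0, 1)")
    if (noise_sd <= 0) stop("noise_sd must be positive")
  })
  structure(cfg, class = "dcnet_sim_config")
}

#' Latent-factor loading for a planted correlation
#'
#' The generator plants a correlated pair by adding `beta * f` to both
#' genes, `f` a shared standard-normal factor on top of independent
#' `N(0, sigma^2)` noise.  `beta = sigma * sqrt(r / (1 - r))` makes the
#' model Pearson correlation exactly `r`.
#'
#' @param noise_sd residual standard deviation `sigma`.
#' @param target_rho target correlation `r` in (0, 1).
#' @return the loading `beta`.
#' @export
planted_loading <- function(noise_sd, target_rho) {
  noise_sd * sqrt(target_rho / (1 - target_rho))
}

#' Generate a scored scale-free PPI network
#'
#' Builds a connected simple graph by preferential attachment (each new
#' edge picks endpoints with probability proportional to degree + 1) and
#' assigns integer combined scores: with probability
#' `fraction_above_900`, uniform on `(900, hi]`, otherwise uniform on
#' `[lo, min(hi, 900)]`.
#'
#' @param config a [sim_config()] object.
#' @return a `dcnet_ppi` data.frame.
#' @export
generate_ppi <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  m <- config$n_ppi_edges
  genes <- sprintf("G%04d", seq_len(n))
  deg <- stats::setNames(rep(0L, n), genes)
  seen <- new.env(parent = emptyenv())
  ea <- eb <- character(m)
  k <- 0L
  tries <- 0L
  while (k < m) {
    a <- sample(genes, 1L, prob = deg + 1)
    b <- sample(setdiff(genes, a), 1L,
                prob = (deg + 1)[setdiff(genes, a)])
    key <- paste(sort(c(a, b)), collapse = "\t")
    tries <- tries + 1L
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      k <- k + 1L
      ea[k] <- a
      eb[k] <- b
      deg[a] <- deg[a] + 1L
      deg[b] <- deg[b] + 1L
      tries <- 0L
    } else if (tries > 200L) {
      # dense regime: fall back to a uniform unseen pair
      repeat {
        ab <- sort(sample(genes, 2L))
        key <- paste(ab, collapse = "\t")
        if (is.null(seen[[key]])) break
      }
      seen[[key]] <- TRUE
      k <- k + 1L
      ea[k] <- ab[1]
      eb[k] <- ab[2]
      deg[ab[1]] <- deg[ab[1]] + 1L
      deg[ab[2]] <- deg[ab[2]] + 1L
      tries <- 0L
    }
  }
  lo <- config$score_range[1]
  hi <- config$score_range[2]
  f <- config$fraction_above_900
  if (hi <= 900L) f <- 0
  if (lo > 900L) f <- 1
  high <- stats::runif(m) < f
  score <- integer(m)
  if (any(high)) score[high] <- sample(seq(901L, hi), sum(high),
                                       replace = TRUE)
  if (any(!high)) score[!high] <- sample(seq(lo, min(hi, 900L)),
                                         sum(!high), replace = TRUE)
  ppi_network(ea, eb, score)
}

#' Generate two-condition expression data with planted signal
#'
#' Per-gene baseline means are drawn once and shared across conditions.
#' Planted DEGs receive a `deg_shift` of random sign in the disease mean.
#' Planted differentially correlated pairs are drawn from PPI edges with
#' combined score above `dcg_min_score` and at least one DEG endpoint
#' (preferring vertex-disjoint pairs); for a `gained` pair both endpoint
#' genes share a latent standard-normal factor with loading
#' [planted_loading()] in disease samples only, so their model Pearson
#' correlation there equals `target_rho` while healthy samples stay
#' independent; `lost` pairs are symmetric.  All other values are
#' independent Gaussian noise around the baseline.
#'
#' In addition to the randomly planted pairs, `forced_groups` plants
#' whole correlated groups: all genes of a group load on one shared
#' latent factor in the group's active condition, so every pair of group
#' genes has model correlation `target_rho` there.  Every PPI edge
#' joining two group genes (above `dcg_min_score`) becomes a true DCG
#' edge, and all group genes are added to the planted DEG set so the
#' DEG-endpoint invariant holds.  This is how a correlated clique or a
#' designated cross-tissue pair is planted.
#'
#' @param ppi a `dcnet_ppi` data.frame, typically from [generate_ppi()].
#' @param config a [sim_config()] object.
#' @param forced_groups optional list of `list(genes = <ids>, direction =
#'   "gained"|"lost")` entries.
#' @return list with `expr` (a `dcnet_expr` over both conditions, healthy
#'   samples `H1..`, disease `D1..`) and `truth` (list with `true_degs`,
#'   a character vector, and `true_dcg_edges`, a data.frame `gene_a`,
#'   `gene_b`, `direction`).
#' @export
generate_expression <- function(ppi, config, forced_groups = NULL) {
  if (nrow(ppi) == 0L) stop("'ppi' must have at least one edge")
  set.seed(config$seed + 1L)
  n <- config$n_genes
  genes <- sort(unique(c(ppi$gene_a, ppi$gene_b)))
  if (length(genes) < n)
    genes <- sort(unique(c(genes, sprintf("G%04d", seq_len(n)))))
  n <- length(genes)
  forced_genes <- character()
  if (!is.null(forced_groups)) {
    forced_genes <- unique(normalize_gene_id(
      unlist(lapply(forced_groups, `[[`, "genes"))))
    missing <- setdiff(forced_genes, genes)
    if (length(missing))
      stop("forced group gene(s) not in the PPI: ",
           paste(missing, collapse = ", "))
  }
  n_deg <- round(config$deg_fraction * n)
  true_degs <- sort(unique(c(sample(genes, n_deg), forced_genes)))
  shift <- stats::setNames(
    sample(c(-1, 1), length(true_degs), replace = TRUE) * config$deg_shift,
    true_degs)
  n_dcg <- round(config$dcg_fraction_of_edges * nrow(ppi))
  forced_edge_idx <- integer()
  groups <- list()
  if (!is.null(forced_groups)) {
    for (grp in forced_groups) {
      gg <- normalize_gene_id(grp$genes)
      idx <- which(ppi$gene_a %in% gg & ppi$gene_b %in% gg &
                     ppi$combined_score > config$dcg_min_score)
      if (!length(idx))
        stop("forced group has no PPI edge above score ",
             config$dcg_min_score)
      groups[[length(groups) + 1L]] <-
        list(genes = gg, direction = grp$direction, edge_idx = idx)
      forced_edge_idx <- c(forced_edge_idx, idx)
    }
  }
  eligible <- ppi$combined_score > config$dcg_min_score &
    (ppi$gene_a %in% true_degs | ppi$gene_b %in% true_degs)
  eligible[forced_edge_idx] <- FALSE
  elig_idx <- which(eligible)
  if (n_dcg > length(elig_idx))
    stop("dcg_fraction_of_edges requests ", n_dcg, " pairs but only ",
         length(elig_idx), " edges have score > ", config$dcg_min_score,
         " and a DEG endpoint")
  # prefer a vertex-disjoint set of pairs so each planted correlation is
  # exactly calibrated; overlap is allowed only when unavoidable
  pick <- integer(0)
  touched <- forced_genes
  for (i in sample(elig_idx)) {
    if (length(pick) >= n_dcg) break
    ends <- c(ppi$gene_a[i], ppi$gene_b[i])
    if (!any(ends %in% touched)) {
      pick <- c(pick, i)
      touched <- c(touched, ends)
    }
  }
  if (length(pick) < n_dcg)
    pick <- c(pick, sample(setdiff(elig_idx, pick),
                           n_dcg - length(pick)))
  for (i in pick)
    groups[[length(groups) + 1L]] <-
      list(genes = c(ppi$gene_a[i], ppi$gene_b[i]),
           direction = sample(c("gained", "lost"), 1L), edge_idx = i)
  if (length(groups)) {
    truth_edges <- do.call(rbind, lapply(groups, function(g)
      data.frame(gene_a = ppi$gene_a[g$edge_idx],
                 gene_b = ppi$gene_b[g$edge_idx],
                 direction = g$direction, stringsAsFactors = FALSE)))
    truth_edges <- truth_edges[!duplicated(
      paste(truth_edges$gene_a, truth_edges$gene_b)), , drop = FALSE]
    rownames(truth_edges) <- NULL
  } else {
    truth_edges <- data.frame(gene_a = character(), gene_b = character(),
                              direction = character(),
                              stringsAsFactors = FALSE)
  }
  truth <- list(true_degs = true_degs, true_dcg_edges = truth_edges)
  base <- stats::runif(n, config$baseline_mean_range[1],
                       config$baseline_mean_range[2])
  names(base) <- genes
  mu_h <- base
  mu_d <- base
  mu_d[true_degs] <- mu_d[true_degs] + shift[true_degs]
  nh <- config$n_healthy
  nd <- config$n_disease
  sd <- config$noise_sd
  H <- matrix(stats::rnorm(n * nh, mu_h, sd), n, nh,
              dimnames = list(genes, paste0("H", seq_len(nh))))
  D <- matrix(stats::rnorm(n * nd, mu_d, sd), n, nd,
              dimnames = list(genes, paste0("D", seq_len(nd))))
  beta <- planted_loading(sd, config$target_rho)
  for (g in groups) {
    if (g$direction == "gained") {
      f <- stats::rnorm(nd)
      for (a in g$genes) D[a, ] <- D[a, ] + beta * f
    } else {
      f <- stats::rnorm(nh)
      for (a in g$genes) H[a, ] <- H[a, ] + beta * f
    }
  }
  cond <- stats::setNames(rep(c("healthy", "disease"), c(nh, nd)),
                          c(colnames(H), colnames(D)))
  list(expr = expression_set(cbind(H, D), cond), truth = truth)
}

#' Generate a full synthetic tissue (PPI + expression + ground truth)
#'
#' @param config a [sim_config()] object.
#' @param forced_groups passed to [generate_expression()].
#' @return list with `ppi`, `expr`, `truth`.
#' @export
simulate_tissue <- function(config = sim_config(), forced_groups = NULL) {
  ppi <- generate_ppi(config)
  ge <- generate_expression(ppi, config, forced_groups)
  list(ppi = ppi, expr = ge$expr, truth = ge$truth)
}

#' Write a synthetic fixture to TSV files
#'
#' Emits the STRING-dialect PPI, the expression matrix, the condition map
#' and the two ground-truth tables; everything round-trips losslessly
#' through [read_ppi()] and [read_expression()].  No timestamps are
#' embedded, so identical inputs give byte-identical files.
#'
#' @param tissue output of [simulate_tissue()] (or a list with the same
#'   elements).
#' @param dir output directory, created if needed.
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(tissue, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             expression = file.path(dir, "expression.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             truth_degs = file.path(dir, "truth_degs.tsv"),
             truth_dcgs = file.path(dir, "truth_dcg_edges.tsv"))
  ppi_out <- data.frame(protein1 = tissue$ppi$gene_a,
                        protein2 = tissue$ppi$gene_b,
                        combined_score = tissue$ppi$combined_score)
  utils::write.table(ppi_out, paths[["ppi"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression(tissue$expr, paths[["expression"]],
                   paths[["conditions"]])
  utils::write.table(data.frame(gene_id = tissue$truth$true_degs),
                     paths[["truth_degs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tissue$truth$true_dcg_edges, paths[["truth_dcgs"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
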