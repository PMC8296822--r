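#' Venn partition of labeled sets
#'
#' Assigns every element of the union of >= 2 labeled sets to exactly one
#' of the `2^k - 1` membership regions (one per nonempty subset of
#' labels).
#'
#' @param sets named list of character vectors; names are the (unique)
#'   labels.
#' @return object of class `"dcnet_venn"`: list with `labels`, `regions`
#'   (named list of element vectors, names like `"heart&adipose"`) and
#'   `counts` (named integer vector over all regions, empty ones
#'   included).
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets")
  labels <- names(sets)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == ""))
    stop("'sets' must be a named list with unique labels")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row)
    paste(labels[row], collapse = "&"))
  k <- length(labels)
  region_names <- unlist(lapply(seq_len(k), function(sz) {
    apply(utils::combn(labels, sz), 2L, paste, collapse = "&")
  }))
  regions <- lapply(stats::setNames(region_names, region_names),
                    function(r) universe[sig == r])
  counts <- vapply(regions, length, integer(1L))
  structure(list(labels = labels, regions = regions, counts = counts),
            class = "dcnet_venn")
}

#' @export
print.dcnet_venn <- function(x, ...) {
  cat("Venn partition over {", paste(x$labels, collapse = ", "), "}\n",
      sep = "")
  for (r in names(x$counts))
    cat("  ", r, ": ", x$counts[[r]], "\n", sep = "")
  invisible(x)
}

#' Genes and gene pairs shared by all tissues
#'
#' Following the terminology of multi-tissue differential studies,
#' "housekeeping" here means *present in every tissue analyzed* — a DEG
#' called in all tissues, or a differentially correlated pair (in any
#' direction) detected in all tissues.  This is not the conventional
#' constitutive-expression meaning of the word.
#'
#' @param per_tissue_degs named list of DEG gene-id vectors, one per
#'   tissue.
#' @param per_tissue_dns named list of `dcnet_dn` objects (or DN edge
#'   data.frames with `gene_a`, `gene_b`, `status`), same tissue names.
#' @return list of class `"dcnet_housekeeping"` with `housekeeping_degs`
#'   (character) and `housekeeping_dcgs` (data.frame `gene_a`, `gene_b`
#'   plus one `direction_<tissue>` column per tissue).
#' @export
housekeeping <- function(per_tissue_degs, per_tissue_dns) {
  if (length(per_tissue_degs) < 2L || length(per_tissue_dns) < 2L)
    stop("need at least two tissues")
  hk_degs <- sort(Reduce(intersect,
                         lapply(per_tissue_degs, normalize_gene_id)))
  edge_tabs <- lapply(per_tissue_dns, function(net) {
    edges <- if (is.data.frame(net)) net else net$edges
    data.frame(key = edge_key(edges$gene_a, edges$gene_b),
               status = edges$status, stringsAsFactors = FALSE)
  })
  shared <- Reduce(intersect, lapply(edge_tabs, `[[`, "key"))
  shared <- sort(shared)
  if (length(shared)) {
    parts <- strsplit(shared, "\t", fixed = TRUE)
    hk_dcgs <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                          gene_b = vapply(parts, `[`, "", 2L),
                          stringsAsFactors = FALSE)
    for (tis in names(edge_tabs)) {
      tab <- edge_tabs[[tis]]
      hk_dcgs[[paste0("direction_", tis)]] <-
        tab$status[match(shared, tab$key)]
    }
  } else {
    hk_dcgs <- data.frame(gene_a = character(), gene_b = character(),
                          stringsAsFactors = FALSE)
    for (tis in names(edge_tabs))
      hk_dcgs[[paste0("direction_", tis)]] <- character()
  }
  structure(list(housekeeping_degs = hk_degs,
                 housekeeping_dcgs = hk_dcgs),
            class = "dcnet_housekeeping")
}

#' @export
print.dcnet_housekeeping <- function(x, ...) {
  cat("shared across all tissues: ", length(x$housekeeping_degs),
      " DEG(s), ", nrow(x$housekeeping_dcgs), " DCG pair(s)\n", sep = "")
  invisible(x)
}

#' Hub genes shared between tissues
#'
#' For each pair of tissues, returns the hub genes present in both lists
#' with each tissue's hub score retained, plus the genes hub in every
#' tissue.
#'
#' @param hubs_by_tissue named list of hub data.frames as returned by
#'   [select_hubs()].
#' @return list with `pairwise` (named list, one data.frame per tissue
#'   pair `"a|b"` with columns `gene_id`, `score_<a>`, `score_<b>`) and
#'   `all_tissues` (character vector of genes hub everywhere).
#' @export
shared_hubs <- function(hubs_by_tissue) {
  labels <- names(hubs_by_tissue)
  if (length(labels) < 2L) stop("need at least two tissues")
  pairs <- utils::combn(labels, 2L, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr) {
    ha <- hubs_by_tissue[[pr[1]]]
    hb <- hubs_by_tissue[[pr[2]]]
    common <- sort(intersect(ha$gene_id, hb$gene_id))
    out <- data.frame(gene_id = common, stringsAsFactors = FALSE)
    out[[paste0("score_", pr[1])]] <- ha$hub_score[match(common, ha$gene_id)]
    out[[paste0("score_", pr[2])]] <- hb$hub_score[match(common, hb$gene_id)]
    out
  })
  names(pairwise) <- vapply(pairs, paste, "", collapse = "|")
  all_t <- sort(Reduce(intersect, lapply(hubs_by_tissue, `[[`, "gene_id")))
  list(pairwise = pairwise, all_tissues = all_t)
}
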