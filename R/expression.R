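#' Normalize gene identifiers
#'
#' All identifier matching in dcnet is exact string equality after one
#' normalization: leading/trailing whitespace is stripped and letters are
#' uppercased.  No alias or ortholog resolution is attempted.
#'
#' @param x character vector of gene identifiers.
#' @return normalized character vector.
#' @export
normalize_gene_id <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Two-condition expression set
#'
#' Container for a genes x samples matrix of log2 expression values with a
#' healthy/disease condition label per sample.
#'
#' @param values numeric matrix, rows are genes (rownames required), columns
#'   are samples (colnames required); values are log2 expression and must be
#'   finite.
#' @param condition character or factor of length `ncol(values)` with values
#'   in `c("healthy", "disease")`; if named, names must match the sample ids
#'   and are used to align.
#' @return an object of class `"dcnet_expr"`: a list with elements `values`
#'   (the matrix, gene ids normalized) and `condition` (named factor).
#' @export
expression_set <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  rownames(values) <- normalize_gene_id(rownames(values))
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value at gene '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "'")
  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(values), names(condition))
    if (length(missing))
      stop("sample(s) missing from condition map: ",
           paste(missing, collapse = ", "))
    condition <- condition[colnames(values)]
  } else if (length(condition) != ncol(values)) {
    stop("'condition' must have one label per sample")
  }
  condition <- as.character(condition)
  unknown <- setdiff(unique(condition), c("healthy", "disease"))
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  condition <- factor(condition, levels = c("healthy", "disease"))
  names(condition) <- colnames(values)
  structure(list(values = values, condition = condition),
            class = "dcnet_expr")
}

#' @export
print.dcnet_expr <- function(x, ...) {
  tab <- table(x$condition)
  cat("dcnet expression set: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples (", tab[["healthy"]], " healthy, ",
      tab[["disease"]], " disease)\n", sep = "")
  invisible(x)
}

#' @export
dim.dcnet_expr <- function(x) dim(x$values)

#' Extract the sample matrix for one condition
#'
#' @param expr a `dcnet_expr` object.
#' @param condition `"healthy"` or `"disease"`.
#' @return numeric matrix restricted to the samples of that condition.
#' @export
condition_matrix <- function(expr, condition = c("healthy", "disease")) {
  condition <- match.arg(condition)
  expr$values[, expr$condition == condition, drop = FALSE]
}

#' Read an expression matrix and condition map from TSV files
#'
#' The expression file has a `gene_id` first column and one column per
#' sample; the condition map has columns `sample_id` and `condition`
#' (values `healthy` or `disease`).
#'
#' @param path_matrix path to the expression TSV.
#' @param path_condition_map path to the condition-map TSV.
#' @return a [expression_set()] object.
#' @export
read_expression <- function(path_matrix, path_condition_map) {
  tab <- utils::read.delim(path_matrix, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L || names(tab)[1L] != "gene_id")
    stop("expression file must start with a 'gene_id' column: ", path_matrix)
  genes <- normalize_gene_id(tab[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s) in ", path_matrix, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at gene '", genes[bad[1, 1]], "', sample '",
         colnames(vals)[bad[1, 2]], "' in ", path_matrix)
  rownames(num) <- genes
  cmap <- utils::read.delim(path_condition_map, colClasses = "character")
  if (!all(c("sample_id", "condition") %in% names(cmap)))
    stop("condition map must have 'sample_id' and 'condition' columns: ",
         path_condition_map)
  cond <- cmap$condition
  names(cond) <- cmap$sample_id
  expression_set(num, cond)
}

#' Write an expression set as expression + condition-map TSVs
#'
#' @param expr a `dcnet_expr` object.
#' @param path_matrix,path_condition_map output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(expr, path_matrix, path_condition_map) {
  tab <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(tab, path_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cmap <- data.frame(sample_id = names(expr$condition),
                     condition = as.character(expr$condition))
  utils::write.table(cmap, path_condition_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_matrix, path_condition_map))
}
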