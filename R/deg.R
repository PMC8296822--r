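#' Per-gene log2 fold change
#'
#' Values are already on the log2 scale, so the fold change is the mean
#' over disease samples minus the mean over healthy samples.  The sign
#' convention is fixed: positive means higher in disease.
#'
#' @param expr a `dcnet_expr` object with both conditions present.
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
log2_fold_change <- function(expr) {
  h <- condition_matrix(expr, "healthy")
  d <- condition_matrix(expr, "disease")
  if (ncol(h) == 0L || ncol(d) == 0L)
    stop("both conditions must have at least one sample")
  rowMeans(d) - rowMeans(h)
}

# Newton solve of trigamma(y) = x, vectorized; x > 0.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate empirical-Bayes variance moderation parameters
#'
#' Fits the scaled-F model for gene-wise sample variances,
#' `s^2 ~ s0^2 * F(df, d0)`, by moment matching on the log variances
#' (digamma/trigamma equations).  When the observed spread of log
#' variances does not exceed pure sampling noise, the prior degrees of
#' freedom are infinite and every posterior variance equals the common
#' prior variance.
#'
#' @param sample_variances per-gene sample variances (at least two must be
#'   positive).
#' @param residual_df residual degrees of freedom (scalar, shared by all
#'   genes).
#' @return an object of class `"dcnet_moderation"`: list with `d0` (prior
#'   df, possibly `Inf`), `s0_sq` (prior variance), `residual_df`, and
#'   `posterior_var` per gene, `(d0*s0^2 + df*s^2) / (d0 + df)`.
#' @export
estimate_moderation <- function(sample_variances, residual_df) {
  s2 <- sample_variances
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    stop("need at least two positive sample variances")
  df <- residual_df
  z <- log(s2[ok])
  if (max(z) - min(z) < 1e-12) {
    # degenerate case: no spread at all, complete pooling at the common value
    return(structure(list(d0 = Inf, s0_sq = s2[ok][1], residual_df = df,
                          posterior_var = rep(s2[ok][1], length(s2))),
                     class = "dcnet_moderation"))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1)
  # subtract the sampling contribution; what remains is prior spread
  excess <- evar - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
  }
  post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
          else (d0 * s0_sq + df * s2) / (d0 + df)
  structure(list(d0 = d0, s0_sq = s0_sq, residual_df = df,
                 posterior_var = post),
            class = "dcnet_moderation")
}

#' @export
print.dcnet_moderation <- function(x, ...) {
  cat("variance moderation: d0 =", format(x$d0, digits = 4),
      " s0^2 =", format(x$s0_sq, digits = 4),
      " residual df =", x$residual_df, "\n")
  invisible(x)
}

# Moderated pooled-variance t: posterior variance
# (d0*s0^2 + df*s^2)/(d0 + df) on d0 + df degrees of freedom.
# d0 = 0 reduces to the ordinary pooled t; d0 = Inf pools completely.
moderated_t <- function(lfc, s2, df, n1, n2, d0, s0_sq) {
  post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
          else (d0 * s0_sq + df * s2) / (d0 + df)
  tstat <- lfc / sqrt(post * (1 / n1 + 1 / n2))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = d0 + df),
       posterior_var = post)
}

#' Call differentially expressed genes
#'
#' Tests each gene for a disease-vs-healthy mean difference and flags DEGs
#' by the joint criterion raw `p < p_threshold` and
#' `|log2FC| > lfc_threshold` (both inequalities strict).  No
#' multiple-testing adjustment is applied by default; an optional BH
#' adjustment can be switched on for the p-value used in the flag.
#'
#' `method = "moderated"` uses a pooled-variance t-statistic whose
#' variance is shrunk towards the empirical-Bayes prior of
#' [estimate_moderation()], tested on `d0 + df` degrees of freedom.
#' `method = "welch"` is an ordinary Welch two-sample t-test.
#'
#' @param expr a `dcnet_expr` object with >= 2 samples per condition.
#' @param p_threshold p-value threshold (default 0.05, strict `<`).
#' @param lfc_threshold absolute log2-fold-change threshold (default 0.5,
#'   strict `>`).
#' @param method `"moderated"` (default) or `"welch"`.
#' @param adjust `"none"` (default) or `"BH"`; when `"BH"`, the flag uses
#'   the adjusted p-value (reported in column `p_adj`).
#' @return data.frame of class `c("dcnet_degs", "data.frame")` with
#'   columns `gene_id`, `log2fc`, `t`, `p`, (`p_adj` when requested) and
#'   logical `is_deg`.
#' @export
call_degs <- function(expr, p_threshold = 0.05, lfc_threshold = 0.5,
                      method = c("moderated", "welch"),
                      adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  h <- condition_matrix(expr, "healthy")
  d <- condition_matrix(expr, "disease")
  n1 <- ncol(h)
  n2 <- ncol(d)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per condition, got ", n1, " healthy and ",
         n2, " disease")
  lfc <- rowMeans(d) - rowMeans(h)
  v1 <- apply(h, 1L, stats::var)
  v2 <- apply(d, 1L, stats::var)
  if (method == "moderated") {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    mod <- estimate_moderation(s2, df)
    res <- moderated_t(lfc, s2, df, n1, n2, mod$d0, mod$s0_sq)
    tstat <- res$t
    p <- res$p
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    tstat <- lfc / se
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df = df)
  }
  out <- data.frame(gene_id = rownames(expr$values), log2fc = lfc,
                    t = tstat, p = p, stringsAsFactors = FALSE,
                    row.names = NULL)
  p_flag <- out$p
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    p_flag <- out$p_adj
  }
  out$is_deg <- p_flag < p_threshold & abs(out$log2fc) > lfc_threshold
  class(out) <- c("dcnet_degs", "data.frame")
  out
}

#' Write / read a DEG table TSV
#'
#' @param degs a `dcnet_degs` data.frame.
#' @param path output path.
#' @return `write_deg_table` returns the path invisibly; `read_deg_table`
#'   returns the table with `gene_id` normalized.
#' @export
write_deg_table <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "is_deg") %in% names(tab)))
    stop("DEG table must have 'gene_id' and 'is_deg' columns: ", path)
  tab$gene_id <- normalize_gene_id(tab$gene_id)
  tab$is_deg <- as.logical(tab$is_deg)
  class(tab) <- c("dcnet_degs", "data.frame")
  tab
}
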