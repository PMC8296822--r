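#' Pipeline configuration
#'
#' One flat, serializable record of every stage parameter.  Defaults
#' mirror the thresholds conventionally used with this kind of analysis:
#' raw p < 0.05 and |log2FC| > 0.5 for DEGs, PPI combined score above
#' 900, per-test alpha 0.05 for edge correlations, module score above 3,
#' hub score above 10.
#'
#' @param tissues character vector of tissue labels.
#' @param simulate logical; generate synthetic inputs (default `TRUE`).
#'   When `FALSE`, `inputs` must give per-tissue file paths.
#' @param inputs named list (per tissue) of lists with `expression`,
#'   `conditions` and `ppi` paths; ignored when `simulate = TRUE`.
#' @param sim named list of overrides passed to [sim_config()] for
#'   simulated tissues (per-tissue seeds are derived from `seed`).
#' @param seed master integer seed.
#' @param p_threshold,lfc_threshold,deg_method,min_score,strict,alpha,cor_method,vwp,haircut,min_module_score,hub_threshold
#'   stage parameters, see [dcnet()].
#' @return list of class `"dcnet_config"`.
#' @export
pipeline_config <- function(tissues = c("tissue1", "tissue2", "tissue3"),
                            simulate = TRUE, inputs = NULL,
                            sim = list(), seed = 1L,
                            p_threshold = 0.05, lfc_threshold = 0.5,
                            deg_method = "moderated",
                            min_score = 900, strict = TRUE,
                            alpha = 0.05, cor_method = "auto",
                            vwp = 0.2, haircut = TRUE,
                            min_module_score = 3, hub_threshold = 10) {
  cfg <- list(tissues = tissues, simulate = simulate, inputs = inputs,
              sim = sim, seed = as.integer(seed),
              p_threshold = p_threshold, lfc_threshold = lfc_threshold,
              deg_method = deg_method, min_score = min_score,
              strict = strict, alpha = alpha, cor_method = cor_method,
              vwp = vwp, haircut = haircut,
              min_module_score = min_module_score,
              hub_threshold = hub_threshold)
  if (anyDuplicated(tissues)) stop("tissue labels must be unique")
  if (!simulate) {
    if (is.null(inputs) || !all(tissues %in% names(inputs)))
      stop("'inputs' must name every tissue when simulate = FALSE")
  }
  structure(cfg, class = "dcnet_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips unchanged through serialization.
#'
#' @param config a `dcnet_config` object.
#' @param path YAML file path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns the `dcnet_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full multi-tissue pipeline
#'
#' For each tissue: obtain inputs (simulated or read from files), call
#' DEGs, build the WDRN, classify edges, assemble the DN, detect modules
#' and hubs.  Then across tissues: Venn partitions of DEGs, DN nodes and
#' DN edges; housekeeping (all-tissue) DEGs and DCGs; the merged network
#' with its modules; shared hubs.  When `out_dir` is given, every
#' intermediate artifact is written there (TSV/GraphML/SIF), along with
#' `summary.json` (all counts and coverage statistics, no timestamps, so
#' reruns are byte-identical) and `run_log.txt` echoing the resolved
#' configuration.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir optional output directory.
#' @return object of class `"dcnet_run"`: list with `fits` (per-tissue
#'   [dcnet()] objects), `truth` (per-tissue ground truth when
#'   simulated), `venn` (list of `dcnet_venn` for degs/dn_nodes/
#'   dn_edges), `housekeeping`, `merged`, `merged_modules`,
#'   `shared_hubs`, `summary` (the summary list) and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  tissues <- config$tissues
  fits <- list()
  truth <- list()
  for (i in seq_along(tissues)) {
    tis <- tissues[i]
    if (isTRUE(config$simulate)) {
      sim_args <- config$sim
      sim_args$seed <- config$seed + 1000L * i
      scfg <- do.call(sim_config, sim_args)
      dat <- simulate_tissue(scfg)
      truth[[tis]] <- dat$truth
      expr <- dat$expr
      ppi <- dat$ppi
    } else {
      paths <- config$inputs[[tis]]
      expr <- tryCatch(
        read_expression(paths$expression, paths$conditions),
        error = function(e) stop("stage read_expression [", tis, "]: ",
                                 conditionMessage(e), call. = FALSE))
      ppi <- tryCatch(
        read_ppi(paths$ppi),
        error = function(e) stop("stage read_ppi [", tis, "]: ",
                                 conditionMessage(e), call. = FALSE))
    }
    fits[[tis]] <- tryCatch(
      dcnet(expr, ppi, tissue = tis,
            p_threshold = config$p_threshold,
            lfc_threshold = config$lfc_threshold,
            deg_method = config$deg_method,
            min_score = config$min_score, strict = config$strict,
            alpha = config$alpha, cor_method = config$cor_method,
            vwp = config$vwp, haircut = config$haircut,
            min_module_score = config$min_module_score,
            hub_threshold = config$hub_threshold),
      error = function(e) stop("stage dcnet [", tis, "]: ",
                               conditionMessage(e), call. = FALSE))
  }
  venn <- NULL
  hk <- NULL
  merged <- NULL
  merged_modules <- NULL
  sh <- NULL
  if (length(tissues) >= 2L) {
    deg_sets <- lapply(fits, `[[`, "deg_set")
    dn_nodes <- lapply(fits, function(f) f$dn$nodes$gene_id)
    dn_edges <- lapply(fits, function(f)
      edge_key(f$dn$edges$gene_a, f$dn$edges$gene_b))
    venn <- list(degs = venn_partition(deg_sets),
                 dn_nodes = venn_partition(dn_nodes),
                 dn_edges = venn_partition(dn_edges))
    hk <- housekeeping(deg_sets, lapply(fits, `[[`, "dn"))
    merged <- merge_networks(lapply(fits, `[[`, "wdrn"))
    merged_modules <- find_modules(
      merged$edges, vwp = config$vwp, haircut = config$haircut,
      min_component_score = config$min_module_score)
    sh <- shared_hubs(lapply(fits, `[[`, "hubs"))
  }
  summary <- list(
    tissues = lapply(fits, function(f) {
      s <- summary(f)
      s$hubs <- NULL
      unclass(s)
    }),
    venn_counts = if (!is.null(venn)) lapply(venn, `[[`, "counts"),
    housekeeping = if (!is.null(hk))
      list(n_degs = length(hk$housekeeping_degs),
           degs = hk$housekeeping_degs,
           n_dcgs = nrow(hk$housekeeping_dcgs)),
    merged = if (!is.null(merged))
      list(n_edges = nrow(merged$edges), n_nodes = nrow(merged$nodes),
           n_modules = nrow(merged_modules)),
    config = unclass(config))
  run <- structure(list(fits = fits, truth = truth, venn = venn,
                        housekeeping = hk, merged = merged,
                        merged_modules = merged_modules,
                        shared_hubs = sh, summary = summary,
                        config = config),
                   class = "dcnet_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.dcnet_run <- function(x, ...) {
  cat("dcnet pipeline run over ", length(x$fits), " tissue(s)\n",
      sep = "")
  for (f in x$fits) print(f)
  if (!is.null(x$housekeeping)) print(x$housekeeping)
  invisible(x)
}

# Write every pipeline artifact under out_dir.  Artifact files carry no
# timestamps; only the human-readable log does.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tis in names(run$fits)) {
    f <- run$fits[[tis]]
    tdir <- file.path(out_dir, tis)
    dir.create(tdir, showWarnings = FALSE)
    write_deg_table(f$degs, file.path(tdir, "degs.tsv"))
    write_network(f$wdrn, tdir, "wdrn")
    utils::write.table(f$edge_correlations,
                       file.path(tdir, "edge_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(f$dn, tdir, "dn")
    write_sif(f$dn, file.path(tdir, "dn.sif"))
    utils::write.table(f$modules, file.path(tdir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(f$hubs, file.path(tdir, "hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$venn)) {
    for (nm in names(run$venn)) {
      venn <- run$venn[[nm]]
      tab <- data.frame(
        region = rep(names(venn$regions),
                     vapply(venn$regions, length, integer(1L))),
        element = unlist(venn$regions, use.names = FALSE))
      utils::write.table(tab,
                         file.path(out_dir, paste0("venn_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
      data.frame(gene_id = run$housekeeping$housekeeping_degs),
      file.path(out_dir, "housekeeping_degs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$housekeeping$housekeeping_dcgs,
                       file.path(out_dir, "housekeeping_dcgs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$merged_modules,
                       file.path(out_dir, "merged_modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  log <- c(paste("dcnet run at", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           "resolved configuration:",
           utils::capture.output(utils::str(unclass(run$config))))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
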