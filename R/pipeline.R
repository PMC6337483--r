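# End-to-end experiment driver: simulate a multi-study collection, build the
# strategy datasets (single-study and integrated), call DEGs, measure
# robustness, validate on reserved studies, and annotate the final marker
# list with enrichment and network hubs.

#' Run a full multi-strategy integration experiment
#'
#' Orchestrates the whole pipeline on a simulated collection: for each
#' strategy (a named subset of member studies), the member studies are merged
#' by [integrate_studies()], markers are called with [fit_moderated_t()] and
#' [call_degs()], robustness is measured by [robustness_report()] over
#' stratified subsamples, and — when validation studies are reserved — a
#' linear-SVM model trained on the strategy's markers is scored on the
#' integrated validation dataset. Strategies' overlap values are compared
#' pairwise, and the final strategy's marker list is annotated with gene-set
#' enrichment and network hub ranking against the simulated fixtures.
#'
#' @param config A named list (or a path to a YAML/JSON file holding one)
#'   with elements:
#'   \describe{
#'     \item{sim}{arguments for [sim_config()] (optional; defaults used
#'       otherwise).}
#'     \item{strategies}{named list; each element is a character vector of
#'       member study ids (`"study1"`, `"study2"`, ... in simulation order).}
#'     \item{validation}{character vector of reserved validation study ids
#'       (disjoint from every strategy; may be empty to skip classification).}
#'     \item{final}{name of the strategy to annotate (default: the last).}
#'     \item{fc_threshold, alpha}{marker thresholds (defaults 1.5, 0.05).}
#'     \item{robustness}{list with `iterations`, `fraction`,
#'       `overlap_method`.}
#'     \item{seed}{master seed (overrides `sim$seed`).}
#'   }
#' @param outdir Optional directory; when given, marker tables, reports and a
#'   manifest (JSON, including a timestamp) are written there.
#' @return A list of class `ddi_experiment` with `strategies` (per strategy:
#'   `deg_table`, `degs`, `recovery`, `robustness`, `classification`),
#'   `comparisons` (pairwise overlap-value p-values), `annotation`
#'   (enrichment table, immune annotation, hub report for the final
#'   strategy), `truth`, and `manifest` (inputs and seeds; no timestamp, so
#'   reruns are identical).
#' @export
run_experiment <- function(config, outdir = NULL) {
  cfg <- load_config(config)
  sim_args <- cfg$sim %||% list()
  if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
  simcfg <- do.call(sim_config, sim_args)
  sim <- simulate_collection(simcfg)
  studies <- sim$studies
  names(studies) <- vapply(studies, `[[`, character(1), "study_id")

  strategies <- cfg$strategies
  if (is.null(strategies) || is.null(names(strategies)))
    stop("config$strategies must be a named list of member-study vectors",
         call. = FALSE)
  validation_ids <- cfg$validation %||% character(0)
  unknown <- setdiff(c(unlist(strategies), validation_ids), names(studies))
  if (length(unknown))
    stop("unknown study id(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(strategies))
    if (length(intersect(strategies[[nm]], validation_ids)))
      stop(sprintf("strategy '%s' overlaps the validation studies", nm),
           call. = FALSE)

  fc <- cfg$fc_threshold %||% 1.5
  alpha <- cfg$alpha %||% 0.05
  rb <- cfg$robustness %||% list()
  iterations <- rb$iterations %||% 10
  fraction <- rb$fraction %||% (2 / 3)
  overlap_method <- rb$overlap_method %||% "intersection_over_min"

  validation <- if (length(validation_ids))
    integrate_studies(studies[validation_ids]) else NULL

  results <- lapply(names(strategies), function(nm) {
    data <- integrate_studies(studies[strategies[[nm]]])
    deg_table <- fit_moderated_t(data, fc_threshold = fc, alpha = alpha)
    degs <- call_degs(deg_table, fc, alpha)
    plan <- draw_subsamples(data, n_iterations = iterations,
                            fraction = fraction,
                            seed = seed_for(simcfg$seed, paste0("robust:", nm)))
    rob <- robustness_report(subsample_degs(data, plan, fc, alpha),
                             overlap_method = overlap_method)
    cls <- NULL
    if (!is.null(validation) && length(degs)) {
      pred <- train_and_predict(data, validation, degs)
      cls <- classification_report(validation$samples$group, pred$labels,
                                   pred$scores)
    }
    list(name = nm, data = data, deg_table = deg_table, degs = degs,
         recovery = evaluate_against_truth(degs, sim$truth),
         robustness = rob, classification = cls)
  })
  names(results) <- names(strategies)

  comparisons <- list()
  if (length(results) >= 2) {
    for (pair in combn(names(results), 2, simplify = FALSE)) {
      key <- paste(pair, collapse = "_vs_")
      comparisons[[key]] <- compare_strategies(
        results[[pair[1]]]$robustness$overlaps,
        results[[pair[2]]]$robustness$overlaps)
    }
  }

  final <- cfg$final %||% names(results)[length(results)]
  annotation <- NULL
  if (length(results[[final]]$degs)) {
    gsc <- simulate_genesets(sim$truth, simcfg)
    degs <- results[[final]]$degs
    universe <- rownames(results[[final]]$data$values)
    enr <- enrich(degs, gsc, universe, alpha = alpha)
    imm <- annotate_immune(degs, gsc)
    net <- filter_edges(simulate_network(sim$truth, simcfg), 0.7)
    hubs <- suppressWarnings(induce_and_rank(net, degs, names(imm)))
    annotation <- list(strategy = final, enrichment = enr, immune = imm,
                       hubs = hubs)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("ddiexpr")),
                   seed = simcfg$seed, sim = unclass(simcfg),
                   strategies = strategies, validation = validation_ids,
                   fc_threshold = fc, alpha = alpha,
                   robustness = list(iterations = iterations,
                                     fraction = fraction,
                                     overlap_method = overlap_method))
  bundle <- structure(list(strategies = results, comparisons = comparisons,
                           annotation = annotation, truth = sim$truth,
                           manifest = manifest),
                      class = "ddi_experiment")
  if (!is.null(outdir)) write_experiment(bundle, outdir)
  bundle
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
      return(yaml::read_yaml(config))
    }
    if (ext == "json") {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("reading JSON configs needs the 'jsonlite' package", call. = FALSE)
      return(jsonlite::fromJSON(config, simplifyVector = TRUE))
    }
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  if (!is.list(config)) stop("'config' must be a list or a file path",
                             call. = FALSE)
  config
}

write_experiment <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$strategies)) {
    res <- bundle$strategies[[nm]]
    write_tsv(res$deg_table, file.path(outdir, paste0("degs_", nm, ".tsv")))
    rb <- res$robustness
    writeLines(c(sprintf("union_size\t%d", rb$union_size),
                 sprintf("overlap_median\t%.6f", rb$overlap_median)),
               file.path(outdir, paste0("robustness_", nm, ".tsv")))
  }
  if (!is.null(bundle$annotation))
    write_tsv(bundle$annotation$enrichment,
              file.path(outdir, "enrichment.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- c(bundle$manifest, list(written = format(Sys.time(), tz = "UTC")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  invisible(outdir)
}

#' @export
print.ddi_experiment <- function(x, ...) {
  cat("<ddi_experiment>\n")
  for (nm in names(x$strategies)) {
    res <- x$strategies[[nm]]
    cat(sprintf("  %s: %d samples, %d markers, overlap median %.2f",
                nm, ncol(res$data$values), length(res$degs),
                res$robustness$overlap_median))
    if (!is.null(res$classification))
      cat(sprintf(", validation AUC %.2f", res$classification$auc))
    cat("\n")
  }
  invisible(x)
}
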