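# Synthetic multi-study expression collections with known ground truth, plus
# matched gene-set and interaction-network fixtures. The generator emulates
# the structure of a collection of small case/control microarray studies:
# shared gene-level baselines, per-study additive batch shifts, a fraction of
# truly differential genes shifted in cases only, and Gaussian residual noise,
# all on the log2 scale.

#' Simulation configuration
#'
#' Defaults mirror a realistic multi-study collection: seven studies with
#' case:control sizes 4:1, 13:0, 14:9, 4:3, 10:0, 16:0 and 7:3 (68 cases and
#' 16 controls in total), gene baselines drawn from N(7, 2^2) on the log2
#' scale, 5% truly differential genes with a +/-2 log2 shift in cases (signs
#' split 50/50), per-(study, gene) additive batch shifts with SD 1, and unit
#' residual noise.
#'
#' @param n_genes Number of genes (>= 2).
#' @param study_sizes List of `c(n_case, n_control)` pairs, one per study.
#' @param frac_deg Fraction of genes truly differential, in `[0, 1]`.
#' @param effect_size Magnitude of the log2 mean shift applied to cases of
#'   truly differential genes; signs are split 50/50 up/down.
#' @param batch_sd SD of the per-(study, gene) additive batch shift.
#' @param noise_sd Residual SD (> 0).
#' @param baseline_mean,baseline_sd Distribution of gene baseline means on
#'   the log2 scale.
#' @param array_scale Also apply a per-array multiplicative factor drawn
#'   uniformly from `[0.8, 1.25]` (default off); useful for checking that
#'   per-array standardization removes array-level scale effects.
#' @param n_gene_sets Number of background gene sets in the gene-set fixture.
#' @param gene_set_size Members per gene set.
#' @param immune_enrichment Fraction of the synthetic immune set drawn from
#'   true differential genes (`[0, 1]`).
#' @param n_edges Edges in the interaction-network fixture.
#' @param hub_genes Optional gene ids to plant as hubs.
#' @param hub_degree Planted degree of each hub.
#' @param conf_range Range the edge confidences are drawn from (uniform).
#' @param seed Master RNG seed; per-study and per-fixture streams are derived
#'   from it by stable label hashing, so adding a study never perturbs the
#'   draws of the others.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       study_sizes = list(c(4, 1), c(13, 0), c(14, 9),
                                          c(4, 3), c(10, 0), c(16, 0),
                                          c(7, 3)),
                       frac_deg = 0.05, effect_size = 2, batch_sd = 1,
                       noise_sd = 1, baseline_mean = 7, baseline_sd = 2,
                       array_scale = FALSE,
                       n_gene_sets = 20, gene_set_size = 25,
                       immune_enrichment = 0.8,
                       n_edges = 500, hub_genes = NULL, hub_degree = 20,
                       conf_range = c(0, 1), seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 2)
    stop_field("n_genes", "must be a single count >= 2")
  if (!is.list(study_sizes) || !length(study_sizes) ||
      !all(vapply(study_sizes, function(s)
        length(s) == 2 && all(s >= 0) && sum(s) >= 1 && all(s == floor(s)),
        logical(1))))
    stop_field("study_sizes",
               "must be a list of c(n_case, n_control) pairs with >= 1 sample each")
  if (!is.numeric(frac_deg) || frac_deg < 0 || frac_deg > 1)
    stop_field("frac_deg", "must lie in [0, 1]")
  if (!is.numeric(effect_size) || effect_size < 0)
    stop_field("effect_size", "must be >= 0")
  if (!is.numeric(batch_sd) || batch_sd < 0)
    stop_field("batch_sd", "must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_field("noise_sd", "must be > 0")
  if (!is.numeric(immune_enrichment) || immune_enrichment < 0 ||
      immune_enrichment > 1)
    stop_field("immune_enrichment", "must lie in [0, 1]")
  if (!is.numeric(n_edges) || n_edges < 0)
    stop_field("n_edges", "must be >= 0")
  if (length(conf_range) != 2 || any(conf_range < 0) || any(conf_range > 1) ||
      conf_range[1] > conf_range[2])
    stop_field("conf_range", "must be an increasing pair within [0, 1]")
  if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed))
    stop_field("seed", "must be a single integer")
  structure(list(n_genes = as.integer(n_genes), study_sizes = study_sizes,
                 frac_deg = frac_deg, effect_size = effect_size,
                 batch_sd = batch_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 array_scale = array_scale,
                 n_gene_sets = as.integer(n_gene_sets),
                 gene_set_size = as.integer(gene_set_size),
                 immune_enrichment = immune_enrichment,
                 n_edges = as.integer(n_edges), hub_genes = hub_genes,
                 hub_degree = as.integer(hub_degree),
                 conf_range = conf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-study expression collection with known truth
#'
#' Generates one [expression_study()] per entry of `study_sizes`. Expression
#' is `baseline + per-study batch shift + group effect (cases of true DEGs
#' only) + noise`, all on the log2 scale. Every study gets its own RNG stream
#' derived from the master seed, so identical `(config, seed)` reproduces
#' identical matrices and adding a study leaves earlier studies untouched.
#'
#' @param config A [sim_config()].
#' @return A list with `studies` (list of [expression_study()]) and `truth`
#'   (class `ground_truth`: `deg_genes`, the signed per-gene `effect` vector,
#'   and the gene `universe`).
#' @examples
#' sim <- simulate_collection(sim_config(n_genes = 100, seed = 7))
#' length(sim$truth$deg_genes)  # round(0.05 * 100) = 5
#' @export
simulate_collection <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must come from sim_config()", call. = FALSE)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  baseline <- withr::with_seed(
    seed_for(config$seed, "baseline"),
    rnorm(n, config$baseline_mean, config$baseline_sd))
  n_deg <- round(config$frac_deg * n)
  effect <- setNames(numeric(n), genes)
  if (n_deg > 0) {
    drawn <- withr::with_seed(seed_for(config$seed, "truth"), {
      idx <- sample.int(n, n_deg)
      sgn <- sample(rep(c(1, -1), length.out = n_deg))
      list(idx = idx, sgn = sgn)
    })
    effect[drawn$idx] <- drawn$sgn * config$effect_size
  }
  studies <- lapply(seq_along(config$study_sizes), function(s) {
    sizes <- config$study_sizes[[s]]
    study_id <- paste0("study", s)
    n_case <- sizes[1]; n_control <- sizes[2]
    groups <- c(rep("case", n_case), rep("control", n_control))
    ns <- length(groups)
    withr::with_seed(seed_for(config$seed, paste0("study:", study_id)), {
      batch <- rnorm(n, 0, config$batch_sd)
      vals <- baseline + batch +
        matrix(rnorm(n * ns, 0, config$noise_sd), n, ns)
      if (n_case > 0)
        vals[, seq_len(n_case)] <- vals[, seq_len(n_case)] + effect
      if (isTRUE(config$array_scale))
        vals <- sweep(vals, 2, runif(ns, 0.8, 1.25), "*")
      dimnames(vals) <- list(genes, sprintf("%s_s%02d", study_id, seq_len(ns)))
      expression_study(vals, groups, study_id)
    })
  })
  truth <- structure(list(deg_genes = genes[sort(which(effect != 0))],
                          effect = effect, universe = genes),
                     class = "ground_truth")
  list(studies = studies, truth = truth)
}

#' Simulate a matched gene-set collection
#'
#' Builds one set named `"immune system process (synthetic)"` whose members
#' are drawn from the true differential genes with probability given by
#' `immune_enrichment` (the remainder uniformly from the rest of the
#' universe), plus `n_gene_sets` background sets drawn uniformly. Written and
#' read losslessly as GMT.
#'
#' @param truth The `ground_truth` from [simulate_collection()].
#' @param config The matching [sim_config()].
#' @return A named list of gene sets with a `descriptions` attribute.
#' @export
simulate_genesets <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  universe <- truth$universe
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  size <- min(config$gene_set_size, length(universe))
  withr::with_seed(seed_for(config$seed, "genesets"), {
    n_deg_members <- round(config$immune_enrichment * size)
    n_deg_members <- min(n_deg_members, length(truth$deg_genes))
    deg_members <- if (n_deg_members > 0)
      sample(truth$deg_genes, n_deg_members) else character(0)
    rest <- sample(setdiff(universe, deg_members), size - n_deg_members)
    sets <- c(list(sort(c(deg_members, rest))),
              lapply(seq_len(config$n_gene_sets), function(i)
                sort(sample(universe, size))))
    names(sets) <- c("immune system process (synthetic)",
                     sprintf("random_set_%02d", seq_len(config$n_gene_sets)))
    attr(sets, "descriptions") <- setNames(names(sets), names(sets))
    sets
  })
}

#' Simulate a matched interaction network
#'
#' Random undirected edges over the gene universe with confidences drawn
#' uniformly from `conf_range`. Optional hub genes receive exactly
#' `hub_degree` edges each; the remaining edges are drawn among the non-hub
#' genes, so a planted hub's degree is exact.
#'
#' @param truth The `ground_truth` from [simulate_collection()].
#' @param config The matching [sim_config()].
#' @return An [interaction_network()].
#' @export
simulate_network <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  genes <- truth$universe
  hubs <- as.character(config$hub_genes %||% character(0))
  unknown <- setdiff(hubs, genes)
  if (length(unknown))
    stop("hub gene(s) outside the simulated universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- config$n_edges
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
  if (m == 0) return(interaction_network(empty))
  withr::with_seed(seed_for(config$seed, "network"), {
    pool <- setdiff(genes, hubs)
    hub_edges <- empty
    for (h in hubs) {
      partners <- sample(pool, config$hub_degree)
      hub_edges <- rbind(hub_edges,
                         data.frame(gene_a = h, gene_b = partners,
                                    confidence = NA_real_,
                                    stringsAsFactors = FALSE))
    }
    remaining <- m - nrow(hub_edges)
    if (remaining < 0)
      stop("n_edges too small for the requested hub degrees", call. = FALSE)
    pairs <- matrix(character(0), 0, 2)
    while (nrow(pairs) < remaining) {
      a <- sample(pool, remaining, replace = TRUE)
      b <- sample(pool, remaining, replace = TRUE)
      keep <- a != b
      cand <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
      pairs <- unique(rbind(pairs, cand))
    }
    pairs <- pairs[seq_len(remaining), , drop = FALSE]
    edges <- rbind(hub_edges,
                   data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                              confidence = NA_real_, stringsAsFactors = FALSE))
    edges$confidence <- runif(nrow(edges), config$conf_range[1],
                              config$conf_range[2])
    interaction_network(edges)
  })
}

#' Score a called gene set against the simulated truth
#'
#' Sensitivity is the fraction of truly differential genes recovered; the
#' false discovery rate (FDR) is the fraction of called genes that are not
#' truly differential. When the truth is empty: sensitivity is 1 if nothing
#' was called and `NA` otherwise. FDR is 0 when nothing was called.
#'
#' @param called Character vector of called gene ids (must belong to the
#'   simulated universe).
#' @param truth The `ground_truth` from [simulate_collection()].
#' @return A list with `sensitivity` and `fdr`.
#' @export
evaluate_against_truth <- function(called, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  called <- unique(as.character(called))
  unknown <- setdiff(called, truth$universe)
  if (length(unknown))
    stop("called gene(s) outside the simulated universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n_true <- length(truth$deg_genes)
  n_called <- length(called)
  hits <- length(intersect(called, truth$deg_genes))
  sensitivity <- if (n_true == 0) {
    if (n_called == 0) 1 else NA_real_
  } else hits / n_true
  fdr <- if (n_called == 0) 0 else (n_called - hits) / n_called
  list(sensitivity = sensitivity, fdr = fdr)
}
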