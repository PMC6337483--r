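#' Per-array Z-score standardization
#'
#' Standardizes every array (column) of a study to mean 0 and standard
#' deviation 1 across genes: `z = (x - mean(x)) / sd(x)`, with the mean and SD
#' taken over all genes on that array. This is the batch-effect removal step of
#' direct data integration: after it, arrays from different studies and
#' platforms live on one common scale.
#'
#' @param study An [expression_study()] with at least 2 genes.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`; the choice has
#'   no effect on any downstream decision because it rescales all genes of an
#'   array by the same factor.
#' @return The study with each column standardized.
#' @export
zscore_transform <- function(study, sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(study, "expression_study"))
  sd_denominator <- match.arg(sd_denominator)
  x <- study$values
  if (nrow(x) < 2)
    stop("Z-score transform needs >= 2 genes", call. = FALSE)
  mu <- colMeans(x)
  dev <- sqrt(colSums(sweep(x, 2, mu)^2) /
                (nrow(x) - (sd_denominator == "n-1")))
  zero <- which(dev == 0)
  if (length(zero))
    stop("zero variance array: ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  study$values <- sweep(sweep(x, 2, mu), 2, dev, "/")
  study
}

#' Collapse probe-level rows to gene level
#'
#' Maps probe ids to gene ids and, when several probes measure one gene,
#' retains the per-sample arithmetic mean of their values. Probes absent from
#' the map are dropped (count reported via [message()]). Run before
#' [zscore_transform()].
#'
#' @param study An [expression_study()] whose rownames are probe ids.
#' @param probe_map A data.frame with columns `probe` and `gene`; each probe
#'   must map to exactly one gene.
#' @return The study with one row per gene.
#' @export
collapse_probes <- function(study, probe_map) {
  stopifnot(inherits(study, "expression_study"))
  if (!all(c("probe", "gene") %in% colnames(probe_map)))
    stop("'probe_map' needs columns probe and gene", call. = FALSE)
  probe_map$probe <- as.character(probe_map$probe)
  probe_map$gene <- as.character(probe_map$gene)
  multi <- unique(probe_map$probe[duplicated(probe_map$probe)])
  multi <- intersect(multi, rownames(study$values))
  if (length(multi))
    stop("probe(s) mapped to more than one gene: ",
         paste(multi, collapse = ", "), call. = FALSE)
  keep <- intersect(rownames(study$values), probe_map$probe)
  dropped <- nrow(study$values) - length(keep)
  if (dropped > 0)
    message(sprintf("%s: dropped %d unmapped probe(s)", study$study_id, dropped))
  if (!length(keep))
    stop("no probes left after applying the probe map", call. = FALSE)
  gene <- probe_map$gene[match(keep, probe_map$probe)]
  x <- study$values[keep, , drop = FALSE]
  summed <- rowsum(x, group = gene)
  counts <- as.vector(table(gene)[rownames(summed)])
  study$values <- summed / counts
  study
}

#' Flag outlier arrays by inter-array correlation
#'
#' A single-pass screen: each array's mean Pearson correlation with all other
#' arrays is computed; arrays falling below `mean - k * SD` of those means are
#' flagged. With fewer than 3 samples the screen is skipped (empty result, with
#' a warning).
#'
#' @param study An [expression_study()].
#' @param k SD multiplier for the flagging threshold (default 2).
#' @return Character vector of flagged sample ids; the per-sample mean
#'   correlations are attached as attribute `"statistic"`.
#' @export
detect_outlier_arrays <- function(study, k = 2) {
  stopifnot(inherits(study, "expression_study"))
  n <- ncol(study$values)
  if (n < 3) {
    warning("fewer than 3 samples; outlier screen skipped", call. = FALSE)
    return(character(0))
  }
  cc <- cor(study$values)
  m <- (colSums(cc) - 1) / (n - 1)
  thr <- mean(m) - k * sd(m)
  flagged <- colnames(study$values)[m < thr]
  structure(flagged, statistic = m)
}

#' Merge studies by direct data integration
#'
#' The DDI strategy: each study is optionally outlier-screened and
#' probe-collapsed, restricted to the exact intersection of the studies' gene
#' ids, Z-scored per array over that shared universe, and column-concatenated.
#' Standardize first, merge second: every array enters the merged matrix with
#' mean 0 and SD 1, so study-level location/scale batch effects cancel.
#'
#' @param studies A list of [expression_study()] objects (at least one), with
#'   globally unique sample ids.
#' @param probe_maps Optional named list of probe maps (see
#'   [collapse_probes()]), indexed by study id.
#' @param remove_outliers Run [detect_outlier_arrays()] per study and drop the
#'   flagged arrays (off by default; removals are reported via [message()]).
#' @param k SD multiplier passed to the outlier screen.
#' @return An `integrated_dataset`: the standardized merged matrix, a sample
#'   table (`sample_id`, `study_id`, `group`) and the member study ids as
#'   `provenance`.
#' @export
integrate_studies <- function(studies, probe_maps = NULL,
                              remove_outliers = FALSE, k = 2) {
  if (!length(studies)) stop("need at least one study", call. = FALSE)
  if (!all(vapply(studies, inherits, logical(1), "expression_study")))
    stop("'studies' must be a list of expression_study objects", call. = FALSE)
  prepped <- lapply(studies, function(st) {
    if (!is.null(probe_maps) && !is.null(probe_maps[[st$study_id]]))
      st <- collapse_probes(st, probe_maps[[st$study_id]])
    if (remove_outliers) {
      out <- detect_outlier_arrays(st, k = k)
      if (length(out)) {
        message(sprintf("%s: removed %d outlier array(s): %s", st$study_id,
                        length(out), paste(out, collapse = ", ")))
        keep <- setdiff(colnames(st$values), out)
        st <- expression_study(st$values[, keep, drop = FALSE],
                               st$groups[keep], st$study_id)
      }
    }
    st
  })
  shared <- Reduce(intersect, lapply(prepped, function(s) rownames(s$values)))
  if (length(shared) < 2) {
    counts <- vapply(prepped, function(s)
      sprintf("%s: %d genes", s$study_id, nrow(s$values)), character(1))
    stop("fewer than 2 genes shared by all studies (",
         paste(counts, collapse = "; "), ")", call. = FALSE)
  }
  # Standardize on the shared gene universe so every merged column has
  # mean 0 / SD 1 exactly, then concatenate.
  prepped <- lapply(prepped, function(s) {
    s$values <- s$values[shared, , drop = FALSE]
    zscore_transform(s)
  })
  values <- do.call(cbind, lapply(prepped, `[[`, "values"))
  if (anyDuplicated(colnames(values)))
    stop("sample ids collide across studies: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  samples <- do.call(rbind, lapply(prepped, function(s)
    data.frame(sample_id = colnames(s$values), study_id = s$study_id,
               group = unname(s$groups), stringsAsFactors = FALSE)))
  rownames(samples) <- NULL
  integrated_dataset(values, samples,
                     vapply(prepped, `[[`, character(1), "study_id"))
}
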