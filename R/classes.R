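#' One study's expression matrix with sample metadata
#'
#' Container for a single microarray study: a genes x samples matrix of
#' log-scale intensities plus the case/control label of every sample. This is
#' the unit that the integration step standardizes and merges.
#'
#' @param values Numeric matrix, genes in rows (unique rownames) and samples in
#'   columns (unique colnames); log-scale intensities.
#' @param groups Character vector of per-sample labels, `"case"` or
#'   `"control"`, in column order (or named by sample id).
#' @param study_id Single string identifying the study.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `study_id`, `values` and `groups` (named by sample id).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' st <- expression_study(m, c("case", "case", "control", "control"), "demo")
#' @export
expression_study <- function(values, groups, study_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in 'values' rownames; collapse probes first or ",
         "supply a probe map", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in 'values' colnames", call. = FALSE)
  if (length(study_id) != 1L || !nzchar(study_id))
    stop("'study_id' must be a single non-empty string", call. = FALSE)
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("metadata missing sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values))
    stop(sprintf("'groups' has %d labels for %d samples",
                 length(groups), ncol(values)), call. = FALSE)
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected 'case'/'control'", call. = FALSE)
  structure(
    list(study_id = as.character(study_id), values = values,
         groups = setNames(as.character(groups), colnames(values))),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%d case, %d control)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

# Internal constructor for the merged multi-study dataset produced by
# integrate_studies(). `samples` is a data.frame(sample_id, study_id, group).
integrated_dataset <- function(values, samples, provenance) {
  stopifnot(is.matrix(values), ncol(values) == nrow(samples))
  stopifnot(identical(colnames(values), samples$sample_id))
  structure(list(values = values, samples = samples, provenance = provenance),
            class = "integrated_dataset")
}

#' @export
print.integrated_dataset <- function(x, ...) {
  cat(sprintf("<integrated_dataset> %d genes x %d samples (%d case, %d control) from %d studies: %s\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$group == "case"), sum(x$samples$group == "control"),
              length(x$provenance), paste(x$provenance, collapse = ", ")))
  invisible(x)
}

#' Subset an integrated dataset by sample ids
#'
#' @param data An `integrated_dataset`.
#' @param sample_ids Character vector of sample ids to keep.
#' @return An `integrated_dataset` restricted to those samples, in the given
#'   order.
#' @export
subset_samples <- function(data, sample_ids) {
  stopifnot(inherits(data, "integrated_dataset"))
  missing <- setdiff(sample_ids, data$samples$sample_id)
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(sample_ids, data$samples$sample_id)
  integrated_dataset(data$values[, idx, drop = FALSE],
                     data$samples[idx, , drop = FALSE],
                     data$provenance)
}
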