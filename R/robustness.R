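# Marker-list robustness by stratified subsampling: repeated 2/3 subsamples,
# DEG calling per subsample, pairwise overlap values and the co-discovery
# profile.

#' Draw stratified subsamples of an integrated dataset
#'
#' Each iteration samples, without replacement and independently per group,
#' `floor(fraction * group size)` cases and controls (minimum 2 per group).
#' Ten iterations at fraction 2/3 is the standard robustness protocol; with
#' 10 iterations the downstream report holds `C(10, 2) = 45` pairwise overlap
#' values.
#'
#' @param data An `integrated_dataset` with at least 3 samples per group.
#' @param n_iterations Number of subsamples (default 10).
#' @param fraction Per-group sampling fraction (default `2/3`).
#' @param seed Integer seed making the plan reproducible.
#' @return An object of class `subsample_plan`: a list with `iterations` (each
#'   a list with `case` and `control` sample-id vectors) plus the plan
#'   parameters.
#' @export
draw_subsamples <- function(data, n_iterations = 10, fraction = 2 / 3,
                            seed = 1) {
  stopifnot(inherits(data, "integrated_dataset"))
  if (n_iterations < 2) stop("need >= 2 iterations", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie in (0, 1)", call. = FALSE)
  cases <- data$samples$sample_id[data$samples$group == "case"]
  controls <- data$samples$sample_id[data$samples$group == "control"]
  for (g in list(c("case", length(cases)), c("control", length(controls))))
    if (as.integer(g[2]) < 3)
      stop(sprintf("group '%s' has %s samples; subsampling needs >= 3",
                   g[1], g[2]), call. = FALSE)
  # small tolerance so e.g. 2/3 of 60 floors to 40, not 39, despite binary
  # representation of 2/3
  n_case <- max(2L, as.integer(floor(fraction * length(cases) + 1e-9)))
  n_control <- max(2L, as.integer(floor(fraction * length(controls) + 1e-9)))
  iterations <- withr::with_seed(seed, lapply(seq_len(n_iterations), function(i)
    list(case = sample(cases, n_case), control = sample(controls, n_control))))
  structure(list(iterations = iterations, n_iterations = n_iterations,
                 fraction = fraction, seed = seed,
                 n_case = n_case, n_control = n_control),
            class = "subsample_plan")
}

#' Call DEGs on every subsample of a plan
#'
#' Reuses the moderated-t caller with identical thresholds on each subsample.
#'
#' @param data The `integrated_dataset` the plan was drawn from.
#' @param plan A [draw_subsamples()] plan.
#' @param fc_threshold,alpha Thresholds passed to [call_degs()].
#' @param ebayes Passed to [fit_moderated_t()].
#' @return A list of character vectors (one DEG list per iteration).
#' @export
subsample_degs <- function(data, plan, fc_threshold = 1.5, alpha = 0.05,
                           ebayes = TRUE) {
  stopifnot(inherits(plan, "subsample_plan"))
  lapply(plan$iterations, function(it) {
    sub <- subset_samples(data, c(it$case, it$control))
    call_degs(fit_moderated_t(sub, ebayes = ebayes), fc_threshold, alpha)
  })
}

#' Overlap value between two marker lists
#'
#' Symmetric similarity between two gene sets. The default,
#' `"intersection_over_min"`, is the intersection size divided by the smaller
#' list size; `"jaccard"` divides by the union size; `"mean_containment"`
#' averages the two containment fractions. All lie in `[0, 1]`. If a set is
#' empty the value is defined as 0 (with a warning), reflecting a subsample
#' that yielded no markers.
#'
#' @param a,b Character vectors (duplicates ignored).
#' @param method `"intersection_over_min"` (default), `"jaccard"` or
#'   `"mean_containment"`.
#' @return A single value in `[0, 1]`.
#' @examples
#' overlap_value(paste0("g", 1:4), paste0("g", c(1, 2, 5:8)))
#' @export
overlap_value <- function(a, b, method = c("intersection_over_min", "jaccard",
                                           "mean_containment")) {
  method <- match.arg(method)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) || !length(b)) {
    warning("empty marker list; overlap value defined as 0", call. = FALSE)
    return(0)
  }
  i <- length(intersect(a, b))
  switch(method,
         intersection_over_min = i / min(length(a), length(b)),
         jaccard = i / length(union(a, b)),
         mean_containment = (i / length(a) + i / length(b)) / 2)
}

#' Robustness report for a set of resampled marker lists
#'
#' Computes all `C(n, 2)` pairwise overlap values, their median, the union of
#' all lists, and the co-discovery profile: for each threshold `N` (from `n`
#' down to `n - 4`), the number and fraction (of the union) of genes appearing
#' in at least `N` of the lists. Fractions are also reported rounded to 2
#' decimals, the table convention. The pairwise values share subsamples and
#' are therefore not independent; treat downstream tests on them as
#' descriptive (`dependent_pairs` flag).
#'
#' @param deg_lists A list of at least 2 character vectors.
#' @param overlap_method Passed to [overlap_value()].
#' @return An object of class `robustness_report`: a list with
#'   `per_iteration_counts`, `union_size`, `overlaps` (vector of pairwise
#'   values), `overlap_median`, and `co_discovery` (data.frame with columns
#'   `n_lists`, `count`, `fraction`, `fraction_2dp`).
#' @export
robustness_report <- function(deg_lists,
                              overlap_method = "intersection_over_min") {
  if (length(deg_lists) < 2) stop("need >= 2 marker lists", call. = FALSE)
  deg_lists <- lapply(deg_lists, function(x) unique(as.character(x)))
  n <- length(deg_lists)
  pairs <- combn(n, 2)
  overlaps <- apply(pairs, 2, function(ij)
    overlap_value(deg_lists[[ij[1]]], deg_lists[[ij[2]]],
                  method = overlap_method))
  all_genes <- unlist(deg_lists, use.names = FALSE)
  union_size <- length(unique(all_genes))
  times <- table(all_genes)
  thresholds <- seq(n, max(2L, n - 4L))
  counts <- vapply(thresholds, function(k) sum(times >= k), integer(1))
  fraction <- if (union_size > 0) counts / union_size else {
    warning("all marker lists empty; co-discovery fractions set to 0",
            call. = FALSE)
    rep(0, length(counts))
  }
  structure(list(
    per_iteration_counts = lengths(deg_lists),
    union_size = union_size,
    overlaps = as.numeric(overlaps),
    overlap_median = median(as.numeric(overlaps)),
    overlap_method = overlap_method,
    co_discovery = data.frame(n_lists = thresholds, count = counts,
                              fraction = fraction,
                              fraction_2dp = round(fraction, 2)),
    dependent_pairs = TRUE), class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d lists, union %d genes, median overlap %.2f (%s)\n",
              length(x$per_iteration_counts), x$union_size,
              x$overlap_median, x$overlap_method))
  print(x$co_discovery, row.names = FALSE)
  invisible(x)
}

#' Compare overlap values between two strategies
#'
#' Two-sided test of a location difference between two vectors of overlap
#' values (Welch t-test by default, Mann-Whitney as an option). Overlap values
#' from one resampling scheme share subsamples, so the p-value is a
#' descriptive summary rather than an exact error rate.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return The two-sided p-value.
#' @export
compare_strategies <- function(values_a, values_b,
                               test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each strategy needs >= 3 overlap values", call. = FALSE)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b)))) {
      warning("both strategies constant and equal; p = 1", call. = FALSE)
      return(1)
    }
    warning("both strategies constant with different values; p = 0",
            call. = FALSE)
    return(0)
  }
  if (test == "welch") t.test(values_a, values_b)$p.value
  else suppressWarnings(wilcox.test(values_a, values_b))$p.value
}
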