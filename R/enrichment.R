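# Hypergeometric over-representation of a marker list against a gene-set
# collection, with BH correction and immune-term annotation.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Computed by exact
#' summation of the tail terms with log-space binomial coefficients, so it is
#' stable for large counts and tiny tails.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Annotated genes in the universe.
#' @param n Drawn genes (the marker list size).
#' @param N Universe size.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_upper(3, 5, 5, 20)  # 1126/15504
#' @export
hypergeom_upper <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals)))
    stop("k, K, n, N must be non-negative integers", call. = FALSE)
  if (K > N || n > N)
    stop(sprintf("inconsistent counts: K = %d, n = %d must not exceed N = %d",
                 K, n, N), call. = FALSE)
  if (k > min(K, n))
    stop(sprintf("inconsistent counts: k = %d exceeds min(K, n) = %d",
                 k, min(K, n)), call. = FALSE)
  if (k == 0) return(1)
  j <- seq(k, min(K, n))
  terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(terms)
  min(1, exp(mx) * sum(exp(terms - mx)))
}

#' Over-representation test of a marker list against a gene-set collection
#'
#' For each set, counts the overlap with the marker list within the stated
#' universe and computes the upper-tail hypergeometric p-value; p-values are
#' BH-adjusted across all tested sets (one family per collection) and flagged
#' significant at adjusted p below `alpha`. Set sizes are recomputed within
#' the universe; sets with no member in the universe are skipped. Marker genes
#' outside the universe are dropped with a warning.
#'
#' @param degs Character vector of marker gene ids.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector: the gene universe, typically the genes of
#'   the integrated dataset the markers were called from.
#' @param alpha Significance cut-off on adjusted p-values (default 0.05).
#' @return A data.frame sorted by (`p_adj`, `p`, `set`) with columns `set`,
#'   `K`, `n`, `k`, `N`, `p`, `p_adj`, `significant`, `overlap_genes`
#'   (comma-separated).
#' @export
enrich <- function(degs, collection, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(collection) || is.null(names(collection)))
    stop("'collection' must be a non-empty named list", call. = FALSE)
  degs <- unique(as.character(degs))
  outside <- setdiff(degs, universe)
  if (length(outside)) {
    warning(sprintf("dropped %d marker gene(s) outside the universe",
                    length(outside)), call. = FALSE)
    degs <- intersect(degs, universe)
  }
  empty <- data.frame(set = character(0), K = integer(0), n = integer(0),
                      k = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      overlap_genes = character(0), stringsAsFactors = FALSE)
  if (!length(degs)) {
    warning("no marker genes left after universe filtering", call. = FALSE)
    return(empty)
  }
  N <- length(universe)
  n <- length(degs)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), universe)
    if (!length(members)) return(NULL)
    hits <- intersect(members, degs)
    data.frame(set = nm, K = length(members), n = n, k = length(hits), N = N,
               p = hypergeom_upper(length(hits), length(members), n, N),
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  tab <- do.call(rbind, rows)
  tab$p_adj <- adjust_bh(tab$p)
  tab$significant <- tab$p_adj < alpha
  tab <- tab[order(tab$p_adj, tab$p, tab$set),
             c("set", "K", "n", "k", "N", "p", "p_adj", "significant",
               "overlap_genes")]
  rownames(tab) <- NULL
  tab
}

#' Annotate marker genes with immune-related set terms
#'
#' Returns the marker genes belonging to at least one gene set whose name
#' matches `pattern` (case-insensitive regular expression), together with the
#' matching term names.
#'
#' @param degs Character vector of marker gene ids.
#' @param collection Named list of gene sets.
#' @param pattern Case-insensitive regex on set names (default `"immune"`).
#' @return A named list: for each annotated gene, the character vector of
#'   matched term names. Empty (with a warning) when no set name matches.
#' @export
annotate_immune <- function(degs, collection, pattern = "immune") {
  degs <- unique(as.character(degs))
  hits <- grep(pattern, names(collection), ignore.case = TRUE, value = TRUE)
  if (!length(hits)) {
    warning(sprintf("no set name matches pattern '%s'", pattern),
            call. = FALSE)
    return(setNames(list(), character(0)))
  }
  out <- lapply(degs, function(g)
    hits[vapply(hits, function(nm) g %in% collection[[nm]], logical(1))])
  names(out) <- degs
  out[lengths(out) > 0]
}
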