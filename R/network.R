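# Interaction-network analysis: confidence filtering, marker-induced
# subgraph, and degree-based hub ranking.

#' Filter network edges by confidence
#'
#' Keeps edges with confidence strictly greater than `min_conf` (the
#' high-confidence convention: an edge at exactly the threshold is removed).
#'
#' @param net An [interaction_network()].
#' @param min_conf Confidence threshold in `[0, 1]` (default 0.7).
#' @return The filtered network.
#' @export
filter_edges <- function(net, min_conf = 0.7) {
  stopifnot(inherits(net, "interaction_network"))
  if (min_conf < 0 || min_conf > 1)
    stop("'min_conf' must lie in [0, 1]", call. = FALSE)
  out <- net[net$confidence > min_conf, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_network", "data.frame")
  out
}

#' Induce the marker subgraph and rank hub genes by degree
#'
#' Keeps edges whose endpoints are both in `genes` (the marker list), computes
#' each retained gene's degree within that induced subgraph, and ranks genes
#' by decreasing degree (gene id breaks ties). With `global_degree = TRUE` the
#' degree instead counts edges from a marker gene to any network node.
#'
#' @param net An [interaction_network()] (typically already
#'   confidence-filtered).
#' @param genes Character vector of marker gene ids.
#' @param immune Optional character vector of immune-annotated gene ids, used
#'   to fill the `immune` flag.
#' @param global_degree Count edges to any node rather than within the induced
#'   subgraph (default `FALSE`).
#' @return A data.frame of class `hub_report` with columns `gene`, `degree`,
#'   `immune`, sorted by decreasing degree then gene id; the number of induced
#'   edges is attached as attribute `n_edges`. Empty (with a warning) when no
#'   marker gene touches the network.
#' @export
induce_and_rank <- function(net, genes, immune = character(0),
                            global_degree = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  genes <- unique(as.character(genes))
  if (global_degree) {
    keep <- net$gene_a %in% genes | net$gene_b %in% genes
    sub <- net[keep, , drop = FALSE]
    ends <- c(sub$gene_a, sub$gene_b)
    ends <- ends[ends %in% genes]
  } else {
    keep <- net$gene_a %in% genes & net$gene_b %in% genes
    sub <- net[keep, , drop = FALSE]
    ends <- c(sub$gene_a, sub$gene_b)
  }
  if (!nrow(sub) || !length(ends)) {
    warning("no marker gene touches the network at this confidence level",
            call. = FALSE)
    out <- data.frame(gene = character(0), degree = integer(0),
                      immune = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_edges") <- 0L
    class(out) <- c("hub_report", "data.frame")
    return(out)
  }
  deg <- table(ends)
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out$immune <- out$gene %in% immune
  out <- out[order(-out$degree, out$gene), ]
  rownames(out) <- NULL
  attr(out, "n_edges") <- nrow(sub)
  class(out) <- c("hub_report", "data.frame")
  out
}
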