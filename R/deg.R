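# Differential expression: two-group linear model per gene with
# empirical-Bayes variance moderation, BH adjustment and the dual
# fold-change / adjusted-p threshold.

#' Moderated two-group t-statistics for an integrated dataset
#'
#' Fits, per gene, the two-group model `expression ~ group` on the processed
#' (per-array standardized) scale. The effect is the case-minus-control mean
#' difference (reported as `logFC`, the convention of the upstream log2
#' pipeline); the pooled residual variance is shrunk towards an
#' empirical-Bayes prior estimated by method of moments on the log sample
#' variances, and the moderated t uses `d0 + df` degrees of freedom, where
#' `d0` is the prior df. With `ebayes = FALSE` this is the classical pooled
#' two-sample t-test.
#'
#' @param data An `integrated_dataset` (or [expression_study()]) with at least
#'   2 samples per group.
#' @param ebayes Moderate the per-gene variances (default `TRUE`).
#' @param prior Optional list with `d0` and `s0_sq` overriding the estimated
#'   prior (e.g. `d0 = Inf` for complete shrinkage to `s0_sq`); ignored when
#'   `ebayes = FALSE`.
#' @param fc_threshold,alpha Thresholds used to fill the `is_deg` column:
#'   `|logFC| > log2(fc_threshold)` and `p_adj < alpha`.
#' @return A data.frame (one row per gene, deterministically sorted by
#'   `p_adj`, then `p`, then decreasing `|logFC|`, then gene id) with columns
#'   `gene`, `logFC`, `s2`, `df_resid`, `t`, `p`, `p_adj`, `is_deg`.
#'   Attributes `d0`, `s0_sq`, `n_case`, `n_control`, `fc_threshold`, `alpha`
#'   record the fit.
#' @examples
#' m <- matrix(rnorm(200 * 8), 200, 8,
#'             dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
#' st <- expression_study(m, rep(c("case", "control"), each = 4), "demo")
#' tab <- fit_moderated_t(integrate_studies(list(st)))
#' head(tab)
#' @export
fit_moderated_t <- function(data, ebayes = TRUE, prior = NULL,
                            fc_threshold = 1.5, alpha = 0.05) {
  if (inherits(data, "expression_study")) {
    grp <- unname(data$groups)
    x <- data$values
  } else if (inherits(data, "integrated_dataset")) {
    grp <- data$samples$group
    x <- data$values
  } else stop("'data' must be an integrated_dataset or expression_study",
              call. = FALSE)
  i1 <- grp == "case"; i2 <- grp == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2)
    stop(sprintf("need >= 2 samples per group (got %d case, %d control)",
                 n1, n2), call. = FALSE)
  if (ebayes && nrow(x) < 2)
    stop("empirical-Bayes moderation needs >= 2 genes", call. = FALSE)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- row_vars(x[, i1, drop = FALSE])
  v2 <- row_vars(x[, i2, drop = FALSE])
  logfc <- m1 - m2
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  if (ebayes) {
    pos <- s2 > 0
    if (is.null(prior)) {
      if (!any(pos))
        stop("all genes have zero residual variance; cannot estimate the prior",
             call. = FALSE)
      prior <- fit_fdist(s2[pos], df)
    } else {
      if (!is.list(prior) || is.null(prior$d0) || is.null(prior$s0_sq) ||
          prior$d0 <= 0 || prior$s0_sq <= 0)
        stop("'prior' must be a list with d0 > 0 (possibly Inf) and s0_sq > 0",
             call. = FALSE)
    }
    d0 <- prior$d0; s0_sq <- prior$s0_sq
    if (any(!pos))
      message(sprintf("%d zero-variance gene(s): s2 replaced by the prior variance",
                      sum(!pos)))
    s2g <- ifelse(pos, s2, s0_sq)
    s2_post <- if (is.finite(d0)) (d0 * s0_sq + df * s2g) / (d0 + df) else
      rep(s0_sq, length(s2g))
    # cap total df at the pooled residual df, the usual guard when d0 is
    # huge/infinite
    df_total <- min(d0 + df, nrow(x) * df)
  } else {
    d0 <- 0; s0_sq <- NA_real_
    s2_post <- s2
    df_total <- df
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[is.na(p)] <- 1
  p_adj <- adjust_bh(p)
  tab <- data.frame(gene = rownames(x), logFC = logfc, s2 = s2,
                    df_resid = df, t = tstat, p = p, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  tab$is_deg <- abs(tab$logFC) > log2(fc_threshold) & tab$p_adj < alpha
  tab <- tab[order(tab$p_adj, tab$p, -abs(tab$logFC), tab$gene), ]
  rownames(tab) <- NULL
  attr(tab, "d0") <- d0
  attr(tab, "s0_sq") <- s0_sq
  attr(tab, "n_case") <- n1
  attr(tab, "n_control") <- n2
  attr(tab, "fc_threshold") <- fc_threshold
  attr(tab, "alpha") <- alpha
  tab
}

# Method-of-moments fit of the scaled inverse-chi-square prior for gene-wise
# variances: moments of log(s2) around digamma/trigamma of df/2 give the prior
# df (d0) and prior variance (s0_sq). No positive solution for the trigamma
# equation means the variances are no more dispersed than chi-square sampling
# noise allows, i.e. complete shrinkage (d0 = Inf).
fit_fdist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (length(e) >= 2 && !is.na(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The step-up procedure: sort the m p-values ascending, set
#' `p_adj(i) = min over j >= i of min(1, p(j) * m / j)`, and return the
#' adjusted values in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_bh(c(0.01, 0.04, 0.03, 0.005))
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Call differentially expressed genes
#'
#' Applies the dual threshold: fold change above `fc_threshold` (i.e.
#' `|logFC| > log2(fc_threshold)`) and BH-adjusted p-value below `alpha`.
#'
#' @param table A DEG table from [fit_moderated_t()].
#' @param fc_threshold Fold-change threshold on the natural scale, `> 1`
#'   (default 1.5).
#' @param alpha Adjusted-p cut-off in `(0, 1]` (default 0.05).
#' @return Character vector of gene ids, in the table's deterministic order.
#' @export
call_degs <- function(table, fc_threshold = 1.5, alpha = 0.05) {
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1 || fc_threshold <= 1)
    stop("'fc_threshold' must be a single value > 1", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  need <- c("gene", "logFC", "p_adj")
  if (!all(need %in% colnames(table)))
    stop("'table' must have columns gene, logFC, p_adj", call. = FALSE)
  table$gene[abs(table$logFC) > log2(fc_threshold) & table$p_adj < alpha]
}
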