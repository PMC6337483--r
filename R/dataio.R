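#' Read an expression matrix and its sample metadata
#'
#' Reads a tab-delimited expression matrix (first column gene id, one column
#' per sample, log-scale intensities) together with a metadata table
#' (`sample`, `study`, `group`) and returns a validated [expression_study()].
#' All samples must belong to one study; read multi-study metadata one study at
#' a time.
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV with columns `sample`,
#'   `study`, `group`.
#' @param drop_na Drop genes containing non-numeric or missing cells instead of
#'   erroring; the number of dropped genes is reported via [message()].
#' @param log2_transform Apply `log2(x + 1)` on read, for matrices stored as
#'   raw (non-logged) intensities.
#' @param case_label,control_label Strings used in the metadata `group` column
#'   for cases and controls; mapped onto the internal `"case"`/`"control"`
#'   vocabulary.
#'
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, metadata_path, drop_na = FALSE,
                            log2_transform = FALSE,
                            case_label = "case", control_label = "control") {
  if (!file.exists(matrix_path))
    stop("expression file not found: ", matrix_path, call. = FALSE)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  raw <- read.delim(matrix_path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2)
    stop(sprintf("%s: expected a gene-id column plus >= 1 sample column",
                 matrix_path), call. = FALSE)
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    stop(sprintf("%s: duplicate gene id '%s'; collapse probes with a probe map",
                 matrix_path, gene_ids[anyDuplicated(gene_ids)]), call. = FALSE)
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, colnames(raw)[-1]))
  rownames(vals) <- gene_ids
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    if (drop_na) {
      drop <- unique(bad[, 1])
      message(sprintf("%s: dropped %d gene(s) with missing/non-numeric values",
                      matrix_path, length(drop)))
      vals <- vals[-drop, , drop = FALSE]
      if (!nrow(vals))
        stop(sprintf("%s: no genes left after dropping missing values",
                     matrix_path), call. = FALSE)
    } else {
      stop(sprintf("%s: non-numeric or missing value at gene '%s', sample '%s' (row %d, column %d); use drop_na = TRUE to drop such genes",
                   matrix_path, gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                   bad[1, 1], bad[1, 2] + 1L), call. = FALSE)
    }
  }
  if (log2_transform) vals <- log2(vals + 1)

  meta <- read_metadata(metadata_path)
  missing <- setdiff(colnames(vals), meta$sample)
  if (length(missing))
    stop(sprintf("%s: metadata missing sample(s): %s", metadata_path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  meta <- meta[match(colnames(vals), meta$sample), ]
  studies <- unique(meta$study)
  if (length(studies) != 1L)
    stop(sprintf("%s: samples span multiple studies (%s); read one study at a time",
                 metadata_path, paste(studies, collapse = ", ")), call. = FALSE)
  grp <- meta$group
  grp[grp == case_label] <- "case"
  grp[grp == control_label] <- "control"
  unknown <- setdiff(unique(grp), c("case", "control"))
  if (length(unknown))
    stop(sprintf("%s: unknown group label(s): %s", metadata_path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  expression_study(vals, setNames(grp, meta$sample), studies)
}

read_metadata <- function(path) {
  meta <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("sample", "study", "group")
  absent <- setdiff(need, colnames(meta))
  if (length(absent))
    stop(sprintf("%s: metadata missing column(s): %s", path,
                 paste(absent, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(meta$sample))
    stop(sprintf("%s: duplicate sample id '%s'", path,
                 meta$sample[anyDuplicated(meta$sample)]), call. = FALSE)
  meta
}

#' Write an expression study to TSV
#'
#' Writes the expression matrix (first column `gene`, then one column per
#' sample) and, optionally, the matching metadata table. Output is UTF-8 with
#' LF line endings and deterministic column order, so write -> read -> write
#' round-trips byte-identically.
#'
#' @param study An [expression_study()].
#' @param matrix_path Output path for the expression TSV.
#' @param metadata_path Optional output path for the metadata TSV (`sample`,
#'   `study`, `group`).
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(study, matrix_path, metadata_path = NULL) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$values), study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  if (!is.null(metadata_path)) {
    meta <- data.frame(sample = colnames(study$values),
                       study = study$study_id,
                       group = unname(study$groups),
                       stringsAsFactors = FALSE)
    write_tsv(meta, metadata_path)
  }
  invisible(matrix_path)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene ids. Duplicate members within a line are deduplicated;
#' duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (the gene sets), with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("%s: line %d has %d field(s); GMT needs name, description and >= 1 member",
                 path, short[1], lengths(fields)[short[1]]), call. = FALSE)
  names_ <- vapply(fields, `[[`, character(1), 1L)
  dup <- names_[duplicated(names_)]
  if (length(dup))
    stop(sprintf("%s: duplicate set name '%s'", path, dup[1]), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <-
    setNames(vapply(fields, `[[`, character(1), 2L), names_)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param collection Named list of character vectors; an optional
#'   `descriptions` attribute supplies the second GMT field (defaults to the
#'   set name).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  if (!length(collection) || is.null(names(collection)))
    stop("'collection' must be a non-empty named list", call. = FALSE)
  if (any(!lengths(collection)))
    stop("empty gene set(s): ",
         paste(names(collection)[!lengths(collection)], collapse = ", "),
         call. = FALSE)
  desc <- attr(collection, "descriptions") %||%
    setNames(names(collection), names(collection))
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, desc[[nm]] %||% nm, collection[[nm]]), collapse = "\t"),
    character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Build a validated undirected interaction network
#'
#' Self-loops are dropped (with a warning); `(a, b)`/`(b, a)` duplicates are
#' merged keeping the maximum confidence; endpoint order is normalized so
#' `gene_a < gene_b`.
#'
#' @param edges A data.frame with columns `gene_a`, `gene_b`, `confidence`
#'   (confidence in `[0, 1]`).
#' @return A data.frame of class `interaction_network`, sorted by endpoints.
#' @export
interaction_network <- function(edges) {
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% colnames(edges)))
    stop("'edges' needs columns gene_a, gene_b, confidence", call. = FALSE)
  edges <- edges[, need, drop = FALSE]
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$confidence <- as.numeric(edges$confidence)
  if (nrow(edges)) {
    if (any(is.na(edges$confidence) | edges$confidence < 0 | edges$confidence > 1))
      stop("edge confidence outside [0, 1]", call. = FALSE)
    loops <- edges$gene_a == edges$gene_b
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
      edges <- edges[!loops, , drop = FALSE]
    }
  }
  if (nrow(edges)) {
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    key <- paste(a, b, sep = "\r")
    conf <- tapply(edges$confidence, key, max)
    keys <- sort(names(conf))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(parts, `[[`, character(1), 1L),
                        gene_b = vapply(parts, `[[`, character(1), 2L),
                        confidence = as.numeric(conf[keys]),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  class(edges) <- c("interaction_network", "data.frame")
  edges
}

#' Read an interaction edge list
#'
#' Three-column TSV `gene_a`, `gene_b`, `confidence`. `scale = "string1000"`
#' declares STRING-convention scores in 0-1000, which are divided by 1000;
#' `"unit"` declares scores already in `[0, 1]`. Scores outside the declared
#' range are an error.
#'
#' @param path Path to the edge TSV (with or without a header line).
#' @param scale `"unit"` or `"string1000"`.
#' @return An [interaction_network()].
#' @export
read_edges <- function(path, scale = c("unit", "string1000")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("edge file not found: ", path, call. = FALSE)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  df <- read.delim(path, header = has_header, colClasses = "character")
  if (ncol(df) < 3)
    stop(sprintf("%s: expected 3 columns (gene_a, gene_b, confidence)", path),
         call. = FALSE)
  conf <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(conf)) {
    line <- which(is.na(conf))[1] + has_header
    stop(sprintf("%s: non-numeric confidence at line %d", path, line),
         call. = FALSE)
  }
  hi <- if (scale == "string1000") 1000 else 1
  out <- which(conf < 0 | conf > hi)
  if (length(out))
    stop(sprintf("%s: confidence %g at line %d outside declared range [0, %g]",
                 path, conf[out[1]], out[1] + has_header, hi), call. = FALSE)
  if (scale == "string1000") conf <- conf / 1000
  interaction_network(data.frame(gene_a = df[[1]], gene_b = df[[2]],
                                 confidence = conf, stringsAsFactors = FALSE))
}

#' Write an interaction network to TSV
#'
#' @param net An [interaction_network()].
#' @param path Output path; written with a `gene_a`/`gene_b`/`confidence`
#'   header, scores on the unit scale.
#' @return Invisibly, `path`.
#' @export
write_edges <- function(net, path) {
  write_tsv(as.data.frame(net), path)
  invisible(path)
}
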