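# Readers and writers for the tabular formats the pipeline touches.
# Everything is TSV (UTF-8, '#' comment lines allowed) except the edge list,
# which is a plain whitespace-delimited weighted edge list, and GMT.

#' Read a log2 expression matrix from TSV
#'
#' The file must have a header row (first field names the identifier column,
#' remaining fields are array ids) and one row per probeset. Lines starting
#' with `#` are ignored. Every cell must be a finite number; identifiers
#' must be unique; at least one probeset and two arrays are required.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, probesets in rows, arrays in columns.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 3) {
    stop_immunet("expression matrix needs an id column and >= 2 arrays, found %d columns",
                 ncol(df))
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop_immunet("duplicated probeset id '%s'", ids[duplicated(ids)][1])
  }
  arrays <- colnames(df)[-1]
  if (anyDuplicated(arrays)) {
    stop_immunet("duplicated array id '%s'", arrays[duplicated(arrays)][1])
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_immunet("non-numeric or missing value at probeset '%s', array '%s'",
                 ids[bad[1, 1]], arrays[bad[1, 2]])
  }
  if (nrow(num) < 1) stop_immunet("expression matrix has no probesets")
  dimnames(num) <- list(ids, arrays)
  num
}

#' Write an expression matrix to TSV
#'
#' Values are written with 6 decimals, so `write` then `read` reproduces the
#' matrix to within 1e-6. Row order is preserved.
#'
#' @param matrix numeric matrix with row (probeset) and column (array) names.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  validate_expression_matrix(matrix)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("probeset_id", colnames(matrix)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.6f", matrix[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

validate_expression_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_immunet("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop_immunet("expression matrix must have probeset and array names")
  }
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop_immunet("expression matrix has duplicated identifiers")
  }
  if (any(!is.finite(matrix))) stop_immunet("expression matrix has missing or non-finite values")
  if (nrow(matrix) < 1 || ncol(matrix) < 2) {
    stop_immunet("expression matrix needs >= 1 probeset and >= 2 arrays")
  }
  invisible(matrix)
}

#' Read a sample sheet and validate it against a matrix
#'
#' Expects a TSV with columns `array_id`, `dataset_id`, `condition`
#' (`control` or `treated`); extra label columns (tissue, pathogen,
#' timepoint, ...) are carried through. When `matrix` is supplied the sheet
#' must cover its arrays exactly once each. Each dataset must have at least
#' `min_group_size` arrays (Pearson correlation needs >= 3 points per group
#' for a non-degenerate estimate).
#'
#' @param path path to a TSV file.
#' @param matrix optional expression matrix to validate against.
#' @param min_group_size minimum arrays per dataset (default 3).
#' @return data.frame, one row per array.
#' @export
read_sample_sheet <- function(path, matrix = NULL, min_group_size = 3) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  validate_sample_sheet(df, matrix, min_group_size)
}

validate_sample_sheet <- function(sheet, matrix = NULL, min_group_size = 3) {
  need <- c("array_id", "dataset_id", "condition")
  missing_cols <- setdiff(need, colnames(sheet))
  if (length(missing_cols) > 0) {
    stop_immunet("sample sheet lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sheet$array_id)) {
    stop_immunet("sample sheet lists array '%s' more than once",
                 sheet$array_id[duplicated(sheet$array_id)][1])
  }
  bad_cond <- setdiff(unique(sheet$condition), c("control", "treated"))
  if (length(bad_cond) > 0) {
    stop_immunet("condition must be 'control' or 'treated', found '%s'", bad_cond[1])
  }
  if (!is.null(matrix)) {
    absent <- setdiff(colnames(matrix), sheet$array_id)
    if (length(absent) > 0) {
      stop_immunet("sample sheet is missing matrix array(s): %s",
                   paste(absent, collapse = ", "))
    }
    unknown <- setdiff(sheet$array_id, colnames(matrix))
    if (length(unknown) > 0) {
      stop_immunet("sample sheet names unknown array(s): %s",
                   paste(unknown, collapse = ", "))
    }
    sheet <- sheet[match(colnames(matrix), sheet$array_id), , drop = FALSE]
    rownames(sheet) <- NULL
  }
  sizes <- table(sheet$dataset_id)
  if (any(sizes < min_group_size)) {
    small <- names(sizes)[sizes < min_group_size][1]
    stop_immunet("dataset '%s' has %d arrays, below the minimum of %d",
                 small, sizes[[small]], min_group_size)
  }
  sheet
}

#' Write a sample sheet to TSV
#' @param sheet data.frame as returned by [read_sample_sheet()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read annotation sources: a term map and optionally a GMT collection
#'
#' The term map may be a two-column TSV (`entity`, `term`) or a GAF-style
#' file (15+ tab-separated fields; columns 2 and 5 are used, `!` comment
#' lines skipped). Repeated (entity, term) pairs are deduplicated. The GMT
#' file follows the usual convention: set name, description, then members;
#' lines with fewer than 3 fields are an error.
#'
#' @param term_map_path path to the term map, or `NULL`.
#' @param gmt_path optional path to a GMT file.
#' @return list with `term_map` (named list: entity -> character vector of
#'   terms) and `gene_sets` (named list: set name -> member ids).
#' @export
read_annotation_sources <- function(term_map_path, gmt_path = NULL) {
  term_map <- if (is.null(term_map_path)) list() else read_term_map(term_map_path)
  gene_sets <- if (is.null(gmt_path)) list() else read_gmt(gmt_path)
  list(term_map = term_map, gene_sets = gene_sets)
}

read_term_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[!#]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning(sprintf("term map '%s' is empty", path), call. = FALSE)
    return(list())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf >= 15)) {            # GAF subset: DB object id (2), GO id (5)
    entity <- vapply(fields, `[[`, character(1), 2)
    term <- vapply(fields, `[[`, character(1), 5)
  } else {
    short <- which(nf < 2)
    if (length(short) > 0) {
      stop_immunet("term map line %d has fewer than 2 fields", short[1])
    }
    entity <- vapply(fields, `[[`, character(1), 1)
    term <- vapply(fields, `[[`, character(1), 2)
  }
  if (any(!nzchar(term))) stop_immunet("term map contains an empty term id")
  lapply(split(term, entity), unique)
}

read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warning(sprintf("GMT file '%s' is empty", path), call. = FALSE)
    return(list())
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_immunet("GMT line %d has fewer than 3 fields", which(keep)[nf < 3][1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    stop_immunet("duplicated gene set name '%s'",
                 names(sets)[duplicated(names(sets))][1])
  }
  sets
}

#' Write / read a weighted edge list
#'
#' One edge per line, `idA idB weight`, whitespace-delimited, weight with 6
#' decimals, smaller id first. Readers reject self edges, duplicate pairs
#' and weights outside \[-1, 1\].
#'
#' @param edges data.frame with columns `a`, `b`, `weight`.
#' @param path file path.
#' @return `write_edge_list` returns the path invisibly; `read_edge_list`
#'   returns the validated edge data.frame sorted canonically.
#' @export
write_edge_list <- function(edges, path) {
  edges <- validate_edge_list(edges)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(edges) > 0) {
    writeLines(sprintf("%s %s %.6f", edges$a, edges$b, edges$weight), con)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) {
    return(data.frame(a = character(0), b = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(fields) != 3)) {
    stop_immunet("edge list line %d does not have 3 fields",
                 which(lengths(fields) != 3)[1])
  }
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (any(is.na(w))) stop_immunet("non-numeric edge weight on line %d", which(is.na(w))[1])
  flip <- a > b
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  validate_edge_list(data.frame(a = a, b = b, weight = w,
                                stringsAsFactors = FALSE))
}

validate_edge_list <- function(edges) {
  if (!all(c("a", "b", "weight") %in% colnames(edges))) {
    stop_immunet("edge list needs columns a, b, weight")
  }
  if (any(edges$a == edges$b)) {
    stop_immunet("self edge on node '%s'", edges$a[edges$a == edges$b][1])
  }
  if (any(edges$a > edges$b)) {
    stop_immunet("edge pair not in canonical (lexicographic) order: %s %s",
                 edges$a[edges$a > edges$b][1], edges$b[edges$a > edges$b][1])
  }
  key <- paste(edges$a, edges$b)
  if (anyDuplicated(key)) {
    stop_immunet("duplicated edge %s", key[duplicated(key)][1])
  }
  if (any(abs(edges$weight) > 1 + 1e-9)) {
    stop_immunet("edge weight %.6f outside [-1, 1]",
                 edges$weight[abs(edges$weight) > 1 + 1e-9][1])
  }
  edges[order(edges$a, edges$b), , drop = FALSE]
}

#' Write a pipeline result table to TSV with deterministic row order
#'
#' Cluster assignments are sorted by cluster number then id; enrichment
#' tables by (cluster, q, p, term); QC reports by array id; any other
#' data.frame is written as-is. Two writes of the same object are
#' byte-identical.
#'
#' @param x a result data.frame (classes `immunet_clusters`,
#'   `immunet_enrichment`, `immunet_qc`, or plain).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "immunet_clusters")) {
    df <- df[order(df$cluster, df$id, na.last = TRUE), , drop = FALSE]
  } else if (inherits(x, "immunet_enrichment")) {
    df <- df[order(df$cluster, df$q, df$p, df$term), , drop = FALSE]
  } else if (inherits(x, "immunet_qc")) {
    df <- df[order(df$array_id), , drop = FALSE]
  }
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.6g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
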