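# Headered-TSV readers/writers for the tabular inputs: disease-enhancer
# associations, term->gene annotations, disease->term maps, enhancer->gene
# maps, and pairwise similarity matrices.  IDs are opaque strings.

read_tsv_checked <- function(path, required) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease-enhancer association table
#'
#' TSV with a one-line header and columns `disease`, `enhancer`, plus an
#' optional `provenance` column.  Duplicate (disease, enhancer) pairs are
#' collapsed to one row.
#'
#' @param path input TSV path.
#' @return data.frame with columns `disease`, `enhancer` (and
#'   `provenance` if present).
#' @export
read_association_table <- function(path) {
  df <- read_tsv_checked(path, c("disease", "enhancer"))
  dup <- duplicated(df[, c("disease", "enhancer")])
  if (any(dup)) {
    message("collapsing ", sum(dup), " duplicate association row(s)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a disease-enhancer association table
#' @param assoc data.frame with columns `disease`, `enhancer`.
#' @param path output path.
#' @export
write_association_table <- function(assoc, path) write_tsv(assoc, path)

#' Read a term->gene annotation table (columns `term`, `gene`)
#' @param path input TSV path.
#' @return data.frame.
#' @export
read_annotation_table <- function(path) read_tsv_checked(path, c("term", "gene"))

#' Write a term->gene annotation table
#' @param annotations data.frame with columns `term`, `gene`.
#' @param path output path.
#' @export
write_annotation_table <- function(annotations, path)
  write_tsv(annotations[, c("term", "gene")], path)

#' Read a disease->term map (columns `disease`, `term`)
#' @param path input TSV path.
#' @return data.frame.
#' @export
read_disease_map <- function(path) read_tsv_checked(path, c("disease", "term"))

#' Write a disease->term map
#' @param disease_map data.frame with columns `disease`, `term`.
#' @param path output path.
#' @export
write_disease_map <- function(disease_map, path)
  write_tsv(disease_map[, c("disease", "term")], path)

#' Read an enhancer->target-gene table into a catalog
#'
#' TSV with columns `enhancer`, `gene`, one row per pair.  Optionally a
#' BED file supplies enhancer coordinates (matched by the BED name/id
#' column).
#'
#' @param path enhancer-gene TSV path.
#' @param bed optional BED path with enhancer coordinates.
#' @return an [enhancer_catalog()].
#' @export
read_enhancer_catalog <- function(path, bed = NULL) {
  df <- read_tsv_checked(path, c("enhancer", "gene"))
  targets <- lapply(split(df$gene, df$enhancer), unique)
  intervals <- if (!is.null(bed)) read_bed(bed) else NULL
  enhancer_catalog(targets, intervals = intervals)
}

#' Write an enhancer->target-gene table
#' @param catalog an [enhancer_catalog()].
#' @param path output path.
#' @export
write_enhancer_catalog <- function(catalog, path) {
  df <- data.frame(
    enhancer = rep(catalog$ids, lengths(catalog$targets[catalog$ids])),
    gene = unlist(catalog$targets[catalog$ids], use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a pairwise similarity matrix
#'
#' Two dialects are supported: `"square"` — a labelled square TSV whose
#' first column and header carry the labels; `"clustal"` — the Clustal
#' Omega full-matrix percent-identity format (first line: count; then one
#' row per sequence: label followed by whitespace-separated values).
#' Mildly asymmetric input is symmetrized by averaging when the maximum
#' discrepancy is within `tolerance` (default `1e-6 * max(|A|)`);
#' otherwise the input is rejected with the worst pair reported.
#'
#' @param path input path.
#' @param dialect `"square"` or `"clustal"`.
#' @param tolerance symmetrization tolerance; `NULL` for the default.
#' @return numeric matrix with label dimnames.
#' @export
read_similarity_matrix <- function(path, dialect = c("square", "clustal"),
                                   tolerance = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "square") {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as.matrix(df)
    labels <- rownames(mat)
    if (!identical(labels, colnames(mat)))
      stop("row and column labels differ in ", path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- suppressWarnings(as.integer(trimws(lines[1L])))
    if (is.na(n)) stop("clustal matrix must start with the sequence count")
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    if (length(rows) != n) stop("expected ", n, " matrix rows in ", path)
    labels <- vapply(rows, `[`, "", 1L)
    mat <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
    dimnames(mat) <- list(labels, labels)
  }
  if (anyDuplicated(labels)) stop("duplicate labels in ", path)
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric cells in ", path)
  if (nrow(mat) != ncol(mat)) stop("similarity matrix is not square")
  if (is.null(tolerance)) tolerance <- 1e-6 * max(abs(mat), 0)
  d <- abs(mat - t(mat))
  if (max(d) > tolerance) {
    ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "similarity matrix asymmetric beyond tolerance %g: A[%s,%s]=%g vs A[%s,%s]=%g",
      tolerance, labels[ij[1L]], labels[ij[2L]], mat[ij[1L], ij[2L]],
      labels[ij[2L]], labels[ij[1L]], mat[ij[2L], ij[1L]]))
  }
  (mat + t(mat)) / 2
}

#' Write a pairwise similarity matrix
#' @param mat labelled square numeric matrix.
#' @param path output path.
#' @param dialect `"square"` (labelled TSV) or `"clustal"`.
#' @export
write_similarity_matrix <- function(mat, path,
                                    dialect = c("square", "clustal")) {
  dialect <- match.arg(dialect)
  labels <- rownames(mat)
  if (dialect == "square") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste(c("id", labels), collapse = "\t"), con)
    for (i in seq_along(labels))
      writeLines(paste(c(labels[i], sprintf("%.10g", mat[i, ])),
                       collapse = "\t"), con)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(as.character(nrow(mat)), con)
    for (i in seq_along(labels))
      writeLines(paste(c(labels[i], sprintf("%.10g", mat[i, ])),
                       collapse = " "), con)
  }
  invisible(path)
}

#' Export a supra matrix as coordinate-format TSV (debugging aid)
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @export
write_supra_tsv <- function(mat, path) {
  nz <- which(mat != 0, arr.ind = TRUE)
  df <- data.frame(row = rownames(mat)[nz[, 1L]],
                   col = colnames(mat)[nz[, 2L]],
                   value = mat[nz], stringsAsFactors = FALSE)
  write_tsv(df, path)
}
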