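#' Genomic intervals
#'
#' Enhancers are identified by genomic intervals.  Internally all
#' coordinates are 0-based half-open (the BED convention); rendered
#' identifiers use 1-based inclusive display coordinates of the form
#' `"chr10:6074002–6104800"` (en dash), the convention of curated
#' enhancer identifiers.
#'
#' @param chrom chromosome names.
#' @param start 0-based start positions.
#' @param end end positions (exclusive); must satisfy `start < end`.
#' @param id optional identifiers; default is [render_interval()].
#' @return data.frame of class `genomic_intervals` with columns `chrom`,
#'   `start`, `end`, `id`.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("interval start must be < end")
  if (any(start < 0)) stop("negative start coordinate")
  if (is.null(id)) id <- render_interval(chrom, start, end)
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    id = as.character(id), stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Render an interval identifier
#'
#' Display coordinates are 1-based inclusive: display start = internal
#' start + 1, display end = internal end.
#'
#' @param chrom,start,end vectors as in [genomic_intervals()].
#' @return character vector like `"chr1:10–20"`.
#' @export
render_interval <- function(chrom, start, end) {
  sprintf("%s:%d–%d", chrom, as.integer(start) + 1L, as.integer(end))
}

#' Parse interval identifiers
#'
#' Accepts both the en dash used in rendered identifiers and a plain
#' hyphen.  Inverse of [render_interval()].
#'
#' @param x character vector of identifiers.
#' @return a [genomic_intervals()] data.frame.
#' @export
parse_interval <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)[–-]([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("cannot parse interval id(s): ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  dstart <- as.integer(vapply(m, `[`, "", 3L))
  dend <- as.integer(vapply(m, `[`, "", 4L))
  genomic_intervals(chrom, dstart - 1L, dend, id = x)
}

#' Read a BED file (BED3+)
#'
#' Coordinates are kept in BED's native 0-based half-open convention.
#' Rows with `start >= end` are dropped with a warning.  A fourth column,
#' if present, supplies the interval id; otherwise ids are rendered from
#' the coordinates.
#'
#' @param path BED file path.
#' @return a [genomic_intervals()] data.frame (possibly 0-row).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(genomic_intervals(character(), integer(), integer())[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 3L))
    stop("BED rows must have at least 3 tab-separated columns")
  chrom <- vapply(parts, `[`, "", 1L)
  start <- as.integer(vapply(parts, `[`, "", 2L))
  end <- as.integer(vapply(parts, `[`, "", 3L))
  id <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, "")
  keep <- start < end
  if (any(!keep))
    warning(sum(!keep), " BED row(s) with start >= end dropped")
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]; id <- id[keep]
  id[is.na(id)] <- render_interval(chrom[is.na(id)], start[is.na(id)],
                                   end[is.na(id)])
  if (!length(chrom))
    return(genomic_intervals(character(), integer(), integer())[0, ])
  genomic_intervals(chrom, start, end, id = id)
}

#' Write intervals as BED3+1
#' @param intervals a [genomic_intervals()] data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom, intervals$start,
                     intervals$end, intervals$id), path)
  invisible(path)
}

#' Extract interval sequences from a genome FASTA
#'
#' Minimal plus-strand extraction: sequence length equals `end - start`
#' and output is uppercased.  Enhancers are treated as unstranded.
#'
#' @param intervals a [genomic_intervals()] data.frame.
#' @param genome path to a FASTA file or a `Biostrings::DNAStringSet`.
#' @return named character vector of sequences (names = interval ids).
#' @export
extract_fasta <- function(intervals, genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  gnames <- sub("\\s.*$", "", names(genome))
  out <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[i]
    j <- match(chrom, gnames)
    if (is.na(j))
      stop("chromosome not found in genome: ", chrom)
    w <- Biostrings::width(genome)[j]
    if (intervals$end[i] > w)
      stop("interval ", intervals$id[i], " extends beyond contig end (",
           w, " bp)")
    out[i] <- toupper(as.character(Biostrings::subseq(
      genome[[j]], start = intervals$start[i] + 1L, end = intervals$end[i])))
  }
  names(out) <- intervals$id
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
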