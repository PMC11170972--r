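# FASTA and GFF3 input/output. Sequences travel through the package as named
# character vectors (names = record ids, optional "desc" attribute); gene
# models as data frames with 1-based inclusive coordinates, the same
# convention GFF3 uses on disk.

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] and returns a named character vector.
#' The record id is the first whitespace-delimited token of the header; any
#' remainder is kept in the `"desc"` attribute. Duplicate ids and empty
#' sequences are rejected. CRLF line endings are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences with a `"desc"` attribute
#'   (character vector of descriptions, `""` where absent).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  attr(seqs, "desc") <- desc
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector (names become ids). An optional
#'   `"desc"` attribute is appended to headers.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) stop("all records need ids")
  if (anyDuplicated(names(seqs))) stop("duplicate ids")
  if (any(nchar(seqs) == 0L)) stop("refusing to write empty records")
  desc <- attr(seqs, "desc") %||% rep("", length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    header <- if (nzchar(desc[i])) paste(names(seqs)[i], desc[i]) else names(seqs)[i]
    writeLines(paste0(">", header), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses with [rtracklayer::readGFF()] and returns a plain data frame with
#' 1-based inclusive coordinates, columns `seqid, source, type, start, end,
#' score, strand, phase` plus the attribute columns `ID`, `gene` and
#' `product` (NA where absent).
#'
#' @param path Path to a GFF3 file.
#' @return Data frame of features.
#' @export
read_gff3 <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  for (col in c("ID", "gene", "product")) {
    if (is.null(g[[col]])) g[[col]] <- NA_character_
  }
  if (any(g$end < g$start)) stop("GFF3 feature with end < start")
  if (any(!g$strand %in% c("+", "-", "*", NA))) stop("unknown strand value")
  cds <- g$type == "CDS"
  bad <- cds & ((g$end - g$start + 1L) %% 3L != 0L)
  if (any(bad)) {
    warning(sum(bad), " CDS feature(s) with length not divisible by 3")
  }
  g[, c("seqid", "source", "type", "start", "end", "score", "strand",
        "phase", "ID", "gene", "product")]
}

#' Write gene models as GFF3
#'
#' @param features Data frame as returned by [read_gff3()] (columns `seqid`,
#'   `type`, `start`, `end`, `strand`; optional `source`, `score`, `phase`,
#'   `ID`, `gene`, `product`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  if (any(features$end < features$start)) stop("feature with end < start")
  n <- nrow(features)
  get_col <- function(col, default) {
    if (is.null(features[[col]])) rep(default, n) else features[[col]]
  }
  src <- get_col("source", "panlachno")
  score <- get_col("score", NA)
  phase <- get_col("phase", NA)
  attrs <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (col in c("ID", "gene", "product")) {
      v <- features[[col]][i]
      if (!is.null(v) && !is.na(v) && nzchar(v)) {
        parts <- c(parts, paste0(col, "=", v))
      }
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   features$seqid, src, features$type,
                   as.integer(features$start), as.integer(features$end),
                   ifelse(is.na(score), ".", as.character(score)),
                   as.character(features$strand),
                   ifelse(is.na(phase), ".", as.character(phase)),
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a numeric matrix as square TSV with row/column ids
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
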