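#' Read a multi-FASTA file of contigs
#'
#' Parses a (optionally gzip-compressed, detected by a `.gz` suffix) FASTA
#' file into a data frame of sequence records. The record id is the first
#' whitespace-delimited token of the header; the remainder of the header is
#' kept as the description. Sequence lines are concatenated and uppercased.
#'
#' Structural problems are reported with the offending line number: a
#' sequence line before any header, a duplicate record id, or an entirely
#' empty file are all errors. Characters are validated against the IUPAC
#' nucleotide alphabet (ambiguity codes and gap characters are accepted here;
#' they are removed later by [sanitize_sequence()] before any word counting).
#'
#' @param path Path to a FASTA file, plain text or gzip-compressed.
#' @return A data frame with columns `id`, `description`, `sequence`,
#'   `length`, one row per FASTA entry in file order.
#' @seealso [write_fasta()], [sanitize_sequence()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  is_header <- startsWith(lines, ">")
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!is_header[first_content]) {
    stop("line ", first_content, ": sequence data before any '>' header in ",
         path, call. = FALSE)
  }
  hdr_idx <- which(is_header)
  headers <- sub("^>", "", lines[hdr_idx])
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    bad <- hdr_idx[which(!nzchar(ids))[1]]
    stop("line ", bad, ": FASTA header with empty id in ", path, call. = FALSE)
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    bad <- which(dup)[1]
    stop("line ", hdr_idx[bad], ": duplicate sequence id '", ids[bad],
         "' in ", path, call. = FALSE)
  }
  descriptions <- trimws(sub("^\\S+\\s*", "", headers))
  block <- findInterval(seq_along(lines), hdr_idx)
  seq_lines <- !is_header & nzchar(trimws(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    toupper(paste0(gsub("[ \t]", "", lines[seq_lines & block == i]),
                   collapse = ""))
  }, character(1))
  bad_char <- regexpr(sprintf("[^%s]", .iupac_chars), seqs)
  if (any(bad_char > 0)) {
    i <- which(bad_char > 0)[1]
    stop("record '", ids[i], "': invalid character '",
         substr(seqs[i], bad_char[i], bad_char[i]), "' in sequence",
         call. = FALSE)
  }
  data.frame(id = ids, description = descriptions, sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

# IUPAC nucleotide codes plus gap characters tolerated on input
.iupac_chars <- "ACGTURYSWKMBDHVN.\\-"

#' Write sequence records to a FASTA file
#'
#' @param records A data frame as returned by [read_fasta()] (columns `id`,
#'   `description`, `sequence`).
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param width Line-wrap width for sequence lines (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide sequence
#'
#' @param sequence A single string over the alphabet A, C, G, T.
#' @return The reversed Watson-Crick complement.
#' @examples
#' reverse_complement("ACG")  # "CGT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (grepl("[^ACGT]", sequence)) {
    stop("reverse_complement: sequence contains characters outside {A,C,G,T}",
         call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Split a sequence into unambiguous ACGT segments
#'
#' Assembled contigs and scaffolds routinely contain N runs and other IUPAC
#' ambiguity codes. Word counting must never produce words that span an
#' ambiguous position, so the sequence is split at every non-ACGT character
#' and the maximal ACGT runs are returned in order. An all-ambiguous input
#' yields an empty character vector.
#'
#' @param raw A nucleotide string (IUPAC codes and gaps allowed).
#' @return Character vector of ACGT segments, possibly empty.
#' @export
sanitize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1)
  segs <- strsplit(toupper(raw), "[^ACGT]+")[[1]]
  segs[nzchar(segs)]
}
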