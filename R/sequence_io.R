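## Sequence records, FASTA/FASTQ I/O and elementary sequence operations.
##
## Internally all sequences live on the DNA alphabet {A,C,G,T,N}; U is
## accepted on input and converted losslessly (display of mature miRNAs uses
## U, as in miRBase). All input is uppercased on read.

VALID_CHARS <- c("A", "C", "G", "T", "U", "N")

#' Normalise a nucleotide sequence
#'
#' Uppercases and converts between the DNA (T) and RNA (U) views of the same
#' sequence. Conversion is lossless; any character outside `A,C,G,T,U,N`
#' raises an error naming the character and its position.
#'
#' @param x character vector of sequences.
#' @param to `"dna"` (default) or `"rna"`.
#' @return character vector of normalised sequences.
#' @export
#' @examples
#' norm_seq("acgu")          # "ACGT"
#' norm_seq("ACGT", "rna")   # "ACGU"
norm_seq <- function(x, to = c("dna", "rna")) {
  to <- match.arg(to)
  x <- toupper(x)
  bad <- grepl("[^ACGTUN]", x)
  if (any(bad)) {
    i <- which(bad)[1L]
    m <- regexpr("[^ACGTUN]", x[i])
    stop(sprintf("invalid character '%s' at position %d of sequence %d",
                 substr(x[i], m, m), as.integer(m), i))
  }
  if (to == "dna") chartr("U", "T", x) else chartr("T", "U", x)
}

#' Read a FASTA file
#'
#' @param path path to a (possibly multi-line) FASTA file.
#' @return a data.frame with columns `id`, `sequence` (uppercased, DNA
#'   alphabet) and `desc` (text after the first whitespace in the header,
#'   `NA` if absent). Record order is preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  seqs <- as.character(ss)
  id <- sub("\\s.*$", "", ids)
  desc <- ifelse(grepl("\\s", ids), sub("^\\S+\\s+", "", ids), NA_character_)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ", id[which(empty)[1L]])
  }
  data.frame(id = id, sequence = norm_seq(unname(seqs)), desc = desc,
             stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `desc`, as returned by [read_fasta()].
#' @param path output path.
#' @param rna write sequences on the RNA alphabet (U) instead of DNA.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, rna = FALSE, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  seqs <- norm_seq(records$sequence, if (rna) "rna" else "dna")
  nm <- records$id
  if (!is.null(records$desc)) {
    has <- !is.na(records$desc) & nzchar(records$desc)
    nm[has] <- paste(nm[has], records$desc[has])
  }
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records with Sanger/Phred+33 qualities.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `sequence` (uppercased DNA) and
#'   `quality`; sequence and quality lengths are equal per record.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- tryCatch({
    ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    list(ss = ss, qual = as.character(S4Vectors::mcols(ss)$qualities))
  }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  ss <- parsed$ss
  qual <- parsed$qual
  out <- data.frame(id = sub("\\s.*$", "", names(ss)),
                    sequence = toupper(unname(as.character(ss))),
                    quality = unname(qual), stringsAsFactors = FALSE)
  n_q <- nchar(out$quality, type = "bytes", allowNA = TRUE)
  bad <- is.na(n_q) | nchar(out$sequence, type = "bytes") != n_q
  if (any(bad)) {
    stop("malformed FASTQ: record ", which(bad)[1L],
         " has a sequence/quality length mismatch")
  }
  out
}

#' Write a FASTQ file
#'
#' @param records data.frame with columns `id`, `sequence` and `quality` (if
#'   `quality` is missing a constant "I" string is used).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  seqs <- norm_seq(records$sequence)
  qual <- records$quality
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  if (any(nchar(qual) != nchar(seqs))) {
    stop("FASTQ record ", which(nchar(qual) != nchar(seqs))[1L],
         " has sequence/quality length mismatch")
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Reverse complement
#'
#' Vectorised reverse complement on the DNA/RNA alphabet. `N` maps to `N`;
#' applying twice returns the input. RNA input (containing U) returns RNA.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  is_rna <- grepl("U", toupper(x), fixed = TRUE)
  d <- norm_seq(x)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(d)))
  rc <- unname(rc)
  rc[is_rna] <- chartr("T", "U", rc[is_rna])
  rc
}

#' GC percentage
#'
#' Percentage of G+C over the non-N length of each sequence (N is excluded
#' from both numerator and denominator).
#'
#' @param x character vector of non-empty sequences.
#' @return numeric vector of percentages in `[0, 100]`.
#' @export
#' @examples
#' gc_percent("GGCC")  # 100
#' gc_percent("AUAU")  # 0
gc_percent <- function(x) {
  s <- norm_seq(x)
  if (any(!nzchar(s))) stop("empty sequence")
  gc <- nchar(gsub("[^GC]", "", s))
  len <- nchar(gsub("N", "", s, fixed = TRUE))
  if (any(len == 0L)) stop("sequence with no non-N characters")
  100 * gc / len
}

## round half away from zero (display rounding used for MFEI tables)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
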