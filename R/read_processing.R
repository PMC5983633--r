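## sRNA read filtering, adapter trimming, collapsing and length statistics.
##
## The filter rules are the study's printed ones: inserts of 10-30 nt, no
## single-nucleotide run longer than 10 nt, at most 10% N, no 5' adapter
## contamination, and a 3' adapter must be present on (and is trimmed from)
## every read. Rejection reasons are tallied under the first failing rule in
## a fixed order so tallies are reproducible.

#' Filtering parameters for sRNA reads
#'
#' @param adapter3 3' adapter sequence (must be present on every insert).
#' @param adapter5 5' adapter sequence (reads beginning with it are rejected
#'   as contaminants); `""` disables the check.
#' @param min_len,max_len insert length bounds in nt (defaults 10 and 30).
#' @param max_homopolymer longest allowed single-nucleotide run (default 10;
#'   runs strictly longer are rejected).
#' @param max_n_fraction maximum N fraction (default 0.10, strict).
#' @param min_adapter_overlap minimum adapter prefix length that counts as an
#'   adapter match (default 8 nt, exact matching).
#' @param min_mean_quality optional mean Phred quality threshold applied to
#'   raw reads before trimming; `NA` (default) disables quality filtering.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                          adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                          min_len = 10L, max_len = 30L,
                          max_homopolymer = 10L, max_n_fraction = 0.10,
                          min_adapter_overlap = 8L,
                          min_mean_quality = NA_real_) {
  stopifnot(min_len <= max_len, max_n_fraction >= 0, max_n_fraction <= 1,
            max_homopolymer >= 1)
  if (nzchar(adapter3) && nchar(adapter3) < min_adapter_overlap) {
    stop("adapter3 is shorter than min_adapter_overlap")
  }
  structure(list(adapter3 = norm_seq(adapter3),
                 adapter5 = if (nzchar(adapter5)) norm_seq(adapter5) else "",
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_homopolymer = as.integer(max_homopolymer),
                 max_n_fraction = max_n_fraction,
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 min_mean_quality = min_mean_quality),
            class = "filter_params")
}

#' Trim the 3' adapter from raw reads
#'
#' The insert is the subsequence 5' of the first occurrence of an `adapter3`
#' prefix of length >= `min_adapter_overlap` (exact match). Reads without
#' such an occurrence are rejected with reason `no_adapter`.
#'
#' @param reads character vector of raw read sequences.
#' @param params a [filter_params()] object with non-empty `adapter3`.
#' @return list with `insert` (character vector, `NA` where rejected) and
#'   `n_no_adapter` (count of rejected reads).
#' @export
trim_adapter3 <- function(reads, params) {
  stopifnot(inherits(params, "filter_params"))
  if (!nzchar(params$adapter3)) stop("adapter3 is empty")
  key <- substr(params$adapter3, 1L, params$min_adapter_overlap)
  reads <- toupper(reads)
  pos <- regexpr(key, reads, fixed = TRUE)
  insert <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), NA_character_)
  list(insert = insert, n_no_adapter = sum(pos < 0L))
}

#' Apply the sRNA insert filters
#'
#' Keeps adapter-trimmed inserts that satisfy all rules; every rejected read
#' is tallied under exactly one reason, the first failing rule in the fixed
#' order length -> adapter5 contaminant -> homopolymer -> N fraction.
#'
#' @param inserts character vector of adapter-trimmed inserts.
#' @param params a [filter_params()] object.
#' @return list with `kept` (character vector) and `tally` (named integer
#'   vector over reasons `length`, `adapter5`, `homopolymer`, `n_fraction`).
#' @export
filter_reads <- function(inserts, params) {
  stopifnot(inherits(params, "filter_params"))
  reasons <- c("length", "adapter5", "homopolymer", "n_fraction")
  if (length(inserts) == 0L) {
    return(list(kept = character(0),
                tally = setNames(integer(4), reasons)))
  }
  x <- toupper(inserts)
  len <- nchar(x)
  bad_len <- len < params$min_len | len > params$max_len
  bad_a5 <- if (nzchar(params$adapter5)) {
    startsWith(x, substr(params$adapter5, 1L, params$min_adapter_overlap))
  } else rep(FALSE, length(x))
  homopat <- sprintf("([ACGTN])\\1{%d,}", params$max_homopolymer)
  bad_homo <- grepl(homopat, x, perl = TRUE)
  n_count <- nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))
  bad_n <- n_count / pmax(len, 1L) > params$max_n_fraction
  reason <- rep(NA_character_, length(x))
  reason[bad_n] <- "n_fraction"
  reason[bad_homo] <- "homopolymer"
  reason[bad_a5] <- "adapter5"
  reason[bad_len] <- "length"
  tally <- setNames(tabulate(factor(reason, levels = reasons), nbins = 4L),
                    reasons)
  list(kept = x[is.na(reason)], tally = tally)
}

#' Collapse reads to unique sequences with counts
#'
#' @param reads either a character vector of clean reads (one library) or a
#'   named list of such vectors (one element per library).
#' @return a data.frame sorted lexicographically (C locale) by `sequence`;
#'   for a single library it has columns `sequence` and `count`, for a list
#'   one count column per library plus `total`.
#' @export
collapse_unique <- function(reads) {
  if (is.character(reads)) {
    if (length(reads) == 0L) {
      return(data.frame(sequence = character(0), count = integer(0)))
    }
    dt <- data.table(sequence = reads)[, .(count = .N), by = sequence]
    setkey(dt, sequence)
    return(as.data.frame(dt))
  }
  stopifnot(is.list(reads), !is.null(names(reads)))
  per <- lapply(names(reads), function(lib) {
    d <- as.data.table(collapse_unique(reads[[lib]]))
    if (nrow(d)) d[, library_id := lib]
    d
  })
  dt <- rbindlist(per[vapply(per, nrow, 1L) > 0L])
  if (is.null(dt) || nrow(dt) == 0L) {
    out <- data.frame(sequence = character(0))
    out[names(reads)] <- lapply(names(reads), function(x) integer(0))
    out$total <- integer(0)
    return(out)
  }
  wide <- data.table::dcast(dt, sequence ~ library_id, value.var = "count",
                            fill = 0L)
  missing <- setdiff(names(reads), names(wide))
  for (m in missing) wide[, (m) := 0L]
  data.table::setcolorder(wide, c("sequence", names(reads)))
  wide[, total := rowSums(.SD), .SDcols = names(reads)]
  setkey(wide, sequence)
  as.data.frame(wide)
}

#' Read-length distribution
#'
#' Histogram of read lengths over `lengths`, both count-weighted (total) and
#' over distinct sequences (unique).
#'
#' @param sequences character vector of distinct sequences.
#' @param counts integer vector of per-sequence read counts (default 1 each,
#'   i.e. `sequences` are individual reads).
#' @param lengths integer range of lengths to tabulate (default 10:30).
#' @return data.frame with columns `length`, `total`, `unique`.
#' @export
size_distribution <- function(sequences, counts = NULL, lengths = 10:30) {
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  stopifnot(length(counts) == length(sequences))
  len <- nchar(sequences)
  if (length(len) && (min(len) < min(lengths) || max(len) > max(lengths))) {
    stop("read length outside the tabulated range")
  }
  f <- factor(len, levels = lengths)
  total <- tapply(as.numeric(counts), f, sum, default = 0)
  data.frame(length = as.integer(lengths),
             total = as.numeric(total),
             unique = as.integer(table(f)))
}

#' Per-library sequencing statistics
#'
#' Assembles the per-library read-accounting row (raw, clean, length
#' filtered, mapped, and the corresponding unique-sequence counts), checking
#' the containment invariants.
#'
#' @param raw_reads,clean_reads,length_filtered_reads,mapped_reads totals
#'   (reads weighted by count).
#' @param length_filtered_unique,mapped_unique distinct-sequence counts.
#' @return an object of class `library_stats` (a one-row data.frame with a
#'   `clean_pct` column).
#' @export
library_stats <- function(raw_reads, clean_reads, length_filtered_reads,
                          mapped_reads, length_filtered_unique, mapped_unique) {
  stopifnot(clean_reads <= raw_reads,
            length_filtered_reads <= clean_reads,
            mapped_reads <= length_filtered_reads,
            length_filtered_unique <= length_filtered_reads,
            mapped_unique <= length_filtered_unique)
  out <- data.frame(raw_reads = raw_reads, clean_reads = clean_reads,
                    clean_pct = 100 * clean_reads / max(raw_reads, 1),
                    length_filtered_reads = length_filtered_reads,
                    mapped_reads = mapped_reads,
                    length_filtered_unique = length_filtered_unique,
                    mapped_unique = mapped_unique)
  class(out) <- c("library_stats", class(out))
  out
}

#' Format library statistics as a deep-sequencing summary table
#'
#' @param stats named list of `library_stats` (one per library).
#' @return data.frame with the conventional column names (`Sample`,
#'   `Raw Data`, `Clean Reads`, `Length Filtered Reads`, `Mapped Reads`,
#'   `Length Filtered Unique Reads`, `Mapped Unique Reads`).
#' @export
format_stats_table <- function(stats) {
  rows <- lapply(names(stats), function(s) {
    st <- stats[[s]]
    data.frame(Sample = s,
               `Raw Data` = st$raw_reads,
               `Clean Reads` = sprintf("%d (%.2f%%)", st$clean_reads, st$clean_pct),
               `Length Filtered Reads` = st$length_filtered_reads,
               `Mapped Reads` = st$mapped_reads,
               `Length Filtered Unique Reads` = st$length_filtered_unique,
               `Mapped Unique Reads` = st$mapped_unique,
               check.names = FALSE)
  })
  do.call(rbind, rows)
}
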