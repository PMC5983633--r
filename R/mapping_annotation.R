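## Exact (zero-mismatch) genome mapping and read annotation.
##
## Mapping is a seed-hash lookup (fixed-length seed, default 10 nt = the
## minimum read length) followed by full-length verification against the
## stored scaffold sequence, on both strands. This is exactly the set of
## zero-mismatch occurrences, verifiable against a brute-force scan.
## Coordinates are 0-based half-open internally; GFF3 export is 1-based.

#' Build an exact-match genome index
#'
#' @param genome data.frame with columns `id` and `sequence` (as from
#'   [read_fasta()]) or a named character vector of scaffold sequences.
#' @param seed_len seed length in nt; must not exceed the minimum query
#'   length (default 10).
#' @return object of class `genome_index`.
#' @export
build_index <- function(genome, seed_len = 10L) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  if (length(genome) == 0L || all(!nzchar(genome))) stop("empty genome")
  genome <- norm_seq(genome)
  seed_len <- as.integer(seed_len)
  seeds <- lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    L <- nchar(s)
    if (L < seed_len) return(NULL)
    p <- seq_len(L - seed_len + 1L)
    data.table(seed = substring(s, p, p + seed_len - 1L),
               chrom = ch, pos0 = p - 1L)
  })
  dt <- rbindlist(seeds)
  setkey(dt, seed)
  structure(list(sequences = genome, seed_len = seed_len, seeds = dt),
            class = "genome_index")
}

#' Map reads to the genome with zero mismatches
#'
#' Reports all and only exact occurrences of each read on both strands
#' (minus-strand hits are occurrences of the reverse complement). A read is
#' "mapped" iff it has at least one hit.
#'
#' @param reads character vector of reads (each at least `seed_len` long).
#' @param index a [build_index()] object.
#' @return data.frame with columns `read`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`, sorted by `(read, chrom, start, strand)`.
#' @export
map_exact <- function(reads, index) {
  stopifnot(inherits(index, "genome_index"))
  reads <- norm_seq(reads)
  if (any(nchar(reads) < index$seed_len)) {
    stop("read shorter than the index seed length")
  }
  hit_strand <- function(qseq, strand) {
    dt <- data.table(read = reads, qseq = qseq, len = nchar(qseq),
                     seed = substr(qseq, 1L, index$seed_len))
    hits <- index$seeds[dt, on = "seed", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) return(NULL)
    g <- index$sequences[hits$chrom]
    full <- substring(g, hits$pos0 + 1L, hits$pos0 + hits$len)
    hits <- hits[full == hits$qseq]
    if (nrow(hits) == 0L) return(NULL)
    hits[, .(read, chrom, start = pos0, end = pos0 + len, strand = strand)]
  }
  plus <- hit_strand(reads, "+")
  minus <- hit_strand(reverse_complement(reads), "-")
  out <- rbindlist(list(plus, minus))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(read = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  setorder(out, read, chrom, start, strand)
  as.data.frame(out)
}

#' Annotate reads as known miRNAs
#'
#' A read is a known-miRNA hit iff it is identical to a reference mature
#' sequence and that mature is a forward substring of its corresponding
#' hairpin. Correspondence is by identifier: the hairpin whose id equals the
#' mature id after stripping a trailing `-5p`/`-3p` arm suffix
#' (case-insensitive, `miR`/`MIR` folded).
#'
#' @param reads character vector of (distinct) read sequences.
#' @param mature_ref,hairpin_ref data.frames with `id` and `sequence`
#'   columns (miRBase-style, RNA or DNA alphabet).
#' @return data.frame with columns `read`, `mature_id`, `family` for hits
#'   (zero rows if none).
#' @export
annotate_known <- function(reads, mature_ref, hairpin_ref) {
  stopifnot(nrow(mature_ref) > 0L, nrow(hairpin_ref) > 0L)
  mat <- data.table(mature_id = mature_ref$id,
                    mseq = norm_seq(mature_ref$sequence))
  hp_key <- toupper(sub("-[35]p$", "", hairpin_ref$id, ignore.case = TRUE))
  hp_seq <- setNames(norm_seq(hairpin_ref$sequence), hp_key)
  mat_key <- toupper(sub("-[35]p$", "", mat$mature_id, ignore.case = TRUE))
  missing <- !(mat_key %in% hp_key)
  if (any(missing)) {
    stop("mature id without corresponding hairpin record: ",
         mat$mature_id[which(missing)[1L]])
  }
  contained <- mapply(function(m, k) {
    any(vapply(which(hp_key == k),
               function(i) grepl(m, hp_seq[[i]], fixed = TRUE), logical(1)))
  }, mat$mseq, mat_key)
  mat <- mat[contained]
  dt <- data.table(read = norm_seq(reads))
  hits <- mat[dt, on = c(mseq = "read"), nomatch = NULL]
  if (nrow(hits) == 0L) {
    return(data.frame(read = character(0), mature_id = character(0),
                      family = character(0)))
  }
  data.frame(read = hits$mseq, mature_id = hits$mature_id,
             family = mirna_family(hits$mature_id), stringsAsFactors = FALSE)
}

#' miRNA family from a miRBase-style identifier
#'
#' Drops the species prefix and any arm/variant suffix, e.g.
#' `peu-miR394a-5p` -> `miR394`, `peu-miR-n68` -> `miR-n68`.
#'
#' @param id character vector of identifiers.
#' @return character vector of family names.
#' @export
mirna_family <- function(id) {
  x <- sub("^[A-Za-z]{3,4}-", "", id)
  x <- sub("-[35]p$", "", x)
  m <- regexpr("^(miR-n[0-9]+|miR[0-9]+)", x, ignore.case = TRUE)
  ifelse(m > 0L, substr(x, 1L, attr(m, "match.length")), x)
}

#' Classify reads into annotation classes
#'
#' Assigns exactly one class per read: the first matching class in the fixed
#' hierarchy `known_miRNA` -> the supplied reference classes (in order) ->
#' `novel_candidate`; unmapped reads are `other`. A read matches a reference
#' class iff it is an exact substring of any sequence in that class's set.
#'
#' @param reads character vector of distinct read sequences.
#' @param mapped logical vector: does the read map to the genome.
#' @param known_hits data.frame from [annotate_known()].
#' @param class_refs named list of data.frames (`id`, `sequence`), one per
#'   class, in hierarchy order (e.g. rRNA, tRNA, snRNA, snoRNA, scRNA,
#'   repeat, nat_siRNA, exon, intron). May be empty.
#' @param seed_len seed length used for the substring lookups.
#' @return character vector of class labels, parallel to `reads`.
#' @export
classify_read <- function(reads, mapped, known_hits,
                          class_refs = list(), seed_len = 10L) {
  stopifnot(length(mapped) == length(reads))
  reads <- norm_seq(reads)
  cls <- rep(NA_character_, length(reads))
  cls[!mapped] <- "other"
  is_known <- reads %in% known_hits$read
  cls[is.na(cls) & is_known] <- "known_miRNA"
  for (nm in names(class_refs)) {
    todo <- which(is.na(cls))
    if (length(todo) == 0L) break
    ref <- class_refs[[nm]]
    if (is.null(ref) || nrow(ref) == 0L) next
    idx <- build_index(ref, seed_len = seed_len)
    ok <- nchar(reads[todo]) >= seed_len
    hit <- rep(FALSE, length(todo))
    if (any(ok)) {
      found <- map_exact(reads[todo][ok], idx)
      hit[ok] <- reads[todo][ok] %in% found$read[found$strand == "+"]
    }
    cls[todo[hit]] <- nm
  }
  cls[is.na(cls)] <- "novel_candidate"
  cls
}

#' Library mapping statistics from collapsed reads
#'
#' Totals weight each unique sequence by its per-library count; unique
#' columns count distinct sequences.
#'
#' @param sequences character vector of distinct clean sequences.
#' @param counts integer vector of per-library counts for `sequences`.
#' @param mapped logical vector: does each sequence map to the genome.
#' @return list with `mapped_reads`, `mapped_unique`,
#'   `length_filtered_reads`, `length_filtered_unique`.
#' @export
mapping_stats <- function(sequences, counts, mapped) {
  stopifnot(length(sequences) == length(counts),
            length(sequences) == length(mapped))
  present <- counts > 0L
  list(length_filtered_reads = sum(as.numeric(counts)),
       length_filtered_unique = sum(present),
       mapped_reads = sum(as.numeric(counts)[mapped]),
       mapped_unique = sum(present & mapped))
}

#' Export alignments as GFF3
#'
#' Converts internal 0-based half-open alignments to 1-based inclusive GFF3.
#'
#' @param alignments data.frame as returned by [map_exact()], optionally
#'   with a `name` column used for the `ID` attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(alignments)) {
    nm <- if (!is.null(alignments$name)) alignments$name else alignments$read
    lines <- sprintf("%s\tmirstalk\tmatch\t%d\t%d\t.\t%s\t.\tID=%s",
                     alignments$chrom, alignments$start + 1L,
                     alignments$end, alignments$strand, nm)
    writeLines(lines, con)
  }
  invisible(path)
}
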