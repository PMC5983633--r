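## miRNA target prediction by complementarity penalty scoring and degradome
## (PARE) cleavage-site profiling with the five-category classification.
##
## The alignment is antiparallel and ungapped: miRNA position i (1 = 5' end)
## pairs with site position |site| - i + 1. Watson-Crick pairs cost 0, G:U
## wobbles and other mismatches cost 0.5 each, doubled when the miRNA
## position lies in the 5' core (positions 2-13). Sites scoring at most 4
## points pass the screen.

#' Penalty-scoring parameters
#'
#' @param gu_penalty penalty for a G:U wobble (default 0.5).
#' @param mismatch_penalty penalty for any other mismatch (default 0.5).
#' @param core_range miRNA positions whose penalties are multiplied
#'   (default `c(2, 13)`, 1 = 5' end).
#' @param core_multiplier multiplier inside the core (default 2).
#' @param score_cutoff maximal admissible total score (default 4,
#'   inclusive).
#' @return object of class `penalty_params`.
#' @export
penalty_params <- function(gu_penalty = 0.5, mismatch_penalty = 0.5,
                           core_range = c(2L, 13L), core_multiplier = 2,
                           score_cutoff = 4) {
  stopifnot(gu_penalty >= 0, mismatch_penalty >= 0,
            length(core_range) == 2L, core_range[1L] <= core_range[2L])
  structure(list(gu_penalty = gu_penalty,
                 mismatch_penalty = mismatch_penalty,
                 core_range = as.integer(core_range),
                 core_multiplier = core_multiplier,
                 score_cutoff = score_cutoff),
            class = "penalty_params")
}

## per-position pair class for miRNA char vs (already reversed) site char:
## "|" Watson-Crick, "o" G:U wobble, "x" mismatch
pair_class <- function(mi, si) {
  wc <- (mi == "A" & si == "T") | (mi == "T" & si == "A") |
    (mi == "G" & si == "C") | (mi == "C" & si == "G")
  gu <- (mi == "G" & si == "T") | (mi == "T" & si == "G")
  ifelse(wc, "|", ifelse(gu, "o", "x"))
}

#' Score a miRNA:target duplex
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param site target-site sequence 5'->3', same length as `mirna`.
#' @param params a [penalty_params()] object.
#' @return list of class `target_site` with `pairing` (string of `|`, `o`,
#'   `x` along miRNA positions 1..L), `penalties` (per miRNA position),
#'   `score`, `accepted`.
#' @export
score_duplex <- function(mirna, site, params = penalty_params()) {
  m <- strsplit(norm_seq(mirna), "")[[1]]
  s <- strsplit(norm_seq(site), "")[[1]]
  if (length(m) != length(s)) stop("miRNA and site lengths differ")
  s_rev <- rev(s)  # miRNA position i faces site position L - i + 1
  cls <- pair_class(m, s_rev)
  pen <- ifelse(cls == "|", 0,
                ifelse(cls == "o", params$gu_penalty,
                       params$mismatch_penalty))
  pos <- seq_along(m)
  core <- pos >= params$core_range[1L] & pos <= params$core_range[2L]
  pen[core] <- pen[core] * params$core_multiplier
  score <- sum(pen)
  structure(list(pairing = paste(cls, collapse = ""), penalties = pen,
                 score = score, accepted = score <= params$score_cutoff),
            class = "target_site")
}

#' Scan a transcript for miRNA target sites
#'
#' Scores every window of width `|mirna|` along the transcript and returns
#' the accepted sites (score <= cutoff) sorted by `(score, position)`.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcript transcript sequence 5'->3'.
#' @param params a [penalty_params()] object.
#' @return data.frame with columns `start` (0-based window start on the
#'   transcript), `end` (half-open), `score`, `pairing`; zero rows (with a
#'   warning) when the transcript is shorter than the miRNA.
#' @export
scan_transcript <- function(mirna, transcript, params = penalty_params()) {
  m <- strsplit(norm_seq(mirna), "")[[1]]
  tc <- strsplit(norm_seq(transcript), "")[[1]]
  L <- length(m)
  n_win <- length(tc) - L + 1L
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), pairing = character(0))
  if (n_win < 1L) {
    warning("transcript shorter than miRNA")
    return(empty)
  }
  pos <- seq_len(L)
  core <- pos >= params$core_range[1L] & pos <= params$core_range[2L]
  mult <- ifelse(core, params$core_multiplier, 1)
  scores <- numeric(n_win)
  w0 <- seq_len(n_win) - 1L
  for (i in pos) {
    si <- tc[w0 + (L - i) + 1L]   # site position L - i + 1 within window
    cls <- pair_class(m[i], si)
    pen <- ifelse(cls == "|", 0,
                  ifelse(cls == "o", params$gu_penalty,
                         params$mismatch_penalty)) * mult[i]
    scores <- scores + pen
  }
  hit <- which(scores <= params$score_cutoff)
  if (!length(hit)) return(empty)
  site_seq <- substring(paste(tc, collapse = ""), hit, hit + L - 1L)
  pairing <- vapply(site_seq,
                    function(ss) score_duplex(mirna, ss, params)$pairing,
                    character(1), USE.NAMES = FALSE)
  out <- data.frame(start = hit - 1L, end = hit - 1L + L,
                    score = scores[hit], pairing = pairing)
  out[order(out$score, out$start), , drop = FALSE]
}

#' Map degradome reads onto transcripts
#'
#' Each read's 5' end marks the 5' terminus of a cleavage product: exact
#' matches of the read prefix (default 20 nt, tolerating 3' quality decay)
#' increment a per-position 5'-end counter at the match start. Reads hitting
#' several transcripts increment each hit.
#'
#' @param reads character vector of adapter-trimmed degradome reads.
#' @param transcripts data.frame (`id`, `sequence`) or named character
#'   vector of transcript sequences.
#' @param prefix_len prefix length matched exactly (default 20 nt); shorter
#'   reads are matched full-length.
#' @return object of class `degradome_profile`: list with `counts` (a
#'   data.frame `transcript`, `pos` (0-based), `count`) and `total` (sum of
#'   all 5'-end counts).
#' @export
map_degradome <- function(reads, transcripts, prefix_len = 20L) {
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  }
  transcripts <- norm_seq(transcripts)
  empty <- structure(list(
    counts = data.frame(transcript = character(0), pos = integer(0),
                        count = integer(0)),
    total = 0), class = "degradome_profile")
  if (length(reads) == 0L) return(empty)
  reads <- norm_seq(reads)
  prefix <- substr(reads, 1L, prefix_len)
  idx <- rbindlist(lapply(names(transcripts), function(id) {
    s <- transcripts[[id]]
    ks <- sort(unique(nchar(prefix)))
    rbindlist(lapply(ks, function(k) {
      if (nchar(s) < k) return(NULL)
      p <- seq_len(nchar(s) - k + 1L)
      data.table(prefix = substring(s, p, p + k - 1L), transcript = id,
                 pos = p - 1L)
    }))
  }))
  q <- data.table(prefix = prefix)[, .(count = .N), by = prefix]
  hits <- idx[q, on = "prefix", nomatch = NULL]
  if (nrow(hits) == 0L) return(empty)
  prof <- hits[, .(count = sum(count)), by = .(transcript, pos)]
  setorder(prof, transcript, pos)
  structure(list(counts = as.data.frame(prof),
                 total = sum(prof$count)),
            class = "degradome_profile")
}

#' Expected cleavage position of a target site
#'
#' The transcript coordinate pairing with miRNA position 10 (the 5' end of
#' the 3' cleavage fragment) under the antiparallel convention:
#' `window_start + (|mirna| - 10)`.
#'
#' @param window_start 0-based start of the site window on the transcript.
#' @param mirna_len miRNA length in nt.
#' @return 0-based transcript position.
#' @export
#' @examples
#' cleavage_position(100, 21)  # 111
cleavage_position <- function(window_start, mirna_len) {
  window_start + (mirna_len - 10L)
}

#' Categorise a cleavage site from a degradome 5'-end profile
#'
#' Evaluated in declared precedence on the per-position 5'-end counts of one
#' transcript: count 1 at the site -> category 5 (single match); unique
#' maximum -> 1; tied maximum -> 2; >= median -> 3; otherwise -> 4. The
#' median is computed over positions with at least one read. A site with no
#' reads is an error (no cleavage evidence).
#'
#' @param profile either a `degradome_profile` or a data.frame
#'   (`transcript`, `pos`, `count`).
#' @param transcript transcript id.
#' @param pos 0-based transcript position of the putative cleavage site.
#' @return integer category in 1..5.
#' @export
categorize <- function(profile, transcript, pos) {
  counts <- if (inherits(profile, "degradome_profile")) profile$counts
            else profile
  tr <- counts[counts$transcript == transcript & counts$count >= 1L, ,
               drop = FALSE]
  if (nrow(tr) == 0L) stop("no degradome reads on transcript ", transcript)
  at <- tr$count[tr$pos == pos]
  if (length(at) == 0L || at == 0L) {
    stop("no cleavage evidence at position ", pos, " of ", transcript)
  }
  if (at == 1L) return(5L)
  mx <- max(tr$count)
  if (at == mx) {
    if (sum(tr$count == mx) == 1L) return(1L) else return(2L)
  }
  med <- median(tr$count)
  if (at >= med) 3L else 4L
}

#' Verify predicted target sites against a degradome profile
#'
#' For each accepted site, looks up the degradome 5'-end count at the
#' expected cleavage position and, when evidence exists, assigns the
#' cleavage category.
#'
#' @param sites data.frame of accepted sites with columns `mirna_id`,
#'   `transcript`, `start`, `end`, `score` (as produced by scanning).
#' @param profile a `degradome_profile` from [map_degradome()].
#' @return `sites` with added columns `cleavage_pos`, `cleavage_count`,
#'   `category` (`NA` where no degradome evidence).
#' @export
call_cleavage <- function(sites, profile) {
  if (nrow(sites) == 0L) {
    sites$cleavage_pos <- integer(0)
    sites$cleavage_count <- integer(0)
    sites$category <- integer(0)
    return(sites)
  }
  cp <- cleavage_position(sites$start, sites$end - sites$start)
  cnt <- integer(nrow(sites))
  cat <- rep(NA_integer_, nrow(sites))
  pc <- profile$counts
  key <- paste(pc$transcript, pc$pos)
  lut <- setNames(pc$count, key)
  cnt <- unname(lut[paste(sites$transcript, cp)])
  cnt[is.na(cnt)] <- 0L
  for (i in which(cnt > 0L)) {
    cat[i] <- categorize(profile, sites$transcript[i], cp[i])
  }
  sites$cleavage_pos <- cp
  sites$cleavage_count <- as.integer(cnt)
  sites$category <- cat
  sites
}
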