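## Novel miRNA discovery: precursor excision, secondary-structure folding,
## stability metrics (MFE, MFEI), miRNA/miRNA* duplex geometry and the two
## acceptance rules (star-supported, or detected in multiple independent
## libraries when no star is read-covered).
##
## Folding is a deterministic maximum-weighted base-pairing dynamic program
## (GC = 3, AU = 2, GU = 1; minimum hairpin loop 3 nt). The DP score is a
## pseudo-energy, -(total pair weight); a thermodynamic MFE in kcal/mol can
## be supplied externally wherever MFEI is computed.

PAIR_WEIGHTS <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)

pair_weight <- function(a, b) {
  w <- PAIR_WEIGHTS[paste0(a, b)]
  ifelse(is.na(w), 0, w)
}

#' Fold an RNA sequence by maximum-weighted base pairing
#'
#' Nussinov-style dynamic program maximising total pair weight (GC = 3,
#' AU = 2, GU wobble = 1) with a minimum hairpin loop of `min_loop` nt and a
#' deterministic traceback (pairing is preferred, then leaving the 5' end
#' unpaired, then the 3' end, then the leftmost bifurcation).
#'
#' @param sequence nucleotide string (DNA or RNA alphabet).
#' @param min_loop minimum number of unpaired nt in a hairpin loop.
#' @return list with `structure` (dot-bracket), `score` (pseudo-energy,
#'   `-total_weight`), `weight` (total pair weight) and `pairs` (integer
#'   partner vector, `NA` where unpaired).
#' @export
#' @examples
#' fold_rna("GGGAAACCC")$structure  # "(((...)))"
fold_rna <- function(sequence, min_loop = 3L) {
  s <- strsplit(norm_seq(sequence), "")[[1]]
  n <- length(s)
  if (n < min_loop + 2L) stop("sequence too short to fold")
  W <- matrix(0, n, n)
  for (i in 1:(n - 1L)) {
    js <- (i + 1L):n
    W[i, js] <- pair_weight(s[i], s[js])
  }
  M <- matrix(0, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- max(M[i + 1L, j], M[i, j - 1L])
      if (W[i, j] > 0) best <- max(best, W[i, j] + M[i + 1L, j - 1L])
      ks <- (i + 1L):(j - 2L)
      if (length(ks)) {
        best <- max(best, max(M[i, ks] + M[ks + 1L, j]))
      }
      M[i, j] <- best
    }
  }
  pairs <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i <= min_loop) next
    m <- M[i, j]
    if (m == 0) next
    if (W[i, j] > 0 && m == W[i, j] + M[i + 1L, j - 1L]) {
      pairs[i] <- j; pairs[j] <- i
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
    } else if (m == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else if (m == M[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else {
      for (k in (i + 1L):(j - 2L)) {
        if (M[i, k] + M[k + 1L, j] == m) {
          stack[[length(stack) + 1L]] <- c(i, k)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  db <- rep(".", n)
  db[!is.na(pairs) & seq_len(n) < pairs] <- "("
  db[!is.na(pairs) & seq_len(n) > pairs] <- ")"
  list(structure = paste(db, collapse = ""), score = -M[1L, n],
       weight = M[1L, n], pairs = pairs)
}

#' Partner table of a dot-bracket structure
#'
#' @param structure dot-bracket string (balanced brackets).
#' @return integer vector: position of the pairing partner, `NA` if unpaired.
#' @export
dotbracket_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pairs <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure: unclosed bracket")
  pairs
}

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = (|MFE| / LP x 100) / GC%`, the standard hairpin stability index
#' used to separate miRNA precursors from other non-coding RNAs.
#'
#' @param mfe minimal folding free energy in kcal/mol (negative).
#' @param lp precursor length in nt (> 0).
#' @param gc GC percentage (0-100, > 0).
#' @param digits if non-NULL, round half-up to this many decimals (tables
#'   conventionally print 2).
#' @return the MFEI (dimensionless).
#' @export
#' @examples
#' compute_mfei(-26.3, 62, 9.68, digits = 2)   # 4.38
#' compute_mfei(-38.0, 84, 38.10, digits = 2)  # 1.19
compute_mfei <- function(mfe, lp, gc, digits = NULL) {
  if (any(lp <= 0)) stop("precursor length must be positive")
  if (any(gc <= 0)) stop("GC percentage must be positive (division by zero)")
  mfei <- (abs(mfe) / lp * 100) / gc
  if (!is.null(digits)) mfei <- round_half_up(mfei, digits)
  mfei
}

#' Mature miRNA length (LM)
#'
#' @param sequence non-empty nucleotide string.
#' @return integer length in nt.
#' @export
#' @examples
#' mature_length("CUGUUGGUCUCUCUUUGUAA")  # 20
mature_length <- function(sequence) {
  s <- norm_seq(sequence)
  if (any(!nzchar(s))) stop("empty sequence")
  nchar(s)
}

#' First-nucleotide bias of a mature miRNA set
#'
#' @param sequences character vector of mature sequences.
#' @return named numeric vector of fractions over `A`, `C`, `G`, `U`
#'   (summing to 1).
#' @export
first_nt_bias <- function(sequences) {
  if (length(sequences) == 0L) stop("empty sequence set")
  first <- substr(norm_seq(sequences, "rna"), 1L, 1L)
  tab <- table(factor(first, levels = c("A", "C", "G", "U")))
  as.numeric(tab) / length(sequences) -> fr
  setNames(fr, c("A", "C", "G", "U"))
}

#' Check miRNA/miRNA* duplex overhang geometry
#'
#' Under the computed structure, the star interval must equal the pairing
#' partner of the mature interval shifted to leave 2-nt 3' overhangs on both
#' duplex ends: `p(m2 - 2) = s1` and `p(m1) = s2 - 2` (within `tol` nt),
#' where `p` is the partner table and intervals are 1-based inclusive on the
#' precursor. The same two equations hold whether the mature sits on the 5p
#' or the 3p arm.
#'
#' @param structure dot-bracket string of the precursor (or an integer
#'   partner vector as from [dotbracket_pairs()]).
#' @param mature integer `c(start, end)` of the mature on the precursor.
#' @param star integer `c(start, end)` of the putative star.
#' @param tol positional tolerance in nt (default 1).
#' @return logical: does the star satisfy the 2-nt 3'-overhang geometry.
#' @export
check_duplex <- function(structure, mature, star, tol = 1L) {
  p <- if (is.character(structure)) dotbracket_pairs(structure) else structure
  n <- length(p)
  m1 <- mature[1L]; m2 <- mature[2L]
  if (m1 < 1L || m2 > n || m1 >= m2) stop("mature interval not within precursor")
  s1 <- star[1L]; s2 <- star[2L]
  if (max(m1, s1) <= min(m2, s2)) return(FALSE)  # overlapping intervals
  pa <- p[m2 - 2L]; pb <- p[m1]
  if (is.na(pa) || is.na(pb)) return(FALSE)
  abs(pa - s1) <= tol && abs(pb - (s2 - 2L)) <= tol
}

#' Excise precursor candidate windows around a read stack
#'
#' Returns the genomic window `[start - flank, end + flank)` (clipped to the
#' scaffold, with a warning when truncated), strand-resolved, carrying both
#' arm hypotheses: the mature may sit on the 5p or the 3p arm of the folded
#' window.
#'
#' @param alignment list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param genome named character vector (or data.frame) of scaffolds.
#' @param flank flank length in nt on each side (default 70); reduced when
#'   the window would exceed `max_lp`.
#' @param max_lp maximum precursor length in nt (default 292).
#' @return list of two candidates (arms `"5p"`, `"3p"`), each a list with
#'   `sequence`, `chrom`, `start`, `end`, `strand`, `arm`, `mature_start`,
#'   `mature_end` (1-based on the precursor).
#' @export
excise_precursor <- function(alignment, genome, flank = 70L, max_lp = 292L) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  a <- as.list(alignment)
  read_len <- a$end - a$start
  flank <- min(flank, (max_lp - read_len) %/% 2L)
  L <- nchar(genome[[a$chrom]])
  ws <- a$start - flank
  we <- a$end + flank
  if (ws < 0L || we > L) {
    warning("precursor window truncated at scaffold boundary")
    ws <- max(0L, ws); we <- min(L, we)
  }
  seq_fwd <- substr(genome[[a$chrom]], ws + 1L, we)
  seq <- if (a$strand == "-") reverse_complement(seq_fwd) else seq_fwd
  if (a$strand == "+") {
    m1 <- a$start - ws + 1L; m2 <- a$end - ws
  } else {
    m1 <- we - a$end + 1L; m2 <- we - a$start
  }
  lapply(c("5p", "3p"), function(arm) {
    list(sequence = seq, chrom = a$chrom, start = ws, end = we,
         strand = a$strand, arm = arm, mature_start = m1, mature_end = m2)
  })
}

#' Precursor hairpin metrics
#'
#' Folds the candidate and reports the standard precursor columns. When a
#' thermodynamic `mfe` (kcal/mol) is supplied it is used for MFEI; otherwise
#' the folder's pseudo-energy is used and flagged.
#'
#' @param sequence precursor sequence.
#' @param mfe optional thermodynamic MFE (kcal/mol).
#' @return list with `LP`, `GC`, `MFE`, `mfe_is_pseudo`, `MFEI`,
#'   `structure`, `pairs`.
#' @export
precursor_metrics <- function(sequence, mfe = NULL) {
  fold <- fold_rna(sequence)
  lp <- nchar(sequence)
  gc <- gc_percent(sequence)
  pseudo <- is.null(mfe)
  if (pseudo) mfe <- fold$score
  list(LP = lp, GC = gc, MFE = mfe, mfe_is_pseudo = pseudo,
       MFEI = if (gc > 0 && mfe != 0) compute_mfei(mfe, lp, gc) else 0,
       structure = fold$structure, pairs = fold$pairs)
}

#' Apply the novel-miRNA acceptance rules
#'
#' Rule (i): the miRNA and its star are both covered by reads and the duplex
#' shows 2-nt 3' overhangs (`star_supported`). Rule (ii): without read-
#' covered star support the candidate must be detected in at least
#' `min_libraries` distinct libraries (`multi_library`).
#'
#' @param mature_counts named numeric vector of per-library mature read
#'   counts.
#' @param star_count total star read count (0 if none).
#' @param overhang_ok logical from [check_duplex()].
#' @param min_libraries minimum number of distinct libraries for rule (ii)
#'   (default 2).
#' @return list with `accepted` and `rule_fired`
#'   (`star_supported`/`multi_library`/`rejected`) and `libraries_detected`.
#' @export
call_novel <- function(mature_counts, star_count = 0, overhang_ok = FALSE,
                       min_libraries = 2L) {
  libs <- names(mature_counts)[mature_counts > 0]
  star_supported <- star_count > 0 && isTRUE(overhang_ok)
  if (star_supported) {
    list(accepted = TRUE, rule_fired = "star_supported",
         libraries_detected = libs)
  } else if (length(libs) >= min_libraries) {
    list(accepted = TRUE, rule_fired = "multi_library",
         libraries_detected = libs)
  } else {
    list(accepted = FALSE, rule_fired = "rejected",
         libraries_detected = libs)
  }
}

## ---- pipeline-level novel discovery -------------------------------------

## Geometry gate applied before the printed rules: the mature must look like
## a stem arm (>= min_paired_frac of its nt paired, partners forming a
## contiguous interval disjoint from the mature, and at least half of the
## mature in one uninterrupted helix -- random windows pair diffusely and
## fail the helix-run requirement). Returns the predicted star interval:
## from the 2-nt-overhang anchor pairs when both are paired, otherwise from
## the bulk of the partner interval.
candidate_geometry <- function(pairs, m1, m2, min_paired_frac = 0.6,
                               min_helix_frac = 0.5) {
  part <- pairs[m1:m2]
  part <- part[!is.na(part)]
  lm <- m2 - m1 + 1L
  if (length(part) < min_paired_frac * lm) return(NULL)
  lo <- min(part); hi <- max(part)
  if (hi - lo + 1L > lm + 6L) return(NULL)
  if (max(m1, lo) <= min(m2, hi)) return(NULL)
  ## longest uninterrupted helix (consecutive stacked pairs) in the mature
  pm <- pairs[m1:m2]
  stacked <- !is.na(pm[-lm]) & !is.na(pm[-1L]) & pm[-1L] == pm[-lm] - 1L
  run <- rle(stacked)
  best_run <- if (any(run$values)) max(run$lengths[run$values]) + 1L else
    as.integer(any(!is.na(pm)))
  if (best_run < ceiling(min_helix_frac * lm)) return(NULL)
  if (!is.na(pairs[m1]) && !is.na(pairs[m2 - 2L])) {
    c(star_start = pairs[m2 - 2L], star_end = pairs[m1] + 2L)
  } else {
    c(star_start = lo, star_end = min(hi + 2L, length(pairs)))
  }
}

## fast pre-screen before any folding: does `b` contain a k-mer of the
## reverse complement of `a`? (a star arm must, by definition of pairing)
rc_kmer_hit <- function(a, b, k = 11L) {
  ra <- reverse_complement(a)
  n <- nchar(ra)
  if (n < k || nchar(b) < k) return(FALSE)
  p <- seq_len(n - k + 1L)
  kmers <- substring(ra, p, p + k - 1L)
  any(vapply(kmers, grepl, logical(1), x = b, fixed = TRUE,
             USE.NAMES = FALSE))
}

#' Detect candidate read stacks from alignments
#'
#' A stack is a uniquely collapsed read with a genomic alignment whose
#' maximum single-library count reaches `min_stack_count`.
#'
#' @param alignments data.frame from [map_exact()] over distinct sequences.
#' @param counts data.frame with a `sequence` column and one count column
#'   per library (as from [collapse_unique()] on a list).
#' @param libraries character vector of library ids (count column names).
#' @param min_stack_count minimum single-library read count (default 10).
#' @return data.frame of stacks with per-library counts and `total`.
#' @export
detect_stacks <- function(alignments, counts, libraries, min_stack_count = 10L) {
  dt <- as.data.table(alignments)
  cn <- as.data.table(counts)
  dt <- cn[dt, on = c(sequence = "read")]
  mx <- do.call(pmax, as.list(dt[, ..libraries]))
  dt <- dt[mx >= min_stack_count]
  dt[, total := rowSums(.SD), .SDcols = libraries]
  setorder(dt, chrom, start, strand)
  as.data.frame(dt)
}

#' Discover novel miRNAs from read stacks
#'
#' Pairs read stacks on the same scaffold and strand into mature/star duplex
#' candidates (the more abundant stack is the mature), folds the spanned
#' precursor, checks the 2-nt 3'-overhang geometry, and applies the
#' acceptance rules; orphan stacks are folded inside a flanked window and
#' may be accepted by the multi-library rule when their arm geometry holds.
#'
#' @param stacks data.frame from [detect_stacks()], excluding known-miRNA
#'   and other annotated reads.
#' @param genome named character vector (or data.frame) of scaffolds.
#' @param libraries character vector of library ids.
#' @param max_precursor maximum mature..star span in nt (default 292).
#' @param min_gap minimum loop gap between paired stacks (default 3).
#' @param flank window flank for orphan stacks (default 70).
#' @param tol duplex overhang tolerance in nt (default 1).
#' @param min_libraries rule (ii) threshold (default 2).
#' @return data.frame of candidates (accepted and rejected) with location,
#'   arm, sequences, LM/LP/GC/MFE/MFEI, structure, support and rule fired,
#'   plus per-library mature counts.
#' @export
find_novel_mirnas <- function(stacks, genome, libraries,
                              max_precursor = 292L, min_gap = 3L,
                              flank = 70L, tol = 1L, min_libraries = 2L) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  st <- as.data.table(stacks)
  if (nrow(st) == 0L) return(novel_empty(libraries))
  setorder(st, -total, chrom, start)
  st[, idx := .I]
  used <- rep(FALSE, nrow(st))
  out <- list()
  ## first pass: duplex candidates, most abundant stack first; stacks are
  ## consumed only when the paired candidate survives the geometry gate
  for (i in seq_len(nrow(st))) {
    if (used[i]) next
    same <- st[chrom == st$chrom[i] & strand == st$strand[i] & idx != st$idx[i]]
    same <- same[!used[same$idx]]
    if (nrow(same) == 0L) next
    gap_r <- same$start - st$end[i]
    gap_l <- st$start[i] - same$end
    span <- pmax(same$end, st$end[i]) - pmin(same$start, st$start[i])
    ok <- (gap_r >= min_gap | gap_l >= min_gap) & span <= max_precursor
    if (!any(ok)) next
    partner <- same[which(ok)[which.min(span[ok])]]
    ## a genuine star arm must carry reverse-complement sequence of the
    ## mature; skip the fold entirely otherwise
    if (!rc_kmer_hit(st$sequence[i], partner$sequence)) next
    cand <- novel_candidate_call(st[i], partner, genome, libraries,
                                 flank, tol, min_libraries)
    if (!is.null(cand)) {
      used[i] <- TRUE
      used[partner$idx] <- TRUE
      out[[length(out) + 1L]] <- cand
    }
  }
  ## second pass: remaining stacks as orphans (windowed arm search); the
  ## flanked window must contain reverse-complement sequence of the mature
  ## before any fold is attempted
  for (i in which(!used)) {
    L <- nchar(genome[[st$chrom[i]]])
    ws <- max(0L, st$start[i] - flank)
    we <- min(L, st$end[i] + flank)
    wseq <- substr(genome[[st$chrom[i]]], ws + 1L, we)
    if (st$strand[i] == "-") wseq <- reverse_complement(wseq)
    if (!rc_kmer_hit(st$sequence[i], wseq)) next
    out[[length(out) + 1L]] <- novel_candidate_call(
      st[i], NULL, genome, libraries, flank, tol, min_libraries)
  }
  res <- rbindlist(out[!vapply(out, is.null, logical(1))], fill = TRUE)
  if (is.null(res) || nrow(res) == 0L) return(novel_empty(libraries))
  ## passenger-strand deduplication: a duplex is reported once, so drop any
  ## candidate whose mature is the star sequence of another candidate
  stars <- res$star_seq[!is.na(res$star_seq)]
  res <- res[!(mature_seq %chin% stars)]
  if (nrow(res) == 0L) return(novel_empty(libraries))
  ## locus deduplication: overlapping candidate precursors describe one
  ## hairpin (arm fragments, or the quasi-palindromic opposite strand);
  ## keep the most abundant call at each locus, accepted calls first
  tot <- rowSums(as.matrix(res[, ..libraries]))
  res <- res[order(-res$accepted, -tot)]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1L]) {
    prev <- which(keep[seq_len(i - 1L)])
    keep[i] <- !any(res$chrom[prev] == res$chrom[i] &
                      res$start[prev] < res$end[i] &
                      res$end[prev] > res$start[i])
  }
  res <- res[keep]
  res[, mirna_id := sprintf("miR-n%d", seq_len(.N))]
  data.table::setcolorder(res, "mirna_id")
  as.data.frame(res)
}

novel_empty <- function(libraries) {
  out <- data.frame(mirna_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), arm = character(0),
                    mature_seq = character(0), star_seq = character(0),
                    LM = integer(0), LP = integer(0), GC = numeric(0),
                    MFE = numeric(0), MFEI = numeric(0),
                    structure = character(0), star_count = numeric(0),
                    n_libraries = integer(0), overhang_ok = logical(0),
                    accepted = logical(0), rule_fired = character(0))
  out[libraries] <- lapply(libraries, function(x) numeric(0))
  out
}

## fold one candidate (paired or orphan stack) and apply the rules
novel_candidate_call <- function(mstack, partner, genome, libraries,
                                 flank, tol, min_libraries) {
  mstack <- as.list(mstack)
  L <- nchar(genome[[mstack$chrom]])
  fold_window <- function(ws, we) {
    ws <- max(0L, ws); we <- min(L, we)
    seq_fwd <- substr(genome[[mstack$chrom]], ws + 1L, we)
    prec <- if (mstack$strand == "-") reverse_complement(seq_fwd) else seq_fwd
    to_prec <- function(a, b) {
      if (mstack$strand == "+") c(a - ws + 1L, b - ws)
      else c(we - b + 1L, we - a)
    }
    m <- to_prec(mstack$start, mstack$end)
    fold <- fold_rna(prec)
    list(ws = ws, we = we, prec = prec, m = m, fold = fold,
         to_prec = to_prec,
         geom = candidate_geometry(fold$pairs, m[1L], m[2L]))
  }
  win <- NULL
  if (!is.null(partner)) {
    partner <- as.list(partner)
    if (partner$total > mstack$total) {
      tmp <- mstack; mstack <- partner; partner <- tmp
    }
    win <- fold_window(min(mstack$start, partner$start),
                       max(mstack$end, partner$end))
    if (is.null(win$geom)) return(NULL)
  } else {
    ## orphan stack: the mature should sit at one end of its precursor, so
    ## try a ladder of one-sided extensions (star arm downstream = 5p
    ## hypothesis, upstream = 3p) and keep the first window whose arm
    ## geometry holds on the extended side
    rl <- mstack$end - mstack$start
    for (ext in unique(c(rl + 12L, 45L, flank))) {
      for (side in c("right", "left")) {
        w <- if (side == "right") fold_window(mstack$start, mstack$end + ext)
             else fold_window(mstack$start - ext, mstack$end)
        if (is.null(w$geom)) next
        ## star must lie on the extension side of the mature
        star_right <- w$geom[["star_start"]] > w$m[2L]
        ext_right <- (side == "right") == (mstack$strand == "+")
        if (star_right == ext_right) { win <- w; break }
      }
      if (!is.null(win)) break
    }
    if (is.null(win)) return(NULL)
  }
  prec <- win$prec
  ws <- win$ws; we <- win$we
  m <- win$m
  fold <- win$fold
  star_count <- 0
  star_seq <- NA_character_
  overhang_ok <- FALSE
  if (!is.null(partner)) {
    star_iv <- win$to_prec(partner$start, partner$end)
    star_count <- partner$total
    star_seq <- partner$sequence
    overhang_ok <- check_duplex(fold$pairs, m, star_iv, tol = tol)
  } else {
    star_iv <- unname(win$geom)
  }
  mcounts <- setNames(as.numeric(mstack[libraries]), libraries)
  call <- call_novel(mcounts, star_count = star_count,
                     overhang_ok = overhang_ok, min_libraries = min_libraries)
  met <- precursor_metrics(prec)
  arm <- if (m[1L] < star_iv[1L]) "5p" else "3p"
  res <- data.table(chrom = mstack$chrom, start = ws, end = we,
                    strand = mstack$strand, arm = arm,
                    mature_seq = mstack$sequence, star_seq = star_seq,
                    LM = nchar(mstack$sequence), LP = met$LP, GC = met$GC,
                    MFE = met$MFE, MFEI = met$MFEI,
                    structure = met$structure, star_count = star_count,
                    n_libraries = length(call$libraries_detected),
                    overhang_ok = overhang_ok, accepted = call$accepted,
                    rule_fired = call$rule_fired)
  for (l in libraries) res[, (l) := mcounts[[l]]]
  res
}

#' Format novel-miRNA calls as a precursor-metrics table
#'
#' @param novel data.frame from [find_novel_mirnas()] (accepted rows are
#'   conventionally reported).
#' @param digits decimals for MFE/MFEI display (half-up).
#' @return data.frame with columns `miRNA`, `Sequence`, `miRNA*`, `Arm`,
#'   `LM(nt)`, `Location`, `Strand`, `MFE`, `LP(nt)`, `GC%`, `MFEI`.
#' @export
format_novel_table <- function(novel, digits = 2L) {
  data.frame(
    miRNA = novel$mirna_id,
    Sequence = tolower(norm_seq(novel$mature_seq, "rna")),
    `miRNA*` = ifelse(novel$star_count > 0, "Yes", "No"),
    Arm = novel$arm,
    `LM(nt)` = novel$LM,
    Location = sprintf("%s:%d..%d", novel$chrom, novel$start + 1L, novel$end),
    Strand = novel$strand,
    MFE = round_half_up(novel$MFE, digits),
    `LP(nt)` = novel$LP,
    `GC%` = round_half_up(novel$GC, digits),
    MFEI = round_half_up(novel$MFEI, digits),
    check.names = FALSE)
}
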