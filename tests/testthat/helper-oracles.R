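# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

rand_dna <- function(n, len, chars = c("A", "C", "G", "T")) {
  vapply(rep_len(len, n), function(l) {
    paste(sample(chars, l, replace = TRUE), collapse = "")
  }, character(1))
}

# character-by-character reverse complement (oracle for reverse_complement)
rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force exact mapping by scanning every genomic position
map_oracle <- function(read, genome) {
  hits <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(read)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else rc_oracle(read)
      p <- 1L
      repeat {
        m <- regexpr(q, substr(s, p, nchar(s)), fixed = TRUE)
        if (m < 0L) break
        st <- p + m - 2L  # 0-based
        hits[[length(hits) + 1L]] <- data.frame(
          read = read, chrom = ch, start = st, end = st + L,
          strand = strand, stringsAsFactors = FALSE)
        p <- p + m
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(read = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$read, out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# exhaustive maximum-weight pairing over all nested structures (oracle for
# fold_rna); feasible for sequences up to ~18 nt
fold_oracle <- function(seq, min_loop = 3L) {
  w <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(s)
  best <- function(i, j) {
    if (j - i <= min_loop) return(0)
    # j unpaired
    b <- best(i, j - 1L)
    # j paired with some k in i..(j - min_loop - 1)
    for (k in i:(j - min_loop - 1L)) {
      wk <- w[paste0(s[k], s[j])]
      if (is.na(wk)) next
      left <- if (k > i) best(i, k - 1L) else 0
      b <- max(b, left + wk + best(k + 1L, j - 1L))
    }
    b
  }
  best(1L, n)
}

# direct textbook BH step-up (oracle for bh_adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# per-window penalty scorer with plain loops (oracle for scan_transcript)
scan_oracle <- function(mirna, transcript, gu = 0.5, mm = 0.5,
                        core = c(2, 13), mult = 2, cutoff = 4) {
  m <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1]]
  tc <- strsplit(toupper(chartr("U", "T", transcript)), "")[[1]]
  L <- length(m)
  res <- list()
  wc <- list(A = "T", T = "A", G = "C", C = "G")
  for (w0 in 0:(length(tc) - L)) {
    sc <- 0
    for (i in seq_len(L)) {
      tch <- tc[w0 + (L - i) + 1L]
      pen <- if (identical(wc[[m[i]]], tch)) 0
             else if ((m[i] == "G" && tch == "T") ||
                      (m[i] == "T" && tch == "G")) gu
             else mm
      if (i >= core[1] && i <= core[2]) pen <- pen * mult
      sc <- sc + pen
    }
    if (sc <= cutoff) {
      res[[length(res) + 1L]] <- data.frame(start = w0, score = sc)
    }
  }
  if (!length(res)) return(data.frame(start = integer(0), score = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$score, out$start), , drop = FALSE]
}

# tiny FASTA/FASTQ writers independent of the package
write_fasta_oracle <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
}
write_fastq_oracle <- function(ids, seqs, quals, path) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
}
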