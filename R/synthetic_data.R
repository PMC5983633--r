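## Seeded synthetic-data generator.
##
## Emulates the structure of an 18-library plant sRNA-seq experiment: two
## tissues (stem, root) x three treatments (control, short-term, long-term
## hormone irrigation) x three replicates, read-length distributions
## dominated by 24- then 21-nt tags, planted known and novel miRNA hairpin
## loci with mature/star duplexes, negative-binomial counts with configured
## log2 fold-changes, and a pooled degradome library with planted 5'-end
## peaks at cleavage sites engineered to fall into each of the five
## categories. Every emitter derives its own RNG substream from the config
## seed so adding one emitter does not perturb the others.

#' Simulation configuration
#'
#' Defaults define the standard study conditions: 18 libraries (2 tissues x
#' 3 treatments x 3 replicates), 1e6 reads per library, NB dispersion 0.05,
#' planted 4-fold changes in the stem short-term treatment, and modal read
#' lengths 24 then 21 nt.
#'
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @param n_scaffolds,scaffold_len toy genome dimensions.
#' @param n_known,n_novel planted known/novel hairpin counts.
#' @param novel_star_frac fraction of novel hairpins whose star is read-
#'   covered (the rest must be rescued by the multi-library rule).
#' @param n_decoys single-library decoy loci that must be rejected.
#' @param tissues,treatments,replicates the library design (`S` stem, `R`
#'   root; treatments `C` control, `S` short-term, `L` long-term).
#' @param depth raw reads per library.
#' @param frac_mirna,frac_background,frac_junk composition of each library
#'   (planted miRNA reads, genome-derived background fragments, unmappable
#'   clean tags); small extra fractions emulate reads removed by each
#'   filter (`frac_no_adapter`, `frac_adapter5`, `frac_len_out`,
#'   `frac_homopolymer`, `frac_n_rich`).
#' @param dispersion NB dispersion of the count model.
#' @param star_ratio star read abundance relative to the mature.
#' @param de_spec data.frame (`mirna_id`, `tissue`, `treatment`, `log2fc`)
#'   of planted effects relative to control; `NULL` installs the default
#'   (ten 4-fold up, ten 4-fold down in stem short-term).
#' @param adapter3,adapter5 adapter sequences appended to inserts.
#' @param background_pool,junk_pool sizes of the shared fragment pools.
#' @param decoy_count reads given to each decoy locus (library 1 only).
#' @param min_stack_count stack threshold used downstream.
#' @param n_transcripts,transcript_len,sites_per_category degradome design
#'   (planted cleavage sites per intended category 1..5).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 2L, scaffold_len = 50000L,
                       n_known = 25L, n_novel = 20L,
                       novel_star_frac = 0.75, n_decoys = 5L,
                       tissues = c("S", "R"), treatments = c("C", "S", "L"),
                       replicates = 3L, depth = 1e6,
                       frac_mirna = 0.40, frac_background = 0.15,
                       frac_junk = 0.405,
                       frac_no_adapter = 0.02, frac_adapter5 = 0.005,
                       frac_len_out = 0.01, frac_homopolymer = 0.005,
                       frac_n_rich = 0.005,
                       dispersion = 0.05, star_ratio = 0.08,
                       de_spec = NULL,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       background_pool = 50000L, junk_pool = 20000L,
                       decoy_count = 200L, min_stack_count = 10L,
                       n_transcripts = 20L, transcript_len = 600L,
                       sites_per_category = 4L) {
  libs <- expand.grid(replicate = seq_len(replicates), tissue = tissues,
                      treatment = treatments, stringsAsFactors = FALSE)
  libs$library_id <- paste0(libs$treatment, libs$tissue, libs$replicate)
  libs <- libs[order(libs$tissue, match(libs$treatment, treatments),
                     libs$replicate), c("library_id", "tissue", "treatment",
                                        "replicate")]
  rownames(libs) <- NULL
  known_ids <- sprintf("peu-miR9%03d", seq_len(n_known))
  novel_ids <- sprintf("novel%02d", seq_len(n_novel))
  if (is.null(de_spec)) {
    up <- c(known_ids[1:5], novel_ids[1:5])
    down <- c(known_ids[6:10], novel_ids[6:10])
    de_spec <- data.frame(
      mirna_id = c(up, down), tissue = "S", treatment = "S",
      log2fc = rep(c(2, -2), each = 10), stringsAsFactors = FALSE)
  }
  structure(list(seed = as.integer(seed), n_scaffolds = n_scaffolds,
                 scaffold_len = scaffold_len, n_known = n_known,
                 n_novel = n_novel, novel_star_frac = novel_star_frac,
                 n_decoys = n_decoys, libraries = libs,
                 treatments = treatments, depth = depth,
                 frac_mirna = frac_mirna, frac_background = frac_background,
                 frac_junk = frac_junk, frac_no_adapter = frac_no_adapter,
                 frac_adapter5 = frac_adapter5, frac_len_out = frac_len_out,
                 frac_homopolymer = frac_homopolymer,
                 frac_n_rich = frac_n_rich, dispersion = dispersion,
                 star_ratio = star_ratio, de_spec = de_spec,
                 adapter3 = norm_seq(adapter3),
                 adapter5 = norm_seq(adapter5),
                 background_pool = background_pool, junk_pool = junk_pool,
                 decoy_count = decoy_count,
                 min_stack_count = min_stack_count,
                 known_ids = known_ids, novel_ids = novel_ids,
                 n_transcripts = n_transcripts,
                 transcript_len = transcript_len,
                 sites_per_category = sites_per_category),
            class = "sim_config")
}

## substream seeds (kept below 2^31 for any integer seed)
sim_seed <- function(config, stream) {
  (config$seed %% 2147483L) * 1000L + stream
}

rand_seq <- function(n, len) {
  if (n == 0L) return(character(0))
  len <- rep_len(as.integer(len), n)
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  ends <- cumsum(len)
  substring(paste(chars, collapse = ""), ends - len + 1L, ends)
}

## One mature miRNA sequence: first nt U-biased (as T). The terminal
## characters are constrained so the planted duplex has unambiguous anchor
## pairs under maximum-weight folding: the last four nt are fixed to AACC
## (the unpaired 3' duplex end CC cannot pair with the all-C loop or the
## A/C tail, and the loop-adjacent stem start becomes T), and the first two
## nt never contain both U and G (so an inert tail exists for the open
## duplex end).
rand_mature <- function(len) {
  repeat {
    first2 <- c(sample(c("T", "A", "C", "G"), 1L,
                       prob = c(0.485, 0.25, 0.15, 0.115)),
                sample(c("A", "C", "G", "T"), 1L))
    if (!all(c("T", "G") %in% first2)) break
  }
  mid <- sample(c("A", "C", "G", "T"), len - 6L, replace = TRUE)
  paste(c(first2, mid, "A", "A", "C", "C"), collapse = "")
}

HAIRPIN_LOOP <- "CCCCCCCC"

## tail (the star's 2-nt 3' overhang at the open duplex end) chosen so it
## cannot pair with the mature's first two nt
hairpin_tail <- function(mature) {
  if (grepl("T", substr(mature, 1L, 2L), fixed = TRUE)) "CC" else "AA"
}

## precursor with a perfect stem over mature[1..Lm-2] and 2-nt 3' overhangs
## on both duplex ends; returns precursor plus 1-based mature/star intervals
build_hairpin <- function(mature, arm) {
  lm <- nchar(mature)
  stem <- reverse_complement(substr(mature, 1L, lm - 2L))
  tail2 <- hairpin_tail(mature)
  if (arm == "5p") {
    prec <- paste0(mature, HAIRPIN_LOOP, stem, tail2)
    m <- c(1L, lm)
    s <- c(lm + nchar(HAIRPIN_LOOP) + 1L, nchar(prec))
  } else {
    prec <- paste0(stem, tail2, HAIRPIN_LOOP, mature)
    m <- c(nchar(prec) - lm + 1L, nchar(prec))
    s <- c(1L, lm)
  }
  list(precursor = prec, mature_iv = m, star_iv = s,
       star_seq = substr(prec, s[1L], s[2L]))
}

#' Generate the toy genome with planted hairpin loci
#'
#' Random background scaffolds with non-overlapping planted precursors
#' (mature + loop + reverse complement of the mature with 2-nt overhang
#' tails, so the builtin folder recovers the duplex), single-read decoy
#' loci, and designated annotation-class regions (rRNA, tRNA, exon) whose
#' sequences become the per-class reference sets.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (data.frame `id`, `sequence`), `truth`
#'   (data.frame of planted loci), `mature_ref`/`hairpin_ref` (known-miRNA
#'   reference sets, RNA alphabet), `class_refs` (named list of reference
#'   data.frames) and `class_regions`.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, 11L))
  scaf_ids <- sprintf("scaffold%d", seq_len(config$n_scaffolds))
  genome <- setNames(vapply(scaf_ids, function(i) {
    paste(sample(c("A", "C", "G", "T"), config$scaffold_len,
                 replace = TRUE), collapse = "")
  }, character(1)), scaf_ids)

  regions <- data.frame(
    class = c("rRNA", "tRNA", "exon"),
    chrom = c(scaf_ids[1L], scaf_ids[1L], scaf_ids[length(scaf_ids)]),
    start = c(30000L, 33000L, 36000L),
    end = c(32000L, 34000L, 39000L), stringsAsFactors = FALSE)
  regions <- regions[regions$end <= config$scaffold_len, ]

  n_loci <- config$n_known + config$n_novel + config$n_decoys
  lens <- sample(c(21L, 22L, 23L, 24L), n_loci, replace = TRUE,
                 prob = c(0.30, 0.20, 0.15, 0.35))
  a3key <- substr(config$adapter3, 1L, 8L)
  matures <- character(n_loci)
  for (i in seq_len(n_loci)) {
    repeat {
      m <- rand_mature(lens[i])
      star <- paste0(reverse_complement(substr(m, 1L, lens[i] - 2L)),
                     hairpin_tail(m))
      ## planted read sequences must not contain the adapter key, or
      ## trimming would truncate every copy of them
      if (!m %in% matures && !grepl(a3key, m, fixed = TRUE) &&
          !grepl(a3key, star, fixed = TRUE)) break
    }
    matures[i] <- m
  }
  ids <- c(config$known_ids, config$novel_ids,
           sprintf("decoy%02d", seq_len(config$n_decoys)))
  types <- rep(c("known", "novel", "decoy"),
               c(config$n_known, config$n_novel, config$n_decoys))
  arms <- rep(c("5p", "3p"), length.out = n_loci)
  strands <- rep(c("+", "-"), length.out = n_loci)

  placed <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0))
  occupied <- function(ch, a, b) {
    hit_reg <- any(regions$chrom == ch & a < regions$end + 200L &
                     b > regions$start - 200L)
    hit_loc <- any(placed$chrom == ch & a < placed$end + 200L &
                     b > placed$start - 200L)
    hit_reg || hit_loc
  }
  truth <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    if (types[i] == "decoy") {
      insert <- matures[i]
      hp <- NULL
    } else {
      hp <- build_hairpin(matures[i], arms[i])
      insert <- if (strands[i] == "-") reverse_complement(hp$precursor)
                else hp$precursor
    }
    ok <- FALSE
    for (try in 1:1000) {
      ch <- sample(scaf_ids, 1L)
      a <- sample.int(config$scaffold_len - nchar(insert) - 400L, 1L) + 200L
      b <- a + nchar(insert)
      if (!occupied(ch, a, b)) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place hairpin ", ids[i], " without overlap")
    substr(genome[[ch]], a + 1L, b) <- insert
    placed <- rbind(placed, data.frame(chrom = ch, start = a, end = b))
    iv_to_genomic <- function(iv, lp) {
      if (is.null(iv)) return(c(NA_integer_, NA_integer_))
      if (strands[i] == "+") c(a + iv[1L] - 1L, a + iv[2L])
      else c(a + lp - iv[2L], a + lp - iv[1L] + 1L)
    }
    lp <- if (is.null(hp)) nchar(insert) else nchar(hp$precursor)
    mg <- iv_to_genomic(if (is.null(hp)) c(1L, nchar(insert)) else hp$mature_iv, lp)
    sg <- iv_to_genomic(if (is.null(hp)) NULL else hp$star_iv, lp)
    truth[[i]] <- data.frame(
      mirna_id = ids[i], type = types[i], chrom = ch, strand = strands[i],
      arm = arms[i], prec_start = a, prec_end = b,
      mature_seq = matures[i],
      star_seq = if (is.null(hp)) NA_character_ else hp$star_seq,
      precursor = if (is.null(hp)) NA_character_ else hp$precursor,
      lm = lens[i], lp = lp,
      mature_gstart = mg[1L], mature_gend = mg[2L],
      star_gstart = sg[1L], star_gend = sg[2L],
      stringsAsFactors = FALSE)
  }
  truth <- if (n_loci == 0L) {
    data.frame(mirna_id = character(0), type = character(0),
               chrom = character(0), strand = character(0),
               arm = character(0), prec_start = integer(0),
               prec_end = integer(0), mature_seq = character(0),
               star_seq = character(0), precursor = character(0),
               lm = integer(0), lp = integer(0),
               mature_gstart = integer(0), mature_gend = integer(0),
               star_gstart = integer(0), star_gend = integer(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, truth)
  n_star <- round(config$novel_star_frac * config$n_novel)
  truth$has_star_reads <- truth$type == "novel" &
    truth$mirna_id %in% config$novel_ids[seq_len(n_star)]

  known <- truth[truth$type == "known", ]
  arm_suffix <- if (nrow(known)) paste0("-", known$arm) else character(0)
  mature_ref <- data.frame(id = paste0(known$mirna_id, arm_suffix),
                           sequence = norm_seq(known$mature_seq, "rna"),
                           stringsAsFactors = FALSE)
  hairpin_ref <- data.frame(id = known$mirna_id,
                            sequence = norm_seq(known$precursor, "rna"),
                            stringsAsFactors = FALSE)
  class_refs <- lapply(seq_len(nrow(regions)), function(r) {
    data.frame(id = paste0(regions$class[r], "_ref"),
               sequence = substr(genome[[regions$chrom[r]]],
                                 regions$start[r] + 1L, regions$end[r]),
               stringsAsFactors = FALSE)
  })
  names(class_refs) <- regions$class
  list(genome = data.frame(id = scaf_ids, sequence = unname(genome),
                           stringsAsFactors = FALSE),
       truth = truth, mature_ref = mature_ref, hairpin_ref = hairpin_ref,
       class_refs = class_refs, class_regions = regions)
}

#' Simulate the per-miRNA per-library count table
#'
#' Baseline abundances are log-normal; planted effects multiply the mean of
#' the matching tissue x treatment libraries by `2^log2fc`; counts are
#' negative-binomial with the configured dispersion. Star counts follow the
#' mature at `star_ratio` for hairpins with read-covered stars.
#'
#' @param config a [sim_config()].
#' @param truth truth data.frame from [sim_genome()].
#' @return list with `counts` (matrix, planted miRNAs x libraries),
#'   `star_counts`, `mean_matrix` and `true_lfc` (the planted design).
#' @export
sim_counts <- function(config, truth) {
  set.seed(sim_seed(config, 22L))
  ids <- c(config$known_ids, config$novel_ids)
  libs <- config$libraries
  w <- exp(rnorm(length(ids), 0, 0.8))
  base <- config$frac_mirna * config$depth * w / sum(w)
  mu <- matrix(base, length(ids), nrow(libs),
               dimnames = list(ids, libs$library_id))
  for (r in seq_len(nrow(config$de_spec))) {
    d <- config$de_spec[r, ]
    sel <- libs$tissue == d$tissue & libs$treatment == d$treatment
    mu[d$mirna_id, sel] <- mu[d$mirna_id, sel] * 2^d$log2fc
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  starred <- truth$mirna_id[truth$has_star_reads]
  smu <- mu[starred, , drop = FALSE] * config$star_ratio
  star_counts <- matrix(rnbinom(length(smu), mu = smu,
                                size = 1 / config$dispersion),
                        nrow(smu), ncol(smu), dimnames = dimnames(smu))
  list(counts = counts, star_counts = star_counts, mean_matrix = mu,
       true_lfc = config$de_spec)
}

#' Emit the sRNA FASTQ libraries
#'
#' Assembles each library from planted miRNA/star reads, shared background
#' genome fragments, unmappable clean tags, and small planted fractions of
#' reads destined for each filter (no 3' adapter, 5' contaminant, length
#' out of range, homopolymer, N-rich); appends the 3' adapter, shuffles and
#' writes FASTQ.
#'
#' @param config a [sim_config()].
#' @param sim output of [sim_genome()].
#' @param cnt output of [sim_counts()].
#' @param outdir output directory (created if needed).
#' @return list with `files` (named FASTQ paths), `samples` (sample sheet
#'   data.frame) and `pools` (the background/junk pools).
#' @export
sim_libraries <- function(config, sim, cnt, outdir) {
  set.seed(sim_seed(config, 33L))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- setNames(sim$genome$sequence, sim$genome$id)
  truth <- sim$truth

  len_probs <- local({
    p <- rep(0.01, 21)
    names(p) <- 10:30
    p["24"] <- p["24"] + 0.25; p["21"] <- p["21"] + 0.18
    p["23"] <- p["23"] + 0.12; p["22"] <- p["22"] + 0.10
    p["20"] <- p["20"] + 0.05; p["25"] <- p["25"] + 0.05
    p / sum(p)
  })
  planted <- c(truth$mature_seq, truth$star_seq)
  planted <- planted[!is.na(planted)]

  ## shared background pool of genome fragments
  n_pool <- config$background_pool
  pool_len <- sample(10:30, n_pool, replace = TRUE, prob = len_probs)
  pool_chrom <- sample(sim$genome$id, n_pool, replace = TRUE)
  pool_start <- sample.int(config$scaffold_len - 31L, n_pool, replace = TRUE)
  pool_strand <- sample(c("+", "-"), n_pool, replace = TRUE)
  pool_seq <- substring(genome[pool_chrom], pool_start + 1L,
                        pool_start + pool_len)
  flip <- pool_strand == "-"
  pool_seq[flip] <- reverse_complement(pool_seq[flip])
  bad <- pool_seq %in% planted
  if (any(bad)) {  # resample fragments colliding with planted sequences
    pool_seq[bad] <- rand_seq(sum(bad), pool_len[bad])
  }
  pool_w <- rexp(n_pool)
  junk_seq <- rand_seq(config$junk_pool,
                       sample(10:30, config$junk_pool, replace = TRUE,
                              prob = len_probs))
  junk_w <- rexp(config$junk_pool)

  libs <- config$libraries
  a3 <- config$adapter3
  a5p <- substr(config$adapter5, 1L, 10L)
  files <- character(nrow(libs))
  names(files) <- libs$library_id
  for (li in seq_len(nrow(libs))) {
    lib <- libs$library_id[li]
    mir_reads <- rep(truth$mature_seq[match(rownames(cnt$counts), truth$mirna_id)],
                     cnt$counts[, lib])
    star_reads <- rep(truth$star_seq[match(rownames(cnt$star_counts),
                                           truth$mirna_id)],
                      cnt$star_counts[, lib])
    decoy_reads <- if (li == 1L) {
      rep(truth$mature_seq[truth$type == "decoy"], config$decoy_count)
    } else character(0)
    n_bg <- round(config$frac_background * config$depth)
    bg_reads <- pool_seq[sample.int(n_pool, n_bg, replace = TRUE,
                                    prob = pool_w)]
    n_junk <- round(config$frac_junk * config$depth)
    junk_reads <- junk_seq[sample.int(config$junk_pool, n_junk,
                                      replace = TRUE, prob = junk_w)]
    with_adapter <- paste0(
      c(mir_reads, star_reads, decoy_reads, bg_reads, junk_reads), a3)
    n_noad <- round(config$frac_no_adapter * config$depth)
    no_adapter <- rand_seq(n_noad, rep(21L, n_noad))
    n_a5 <- round(config$frac_adapter5 * config$depth)
    a5_reads <- paste0(a5p, rand_seq(n_a5, rep(11L, n_a5)), a3)
    n_len <- round(config$frac_len_out * config$depth)
    len_out <- paste0(rand_seq(n_len, sample(c(5:9, 31:40), n_len,
                                             replace = TRUE)), a3)
    n_homo <- round(config$frac_homopolymer * config$depth)
    homo <- paste0(rand_seq(n_homo, rep(7L, n_homo)), strrep("A", 11L),
                   rand_seq(n_homo, rep(3L, n_homo)), a3)
    n_n <- round(config$frac_n_rich * config$depth)
    n_rich <- paste0(rand_seq(n_n, rep(8L, n_n)), "NNNN",
                     rand_seq(n_n, rep(8L, n_n)), a3)
    reads <- c(with_adapter, no_adapter, a5_reads, len_out, homo, n_rich)
    reads <- reads[sample.int(length(reads))]
    rec <- data.frame(id = sprintf("%s_%07d", lib, seq_along(reads)),
                      sequence = reads,
                      quality = strrep("I", nchar(reads)),
                      stringsAsFactors = FALSE)
    files[lib] <- file.path(outdir, paste0(lib, ".fastq"))
    write_fastq(rec, files[lib])
  }
  samples <- libs
  samples$fastq <- unname(files)
  list(files = files, samples = samples,
       pools = list(background = pool_seq, junk = junk_seq))
}

#' Simulate transcripts with planted target sites and a degradome library
#'
#' Each transcript carries one embedded perfect-complement target site for
#' one planted miRNA; degradome 5'-end reads are emitted at the expected
#' cleavage position (opposite miRNA position 10) and at engineered
#' background positions so that the site falls into its intended category.
#'
#' @param config a [sim_config()].
#' @param truth truth data.frame from [sim_genome()].
#' @param outdir output directory.
#' @return list with `transcripts` (data.frame `id`, `sequence`),
#'   `truth_sites` (transcript, mirna_id, window_start, cleavage_pos,
#'   category), `degradome_fastq` (path) and `reads`.
#' @export
sim_degradome <- function(config, truth, outdir) {
  set.seed(sim_seed(config, 44L))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_tr <- config$n_transcripts
  n_sites <- min(n_tr, 5L * config$sites_per_category)
  categories <- rep(1:5, length.out = n_sites)
  mirnas <- truth[truth$type != "decoy", ]
  site_mirna <- mirnas[sample.int(nrow(mirnas), n_sites), ]
  tr_ids <- sprintf("transcript%02d", seq_len(n_tr))
  tr_seq <- rand_seq(n_tr, rep(config$transcript_len, n_tr))
  sites <- vector("list", n_sites)
  all_reads <- character(0)
  for (i in seq_len(n_sites)) {
    lm <- site_mirna$lm[i]
    w0 <- sample(50:(config$transcript_len - lm - 60L), 1L)
    site_seq <- reverse_complement(site_mirna$mature_seq[i])
    s <- tr_seq[i]
    substr(s, w0 + 1L, w0 + lm) <- site_seq
    tr_seq[i] <- s
    cleav0 <- cleavage_position(w0, lm)
    cat_i <- categories[i]
    bg_pos <- sample(setdiff(seq(0L, config$transcript_len - 21L, by = 7L),
                             cleav0), 3L)
    profile <- switch(as.character(cat_i),
      `1` = c(setNames(12L, cleav0), setNames(c(3L, 2L), bg_pos[1:2])),
      `2` = c(setNames(9L, cleav0), setNames(c(9L, 2L), bg_pos[1:2])),
      `3` = c(setNames(6L, cleav0), setNames(c(15L, 2L, 2L), bg_pos[1:3])),
      `4` = c(setNames(2L, cleav0), setNames(c(9L, 5L, 5L), bg_pos[1:3])),
      `5` = c(setNames(1L, cleav0), setNames(7L, bg_pos[1L])))
    pos <- as.integer(names(profile))
    reads <- rep(substring(tr_seq[i], pos + 1L, pos + 20L), profile)
    all_reads <- c(all_reads, reads)
    sites[[i]] <- data.frame(transcript = tr_ids[i],
                             mirna_id = site_mirna$mirna_id[i],
                             mature_seq = site_mirna$mature_seq[i],
                             window_start = w0, cleavage_pos = cleav0,
                             category = cat_i, stringsAsFactors = FALSE)
  }
  truth_sites <- do.call(rbind, sites)
  all_reads <- all_reads[sample.int(length(all_reads))]
  rec <- data.frame(id = sprintf("deg_%06d", seq_along(all_reads)),
                    sequence = all_reads,
                    quality = strrep("I", nchar(all_reads)),
                    stringsAsFactors = FALSE)
  fq <- file.path(outdir, "degradome.fastq")
  write_fastq(rec, fq)
  transcripts <- data.frame(id = tr_ids, sequence = tr_seq,
                            stringsAsFactors = FALSE)
  write_fasta(transcripts, file.path(outdir, "transcripts.fa"))
  list(transcripts = transcripts, truth_sites = truth_sites,
       degradome_fastq = fq, reads = all_reads)
}

#' Run the full synthetic-data generator
#'
#' @param config a [sim_config()].
#' @param outdir output directory for FASTA/FASTQ files.
#' @return list bundling [sim_genome()], [sim_counts()],
#'   [sim_libraries()] and [sim_degradome()] outputs.
#' @export
simulate_dataset <- function(config, outdir) {
  sim <- sim_genome(config)
  cnt <- sim_counts(config, sim$truth)
  lib <- sim_libraries(config, sim, cnt, outdir)
  deg <- sim_degradome(config, sim$truth, outdir)
  write_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_fasta(sim$mature_ref, file.path(outdir, "mature.fa"), rna = TRUE)
  write_fasta(sim$hairpin_ref, file.path(outdir, "hairpin.fa"), rna = TRUE)
  c(sim, list(config = config, counts = cnt, libraries = lib,
              degradome = deg))
}
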