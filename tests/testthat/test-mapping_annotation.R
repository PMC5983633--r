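test_that("map_exact equals a brute-force scan on a random genome", {
  set.seed(31)
  genome <- c(chr1 = rand_dna(1, 10000), chr2 = rand_dna(1, 3000))
  idx <- build_index(genome)
  # mix of planted and random queries
  pos <- sample(1:9950, 100)
  planted <- substring(genome["chr1"], pos, pos + 20)
  planted_rc <- reverse_complement(substring(genome["chr2"], 101:150, 121:170))
  random <- rand_dna(100, 21)
  queries <- unique(c(planted, planted_rc, random))
  got <- map_exact(queries, idx)
  ora <- do.call(rbind, lapply(queries, map_oracle, genome = genome))
  ora <- ora[order(ora$read, ora$chrom, ora$start, ora$strand), ]
  rownames(ora) <- NULL
  expect_equal(got, ora)
  # emitted alignments satisfy the substring invariant
  g <- genome[got$chrom]
  sub <- substring(g, got$start + 1, got$end)
  expect_true(all(ifelse(got$strand == "+", sub == got$read,
                         sub == reverse_complement(got$read))))
})

test_that("every k-mer of a small genome maps back to its own locus", {
  set.seed(33)
  genome <- c(s = rand_dna(1, 2000))
  idx <- build_index(genome)
  p <- seq(1, 1980, by = 7)
  kmers <- substring(genome, p, p + 20)
  got <- map_exact(unique(kmers), idx)
  key <- paste(got$read, got$start, got$strand)
  expect_true(all(paste(kmers, p - 1, "+") %in% key))
  expect_equal(nrow(map_exact("GGGGGGGGGGGGGGGGGGGGG", idx)) == 0,
               !grepl("G{21}", genome) && !grepl("C{21}", genome))
  expect_error(build_index(character(0)), "empty")
  expect_error(map_exact("ACGT", idx), "seed length")
})

test_that("known-miRNA annotation requires exact mature + hairpin containment", {
  set.seed(35)
  hp <- rand_dna(30, 90)
  mature <- substr(hp, 21, 41)
  mature_ref <- data.frame(id = sprintf("xxx-miR%d-5p", 1:30),
                           sequence = chartr("T", "U", mature))
  hairpin_ref <- data.frame(id = sprintf("xxx-miR%d", 1:30), sequence = hp)
  decoys <- vapply(mature, function(m) {
    i <- sample(nchar(m), 1)
    substr(m, i, i) <- setdiff(c("A", "C", "G", "T"), substr(m, i, i))[1]
    m
  }, character(1), USE.NAMES = FALSE)
  hits <- annotate_known(c(mature, decoys), mature_ref, hairpin_ref)
  expect_equal(sort(hits$read), sort(mature))
  expect_equal(nrow(hits), 30L)
  expect_false(any(decoys %in% hits$read))

  # mature without a corresponding hairpin is a reference error
  expect_error(annotate_known(mature,
                              rbind(mature_ref,
                                    data.frame(id = "xxx-miR99-5p",
                                               sequence = "ACGUACGUACGUACGUA")),
                              hairpin_ref),
               "miR99")
  # mature not contained in its hairpin yields no hit
  bad_hp <- hairpin_ref
  bad_hp$sequence[1] <- rand_dna(1, 90)
  hits2 <- annotate_known(mature, mature_ref, bad_hp)
  expect_false(mature[1] %in% hits2$read)
})

test_that("mirna_family strips species prefix, variant and arm suffix", {
  expect_equal(mirna_family("peu-miR394a-5p"), "miR394")
  expect_equal(mirna_family("ptc-miR169x"), "miR169")
  expect_equal(mirna_family("peu-miR-n68"), "miR-n68")
})

test_that("classification follows the fixed hierarchy and is total", {
  set.seed(37)
  rref <- data.frame(id = "rRNA_1", sequence = rand_dna(1, 500))
  eref <- data.frame(id = "exon_1", sequence = rand_dna(1, 500))
  in_r <- substr(rref$sequence, 100, 120)
  in_e <- substr(eref$sequence, 50, 70)
  in_both_mat <- in_e  # pretend this is also a known mature
  reads <- c(in_r, in_e, rand_dna(1, 21))
  known <- data.frame(read = in_both_mat, mature_id = "m1", family = "miR1")
  cls <- classify_read(reads, mapped = c(TRUE, TRUE, FALSE), known,
                       class_refs = list(rRNA = rref, exon = eref))
  expect_equal(cls, c("rRNA", "known_miRNA", "other"))
  cls2 <- classify_read(reads, mapped = c(TRUE, TRUE, TRUE),
                        known[0, ], class_refs = list(rRNA = rref))
  expect_equal(cls2, c("rRNA", "novel_candidate", "novel_candidate"))
  expect_equal(length(cls2), 3L)
})

test_that("mapping statistics weight unique sequences by their counts", {
  ms <- mapping_stats(c("a", "b", "c"), c(5L, 2L, 1L),
                      c(TRUE, FALSE, TRUE))
  expect_equal(ms$mapped_reads, 6)
  expect_equal(ms$mapped_unique, 2)
  expect_equal(ms$length_filtered_reads, 8)
  none <- mapping_stats(c("a", "b"), c(3L, 4L), c(FALSE, FALSE))
  expect_equal(none$mapped_reads, 0)
  expect_equal(none$mapped_unique, 0)
})

test_that("GFF3 export converts to 1-based inclusive coordinates", {
  aln <- data.frame(read = "ACGT", chrom = "c1", start = 9L, end = 13L,
                    strand = "+")
  fp <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(aln, fp)
  lines <- readLines(fp)
  expect_equal(lines[1], "##gff-version 3")
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(f[4:5]), c(10L, 13L))
})
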