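pp <- penalty_params()

test_that("score_duplex applies the printed penalty rules", {
  set.seed(81)
  mi <- rand_dna(1, 21)
  perfect <- reverse_complement(mi)
  d <- score_duplex(mi, perfect, pp)
  expect_equal(d$score, 0)
  expect_true(d$accepted)
  expect_equal(d$pairing, strrep("|", 21))

  # single G:U at miRNA position 15 (outside core) -> 0.5
  mi2 <- paste0(strrep("A", 14), "G", strrep("A", 6))
  site <- strsplit(reverse_complement(mi2), "")[[1]]
  site[21 - 15 + 1] <- "T"   # G:U wobble at miRNA position 15
  d2 <- score_duplex(mi2, paste(site, collapse = ""), pp)
  expect_equal(d2$score, 0.5)
  expect_equal(substr(d2$pairing, 15, 15), "o")

  # single non-G:U mismatch at miRNA position 5 (core) -> 1.0
  mi3 <- strrep("A", 21)
  site3 <- strsplit(reverse_complement(mi3), "")[[1]]
  site3[21 - 5 + 1] <- "C"   # A opposite C
  d3 <- score_duplex(mi3, paste(site3, collapse = ""), pp)
  expect_equal(d3$score, 1.0)
  expect_equal(substr(d3$pairing, 5, 5), "x")

  expect_error(score_duplex("ACGT", "ACGTA", pp), "lengths differ")
})

test_that("score_duplex is monotone under added mismatches", {
  set.seed(83)
  for (r in 1:10) {
    mi <- rand_dna(1, 21)
    site <- strsplit(reverse_complement(mi), "")[[1]]
    sc_prev <- score_duplex(mi, paste(site, collapse = ""), pp)$score
    for (k in sample(21, 6)) {
      site[k] <- sample(c("A", "C", "G", "T"), 1)
      sc <- score_duplex(mi, paste(site, collapse = ""), pp)$score
      expect_gte(sc, 0)
      expect_gte(sc, sc_prev - 1e-12)
      sc_prev <- sc
    }
  }
})

test_that("scan_transcript finds a planted perfect site and matches brute force", {
  set.seed(85)
  mi <- rand_dna(1, 21)
  tr <- rand_dna(1, 500)
  substr(tr, 201, 221) <- reverse_complement(mi)
  hits <- scan_transcript(mi, tr, pp)
  expect_true(any(hits$start == 200 & hits$score == 0))

  for (r in 1:8) {
    mi <- rand_dna(1, sample(20:22, 1))
    tr <- rand_dna(1, 300)
    got <- scan_transcript(mi, tr, pp)
    ora <- scan_oracle(mi, tr)
    expect_equal(got$start, ora$start, info = r)
    expect_equal(got$score, ora$score, info = r)
  }
  expect_warning(none <- scan_transcript(rand_dna(1, 21), "ACGT", pp),
                 "shorter")
  expect_equal(nrow(none), 0L)
})

test_that("cleavage_position pairs the transcript base with miRNA position 10", {
  expect_equal(cleavage_position(100L, 21L), 111L)
  expect_equal(cleavage_position(0L, 21L), 11L)
  expect_equal(cleavage_position(50L, 24L), 64L)
})

test_that("map_degradome counts read 5' ends at exact prefix matches", {
  set.seed(87)
  trs <- c(t1 = rand_dna(1, 400), t2 = rand_dna(1, 300))
  r1 <- substr(trs["t1"], 101, 125)      # 5' end at position 100
  r2 <- substr(trs["t2"], 51, 70)        # exactly prefix length
  prof <- map_degradome(c(r1, r1, r2), trs)
  expect_equal(prof$total, 3)
  cc <- prof$counts
  expect_equal(cc$count[cc$transcript == "t1" & cc$pos == 100], 2)
  expect_equal(cc$count[cc$transcript == "t2" & cc$pos == 50], 1)
  empty <- map_degradome("GGGGGGGGGGGGGGGGGGGG", trs)
  expect_equal(empty$total, 0)
  # a prefix occurring in both transcripts increments each hit
  trs2 <- c(a = paste0(r2, rand_dna(1, 50)), b = paste0(rand_dna(1, 30), r2))
  both <- map_degradome(r2, trs2)
  expect_equal(nrow(both$counts), 2L)
})

test_that("categorize implements the five category rules with precedence", {
  prof <- function(...) {
    x <- c(...)
    data.frame(transcript = "t", pos = as.integer(names(x)),
               count = as.integer(x))
  }
  expect_equal(categorize(prof(`111` = 8, `50` = 2, `60` = 2), "t", 111), 1L)
  expect_equal(categorize(prof(`111` = 5, `300` = 5, `50` = 2), "t", 111), 2L)
  med3 <- prof(`111` = 6, `300` = 15, `50` = 2, `60` = 2)  # median 4
  expect_equal(categorize(med3, "t", 111), 3L)
  med4 <- prof(`111` = 2, `300` = 9, `50` = 4, `60` = 4)   # median 4 > 2
  expect_equal(categorize(med4, "t", 111), 4L)
  expect_equal(categorize(prof(`111` = 1, `300` = 9), "t", 111), 5L)
  expect_error(categorize(prof(`300` = 9), "t", 111), "no cleavage")
  expect_error(categorize(prof(`300` = 9), "missing", 111), "no degradome")
})

test_that("call_cleavage joins sites with degradome evidence", {
  set.seed(89)
  tr <- c(t1 = rand_dna(1, 400))
  mi <- rand_dna(1, 21)
  substr(tr["t1"], 101, 121) <- reverse_complement(mi)
  cleav <- cleavage_position(100L, 21L)
  reads <- c(rep(substr(tr["t1"], cleav + 1, cleav + 20), 9),
             substr(tr["t1"], 301, 320))
  profile <- map_degradome(reads, tr)
  sites <- scan_transcript(mi, tr[["t1"]])
  sites$mirna_id <- "mi1"
  sites$transcript <- "t1"
  calls <- call_cleavage(sites, profile)
  hit <- calls[calls$start == 100, ]
  expect_equal(hit$cleavage_pos, cleav)
  expect_equal(hit$cleavage_count, 9L)
  expect_equal(hit$category, 1L)
})
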