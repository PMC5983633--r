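params <- filter_params(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                        adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")

test_that("3' adapter trimming recovers planted inserts", {
  set.seed(5)
  inserts <- rand_dna(1000, sample(10:30, 1000, replace = TRUE))
  # adapters at known offsets: insert + full or partial adapter
  cut <- sample(8:21, 1000, replace = TRUE)
  reads <- paste0(inserts, substr(params$adapter3, 1, cut))
  tr <- trim_adapter3(reads, params)
  planted_ok <- !grepl(substr(params$adapter3, 1, 8), inserts, fixed = TRUE)
  expect_true(all(tr$insert[planted_ok] == inserts[planted_ok]))

  one <- trim_adapter3(paste0(strrep("ACG", 7), params$adapter3), params)
  expect_equal(one$insert, strrep("ACG", 7))
  no <- trim_adapter3("ACGTACGTACGTACGTACGTA", params)
  expect_true(is.na(no$insert))
  expect_equal(no$n_no_adapter, 1L)
  expect_error(trim_adapter3("A", filter_params(adapter3 = "ACGT")),
               "shorter")
})

test_that("filters enforce the printed rules with fixed precedence", {
  f <- filter_reads(strrep("A", 35), params)
  expect_equal(unname(f$tally["length"]), 1L)
  expect_equal(length(f$kept), 0L)

  homo <- paste0(strrep("C", 5), strrep("A", 11), strrep("C", 5))
  f <- filter_reads(homo, params)
  expect_equal(unname(f$tally["homopolymer"]), 1L)
  ok_homo <- paste0(strrep("C", 5), strrep("A", 10), strrep("C", 6))
  expect_equal(filter_reads(ok_homo, params)$kept, ok_homo)

  n3 <- paste0("NNN", strrep("ACGT", 4), "A")   # 20 nt, 15% N
  f <- filter_reads(n3, params)
  expect_equal(unname(f$tally["n_fraction"]), 1L)
  n1 <- paste0("N", strrep("ACGT", 4), "ACG")   # 20 nt, 5% N
  expect_equal(filter_reads(n1, params)$kept, n1)

  contam <- paste0(substr(params$adapter5, 1, 8), "ACGTACGTACGTA")
  f <- filter_reads(contam, params)
  expect_equal(unname(f$tally["adapter5"]), 1L)

  # precedence: a 35-nt homopolymer-containing read counts as length
  both <- paste0(strrep("A", 12), strrep("CG", 12))
  expect_equal(unname(filter_reads(both, params)$tally["length"]), 1L)
})

test_that("filtering conserves reads, is idempotent, and kept reads obey all rules", {
  set.seed(9)
  mix <- c(rand_dna(500, sample(10:30, 500, replace = TRUE)),
           rand_dna(50, sample(c(5:9, 31:40), 50, replace = TRUE)),
           paste0(rand_dna(30, 5), strrep("G", 12), rand_dna(30, 5)),
           vapply(1:30, function(i) {
             paste(sample(c("A", "C", "G", "T", rep("N", 4)), 20,
                          replace = TRUE), collapse = "")
           }, character(1)))
  f <- filter_reads(mix, params)
  expect_equal(length(f$kept) + sum(f$tally), length(mix))
  f2 <- filter_reads(f$kept, params)
  expect_equal(f2$kept, f$kept)
  expect_equal(sum(f2$tally), 0L)
  len <- nchar(f$kept)
  expect_true(all(len >= 10 & len <= 30))
  expect_false(any(grepl("([ACGTN])\\1{10,}", f$kept, perl = TRUE)))
  nfrac <- (len - nchar(gsub("N", "", f$kept))) / len
  expect_true(all(nfrac <= 0.10))
})

test_that("collapse_unique matches a hash-count oracle and is sorted", {
  x <- c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
         "TTTTGGGGCCCCAAAATTTTG")
  cu <- collapse_unique(x)
  expect_equal(nrow(cu), 2L)
  expect_equal(cu$count[cu$sequence == x[1]], 2L)
  expect_equal(collapse_unique(character(0)),
               data.frame(sequence = character(0), count = integer(0)))

  set.seed(13)
  reads <- sample(rand_dna(300, 21), 1e4, replace = TRUE)
  cu <- collapse_unique(reads)
  ora <- table(reads)
  expect_equal(sum(cu$count), length(reads))
  expect_equal(cu$sequence, sort(unique(reads), method = "radix"))
  expect_equal(cu$count, as.integer(ora[cu$sequence]))

  two <- collapse_unique(list(l1 = reads[1:100], l2 = reads[1:50]))
  expect_equal(sum(two$l1), 100L)
  expect_equal(sum(two$l2), 50L)
  expect_equal(two$total, two$l1 + two$l2)
})

test_that("size_distribution conserves totals and finds planted modes", {
  sd1 <- size_distribution("ACGTACGTACGTACGTACGTACGT")  # one 24-mer
  expect_equal(sd1$total[sd1$length == 24], 1)
  expect_equal(sum(sd1$total), 1)

  set.seed(21)
  lens <- sample(10:30, 5000, replace = TRUE,
                 prob = c(rep(1, 11), 20, 5, 8, 30, rep(1, 6)))  # modes 24, 21
  reads <- rand_dna(5000, lens)
  cu <- collapse_unique(reads)
  sdist <- size_distribution(cu$sequence, cu$count)
  expect_equal(sum(sdist$total), 5000)
  expect_equal(sdist$length[which.max(sdist$total)], 24L)
  expect_equal(sdist$length[order(-sdist$total)[2]], 21L)
  expect_true(all(sdist$unique <= sdist$total))
})

test_that("library_stats enforces containment invariants", {
  st <- library_stats(100, 90, 80, 40, 30, 20)
  expect_equal(st$clean_pct, 90)
  expect_error(library_stats(100, 110, 80, 40, 30, 20))
  expect_error(library_stats(100, 90, 80, 85, 30, 20))
  tab <- format_stats_table(list(L1 = st))
  expect_equal(tab$Sample, "L1")
  expect_match(tab$`Clean Reads`, "90 \\(90.00%\\)")
})
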