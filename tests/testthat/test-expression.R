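make_cm <- function(counts, totals = NULL) {
  n <- ncol(counts)
  if (is.null(totals)) totals <- rep(1e6, n)
  samples <- data.frame(library_id = colnames(counts),
                        tissue = "S", treatment = rep(c("C", "S"),
                                                      each = n / 2),
                        replicate = rep(seq_len(n / 2), 2),
                        total_clean_reads = totals)
  count_matrix(counts, samples)
}

sim_nb_counts <- function(n_mirna, n_planted, lfc, mu_log = log(500),
                          disp = 0.05, n_per_group = 3, depth = 1e6,
                          seed = 1) {
  set.seed(seed)
  base <- exp(rnorm(n_mirna, mu_log, 1))
  planted <- sample(n_mirna, n_planted)
  muA <- matrix(base, n_mirna, n_per_group)
  muB <- muA
  muB[planted, ] <- muB[planted, ] * 2^lfc
  mu <- cbind(muA, muB)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / disp),
                   n_mirna, 2 * n_per_group)
  rownames(counts) <- sprintf("m%04d", seq_len(n_mirna))
  colnames(counts) <- c(paste0("A", seq_len(n_per_group)),
                        paste0("B", seq_len(n_per_group)))
  list(counts = counts, planted = rownames(counts)[planted])
}

test_that("tpm implements the printed normalisation formula", {
  expect_equal(tpm(1, 1e6), 1)
  expect_equal(tpm(250, 1e7), 25)
  expect_equal(tpm(0, 5e6), 0)
  expect_error(tpm(1, 0), "positive")
})

test_that("TPM per library sums to 1e6 x (miRNA reads / clean reads)", {
  set.seed(61)
  counts <- matrix(rpois(60, 100), 10, 6,
                   dimnames = list(sprintf("m%d", 1:10),
                                   sprintf("L%d", 1:6)))
  totals <- c(2e6, 1e6, 3e6, 1.5e6, 2.5e6, 1e6)
  cm <- make_cm(counts, totals)
  tp <- tpm_matrix(cm)
  expect_equal(colSums(tp), 1e6 * colSums(counts) / totals)
  expect_true(all(colSums(tp) <= 1e6))
})

test_that("bh_adjust equals the textbook step-up and its properties hold", {
  expect_equal(bh_adjust(0.05), 0.05)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), bh_oracle(p))
  set.seed(63)
  for (r in 1:20) {
    p <- runif(50)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p & adj <= 1))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("de_test identity gives log2FC 0 and nothing significant", {
  set.seed(65)
  half <- matrix(rnbinom(30, mu = 200, size = 20), 10, 3)
  counts <- cbind(half, half)
  rownames(counts) <- sprintf("m%d", 1:10)
  colnames(counts) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  cm <- make_cm(counts)
  de <- de_test(cm, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  expect_true(all(de$log2FC == 0))
  expect_false(any(de$significant))
  expect_true(all(de$padj >= de$p))
  expect_error(de_test(cm, c("A1", "A2"), c("A2", "B1")), "overlap")
  expect_error(de_test(cm, "A1", c("B1", "B2")), "at least 2")
})

test_that("de_test is antisymmetric under group swap", {
  s <- sim_nb_counts(50, 10, 2, seed = 67)
  cm <- make_cm(s$counts)
  ab <- de_test(cm, paste0("A", 1:3), paste0("B", 1:3))
  ba <- de_test(cm, paste0("B", 1:3), paste0("A", 1:3))
  expect_equal(ab$log2FC, -ba$log2FC)
  expect_equal(ab$p, ba$p)
})

test_that("planted 4-fold changes are recovered with high sensitivity and low FDR", {
  s <- sim_nb_counts(200, 20, 2, disp = 0.05, n_per_group = 3,
                     depth = 1e6, seed = 1)
  cm <- make_cm(s$counts)
  de <- de_test(cm, paste0("A", 1:3), paste0("B", 1:3))
  called <- de$mirna_id[de$significant]
  tp <- sum(called %in% s$planted)
  expect_gte(tp / length(s$planted), 0.9)
  fdr <- if (length(called)) (length(called) - tp) / length(called) else 0
  expect_lte(fdr, 0.1)
  # estimated log2FC of the planted set is close to the truth
  est <- de$log2FC[de$mirna_id %in% s$planted]
  expect_lt(abs(mean(est) - 2), 0.3)
})

test_that("null simulation controls the significant fraction at the BH level", {
  s <- sim_nb_counts(1000, 0, 0, seed = 2)
  cm <- make_cm(s$counts)
  de <- de_test(cm, paste0("A", 1:3), paste0("B", 1:3))
  expect_lte(mean(de$padj <= 0.05), 0.05)
})

test_that("comparison_summary tallies and Venn regions match enumeration", {
  mk <- function(ids, sig, dir) {
    data.frame(mirna_id = ids, comparison = "x", log2FC = ifelse(dir == "up", 2, -2),
               p = 0.01, padj = 0.01, significant = sig, direction = dir)
  }
  a <- mk(c("m1", "m2", "m3"), c(TRUE, TRUE, FALSE), c("up", "down", "up"))
  b <- mk(c("m1", "m2", "m3"), c(TRUE, TRUE, FALSE), c("up", "down", "up"))
  s <- comparison_summary(list(A = a, B = b))
  expect_equal(s$per_comparison$up, c(1, 1))
  expect_equal(s$per_comparison$down, c(1, 1))
  expect_equal(s$venn$count[s$venn$region == "A & B"], 2)
  expect_equal(sum(s$venn$count[s$venn$region %in% c("A", "B")]), 0)

  d <- mk(c("a", "b"), c(TRUE, FALSE), c("up", "up"))
  e <- mk(c("a", "b"), c(FALSE, TRUE), c("up", "down"))
  s2 <- comparison_summary(list(D = d, E = e))
  expect_equal(s2$venn$count[s2$venn$region == "D"], 1)
  expect_equal(s2$venn$count[s2$venn$region == "E"], 1)
  expect_equal(s2$venn$count[s2$venn$region == "D & E"], 0)

  set.seed(71)
  ids <- sprintf("m%02d", 1:40)
  three <- lapply(1:3, function(i) {
    mk(ids, sample(c(TRUE, FALSE), 40, replace = TRUE),
       sample(c("up", "down"), 40, replace = TRUE))
  })
  names(three) <- c("C1", "C2", "C3")
  s3 <- comparison_summary(three)
  sets <- lapply(three, function(d) d$mirna_id[d$significant])
  for (r in seq_len(nrow(s3$venn))) {
    inc <- strsplit(s3$venn$region[r], " & ")[[1]]
    exc <- setdiff(names(three), inc)
    want <- Reduce(intersect, sets[inc])
    for (x in exc) want <- setdiff(want, sets[[x]])
    expect_equal(s3$venn$count[r], length(want), info = s3$venn$region[r])
  }
})

test_that("ddct implements 2^-ddCt", {
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(20, 15, 18, 15), 0.25)  # ddCt = 2
  expect_equal(ddct(17, 15, 18, 15), 2)     # ddCt = -1
  expect_error(ddct(NA, 15, 18, 15), "missing")
})
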