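test_that("fold_rna DP equals exhaustive enumeration for short sequences", {
  f <- fold_rna("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$weight, 9)  # 3 GC pairs

  f0 <- fold_rna("AAAAAAAAAA")
  expect_equal(f0$weight, 0)
  expect_equal(f0$structure, strrep(".", 10))

  set.seed(41)
  for (len in c(15L, 16L, 18L)) {
    for (r in 1:17) {
      s <- rand_dna(1, len)
      expect_equal(fold_rna(s)$weight, unname(fold_oracle(s)), info = s)
    }
  }
  expect_error(fold_rna("ACG"), "short")
})

test_that("fold_rna structures are well-formed and consistent with pairs", {
  set.seed(43)
  for (r in 1:10) {
    s <- rand_dna(1, 60)
    f <- fold_rna(s)
    expect_equal(nchar(f$structure), 60L)
    p <- dotbracket_pairs(f$structure)
    expect_equal(p, f$pairs)
    paired <- which(!is.na(p))
    expect_true(all(p[p[paired]] == paired))  # involution
    expect_true(all(abs(p[paired] - paired) > 3))  # min loop
  }
  expect_error(dotbracket_pairs("(()"), "unbalanced")
})

test_that("compute_mfei reproduces printed precursor-table values", {
  # MFEI = (|MFE|/LP x 100)/GC, half-up to 2 decimals
  rows <- data.frame(
    mfe = c(-26.3, -38, -67.7, -97.5, -20, -8.8, -84.9),
    lp = c(62, 84, 146, 251, 46, 38, 192),
    gc = c(9.68, 38.10, 47.26, 42.63, 30.43, 36.84, 32.81),
    mfei = c(4.38, 1.19, 0.98, 0.91, 1.43, 0.63, 1.35))
  expect_equal(compute_mfei(rows$mfe, rows$lp, rows$gc, digits = 2),
               rows$mfei)
  expect_equal(compute_mfei(0, 100, 50), 0)
  expect_error(compute_mfei(-10, 100, 0), "zero")
  expect_error(compute_mfei(-10, 0, 50), "positive")
})

test_that("mature_length matches printed worked examples", {
  expect_equal(mature_length("CUGUUGGUCUCUCUUUGUAA"), 20L)
  expect_equal(mature_length("GGAAACCUUUUGUGGGGGUUUG"), 22L)
  expect_error(mature_length(""), "empty")
})

test_that("first_nt_bias counts first characters as fractions", {
  seven <- c("uuauuuaaauuugauuucuuu", "uuggaggaaauauauuuuggc",
             "ugaagagguagagaguguaauu", "gggacaaaaauggcauaagagg",
             "aaggaaaaugcauagaacaagu", "aauuuguacugugaaacu",
             "uauagaugacuauauuuagggagc")
  b <- first_nt_bias(seven)
  expect_equal(unname(b["U"]), 4 / 7)
  expect_equal(sum(b), 1)
  expect_equal(unname(first_nt_bias("UGGA")["U"]), 1)
  set.seed(47)
  expect_equal(sum(first_nt_bias(rand_dna(100, 21))), 1)
  expect_error(first_nt_bias(character(0)), "empty")
})

test_that("check_duplex accepts 2-nt 3' overhangs and rejects shifts", {
  # perfect planted duplex: mature 1..21, loop 8, star with overhangs
  mat <- "TGTGCCTAAGGTCTGGTAACC"
  hp <- mirstalk:::build_hairpin(mat, "5p")
  f <- fold_rna(hp$precursor)
  expect_true(check_duplex(f$pairs, hp$mature_iv, hp$star_iv))
  shifted <- hp$star_iv + 4L
  expect_false(check_duplex(f$pairs, hp$mature_iv, shifted))
  # overlapping intervals are never a duplex
  expect_false(check_duplex(f$pairs, hp$mature_iv,
                            hp$mature_iv + c(2L, 2L)))
  expect_error(check_duplex(f$pairs, c(0L, 21L), hp$star_iv), "within")

  hp3 <- mirstalk:::build_hairpin(mat, "3p")
  f3 <- fold_rna(hp3$precursor)
  expect_true(check_duplex(f3$pairs, hp3$mature_iv, hp3$star_iv))
})

test_that("planted hairpins pass the duplex check and shuffled decoys fail", {
  set.seed(49)
  pass <- 0L
  fail_decoy <- 0L
  for (r in 1:20) {
    arm <- if (r %% 2) "5p" else "3p"
    hp <- mirstalk:::build_hairpin(mirstalk:::rand_mature(21L), arm)
    f <- fold_rna(hp$precursor)
    pass <- pass + check_duplex(f$pairs, hp$mature_iv, hp$star_iv)
    shuf <- paste(sample(strsplit(hp$precursor, "")[[1]]), collapse = "")
    fd <- fold_rna(shuf)
    fail_decoy <- fail_decoy +
      !check_duplex(fd$pairs, hp$mature_iv, hp$star_iv)
  }
  expect_equal(pass, 20L)
  expect_equal(fail_decoy, 20L)
})

test_that("excise_precursor windows contain the planted precursor", {
  set.seed(51)
  bg <- rand_dna(1, 1000)
  hp <- mirstalk:::build_hairpin(mirstalk:::rand_mature(21L), "5p")
  g <- c(s1 = paste0(substr(bg, 1, 500), hp$precursor, substr(bg, 501, 1000)))
  aln <- list(chrom = "s1", start = 500L, end = 521L, strand = "+")
  cands <- excise_precursor(aln, g, flank = 70L)
  expect_equal(length(cands), 2L)
  expect_equal(vapply(cands, `[[`, "", "arm"), c("5p", "3p"))
  expect_true(all(vapply(cands, function(x) nchar(x$sequence), 1L) <= 161L))
  expect_true(grepl(hp$precursor, cands[[1]]$sequence, fixed = TRUE))
  # stack at scaffold start truncates without crashing
  aln0 <- list(chrom = "s1", start = 3L, end = 24L, strand = "+")
  expect_warning(c0 <- excise_precursor(aln0, g), "truncated")
  expect_equal(c0[[1]]$start, 0L)
})

test_that("call_novel applies the star-support and multi-library rules", {
  one_lib <- c(L1 = 30, L2 = 0, L3 = 0)
  multi <- c(L1 = 30, L2 = 12, L3 = 4)
  star <- call_novel(one_lib, star_count = 8, overhang_ok = TRUE)
  expect_true(star$accepted)
  expect_equal(star$rule_fired, "star_supported")
  no_star <- call_novel(one_lib, star_count = 0)
  expect_false(no_star$accepted)
  expect_equal(no_star$rule_fired, "rejected")
  ml <- call_novel(multi, star_count = 0)
  expect_true(ml$accepted)
  expect_equal(ml$rule_fired, "multi_library")
  # star reads without overhang geometry fall back to rule (ii)
  bad_geom <- call_novel(one_lib, star_count = 8, overhang_ok = FALSE)
  expect_false(bad_geom$accepted)
})

test_that("precursor metrics satisfy the MFEI identity", {
  set.seed(53)
  hp <- mirstalk:::build_hairpin(mirstalk:::rand_mature(22L), "5p")
  met <- precursor_metrics(hp$precursor)
  expect_equal(met$LP, nchar(hp$precursor))
  expect_equal(met$MFEI,
               (abs(met$MFE) / met$LP * 100) / met$GC)
  met2 <- precursor_metrics(hp$precursor, mfe = -41.2)
  expect_false(met2$mfe_is_pseudo)
  expect_equal(met2$MFEI, (41.2 / met$LP * 100) / met$GC)
})
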