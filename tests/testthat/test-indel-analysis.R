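test_that("homopolymer classification follows the run rules", {
  #                         123456789012345
  ref <- ref_genome(c(chr1 = "GCAAAAGCGTTTGCG"))
  # insertion of A adjacent to the AAAA run
  ins <- validate_indels(indel_df("s", "chr1", 3, "A", "AA"))
  out <- classify_homopolymer(ins, ref)
  expect_true(out$is_homopolymer_1bp)
  expect_equal(out$homopolymer_run_length, 4L)
  # deletion of C from GCG: run of 1
  del <- validate_indels(indel_df("s", "chr1", 13, "GC", "G"))
  out2 <- classify_homopolymer(del, ref)
  expect_false(out2$is_homopolymer_1bp)
  expect_equal(out2$homopolymer_run_length, 1L)
  # indels longer than 1 bp are never homopolymer_1bp
  long <- validate_indels(indel_df("s", "chr1", 3, "AAA", "A"))
  expect_false(classify_homopolymer(long, ref)$is_homopolymer_1bp)
})

test_that("homopolymer runs match a direct scan oracle", {
  ref <- random_ref(3000, seed = 23, gc = 0.3)  # AT-rich for more runs
  b <- strsplit(unclass(ref)[["chr1"]], "")[[1]]
  run_scan <- function(i) {  # run containing position i, by explicit walk
    l <- i; r <- i
    while (l > 1 && b[l - 1] == b[i]) l <- l - 1
    while (r < length(b) && b[r + 1] == b[i]) r <- r + 1
    r - l + 1
  }
  with_seed(24, {
    pos <- sample(10:2990, 60)
    for (p in pos) {
      del <- validate_indels(indel_df("s", "chr1", p - 1,
                                      paste0(b[p - 1], b[p]), b[p - 1]))
      del <- left_normalize_indels(del, ref)
      got <- classify_homopolymer(del, ref)
      # run length measured at the normalized deletion site
      expect_equal(got$homopolymer_run_length,
                   run_scan(del$pos + 1L))
    }
  })
})

test_that("junction microhomology takes the best flank match, capped", {
  #                         1234567890123456
  ref <- ref_genome(c(chr1 = "GGTACGTACGAAGGTT"))
  # delete ACGT (4..7); right flank begins ACGA -> prefix match 3
  del <- validate_indels(indel_df("s", "chr1", 3, "TACGT", "T"))
  expect_equal(junction_microhomology(del, ref), 3L)
  # deletion inside a homopolymer caps at the deletion length
  ref2 <- ref_genome(c(chr1 = "GGTTTTTTTTGG"))
  del2 <- validate_indels(indel_df("s", "chr1", 2, "GTTTT", "G"))
  expect_equal(junction_microhomology(del2, ref2), 4L)
})

test_that("microhomology equals an exhaustive alignment oracle", {
  ref <- random_ref(4000, seed = 25)
  sq <- unclass(ref)[["chr1"]]
  mh_oracle <- function(s, e) {  # compare base by base, both sides
    L <- e - s + 1
    k1 <- 0
    while (k1 < L && s + k1 <= 4000 - L &&
           substr(sq, s + k1, s + k1) == substr(sq, e + 1 + k1, e + 1 + k1))
      k1 <- k1 + 1
    k2 <- 0
    while (k2 < L && s - 1 - k2 >= 1 &&
           substr(sq, e - k2, e - k2) == substr(sq, s - 1 - k2, s - 1 - k2))
      k2 <- k2 + 1
    min(max(k1, k2), L)
  }
  with_seed(26, {
    for (i in 1:50) {
      L <- sample(2:12, 1)
      s <- sample(30:3900, 1)
      del <- validate_indels(indel_df("s", "chr1", s - 1,
                                      substr(sq, s - 1, s + L - 1),
                                      substr(sq, s - 1, s - 1)))
      expect_equal(junction_microhomology(del, ref), mh_oracle(s, s + L - 1))
    }
  })
})

test_that("templated insertions are detected on both sides", {
  #                         12345678901234
  ref <- ref_genome(c(chr1 = "GGATAGCCTTAGCA"))
  # single-base copy of the adjacent base
  i1 <- validate_indels(indel_df("s", "chr1", 3, "A", "AA"))
  out1 <- detect_templated_insertion(i1, ref)
  expect_equal(out1$templated, "adjacent_copy")
  expect_equal(out1$template_side, "left")
  # TAG duplication after reference TAG (positions 4-6)
  i2 <- validate_indels(indel_df("s", "chr1", 6, "G", "GTAG"))
  expect_equal(detect_templated_insertion(i2, ref)$templated, "adjacent_copy")
  # right-side copy: insert CCT before positions 7-9 = CCT
  i3 <- validate_indels(indel_df("s", "chr1", 6, "G", "GCCT"))
  out3 <- detect_templated_insertion(i3, ref)
  expect_equal(out3$templated, "adjacent_copy")
  expect_equal(out3$template_side, "right")
  # no copy anywhere
  i4 <- validate_indels(indel_df("s", "chr1", 3, "A", "AC"))
  expect_equal(detect_templated_insertion(i4, ref)$templated, "none")
  # one mismatch tolerated only above 2 bp
  i5 <- validate_indels(indel_df("s", "chr1", 6, "G", "GTCG"))  # TAG -> TCG
  out5 <- detect_templated_insertion(i5, ref)
  expect_equal(out5$templated, "adjacent_copy_with_mismatch")
  expect_equal(out5$mismatches, 1L)
  i6 <- validate_indels(indel_df("s", "chr1", 3, "A", "AG"))  # 1 bp mismatch
  expect_equal(detect_templated_insertion(i6, ref)$templated, "none")
})

test_that("per-sample indel summaries recover generator composition", {
  sm0 <- summarize_indels(classify_indels(
    validate_indels(indel_df(character(0), character(0), integer(0),
                             character(0), character(0), qual = numeric(0),
                             vaf = numeric(0))), tiny_ref()), samples = "s")
  expect_equal(sm0$total, 0L)
  expect_equal(sm0$deletions_ge5, 0L)
  cfg <- small_sim_config(seed = 6)
  ref <- make_reference(cfg)
  coh <- simulate_cohort(cfg, ref)
  keep <- coh$indels$qual >= 50  # drop planted artifacts, as the filter does
  cl <- classify_indels(coh$indels[keep, ], ref)
  sm <- summarize_indels(cl, samples = coh$meta$sample_id)
  tr <- coh$truth$per_sample[match(sm$sample_id,
                                   coh$truth$per_sample$sample_id), ]
  truth_lab <- coh$truth$indel_truth[keep, ]
  # deletions >= 5 bp are exactly the generator's planted class
  expect_equal(sm$deletions_ge5,
               vapply(sm$sample_id, function(s)
                 sum(truth_lab$class == "deletion_ge5" &
                       truth_lab$sample_id == s), integer(1)),
               ignore_attr = TRUE)
  # homopolymer count at least the planted slippage events (other 1 bp
  # insertions can legitimately fall in runs too)
  expect_true(all(sm$homopolymer_1bp >= tr$n_hp_indel))
  # a 5 bp deletion sits on the inclusive boundary
  ref2 <- ref_genome(c(chr1 = "GGTACGTACGAAGGTT"))
  one <- classify_indels(validate_indels(
    indel_df("s", "chr1", 3, "TACGTA", "T")), ref2)
  expect_equal(summarize_indels(one)$deletions_ge5, 1L)
})

test_that("indel classification is invariant under reverse complement", {
  ref <- random_ref(1000, seed = 27)
  rc <- revcomp_reference(ref)
  sq <- unclass(ref)[["chr1"]]
  L <- 1000
  with_seed(28, {
    for (i in 1:25) {
      dl <- sample(1:8, 1)
      s <- sample(30:950, 1)   # deleted span s .. s+dl-1
      del <- validate_indels(indel_df("s", "chr1", s - 1,
                                      substr(sq, s - 1, s + dl - 1),
                                      substr(sq, s - 1, s - 1)))
      # mirrored deletion on the reverse-complemented genome
      e <- s + dl - 1
      s2 <- L - e + 1
      rsq <- unclass(rc)[["chr1"]]
      del2 <- validate_indels(indel_df("s", "chr1", s2 - 1,
                                       substr(rsq, s2 - 1, s2 + dl - 1),
                                       substr(rsq, s2 - 1, s2 - 1)))
      a <- classify_indels(del, ref)
      b <- classify_indels(del2, rc)
      expect_equal(a$mh_length, b$mh_length)
      expect_equal(a$is_homopolymer_1bp, b$is_homopolymer_1bp)
      expect_equal(a$is_deletion_ge5, b$is_deletion_ge5)
    }
  })
})
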