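test_that("closely spaced mutations are excluded pairwise", {
  snvs <- snv_df("s", "chr1", c(100, 105, 300, 310, 500), "C", "T")
  kept <- exclude_complex(snvs)
  expect_equal(kept$pos, c(300L, 310L, 500L))  # 100/105 both out, 310 kept
  # different chromosomes and samples do not interact
  two <- rbind(snv_df("a", "chr1", 100, "C", "T"),
               snv_df("b", "chr1", 104, "C", "T"))
  expect_equal(nrow(exclude_complex(two)), 2)
})

test_that("a single hand-counted window gives the documented counts", {
  sig <- motif_signature("nCg->nTg", "nCg", "T")
  # window TTCGA centred on the mutated C: centre trinucleotide TCG matches
  # nCg; the only other countable middle-base occurrence is G at position 4
  # whose reverse complement context CGA -> tCg matches too
  cnt <- count_motif_and_base("TTCGA", sig)
  expect_equal(cnt$mut_in_motif, 1L)
  expect_equal(cnt$mut_in_class, 1L)
  expect_equal(cnt$ctx_base, 1L)
  expect_equal(cnt$ctx_motif, 1L)
})

test_that("degenerate motif nCn gives enrichment exactly 1", {
  sig <- motif_signature("nCn->nTn", "nCn", "T")
  with_seed(21, {
    ref <- random_ref(5000, seed = 22)
    b <- strsplit(unclass(ref)[["chr1"]], "")[[1]]
    cg <- which(b %in% c("C", "G"))     # windows centre on class mutations
    pos <- sample(cg[cg > 100 & cg < 4900], 80)
    win <- vapply(pos, function(p)
      fetch_context(ref, "chr1", p, 10)$sequence, character(1))
    cnt <- count_motif_and_base(win, sig)
    expect_equal(cnt$ctx_motif, cnt$ctx_base)
    expect_equal(enrichment(cnt$mut_in_motif, cnt$mut_in_class,
                            cnt$ctx_motif, cnt$ctx_base), 1)
  })
})

test_that("window counts equal the naive position-by-position oracle", {
  with_seed(31, {
    for (sig_spec in list(c("yCn", "T"), c("nCg", "T"), c("nTt", "C"))) {
      sig <- motif_signature("x", sig_spec[1], sig_spec[2])
      from <- toupper(substr(sig_spec[1], 2, 2))
      win <- vapply(1:40, function(i) {
        b <- sample(c("A", "C", "G", "T", "N"), 11,
                    replace = TRUE, prob = c(rep(0.24, 4), 0.04))
        b[6] <- sample(c(from, chartr("ACGT", "TGCA", from)), 1)
        paste(b, collapse = "")
      }, character(1))
      got <- count_motif_and_base(win, sig)
      exp <- motif_count_oracle(win, sig_spec[1], from)
      expect_equal(got[names(exp)], exp)
    }
  })
})

test_that("enrichment follows its defining ratio", {
  expect_equal(enrichment(10, 20, 50, 200), 2.0)
  expect_equal(enrichment(5, 20, 50, 200), 1.0)
  with_seed(5, {
    for (i in 1:25) {
      mc <- sample(5:50, 1); mm <- sample(0:mc, 1)
      cb <- sample(100:2000, 1); cm <- sample(1:cb, 1)
      expect_equal(enrichment(mm, mc, cm, cb), (mm * cb) / (mc * cm))
    }
  })
  expect_true(is.infinite(enrichment(3, 10, 0, 100)))
  expect_true(is.nan(enrichment(0, 0, 0, 0)))
})

test_that("Fisher enrichment test equals the hypergeometric oracle", {
  expect_equal(enrichment_test(0, 10, 100, 1000), 1)
  expect_equal(enrichment_test(10, 20, 50, 200),
               fisher_oracle(10, 10, 50, 150, "greater"), tolerance = 1e-12)
  with_seed(8, {
    for (i in 1:30) {
      mc <- sample(1:12, 1); mm <- sample(0:mc, 1)
      cb <- sample(2:12, 1); cm <- sample(0:cb, 1)
      expect_equal(enrichment_test(mm, mc, cm, cb),
                   fisher_oracle(mm, mc - mm, cm, cb - cm, "greater"),
                   tolerance = 1e-12)
      expect_equal(enrichment_test(mm, mc, cm, cb, "two.sided"),
                   fisher_oracle(mm, mc - mm, cm, cb - cm, "two.sided"),
                   tolerance = 1e-9)
    }
  })
  expect_error(enrichment_test(5, 3, 10, 100), "negative")
})

test_that("BH correction matches the step-up formula", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  with_seed(9, {
    for (i in 1:10) {
      p <- runif(sample(3:40, 1))
      q <- bh_correct(p)
      expect_equal(q, bh_oracle(p))
      expect_true(all(q >= p - 1e-12))
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
})

test_that("minimum mutation load applies the gated formula", {
  expect_equal(minimum_mutation_load(10, 2.0, 0.001), 5.0)
  expect_equal(minimum_mutation_load(10, 0.8, 0.001), 0)
  expect_equal(minimum_mutation_load(10, 2.0, 0.2), 0)
  # monotone in enrichment and bounded by the motif count
  loads <- vapply(seq(1.01, 50, length.out = 40), function(e)
    minimum_mutation_load(17, e, 1e-5), numeric(1))
  expect_true(all(diff(loads) > 0))
  expect_true(all(loads >= 0 & loads <= 17))
})

test_that("availability-corrected load is exact on noiseless counts", {
  # 60 of 100 class mutations in-motif with availability 0.25:
  # (60 - 100 * 0.25) / 0.75 spiked events plus none from background
  expect_equal(attributable_load(60, 100, 250, 1000, q = 1e-6),
               (60 - 25) / 0.75)
  expect_equal(attributable_load(60, 100, 250, 1000, q = 0.2), 0)
})

test_that("CC->TT pairs are counted once on either strand", {
  snvs <- rbind(
    snv_df("s", "chr1", c(100, 101), "C", "T"),
    snv_df("s", "chr1", c(200, 201), "G", "A"),
    snv_df("s", "chr1", c(300, 303), "C", "T"),
    snv_df("s", "chr2", 100, "C", "T"))
  out <- count_cc_tt(snvs)
  expect_equal(out$cc_tt[out$sample_id == "s"], 2L)
})

test_that("run_panel is deterministic and silent on pure background", {
  ref <- random_ref(3e4, seed = 44)
  with_seed(45, {
    # mutations uniform over C/G occurrences: no motif structure
    b <- strsplit(unclass(ref)[["chr1"]], "")[[1]]
    cg <- which(b %in% c("C", "G"))
    pos <- sample(cg[cg > 25 & cg < length(b) - 25], 120)
    snvs <- snv_df("bg_only", "chr1", pos, b[pos],
                   ifelse(b[pos] == "C", "T", "A"))
  })
  pan <- run_panel(snvs, ref)
  expect_true(all(pan$results$min_load == 0))
  dup <- rbind(snvs, transform(snvs, sample_id = "copy"))
  pan2 <- run_panel(dup, ref)
  a <- pan2$results[pan2$results$sample_id == "bg_only",
                    c("mut_in_motif", "mut_in_class", "enrichment", "p")]
  b2 <- pan2$results[pan2$results$sample_id == "copy",
                     c("mut_in_motif", "mut_in_class", "enrichment", "p")]
  expect_equal(a, b2, ignore_attr = TRUE)
})

test_that("context deduplication collapses overlapping windows", {
  ref <- ref_genome(c(chr1 = strrep("ACGT", 30)))
  sig <- motif_signature("nCg->nTg", "nCg", "T")
  # two heavily overlapping windows double-count without dedup
  pos <- c(60L, 62L)
  win <- fetch_windows(ref, c("chr1", "chr1"), pos, 10L)
  plain <- count_motif_and_base(win, sig)
  dedup <- count_motif_and_base(win, sig, chrom = c("chr1", "chr1"),
                                pos = pos, dedup = TRUE)
  expect_lt(dedup$ctx_base, plain$ctx_base)
})
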