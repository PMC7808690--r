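test_that("hotspot chaining needs two SVs from different samples", {
  svs <- rbind(sv_df("s1", "DEL", "chr1", 1e6, "chr1", 1.2e6),
               sv_df("s2", "DEL", "chr1", 1.5e6, "chr1", 1.7e6))
  hs <- call_hotspots(svs)
  expect_equal(nrow(hs$hotspots), 1)
  expect_true(all(hs$in_hotspot))
  expect_equal(hs$hotspots$n_samples, 2)
  # same sample only: no hotspot
  svs2 <- transform(svs, sample_id = "s1")
  hs2 <- call_hotspots(svs2)
  expect_equal(nrow(hs2$hotspots), 0)
  expect_false(any(hs2$in_hotspot))
  # beyond the gap: no hotspot
  svs3 <- rbind(sv_df("s1", "DEL", "chr1", 1e6, "chr1", 1.1e6),
                sv_df("s2", "DEL", "chr1", 5e6, "chr1", 5.1e6))
  expect_equal(nrow(call_hotspots(svs3)$hotspots), 0)
})

test_that("hotspot membership equals the pairwise-chaining oracle", {
  with_seed(33, {
    for (rep in 1:25) {
      n <- sample(6:20, 1)
      svs <- sv_df(sample(paste0("s", 1:5), n, TRUE),
                   sample(c("DEL", "DUP", "TRA"), n, TRUE),
                   sample(c("chr1", "chr2"), n, TRUE),
                   sample.int(2e7, n), "chr1", 0)
      svs$chrom2 <- ifelse(svs$sv_type == "TRA",
                           sample(c("chr1", "chr2"), n, TRUE), svs$chrom1)
      svs$pos2 <- ifelse(svs$sv_type == "TRA", sample.int(2e7, n),
                         svs$pos1 + sample.int(5e5, n))
      gap <- sample(c(2e5, 1e6), 1)
      expect_equal(call_hotspots(svs, gap)$in_hotspot,
                   hotspot_oracle(svs, gap))
    }
  })
})

test_that("hotspot calls are invariant to order and coordinate shifts", {
  with_seed(34, {
    n <- 15
    svs <- sv_df(sample(paste0("s", 1:4), n, TRUE), "DEL", "chr1",
                 sort(sample.int(3e7, n)), "chr1", 0)
    svs$pos2 <- svs$pos1 + sample.int(4e5, n)
    base <- call_hotspots(svs)$in_hotspot
    perm <- sample.int(n)
    expect_equal(call_hotspots(svs[perm, ])$in_hotspot, base[perm])
    shifted <- transform(svs, pos1 = pos1 + 123456L, pos2 = pos2 + 123456L)
    expect_equal(call_hotspots(shifted)$in_hotspot, base)
  })
})

test_that("every hotspot member is chained to another SV within the gap", {
  cfg <- small_sim_config(seed = 8)
  ref <- make_reference(cfg)
  coh <- simulate_cohort(cfg, ref)
  svs <- filter_sv_clonality(coh$svs)
  hs <- call_hotspots(svs, max_gap = cfg$sv_max_gap)
  expect_true(all(hs$hotspots$n_sv >= 2))
  expect_true(all(hs$hotspots$n_samples >= 2))
  bp <- data.frame(sv = rep(seq_len(nrow(svs)), 2),
                   chrom = c(svs$chrom1, svs$chrom2),
                   pos = c(svs$pos1, svs$pos2))
  # chaining guarantee: each member SV has some other member SV breakpoint
  # within the gap (cross-sample proximity is only guaranteed chain-wide)
  for (h in seq_len(nrow(hs$hotspots))) {
    members <- as.integer(strsplit(hs$hotspots$sv_rows[h], ",")[[1]])
    for (i in members) {
      mine <- bp[bp$sv == i, ]
      rest <- bp[bp$sv %in% setdiff(members, i), ]
      near <- any(vapply(seq_len(nrow(mine)), function(k)
        any(rest$chrom == mine$chrom[k] &
              abs(rest$pos - mine$pos[k]) <= cfg$sv_max_gap), logical(1)))
      expect_true(near)
    }
  }
})

test_that("planted recurrent loci are recalled as hotspots", {
  cfg <- small_sim_config(seed = 9)
  ref <- make_reference(cfg)
  coh <- simulate_cohort(cfg, ref)
  svs <- filter_sv_clonality(coh$svs)
  hs <- call_hotspots(svs, max_gap = cfg$sv_max_gap)
  fr <- coh$fragile_sites
  ann <- annotate_cfs(svs, fr, tra_window = 0)
  # every planted interval holding breakpoint-1 seeds of >= 2 SVs from
  # different samples must be recovered as (part of) a called hotspot
  for (j in seq_along(fr)) {
    g <- suppressWarnings(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(svs$chrom1, IRanges::IRanges(svs$pos1,
                                                          svs$pos1)),
      fr[j]))
    members <- S4Vectors::queryHits(g)
    if (length(unique(svs$sample_id[members])) >= 2)
      expect_true(all(hs$in_hotspot[members]))
  }
})

test_that("CFS annotation distinguishes interval and breakpoint rules", {
  cfs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 2e6))
  names(cfs) <- "FRA1X"
  svs <- rbind(
    sv_df("s", "DEL", "chr1", 2e6, "chr1", 3e6),       # 1 bp edge overlap
    sv_df("s", "DEL", "chr1", 2000001, "chr1", 3e6),   # just outside
    sv_df("s", "TRA", "chr1", 2e6 + 9999, "chr2", 5e7),
    sv_df("s", "TRA", "chr1", 2e6 + 10001, "chr2", 5e7))
  ann <- annotate_cfs(svs, cfs, tra_window = 1e4)
  expect_equal(ann$overlaps_cfs, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ann$rule_used,
               c("interval_intersection", "interval_intersection",
                 "breakpoint_window", "breakpoint_window"))
  expect_equal(ann$cfs_names[1], "FRA1X")
})

test_that("CFS overlap matches a brute-force per-base oracle", {
  with_seed(35, {
    for (rep in 1:15) {
      k <- 3
      starts <- sort(sample.int(1e6, k))
      cfs <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(starts, starts + 5e3))
      n <- 10
      svs <- sv_df("s", "DEL", "chr1", sample.int(9e5, n), "chr1", 0)
      svs$pos2 <- svs$pos1 + sample.int(2e4, n)
      ann <- annotate_cfs(svs, cfs)
      brute <- vapply(seq_len(n), function(i)
        any(svs$pos1[i] <= GenomicRanges::end(cfs) &
              svs$pos2[i] >= GenomicRanges::start(cfs)), logical(1))
      expect_equal(ann$overlaps_cfs, brute)
    }
  })
})

test_that("breakpoint microhomology reads the junction sequence", {
  # engineered deletion junction: bases after pos1 equal bases after pos2
  left <- "ACGTACGTAA"
  mid <- strrep("G", 30)
  sq <- paste0(left, "CATG", mid, "CATT", strrep("A", 20))
  ref <- ref_genome(c(chr1 = sq))
  # DEL removing (pos1, pos2]: right of pos1 = CATG..., right of pos2 = CATT
  sv <- sv_df("s", "DEL", "chr1", 10, "chr1", 44)
  expect_equal(breakpoint_microhomology(sv, ref), 3L)
  # random flanks give mostly zero
  ref2 <- random_ref(5000, seed = 36)
  with_seed(37, {
    mhs <- vapply(1:60, function(i) {
      p1 <- sample(100:2000, 1)
      breakpoint_microhomology(
        sv_df("s", "DEL", "chr1", p1, "chr1", p1 + sample(500:2000, 1)),
        ref2)
    }, integer(1))
    expect_gt(mean(mhs == 0), 0.4)
    expect_lt(mean(mhs >= 2), 0.25)
  })
})

test_that("microhomology-by-CFS Fisher test reproduces printed counts", {
  # 120 rearrangements: 63 in CFS (6 with MH), 57 outside (9 with MH)
  mh_len <- c(rep(2, 6), rep(0, 57), rep(3, 9), rep(0, 48))
  cfs <- c(rep(TRUE, 63), rep(FALSE, 57))
  out <- mh_cfs_fisher(mh_len, cfs)
  expect_equal(unname(out$table), matrix(c(6, 57, 9, 48), 2, byrow = TRUE))
  expect_equal(out$p, 0.41, tolerance = 0.005)
  # identical proportions give p = 1
  even <- mh_cfs_fisher(c(2, 0, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(even$p, 1)
  expect_error(mh_cfs_fisher(integer(0), logical(0)), "empty")
})

test_that("Fisher table p equals the enumeration oracle on random tables", {
  with_seed(38, {
    for (i in 1:20) {
      tab <- matrix(sample(0:10, 4, TRUE), 2)
      if (sum(tab) == 0) next
      mh_len <- c(rep(2, tab[1, 1]), rep(0, tab[1, 2]),
                  rep(2, tab[2, 1]), rep(0, tab[2, 2]))
      cfs <- c(rep(TRUE, sum(tab[1, ])), rep(FALSE, sum(tab[2, ])))
      if (length(mh_len) == 0) next
      got <- mh_cfs_fisher(mh_len, cfs)$p
      expect_equal(got, fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                      tab[2, 2], "two.sided"),
                   tolerance = 1e-9)
    }
  })
})

test_that("SV-type chi-square matches the textbook formula", {
  types <- c(rep("DEL", 30), rep("DUP", 20), rep("DEL", 15), rep("DUP", 35))
  cfs <- c(rep(TRUE, 50), rep(FALSE, 50))
  out <- svtype_cfs_chisq(types, cfs)
  tab <- matrix(c(30, 15, 20, 35), 2, dimnames = list(c("DEL", "DUP"), NULL))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(out$statistic, stat)
  expect_equal(out$p, stats::pchisq(stat, 1, lower.tail = FALSE))
  # identical compositions: statistic 0, p 1
  same <- svtype_cfs_chisq(rep(c("DEL", "DUP"), each = 20),
                           rep(c(TRUE, FALSE), 20))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # zero column dropped with a warning
  expect_warning(
    expect_error(svtype_cfs_chisq(rep("DEL", 5), rep(TRUE, 5)), "degenerate"),
    "dropping")
})
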