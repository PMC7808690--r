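# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes: a cohort of single cell-derived clonal lineages whose
# SNV catalogs mix a CpG-deamination process (rate linear in donor age), a
# UV process (yCn->yTn plus CC->TT and nTt->nCt, race-dependent amplitude,
# age-independent) and uniform background; homopolymer slippage indels
# (linear in age) and >= 5 bp deletions with junction microhomology coupled
# to the UV load; and structural variants enriched at planted fragile-site
# intervals. Every draw is recorded in a truth object so recovery is
# testable. The seed fully determines the output.

#' Simulation configuration
#'
#' Defaults encode the cohort structure the generator emulates: 21 donors
#' aged 25-79 (16 White, 5 African American), 34 fibroblast + 5 melanocyte
#' clonal lineages; CpG-deamination SNVs accruing at 0.4 mutations per year
#' plus a culture-age intercept; a UV yCn->yTn load with White-donor median
#' ~200 in-motif events (log-normal across samples, age-independent, zero
#' in African American donors) of which 5% are emitted as adjacent CC->TT
#' pairs and 5% as nTt->nCt; uniform background substitutions; homopolymer
#' 1 bp indels at 0.22 per year; >= 5 bp deletions coupled to the UV load;
#' and 1-14 SVs per (non-amplified) sample placed preferentially in planted
#' fragile intervals. Sub-clonal artifact records give the clonality filters
#' something to remove.
#'
#' The synthetic genome is deliberately small (2 x 1 Mb); SV hotspot
#' geometry is scaled accordingly: the chaining gap `sv_max_gap` sits above
#' the within-fragile-interval breakpoint spacing but below the typical
#' spacing of scattered breakpoints, and fragile intervals are planted at
#' least `20 * sv_max_gap` apart so recurrent loci remain separable.
#' `call_hotspots()` keeps the 1 Mb default appropriate to real genomes.
#'
#' @param seed integer seed; fully determines all outputs
#' @param genome_length bases per chromosome
#' @param n_chromosomes number of chromosomes
#' @param gc_fraction genome GC fraction
#' @param cpg_enrichment CpG dinucleotide observed/expected scale factor
#'   (1 = composition-neutral, 0 = CpG-free). The default 0.25 reproduces
#'   the CpG depletion of mammalian genomes, which is what makes the
#'   CpG-deamination signal stand out against large UV mutation loads
#' @param homopolymer_density planted homopolymer runs (length 5-9) per Mb
#' @param n_donors,n_fibroblasts,n_melanocytes cohort sizes
#' @param age_range donor age range in years
#' @param race_mix named proportions for donor race assignment
#' @param background_median,background_sdlog log-normal background SNV count
#' @param cpg_slope,cpg_intercept CpG-deamination Poisson mean =
#'   slope * age + intercept (mutations per year / baseline)
#' @param uv_median named per-race median of the log-normal UV in-motif
#'   event count
#' @param uv_sdlog log-sd of the UV load across samples
#' @param cc_tt_fraction fraction of UV events emitted as CC->TT pairs
#' @param ntt_fraction fraction of UV events emitted as nTt->nCt
#' @param clonal_vaf_sd sd of the clonal het allele fraction around 0.5
#' @param hom_fraction fraction of clonal SNVs at homozygous fractions
#' @param artifact_rate sub-clonal artifact SNVs per clonal SNV
#' @param homopolymer_indel_slope homopolymer 1 bp indels per year
#' @param deletion_ge5_base,deletion_ge5_per_uv Poisson mean of >= 5 bp
#'   deletions = base + per_uv * UV count
#' @param mh_probs named distribution of planted deletion junction
#'   microhomology lengths
#' @param ins_1bp_mean,ins_1bp_templated 1 bp insertions per sample and
#'   their templated (adjacent-copy) fraction
#' @param ins_long_mean,ins_long_templated,ins_long_mismatch insertions of
#'   3-8 bp per sample, templated fraction, and mismatched-copy fraction
#'   among templated ones
#' @param ins_2bp_mean random 2 bp insertions per sample
#' @param indel_artifact_rate low-quality artifact indels per true indel
#' @param sv_mean SV count per sample is `1 + Poisson(sv_mean)`, capped at 14
#' @param sv_hotspot_weight probability an SV is seeded inside a fragile
#'   interval
#' @param n_fragile_sites,fragile_width planted fragile intervals
#' @param sv_max_gap hotspot chaining gap matched to the synthetic genome
#' @param sv_mh_probs named distribution of planted DEL breakpoint
#'   microhomology lengths
#' @param sv_artifact_rate sub-clonal/failed SV records per clonal SV
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6, n_chromosomes = 2,
                       gc_fraction = 0.42, cpg_enrichment = 0.25,
                       homopolymer_density = 150,
                       n_donors = 21, n_fibroblasts = 34, n_melanocytes = 5,
                       age_range = c(25, 79),
                       race_mix = c(White = 16 / 21, AfricanAmerican = 5 / 21),
                       background_median = 700, background_sdlog = 0.5,
                       cpg_slope = 0.4, cpg_intercept = 20,
                       uv_median = c(White = 200, AfricanAmerican = 0),
                       uv_sdlog = 1.0,
                       cc_tt_fraction = 0.05, ntt_fraction = 0.05,
                       clonal_vaf_sd = 0.02, hom_fraction = 0.02,
                       artifact_rate = 0.25,
                       homopolymer_indel_slope = 0.22,
                       deletion_ge5_base = 2, deletion_ge5_per_uv = 0.035,
                       mh_probs = c(`0` = 0.5, `1` = 0.25, `2` = 0.15,
                                    `3` = 0.10),
                       ins_1bp_mean = 4.8, ins_1bp_templated = 163 / 186,
                       ins_long_mean = 0.7, ins_long_templated = 18 / 28,
                       ins_long_mismatch = 3 / 18,
                       ins_2bp_mean = 0.3,
                       indel_artifact_rate = 0.15,
                       sv_mean = 2.4, sv_hotspot_weight = 0.6,
                       n_fragile_sites = 6, fragile_width = 2000,
                       sv_max_gap = 2000,
                       sv_mh_probs = c(`0` = 0.85, `2` = 0.09, `3` = 0.06),
                       sv_artifact_rate = 0.3) {
  cfg <- as.list(environment())
  check_that(genome_length >= 1e4, "genome_length must be >= 10 kb")
  rates <- c(background_median, cpg_slope, cpg_intercept, uv_median,
             cc_tt_fraction, ntt_fraction, artifact_rate,
             homopolymer_indel_slope, deletion_ge5_base, deletion_ge5_per_uv,
             sv_mean, sv_hotspot_weight)
  check_that(all(rates >= 0), "all rates must be >= 0")
  check_that(abs(sum(race_mix) - 1) < 1e-8, "race_mix must sum to 1")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic reference genome
#'
#' i.i.d. bases at the configured GC fraction, with planted homopolymer
#' runs (length 5-9) and the CpG dinucleotide frequency scaled by
#' `cpg_enrichment`. Deterministic under `cfg$seed`.
#'
#' @param cfg [sim_config()]
#' @return `ref_genome` with chromosomes chr1..chrN
#' @export
make_reference <- function(cfg) {
  check_that(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  gc <- cfg$gc_fraction
  check_that(gc > 0 && gc < 1, "infeasible gc_fraction")
  with_rng(cfg$seed, {
    seqs <- vapply(seq_len(cfg$n_chromosomes), function(i) {
      L <- as.integer(cfg$genome_length)
      b <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      # plant homopolymer runs
      n_runs <- round(cfg$homopolymer_density * L / 1e6)
      if (n_runs > 0) {
        starts <- sample.int(L - 12L, n_runs)
        lens <- sample(5:9, n_runs, replace = TRUE)
        bases <- sample(c("A", "C", "G", "T"), n_runs, replace = TRUE)
        for (k in seq_len(n_runs))
          b[starts[k]:(starts[k] + lens[k] - 1L)] <- bases[k]
      }
      # scale CpG frequency
      f <- cfg$cpg_enrichment
      if (f != 1) {
        is_cg <- which(b[-L] == "C" & b[-1L] == "G")
        if (f < 1 && length(is_cg) > 0) {
          drop <- is_cg[runif(length(is_cg)) > f]
          # replacing the G with A/T cannot create a new CpG
          b[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
          # restore the GC fraction: convert as many A/T bases back to G at
          # positions not preceded by C (so no new CpG appears either)
          if (length(drop) > 0) {
            cand <- which(b %in% c("A", "T") & c("N", b[-L]) != "C")
            cand <- setdiff(cand, drop + 1L)
            b[sample(cand, length(drop))] <- "G"
          }
        } else if (f > 1) {
          extra <- round((f - 1) * length(is_cg))
          if (extra > 0) {
            at <- sample.int(L - 1L, extra)
            b[at] <- "C"; b[at + 1L] <- "G"
          }
        }
      }
      paste(b, collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(cfg$n_chromosomes))
    ref_genome(seqs)
  })
}

# per-chromosome site indices used for mutation placement
build_site_index <- function(reference) {
  seqs <- unclass(reference)
  idx <- lapply(names(seqs), function(ch) {
    b <- strsplit(seqs[[ch]], "")[[1]]
    L <- length(b)
    prev <- c("N", b[-L])
    nxt <- c(b[-1L], "N")
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= 4L & r$values != "N" & starts > 1L
    runs <- data.frame(start = starts[keep], len = r$lengths[keep],
                       base = r$values[keep], stringsAsFactors = FALSE)
    list(chrom = ch, bases = b, L = L,
         cpg = which(b == "C" & nxt == "G"),
         ycn_fwd = which(b == "C" & (prev == "C" | prev == "T")),
         ycn_rev = which(b == "G" & (nxt == "A" | nxt == "G")),
         ntt_fwd = which(b == "T" & nxt == "T"),
         ntt_rev = which(b == "A" & prev == "A"),
         cc_fwd = which(b == "C" & nxt == "C"),
         cc_rev = which(b == "G" & nxt == "G"),
         runs = runs)
  })
  names(idx) <- names(seqs)
  idx
}

# flatten a per-chromosome site list to a (chrom, pos) frame
site_frame <- function(idx, field) {
  do.call(rbind, lapply(idx, function(x)
    if (length(x[[field]]) == 0) NULL else
      data.frame(chrom = x$chrom, pos = x[[field]],
                 stringsAsFactors = FALSE)))
}

# draw n substitutions uniformly over non-N genome positions, random alt
draw_uniform_snvs <- function(idx, n) {
  ch <- sample(names(idx), n, replace = TRUE,
               prob = vapply(idx, function(x) x$L, numeric(1)))
  pos <- integer(n)
  ref <- character(n)
  for (c2 in unique(ch)) {
    sel <- ch == c2
    p <- sample.int(idx[[c2]]$L, sum(sel), replace = TRUE)
    pos[sel] <- p
    ref[sel] <- idx[[c2]]$bases[p]
  }
  ok <- ref %in% c("A", "C", "G", "T")
  ch <- ch[ok]; pos <- pos[ok]; ref <- ref[ok]
  others <- matrix(c("C", "G", "T",  "A", "G", "T",
                     "A", "C", "T",  "A", "C", "G"),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  alt <- others[cbind(match(ref, rownames(others)),
                      sample.int(3L, length(ref), replace = TRUE))]
  data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

draw_sites <- function(sites, n, what) {
  if (n == 0) return(sites[0, , drop = FALSE])
  check_that(!is.null(sites) && nrow(sites) >= n,
             "reference too small for requested ", what, " count")
  sites[sample.int(nrow(sites), n), , drop = FALSE]
}

# truncated-normal clonal het vafs with a small homozygous admixture
draw_vafs <- function(n, cfg) {
  v <- pmin(pmax(rnorm(n, 0.5, cfg$clonal_vaf_sd), 0), 1)
  hom <- runif(n) < cfg$hom_fraction
  v[hom] <- runif(sum(hom), 0.905, 0.995)
  v
}

#' Simulate a cohort of clonal lineages
#'
#' Draws donor metadata and per-sample somatic catalogs from the processes
#' described in [sim_config()], returning catalogs, metadata, planted
#' fragile-site intervals and a complete ground-truth record.
#'
#' @param cfg [sim_config()]
#' @param reference `ref_genome` from [make_reference()] (or compatible)
#' @return list with `snvs`, `indels`, `svs`, `meta`, `fragile_sites`
#'   (`GRanges`) and `truth` (per-sample realized process counts plus
#'   per-variant process labels)
#' @export
simulate_cohort <- function(cfg, reference) {
  check_that(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  idx <- build_site_index(reference)
  lens <- seq_lengths(reference)
  with_rng(cfg$seed + 1L, {
    meta <- simulate_meta(cfg)
    fragile <- plant_fragile_sites(cfg, lens)
    sites <- list(
      cpg = cbind(site_frame(idx, "cpg"), strand = "+"),
      ycn = rbind(cbind(site_frame(idx, "ycn_fwd"), strand = "+"),
                  cbind(site_frame(idx, "ycn_rev"), strand = "-")),
      ntt = rbind(cbind(site_frame(idx, "ntt_fwd"), strand = "+"),
                  cbind(site_frame(idx, "ntt_rev"), strand = "-")),
      cc = rbind(cbind(site_frame(idx, "cc_fwd"), strand = "+"),
                 cbind(site_frame(idx, "cc_rev"), strand = "-")))
    all_runs <- do.call(rbind, lapply(idx, function(x)
      if (nrow(x$runs) == 0) NULL else cbind(chrom = x$chrom, x$runs)))
    snv_parts <- list(); indel_parts <- list(); sv_parts <- list()
    per_sample <- list()
    for (i in seq_len(nrow(meta))) {
      sm <- simulate_sample(cfg, reference, idx, sites, all_runs, fragile,
                            meta[i, ])
      snv_parts[[i]] <- sm$snvs
      indel_parts[[i]] <- sm$indels
      sv_parts[[i]] <- sm$svs
      per_sample[[i]] <- sm$counts
    }
    snvs <- do.call(rbind, snv_parts)
    indels <- do.call(rbind, indel_parts)
    svs <- do.call(rbind, sv_parts)
    rownames(snvs) <- rownames(indels) <- rownames(svs) <- NULL
    truth <- list(
      per_sample = do.call(rbind, per_sample),
      snv_process = snvs[, c("sample_id", "chrom", "pos", "process")],
      indel_truth = indels[, c("sample_id", "chrom", "pos", "class",
                               "planted_mh")],
      sv_truth = svs[, c("sample_id", "in_fragile", "planted_mh", "clonal")],
      fragile_sites = fragile)
    snv_cat <- validate_snvs(snvs[, SNV_COLS])
    indel_cat <- validate_indels(indels[, INDEL_COLS])
    sv_cat <- validate_svs(svs[, !(names(svs) %in%
                                     c("in_fragile", "planted_mh", "clonal"))])
    fr_gr <- GenomicRanges::GRanges(fragile$chrom,
                                    IRanges::IRanges(fragile$start,
                                                     fragile$end))
    names(fr_gr) <- fragile$name
    list(snvs = snv_cat, indels = indel_cat, svs = sv_cat, meta = meta,
         fragile_sites = fr_gr, truth = truth)
  })
}

simulate_meta <- function(cfg) {
  n_white <- round(cfg$n_donors * cfg$race_mix[["White"]])
  donors <- data.frame(
    donor_id = sprintf("D%02d", seq_len(cfg$n_donors)),
    age = sample(seq(cfg$age_range[1], cfg$age_range[2]), cfg$n_donors,
                 replace = TRUE),
    sex = sample(c("M", "F"), cfg$n_donors, replace = TRUE),
    race = sample(c(rep("White", n_white),
                    rep("AfricanAmerican", cfg$n_donors - n_white))),
    stringsAsFactors = FALSE)
  # every donor gets one fibroblast clone; the rest are assigned at random
  check_that(cfg$n_fibroblasts >= cfg$n_donors,
             "need at least one fibroblast clone per donor")
  fib_donor <- c(seq_len(cfg$n_donors),
                 sample.int(cfg$n_donors, cfg$n_fibroblasts - cfg$n_donors,
                            replace = TRUE))
  mel_donor <- sample.int(cfg$n_donors, cfg$n_melanocytes)
  rows <- list()
  cnt <- integer(cfg$n_donors)
  for (d in fib_donor) {
    cnt[d] <- cnt[d] + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(donors$donor_id[d], "_F", cnt[d]),
      donor_id = donors$donor_id[d], age = donors$age[d],
      sex = donors$sex[d], race = donors$race[d],
      cell_type = "fibroblast", wga = FALSE, stringsAsFactors = FALSE)
  }
  for (k in seq_along(mel_donor)) {
    d <- mel_donor[k]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(donors$donor_id[d], "_M1"),
      donor_id = donors$donor_id[d], age = donors$age[d],
      sex = donors$sex[d], race = donors$race[d],
      cell_type = "melanocyte", wga = k > 1, stringsAsFactors = FALSE)
  }
  validate_sample_meta(do.call(rbind, rows))
}

plant_fragile_sites <- function(cfg, lens) {
  spacing <- 20 * cfg$sv_max_gap
  slots <- list()
  for (ch in names(lens)) {
    n_slots <- floor((lens[[ch]] - cfg$fragile_width) / spacing)
    if (n_slots < 1) next
    for (k in seq_len(n_slots))
      slots[[length(slots) + 1L]] <- c(ch, (k - 1) * spacing + 1)
  }
  check_that(length(slots) >= cfg$n_fragile_sites,
             "genome too small for the requested fragile sites")
  pick <- sample.int(length(slots), cfg$n_fragile_sites)
  out <- do.call(rbind, lapply(seq_along(pick), function(j) {
    sl <- slots[[pick[j]]]
    start <- as.numeric(sl[2]) +
      sample.int(max(1, spacing - cfg$fragile_width - 4 * cfg$sv_max_gap), 1)
    data.frame(name = sprintf("FS%02d", j), chrom = sl[1],
               start = as.integer(start),
               end = as.integer(start + cfg$fragile_width - 1L),
               stringsAsFactors = FALSE)
  }))
  out
}

simulate_sample <- function(cfg, reference, idx, sites, all_runs, fragile,
                            m) {
  age <- m$age
  uv_med <- cfg$uv_median[[m$race]]
  n_cpg <- rpois(1, cfg$cpg_slope * age + cfg$cpg_intercept)
  n_uv <- if (uv_med > 0) round(rlnorm(1, log(uv_med), cfg$uv_sdlog)) else 0L
  n_cc <- round(cfg$cc_tt_fraction * n_uv)
  n_ntt <- round(cfg$ntt_fraction * n_uv)
  n_bg <- if (cfg$background_median > 0)
    round(rlnorm(1, log(cfg$background_median), cfg$background_sdlog)) else 0L

  rec <- function(chrom, pos, ref, alt, process)
    if (length(pos) == 0) NULL else
      data.frame(sample_id = m$sample_id, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, process = process,
                 stringsAsFactors = FALSE)
  parts <- list()
  # UV yCn->yTn: C->T on the strand where the 5' neighbour is a pyrimidine
  if (n_uv > 0) {
    s <- draw_sites(sites$ycn, n_uv, "UV")
    parts$uv <- rec(s$chrom, s$pos, ifelse(s$strand == "+", "C", "G"),
                    ifelse(s$strand == "+", "T", "A"), "uv")
  }
  if (n_cc > 0) {
    s <- draw_sites(sites$cc, n_cc, "CC->TT")
    both <- data.frame(chrom = rep(s$chrom, each = 2),
                       pos = as.vector(rbind(s$pos, s$pos + 1L)),
                       strand = rep(s$strand, each = 2),
                       stringsAsFactors = FALSE)
    parts$uv_cc <- rec(both$chrom, both$pos,
                       ifelse(both$strand == "+", "C", "G"),
                       ifelse(both$strand == "+", "T", "A"), "uv_cc")
  }
  if (n_ntt > 0) {
    s <- draw_sites(sites$ntt, n_ntt, "nTt->nCt")
    parts$uv_ntt <- rec(s$chrom, s$pos, ifelse(s$strand == "+", "T", "A"),
                        ifelse(s$strand == "+", "C", "G"), "uv_ntt")
  }
  if (n_cpg > 0) {
    s <- draw_sites(sites$cpg, n_cpg, "CpG")
    minus <- runif(nrow(s)) < 0.5
    parts$cpg <- rec(s$chrom, ifelse(minus, s$pos + 1L, s$pos),
                     ifelse(minus, "G", "C"), ifelse(minus, "A", "T"), "cpg")
  }
  if (n_bg > 0) {
    bg <- draw_uniform_snvs(idx, n_bg)
    parts$bg <- rec(bg$chrom, bg$pos, bg$ref, bg$alt, "background")
  }
  snvs <- do.call(rbind, parts)
  if (is.null(snvs)) snvs <- cbind(empty_snvs()[0, c("sample_id", "chrom",
                                                     "pos", "ref", "alt")],
                                   process = character(0))
  # one record per genomic position per sample; UV/CC/nTt/CpG take priority
  snvs <- snvs[!duplicated(paste(snvs$chrom, snvs$pos)), , drop = FALSE]
  snvs$vaf <- draw_vafs(nrow(snvs), cfg)
  # sub-clonal culture artifacts
  n_art <- round(cfg$artifact_rate * nrow(snvs))
  if (n_art > 0) {
    a <- draw_uniform_snvs(idx, n_art)
    keep <- !(paste(a$chrom, a$pos) %in% paste(snvs$chrom, snvs$pos))
    art <- rec(a$chrom[keep], a$pos[keep], a$ref[keep], a$alt[keep],
               "artifact")
    if (!is.null(art)) {
      art$vaf <- runif(nrow(art), 0.05, 0.35)
      snvs <- rbind(snvs, art)
    }
  }
  snvs$qual <- rep(NA_real_, nrow(snvs))
  snvs$zygosity_call <- rep(NA_character_, nrow(snvs))

  indels <- simulate_sample_indels(cfg, reference, all_runs, m, age, n_uv)
  svs <- simulate_sample_svs(cfg, reference, fragile, m)

  counts <- data.frame(
    sample_id = m$sample_id, age = age, race = m$race,
    cell_type = m$cell_type,
    n_background = sum(snvs$process == "background"),
    n_cpg = sum(snvs$process == "cpg"),
    n_uv = sum(snvs$process == "uv"),
    n_uv_cc_records = sum(snvs$process == "uv_cc"),
    n_uv_ntt = sum(snvs$process == "uv_ntt"),
    n_artifact = sum(snvs$process == "artifact"),
    n_snv_clonal = sum(snvs$process != "artifact"),
    n_hp_indel = sum(indels$class == "homopolymer"),
    n_del_ge5 = sum(indels$class == "deletion_ge5"),
    n_ins_templated = sum(indels$class %in% c("ins_templated",
                                              "ins_templated_mm")),
    n_indel_artifact = sum(indels$class == "artifact"),
    n_sv_clonal = sum(svs$clonal),
    n_sv_artifact = sum(!svs$clonal),
    stringsAsFactors = FALSE)
  list(snvs = snvs, indels = indels, svs = svs, counts = counts)
}

simulate_sample_indels <- function(cfg, reference, all_runs, m, age, n_uv) {
  seqs <- unclass(reference)
  acc <- new.env(parent = emptyenv())
  acc$chrom <- character(0); acc$pos <- integer(0)
  acc$ref_allele <- character(0); acc$alt_allele <- character(0)
  acc$qual <- numeric(0); acc$class <- character(0); acc$mh <- integer(0)
  add <- function(chrom, pos, ref_allele, alt_allele, qual, class, mh = NA) {
    acc$chrom <- c(acc$chrom, chrom)
    acc$pos <- c(acc$pos, as.integer(pos))
    acc$ref_allele <- c(acc$ref_allele, ref_allele)
    acc$alt_allele <- c(acc$alt_allele, alt_allele)
    acc$qual <- c(acc$qual, qual)
    acc$class <- c(acc$class, class)
    acc$mh <- c(acc$mh, as.integer(mh))
  }
  good_qual <- function() runif(1, 55, 99)
  # homopolymer 1 bp slippage indels, linear in age
  n_hp <- rpois(1, cfg$homopolymer_indel_slope * age)
  check_that(n_hp == 0 || !is.null(all_runs),
             "reference has no homopolymer runs for slippage indels")
  if (n_hp > 0) {
    pick <- sample.int(nrow(all_runs), n_hp, replace = TRUE)
    is_del <- runif(n_hp) < 0.5
    for (k in seq_len(n_hp)) {
      ch <- all_runs$chrom[pick[k]]
      base <- all_runs$base[pick[k]]
      anchor_pos <- all_runs$start[pick[k]] - 1L
      anchor <- substr(seqs[[ch]], anchor_pos, anchor_pos)
      if (is_del[k])
        add(ch, anchor_pos, paste0(anchor, base), anchor, good_qual(),
            "homopolymer")
      else
        add(ch, anchor_pos, anchor, paste0(anchor, base), good_qual(),
            "homopolymer")
    }
  }
  # >= 5 bp deletions coupled to the UV load, with junction microhomology
  n_d5 <- rpois(1, cfg$deletion_ge5_base + cfg$deletion_ge5_per_uv * n_uv)
  mh_lens <- as.integer(names(cfg$mh_probs))
  for (k in seq_len(n_d5)) {
    target <- sample(mh_lens, 1, prob = cfg$mh_probs)
    ch <- sample(names(seqs), 1)
    sq <- seqs[[ch]]
    L <- 5L + rpois(1, 5)
    got <- NULL
    for (try in 1:200) {
      s <- sample.int(nchar(sq) - 3L * L - 2L, 1) + L
      D <- substr(sq, s, s + L - 1L)
      right <- substr(sq, s + L, s + 2L * L - 1L)
      left <- substr(sq, s - L, s - 1L)
      mh <- min(max(lcp_len(D, right), lcs_len(D, left)), L)
      if (mh == target) { got <- list(s = s, L = L, mh = mh); break }
      got <- list(s = s, L = L, mh = mh)
    }
    add(ch, got$s - 1L, substr(sq, got$s - 1L, got$s + got$L - 1L),
        substr(sq, got$s - 1L, got$s - 1L), good_qual(), "deletion_ge5",
        got$mh)
  }
  # insertions
  rnd_pos <- function(ch, pad) sample.int(nchar(seqs[[ch]]) - 2L * pad, 1) + pad
  n_i1 <- rpois(1, cfg$ins_1bp_mean)
  for (k in seq_len(n_i1)) {
    ch <- sample(names(seqs), 1); sq <- seqs[[ch]]
    p <- rnd_pos(ch, 10L)
    anchor <- substr(sq, p, p)
    if (runif(1) < cfg$ins_1bp_templated) {
      add(ch, p, anchor, paste0(anchor, anchor), good_qual(), "ins_templated")
    } else {
      avoid <- c(anchor, substr(sq, p + 1L, p + 1L))
      b <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
      add(ch, p, anchor, paste0(anchor, b), good_qual(), "ins_other")
    }
  }
  n_i2 <- rpois(1, cfg$ins_2bp_mean)
  for (k in seq_len(n_i2)) {
    ch <- sample(names(seqs), 1); sq <- seqs[[ch]]
    p <- rnd_pos(ch, 10L)
    anchor <- substr(sq, p, p)
    S <- paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
               collapse = "")
    add(ch, p, anchor, paste0(anchor, S), good_qual(), "ins_other")
  }
  n_il <- rpois(1, cfg$ins_long_mean)
  for (k in seq_len(n_il)) {
    ch <- sample(names(seqs), 1); sq <- seqs[[ch]]
    L <- sample(3:8, 1)
    p <- rnd_pos(ch, L + 10L)
    anchor <- substr(sq, p, p)
    if (runif(1) < cfg$ins_long_templated) {
      S <- substr(sq, p - L + 1L, p)
      cls <- "ins_templated"
      if (runif(1) < cfg$ins_long_mismatch) {
        at <- sample.int(L, 1)
        old <- substr(S, at, at)
        substr(S, at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        cls <- "ins_templated_mm"
      }
      add(ch, p, anchor, paste0(anchor, S), good_qual(), cls)
    } else {
      S <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      add(ch, p, anchor, paste0(anchor, S), good_qual(), "ins_other")
    }
  }
  # low-quality artifact indels (removed by the quality filter)
  n_true <- length(acc$pos)
  n_art <- round(cfg$indel_artifact_rate * n_true)
  for (k in seq_len(n_art)) {
    ch <- sample(names(seqs), 1); sq <- seqs[[ch]]
    p <- rnd_pos(ch, 10L)
    anchor <- substr(sq, p, p)
    b <- sample(c("A", "C", "G", "T"), 1)
    if (runif(1) < 0.5)
      add(ch, p, paste0(anchor, substr(sq, p + 1L, p + 1L)), anchor,
          runif(1, 5, 49), "artifact")
    else
      add(ch, p, anchor, paste0(anchor, b), runif(1, 5, 49), "artifact")
  }
  out <- data.frame(sample_id = rep(m$sample_id, length(acc$pos)),
                    chrom = acc$chrom, pos = acc$pos,
                    ref_allele = acc$ref_allele,
                    alt_allele = acc$alt_allele, qual = acc$qual,
                    vaf = draw_vafs(length(acc$pos), cfg),
                    class = acc$class, planted_mh = acc$mh,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  out$kind <- ifelse(nchar(out$ref_allele) > nchar(out$alt_allele),
                     "deletion", "insertion")
  out$length <- abs(nchar(out$ref_allele) - nchar(out$alt_allele))
  out$zygosity_call <- rep(NA_character_, nrow(out))
  out
}

simulate_sample_svs <- function(cfg, reference, fragile, m) {
  empty <- data.frame(sample_id = character(0), sv_type = character(0),
                      chrom1 = character(0), pos1 = integer(0),
                      chrom2 = character(0), pos2 = integer(0),
                      junction_reads_variant = integer(0),
                      junction_reads_total = integer(0),
                      blood_variant_reads = integer(0),
                      inserted_or_mh_seq = character(0),
                      pass_filter = logical(0), in_fragile = logical(0),
                      planted_mh = integer(0), clonal = logical(0),
                      stringsAsFactors = FALSE)
  if (m$wga) return(empty)  # amplified genomes give unreliable SV calls
  seqs <- unclass(reference)
  lens <- seq_lengths(reference)
  n_sv <- if (cfg$sv_mean > 0) min(14L, 1L + rpois(1, cfg$sv_mean)) else 0L
  n_art <- round(cfg$sv_artifact_rate * n_sv)
  rows <- list()
  mh_lens <- as.integer(names(cfg$sv_mh_probs))
  for (k in seq_len(n_sv + n_art)) {
    clonal <- k <= n_sv
    type <- sample(c("DEL", "DUP", "INV", "TRA"), 1,
                   prob = c(0.45, 0.2, 0.2, 0.15))
    in_frag <- runif(1) < cfg$sv_hotspot_weight
    if (in_frag) {
      fr <- fragile[sample.int(nrow(fragile), 1), ]
      ch1 <- fr$chrom
      p1 <- fr$start + sample.int(cfg$fragile_width, 1) - 1L
    } else {
      ch1 <- sample(names(lens), 1)
      p1 <- sample.int(lens[[ch1]] - 100L, 1) + 50L
    }
    if (type == "TRA") {
      ch2 <- sample(names(lens), 1)
      p2 <- sample.int(lens[[ch2]] - 100L, 1) + 50L
      planted_mh <- NA_integer_
    } else {
      ch2 <- ch1
      size <- round(rlnorm(1, log(5e3), 0.8))
      size <- max(250L, min(size, lens[[ch1]] - p1 - 60L))
      p2 <- p1 + size
      planted_mh <- NA_integer_
      if (type == "DEL") {
        target <- sample(mh_lens, 1, prob = cfg$sv_mh_probs)
        sq <- seqs[[ch1]]
        best <- p2
        for (try in 1:200) {
          cand <- p1 + size + sample.int(60L, 1) - 30L
          if (cand <= p1 + 1L || cand >= lens[[ch1]] - 25L) next
          mh <- max(lcp_len(substr(sq, p1 + 1L, p1 + 20L),
                            substr(sq, cand + 1L, cand + 20L)),
                    lcs_len(substr(sq, max(1L, p1 - 19L), p1),
                            substr(sq, cand - 19L, cand)))
          best <- cand
          if (mh == target) break
        }
        p2 <- best
        planted_mh <- max(lcp_len(substr(seqs[[ch1]], p1 + 1L, p1 + 20L),
                                  substr(seqs[[ch1]], p2 + 1L, p2 + 20L)),
                          lcs_len(substr(seqs[[ch1]], max(1L, p1 - 19L), p1),
                                  substr(seqs[[ch1]], max(1L, p2 - 19L), p2)))
      }
    }
    total <- 10L + rpois(1, 20)
    if (clonal) {
      variant <- max(ceiling(0.3 * total),
                     rbinom(1, total, runif(1, 0.35, 0.6)))
      blood <- 0L
      pass <- TRUE
    } else if (runif(1) < 0.5) {
      variant <- floor(runif(1, 0, 0.29) * total)
      blood <- 0L
      pass <- TRUE
    } else {
      variant <- max(ceiling(0.3 * total), rbinom(1, total, 0.4))
      blood <- sample(1:3, 1)
      pass <- runif(1) > 0.3
    }
    rows[[length(rows) + 1L]] <- list(
      sv_type = type, chrom1 = ch1, pos1 = as.integer(p1), chrom2 = ch2,
      pos2 = as.integer(p2), variant = as.integer(variant), total = total,
      blood = blood, pass = pass, in_frag = in_frag,
      planted_mh = planted_mh, clonal = clonal)
  }
  if (length(rows) == 0) return(empty)
  g <- function(f) unlist(lapply(rows, `[[`, f))
  data.frame(
    sample_id = rep(m$sample_id, length(rows)), sv_type = g("sv_type"),
    chrom1 = g("chrom1"), pos1 = g("pos1"), chrom2 = g("chrom2"),
    pos2 = g("pos2"), junction_reads_variant = g("variant"),
    junction_reads_total = g("total"), blood_variant_reads = g("blood"),
    inserted_or_mh_seq = NA_character_, pass_filter = g("pass"),
    in_fragile = g("in_frag"),
    planted_mh = vapply(rows, function(r)
      if (is.na(r$planted_mh)) NA_integer_ else as.integer(r$planted_mh),
      integer(1)),
    clonal = g("clonal"), stringsAsFactors = FALSE)
}
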