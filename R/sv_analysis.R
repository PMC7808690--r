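# Structural-variant analyses: recurrent-breakage hotspot clustering,
# common-fragile-site (CFS) colocalization, breakpoint junction
# microhomology and the two association tests (Fisher on microhomology x
# CFS, chi-square on SV type x CFS).

# breakpoint table: one row per breakpoint with its SV row index
sv_breakpoints <- function(svs) {
  data.frame(
    sv = rep(seq_len(nrow(svs)), 2L),
    sample_id = rep(svs$sample_id, 2L),
    chrom = c(svs$chrom1, svs$chrom2),
    pos = c(svs$pos1, svs$pos2),
    stringsAsFactors = FALSE)
}

#' Call rearrangement hotspots
#'
#' Breakpoints on each chromosome are chained by single linkage: consecutive
#' breakpoints at most `max_gap` apart join one chain. A chain is a hotspot
#' when it contains breakpoints of two or more SVs from different samples.
#' An SV is "in a hotspot" when any of its breakpoints is. DEL/DUP/INV
#' contribute both ends (each SV counted once per chain); TRA ends fall on
#' their own chromosomes.
#'
#' @param svs validated SV data.frame
#' @param max_gap maximum breakpoint spacing within a chain in bp
#'   (default 1e6)
#' @return list with `hotspots` (one row per hotspot: chrom, span, number of
#'   member SVs and distinct samples) and `in_hotspot` (logical per SV)
#' @export
call_hotspots <- function(svs, max_gap = 1e6) {
  svs <- validate_svs(svs)
  in_hot <- rep(FALSE, nrow(svs))
  hs <- list()
  if (nrow(svs) > 0) {
    bp <- sv_breakpoints(svs)
    for (ch in unique(bp$chrom)) {
      b <- bp[bp$chrom == ch, , drop = FALSE]
      b <- b[order(b$pos), , drop = FALSE]
      chain_id <- cumsum(c(1L, diff(b$pos) > max_gap))
      for (cid in unique(chain_id)) {
        mem <- b[chain_id == cid, , drop = FALSE]
        sv_ids <- unique(mem$sv)
        n_samp <- length(unique(mem$sample_id))
        if (length(sv_ids) >= 2 && n_samp >= 2) {
          in_hot[sv_ids] <- TRUE
          hs[[length(hs) + 1L]] <- data.frame(
            id = length(hs) + 1L, chrom = ch,
            start = min(mem$pos), end = max(mem$pos),
            n_sv = length(sv_ids), n_samples = n_samp,
            sv_rows = paste(sort(sv_ids), collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hotspots <- if (length(hs)) do.call(rbind, hs) else
    data.frame(id = integer(0), chrom = character(0), start = integer(0),
               end = integer(0), n_sv = integer(0), n_samples = integer(0),
               sv_rows = character(0), stringsAsFactors = FALSE)
  list(hotspots = hotspots, in_hotspot = in_hot)
}

#' Annotate SVs with common-fragile-site overlap
#'
#' DEL/DUP/INV are flagged when the interval `[pos1, pos2]` overlaps a CFS
#' interval by at least 1 bp (`interval_intersection` rule); translocations
#' when either breakpoint lies inside a CFS or within `tra_window` bp of
#' its boundary (`breakpoint_window` rule).
#'
#' @param svs validated SV data.frame
#' @param cfs_intervals `GRanges` of fragile-site intervals (1-based
#'   inclusive, e.g. from [read_intervals()]); names are reported when set
#' @param tra_window breakpoint window for translocations in bp
#'   (default 1e4)
#' @return data.frame with `overlaps_cfs`, `cfs_names`, `rule_used` per SV
#' @export
annotate_cfs <- function(svs, cfs_intervals, tra_window = 1e4) {
  svs <- validate_svs(svs)
  n <- nrow(svs)
  out <- data.frame(overlaps_cfs = rep(FALSE, n),
                    cfs_names = rep(NA_character_, n),
                    rule_used = ifelse(svs$sv_type == "TRA",
                                       "breakpoint_window",
                                       "interval_intersection"),
                    stringsAsFactors = FALSE)
  if (n == 0 || length(cfs_intervals) == 0) return(out)
  nm <- names(cfs_intervals)
  if (is.null(nm)) nm <- as.character(seq_along(cfs_intervals))
  join_names <- function(hits) if (length(hits)) paste(unique(nm[hits]),
                                                       collapse = ",") else
    NA_character_
  intra <- which(svs$sv_type != "TRA")
  if (length(intra)) {
    gr <- GenomicRanges::GRanges(svs$chrom1[intra],
                                 IRanges::IRanges(svs$pos1[intra],
                                                  svs$pos2[intra]))
    # suppressWarnings: SV chromosomes absent from the CFS set are expected
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, cfs_intervals))
    for (k in seq_along(intra)) {
      hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]
      if (length(hits)) {
        out$overlaps_cfs[intra[k]] <- TRUE
        out$cfs_names[intra[k]] <- join_names(hits)
      }
    }
  }
  tra <- which(svs$sv_type == "TRA")
  if (length(tra)) {
    wide <- GenomicRanges::resize(cfs_intervals,
                                  GenomicRanges::width(cfs_intervals) +
                                    2 * tra_window, fix = "center")
    for (k in tra) {
      hits <- integer(0)
      for (end in 1:2) {
        ch <- if (end == 1) svs$chrom1[k] else svs$chrom2[k]
        p <- if (end == 1) svs$pos1[k] else svs$pos2[k]
        g <- GenomicRanges::GRanges(ch, IRanges::IRanges(p, p))
        ov <- suppressWarnings(GenomicRanges::findOverlaps(g, wide))
        hits <- c(hits, S4Vectors::subjectHits(ov))
      }
      if (length(hits)) {
        out$overlaps_cfs[k] <- TRUE
        out$cfs_names[k] <- join_names(hits)
      }
    }
  }
  out
}

#' Breakpoint junction microhomology of an SV
#'
#' Length of the maximal identical sequence shared by the two joined ends
#' at the junction, in junction orientation (same prefix/suffix logic as
#' indel junction microhomology): for a DEL the removed segment is
#' `(pos1, pos2]`; for a DUP the tandem junction joins the segment end back
#' to its start; for an INV the first junction joins the left flank to the
#' reverse complement of the segment end; for a TRA a same-orientation
#' join of the two breakpoints is assumed. Flanks truncated by contig edges
#' are compared on the available bases.
#'
#' @param sv one-row SV data.frame
#' @param reference `ref_genome`
#' @param max_check maximum microhomology length searched (default 20)
#' @return microhomology length (integer >= 0)
#' @export
breakpoint_microhomology <- function(sv, reference, max_check = 20) {
  seqs <- unclass(reference)
  check_that(sv$chrom1 %in% names(seqs) && sv$chrom2 %in% names(seqs),
             "unknown chromosome on SV record")
  K <- max_check
  s1 <- seqs[[sv$chrom1]]; s2 <- seqs[[sv$chrom2]]
  n1 <- nchar(s1); n2 <- nchar(s2)
  p1 <- sv$pos1; p2 <- sv$pos2
  right_of <- function(sq, p, n) substr(sq, p + 1L, min(n, p + K))
  left_of <- function(sq, p) substr(sq, max(1L, p - K + 1L), p)
  mh <- switch(sv$sv_type,
    DEL = max(lcp_len(right_of(s1, p1, n1), right_of(s1, p2, n1)),
              lcs_len(left_of(s1, p1), left_of(s1, p2))),
    DUP = max(lcp_len(substr(s1, p1, min(n1, p1 + K - 1L)),
                      right_of(s1, p2, n1)),
              lcs_len(left_of(s1, p1 - 1L), left_of(s1, p2))),
    INV = max(lcp_len(right_of(s1, p1, n1),
                      revcomp(left_of(s1, p2))),
              lcs_len(left_of(s1, p1), revcomp(right_of(s1, p2, n1)))),
    TRA = max(lcp_len(right_of(s1, p1, n1), right_of(s2, p2, n2)),
              lcs_len(left_of(s1, p1), left_of(s2, p2))))
  as.integer(mh)
}

#' Fisher test of microhomology use inside vs outside fragile sites
#'
#' Builds the 2x2 table `[[MH & CFS, noMH & CFS], [MH & !CFS,
#' noMH & !CFS]]`, where microhomology is "present" when `mh_length >=
#' mh_min`, and tests it two-sided.
#'
#' @param mh_length integer vector of per-SV junction microhomology lengths
#' @param overlaps_cfs logical vector of per-SV CFS overlap flags
#' @param mh_min minimum length counted as microhomology (default 2)
#' @return list with `table` and two-sided `p`
#' @export
mh_cfs_fisher <- function(mh_length, overlaps_cfs, mh_min = 2) {
  check_that(length(mh_length) > 0, "empty input")
  check_that(length(mh_length) == length(overlaps_cfs),
             "inputs differ in length")
  mh <- mh_length >= mh_min
  tab <- matrix(c(sum(mh & overlaps_cfs), sum(!mh & overlaps_cfs),
                  sum(mh & !overlaps_cfs), sum(!mh & !overlaps_cfs)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("CFS", "noCFS"), c("MH", "noMH")))
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}

#' Chi-square test of SV type composition inside vs outside fragile sites
#'
#' Pearson chi-square without continuity correction on the SV type x CFS
#' contingency table; zero rows/columns are dropped with a warning.
#'
#' @param sv_type character vector of SV types
#' @param overlaps_cfs logical vector of CFS overlap flags
#' @return list with `statistic`, `p`, `expected` and the tested `table`
#' @export
svtype_cfs_chisq <- function(sv_type, overlaps_cfs) {
  tab <- table(sv_type, factor(overlaps_cfs, levels = c(FALSE, TRUE)))
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c))
    warning("dropping zero rows/columns from the contingency table")
  tab <- tab[keep_r, keep_c, drop = FALSE]
  check_that(nrow(tab) >= 2 && ncol(tab) >= 2,
             "contingency table degenerate after dropping zero margins")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       expected = ct$expected, table = tab)
}

#' Full per-SV annotation
#'
#' Convenience wrapper combining [call_hotspots()], [annotate_cfs()] and
#' [breakpoint_microhomology()].
#'
#' @param svs validated SV data.frame
#' @param reference `ref_genome` (NULL to skip microhomology)
#' @param cfs_intervals `GRanges` of fragile sites (NULL to skip)
#' @param max_gap hotspot chaining gap (default 1e6)
#' @param tra_window translocation CFS window (default 1e4)
#' @return `svs` with `in_hotspot`, `overlaps_cfs`, `cfs_names`,
#'   `mh_length` columns appended
#' @export
annotate_sv_catalog <- function(svs, reference = NULL, cfs_intervals = NULL,
                                max_gap = 1e6, tra_window = 1e4) {
  svs <- validate_svs(svs)
  svs$in_hotspot <- call_hotspots(svs, max_gap)$in_hotspot
  if (!is.null(cfs_intervals)) {
    ann <- annotate_cfs(svs, cfs_intervals, tra_window)
    svs$overlaps_cfs <- ann$overlaps_cfs
    svs$cfs_names <- ann$cfs_names
  }
  if (!is.null(reference)) {
    svs$mh_length <- vapply(seq_len(nrow(svs)), function(i)
      breakpoint_microhomology(svs[i, , drop = FALSE], reference),
      integer(1))
  }
  svs
}
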