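# Filtering rules that turn raw per-caller somatic call sets into clonal
# somatic catalogs: caller consensus, allele-fraction clonality bands,
# region masks / known-variant removal, indel quality, SV clonality.

#' Default filter configuration
#'
#' Clonality bands and thresholds: heterozygous calls are kept at allele
#' fractions in \[0.45, 0.55\]; homozygous SNVs above 0.90 (strict),
#' homozygous indels in \[0.90, 1\] (the indel band is stated inclusive);
#' indels need quality >= 50; clonal SVs need >= 30% variant junction reads
#' and zero variant reads in blood.
#'
#' @param het_lo,het_hi heterozygous allele-fraction band
#' @param hom_lo homozygous allele-fraction threshold
#' @param indel_min_qual minimum indel quality score
#' @param sv_min_junction_fraction minimum variant junction-read fraction
#' @param sv_max_blood_reads maximum variant-supporting reads in blood
#' @return list of class `filter_config`
#' @export
filter_config <- function(het_lo = 0.45, het_hi = 0.55, hom_lo = 0.90,
                          indel_min_qual = 50,
                          sv_min_junction_fraction = 0.30,
                          sv_max_blood_reads = 0) {
  check_that(0 <= het_lo && het_lo < het_hi && het_hi <= hom_lo && hom_lo <= 1,
             "need 0 <= het_lo < het_hi <= hom_lo <= 1")
  structure(list(het_lo = het_lo, het_hi = het_hi, hom_lo = hom_lo,
                 indel_min_qual = indel_min_qual,
                 sv_min_junction_fraction = sv_min_junction_fraction,
                 sv_max_blood_reads = sv_max_blood_reads),
            class = "filter_config")
}

snv_keys <- function(df) {
  paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Consensus of several callers' SNV call sets
#'
#' Only substitutions reported by every caller are kept (set intersection
#' on the key sample, chrom, pos, ref, alt).
#'
#' @param call_sets list of SNV data.frames (or key character vectors), one
#'   per caller
#' @return records of the first call set present in all others
#' @export
consensus_snvs <- function(call_sets) {
  check_that(is.list(call_sets) && length(call_sets) >= 1,
             "need at least one call set")
  keys <- lapply(call_sets, function(x)
    if (is.character(x)) x else snv_keys(validate_snvs(x)))
  common <- Reduce(intersect, keys)
  first <- call_sets[[1]]
  if (is.character(first)) return(common)
  first[keys[[1]] %in% common, , drop = FALSE]
}

#' Partition records into clonal and sub-clonal by allele fraction
#'
#' Records in the heterozygous band get `zygosity_call = "het"`, records at
#' homozygous fractions `"hom"`; everything else is sub-clonal and removed.
#' For SNVs the homozygous rule is `vaf > hom_lo` (strict); for indels it is
#' `vaf >= hom_lo` (the stated indel band is 90-100% inclusive).
#'
#' @param records SNV or indel data.frame with a `vaf` column
#' @param cfg [filter_config()]
#' @param type "snv" or "indel"
#' @return list with `kept` (zygosity_call set) and `removed`
#' @export
filter_clonal_af <- function(records, cfg = filter_config(),
                             type = c("snv", "indel")) {
  type <- match.arg(type)
  check_that("vaf" %in% names(records), "records need a vaf column")
  check_that(!anyNA(records$vaf), "vaf missing on some records")
  check_that(all(records$vaf >= 0 & records$vaf <= 1), "vaf outside [0, 1]")
  het <- records$vaf >= cfg$het_lo & records$vaf <= cfg$het_hi
  hom <- if (type == "snv") records$vaf > cfg$hom_lo else
    records$vaf >= cfg$hom_lo
  call <- ifelse(het, "het", ifelse(hom, "hom", "subclonal"))
  records$zygosity_call <- call
  list(kept = records[call != "subclonal", , drop = FALSE],
       removed = records[call == "subclonal", , drop = FALSE])
}

#' Remove records overlapping masks or matching known variants
#'
#' A record is removed if its position (for indels: any base of the changed
#' span) overlaps any provided mask interval, or if its key matches the
#' known-variant set (dbSNP-style). Known variants are matched
#' allele-aware on `chrom:pos:ref:alt` by default; `position_only = TRUE`
#' matches on `chrom:pos`.
#'
#' @param records SNV or indel data.frame
#' @param masks list of `GRanges` mask interval sets (may be empty)
#' @param known_variants character vector of known-variant keys
#'   ("chrom:pos:ref:alt", or "chrom:pos" with `position_only`)
#' @param type "snv" or "indel"
#' @param position_only match known variants on position alone
#' @return kept records
#' @export
filter_masks <- function(records, masks = list(), known_variants = character(0),
                         type = c("snv", "indel"), position_only = FALSE) {
  type <- match.arg(type)
  if (nrow(records) == 0) return(records)
  if (type == "snv") {
    start <- records$pos; end <- records$pos
  } else {
    records <- validate_indels(records)
    # deletions change bases pos+1 .. pos+length; insertions sit between
    # pos and pos+1, so both flanking bases are the changed span
    del <- records$kind == "deletion"
    start <- ifelse(del, records$pos + 1L, records$pos)
    end <- ifelse(del, records$pos + records$length, records$pos + 1L)
  }
  drop <- rep(FALSE, nrow(records))
  if (length(masks) > 0) {
    rec_gr <- GenomicRanges::GRanges(records$chrom,
                                     IRanges::IRanges(start, end))
    for (m in masks) {
      if (length(m) == 0) next
      drop <- drop | IRanges::overlapsAny(rec_gr, m)
    }
  }
  if (length(known_variants) > 0) {
    keys <- if (position_only) paste(records$chrom, records$pos, sep = ":")
            else if (type == "snv")
              paste(records$chrom, records$pos, records$ref, records$alt,
                    sep = ":")
            else
              paste(records$chrom, records$pos, records$ref_allele,
                    records$alt_allele, sep = ":")
    drop <- drop | keys %in% known_variants
  }
  records[!drop, , drop = FALSE]
}

#' Filter indels on caller quality score
#' @param indels indel data.frame with `qual`
#' @param cfg [filter_config()]
#' @return indels with quality >= `indel_min_qual`
#' @export
filter_indel_quality <- function(indels, cfg = filter_config()) {
  check_that(!anyNA(indels$qual), "qual missing on some indels")
  indels[indels$qual >= cfg$indel_min_qual, , drop = FALSE]
}

#' Keep clonal structural variants
#'
#' Clonal SVs have at least `sv_min_junction_fraction` of junction reads
#' supporting the variant and at most `sv_max_blood_reads` supporting reads
#' in the matched blood genome. Records with `pass_filter == FALSE`
#' (caller-level LowQual/IMPRECISE) are dropped first.
#'
#' @param svs validated SV data.frame
#' @param cfg [filter_config()]
#' @return kept SV records
#' @export
filter_sv_clonality <- function(svs, cfg = filter_config()) {
  svs <- validate_svs(svs)
  check_that(all(svs$junction_reads_total > 0),
             "junction_reads_total must be > 0")
  svs <- svs[svs$pass_filter, , drop = FALSE]
  frac <- svs$junction_reads_variant / svs$junction_reads_total
  keep <- frac >= cfg$sv_min_junction_fraction &
    svs$blood_variant_reads <= cfg$sv_max_blood_reads
  svs[keep, , drop = FALSE]
}
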