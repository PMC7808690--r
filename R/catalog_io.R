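# Reading and writing of variant catalogs and interval files.
#
# Internal conventions (used everywhere downstream):
#   * coordinates are 1-based inclusive (VCF convention); BED input is
#     converted here and nowhere else (rtracklayer does the conversion),
#   * indels are stored VCF-style: `pos` is the base before the event, and
#     exactly one of ref_allele/alt_allele is a strict prefix of the other,
#   * a catalog is a list with data.frames `snvs` and `indels`.

SNV_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "vaf", "qual",
              "zygosity_call")
INDEL_COLS <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                "kind", "length", "qual", "vaf", "zygosity_call")

empty_snvs <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             vaf = numeric(0), qual = numeric(0),
             zygosity_call = character(0), stringsAsFactors = FALSE)
}

empty_indels <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = integer(0), ref_allele = character(0),
             alt_allele = character(0), kind = character(0),
             length = integer(0), qual = numeric(0), vaf = numeric(0),
             zygosity_call = character(0), stringsAsFactors = FALSE)
}

#' Validate an SNV catalog data.frame
#' @param snvs data.frame with columns sample_id, chrom, pos, ref, alt, vaf
#' @return the validated data.frame (with missing optional columns added)
#' @export
validate_snvs <- function(snvs) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "vaf")
  miss <- setdiff(need, names(snvs))
  check_that(length(miss) == 0, "snvs missing column(s): ",
             paste(miss, collapse = ", "))
  if (!"qual" %in% names(snvs)) snvs$qual <- rep(NA_real_, nrow(snvs))
  if (!"zygosity_call" %in% names(snvs))
    snvs$zygosity_call <- rep(NA_character_, nrow(snvs))
  snvs$pos <- as.integer(snvs$pos)
  snvs$ref <- toupper(snvs$ref)
  snvs$alt <- toupper(snvs$alt)
  check_that(all(snvs$pos >= 1L), "SNV pos must be >= 1")
  check_that(all(snvs$ref %in% c("A", "C", "G", "T")), "SNV ref must be a single base")
  check_that(all(snvs$alt %in% c("A", "C", "G", "T")), "SNV alt must be a single base")
  check_that(all(snvs$ref != snvs$alt), "SNV ref must differ from alt")
  ok_vaf <- is.na(snvs$vaf) | (snvs$vaf >= 0 & snvs$vaf <= 1)
  check_that(all(ok_vaf), "vaf outside [0, 1]")
  snvs[SNV_COLS]
}

#' Validate an indel catalog data.frame
#' @param indels data.frame with columns sample_id, chrom, pos, ref_allele,
#'   alt_allele (VCF-style, shared anchor base) plus optional qual/vaf
#' @return validated data.frame with derived `kind` and `length`
#' @export
validate_indels <- function(indels) {
  need <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(indels))
  check_that(length(miss) == 0, "indels missing column(s): ",
             paste(miss, collapse = ", "))
  if (!"qual" %in% names(indels)) indels$qual <- rep(NA_real_, nrow(indels))
  if (!"vaf" %in% names(indels)) indels$vaf <- rep(NA_real_, nrow(indels))
  if (!"zygosity_call" %in% names(indels))
    indels$zygosity_call <- rep(NA_character_, nrow(indels))
  indels$pos <- as.integer(indels$pos)
  indels$ref_allele <- toupper(indels$ref_allele)
  indels$alt_allele <- toupper(indels$alt_allele)
  ra <- indels$ref_allele
  aa <- indels$alt_allele
  check_that(all(nchar(ra) >= 1 & nchar(aa) >= 1), "empty allele")
  is_prefix <- function(short, long) substr(long, 1L, nchar(short)) == short
  del <- nchar(ra) > nchar(aa)
  pref_ok <- ifelse(del, is_prefix(aa, ra), is_prefix(ra, aa))
  check_that(all(nchar(ra) != nchar(aa)),
             "indel alleles must differ in length")
  check_that(all(pref_ok),
             "one allele must be a strict prefix of the other")
  indels$kind <- ifelse(del, "deletion", "insertion")
  indels$length <- abs(nchar(ra) - nchar(aa))
  ok_vaf <- is.na(indels$vaf) | (indels$vaf >= 0 & indels$vaf <= 1)
  check_that(all(ok_vaf), "vaf outside [0, 1]")
  indels[INDEL_COLS]
}

# classify one MAF-like row; returns list(snvs = df, indels = df)
# multi-base substitutions of equal allele length (DBS/MNP rows) are split
# into per-base SNV records so both MAF encodings of dinucleotide events are
# accepted; adjacent pairs are reconstructed downstream by count_cc_tt().
row_to_records <- function(sample, chrom, pos, ref, alt, vaf, qual, line) {
  ref <- toupper(ref); alt <- toupper(alt)
  bad <- function(why) stop("malformed catalog row at line ", line, ": ", why,
                            call. = FALSE)
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) bad("non-ACGT allele")
  if (ref == alt) bad("ref equals alt")
  if (nchar(ref) == nchar(alt)) {
    rb <- strsplit(ref, "")[[1]]
    ab <- strsplit(alt, "")[[1]]
    diffs <- which(rb != ab)
    list(snvs = data.frame(sample_id = sample, chrom = chrom,
                           pos = pos + diffs - 1L, ref = rb[diffs],
                           alt = ab[diffs], vaf = vaf, qual = qual,
                           zygosity_call = NA_character_,
                           stringsAsFactors = FALSE),
         indels = empty_indels())
  } else {
    short <- if (nchar(ref) < nchar(alt)) ref else alt
    long <- if (nchar(ref) < nchar(alt)) alt else ref
    if (substr(long, 1L, nchar(short)) != short)
      bad("alleles are neither a substitution nor prefix-anchored indel")
    list(snvs = empty_snvs(),
         indels = validate_indels(data.frame(
           sample_id = sample, chrom = chrom, pos = pos,
           ref_allele = ref, alt_allele = alt, qual = qual, vaf = vaf,
           stringsAsFactors = FALSE)))
  }
}

#' Read a somatic variant catalog
#'
#' Supported formats: `maf_tsv`, a tab-separated table with columns
#' `sample`, `chrom`, `pos`, `ref`, `alt`, `vaf` and optionally `qual`
#' (substitutions and VCF-style prefix-anchored indels in the same file;
#' rows with equal-length multi-base alleles are split into per-base SNV
#' records), and `vcf` (VCF 4.x; multi-allelic rows are split, sample ids
#' are taken from the genotype columns, allele fraction from the per-sample
#' `AF`/`VAF` FORMAT field or the INFO `AF` field).
#'
#' @param path input file
#' @param format "maf_tsv" or "vcf"
#' @param reference optional `ref_genome`; when given, indels are
#'   left-normalized on read (see [left_normalize_indels()])
#' @return list with data.frames `snvs` and `indels`
#' @export
read_catalog <- function(path, format = c("maf_tsv", "vcf"),
                         reference = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format tag: ",
                                              format[1], call. = FALSE))
  check_that(file.exists(path), "no such file: ", path)
  cat0 <- switch(format,
                 maf_tsv = read_catalog_maf(path),
                 vcf = read_catalog_vcf(path))
  cat0$snvs <- validate_snvs(cat0$snvs)
  cat0$indels <- validate_indels(cat0$indels)
  if (!is.null(reference) && nrow(cat0$indels) > 0)
    cat0$indels <- left_normalize_indels(cat0$indels, reference)
  cat0
}

read_catalog_maf <- function(path) {
  # colClasses = "character": plain T/F alleles must not become logicals
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  need <- c("sample", "chrom", "pos", "ref", "alt", "vaf")
  miss <- setdiff(need, names(df))
  check_that(length(miss) == 0, "catalog is missing column(s): ",
             paste(miss, collapse = ", "))
  if (!"qual" %in% names(df)) df$qual <- rep(NA_character_, nrow(df))
  if (nrow(df) == 0) return(list(snvs = empty_snvs(), indels = empty_indels()))
  snv_list <- vector("list", nrow(df))
  ind_list <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pos <- suppressWarnings(as.integer(df$pos[i]))
    if (is.na(pos) || pos < 1)
      stop("malformed catalog row at line ", i + 1L, ": bad pos", call. = FALSE)
    rec <- row_to_records(df$sample[i], df$chrom[i], pos, df$ref[i],
                          df$alt[i], as.numeric(df$vaf[i]),
                          as.numeric(df$qual[i]), i + 1L)
    snv_list[[i]] <- rec$snvs
    ind_list[[i]] <- rec$indels
  }
  list(snvs = do.call(rbind, c(list(empty_snvs()), snv_list)),
       indels = do.call(rbind, c(list(empty_indels()), ind_list)))
}

read_catalog_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) return(list(snvs = empty_snvs(), indels = empty_indels()))
  gt <- v@gt
  has_gt <- !is.null(gt) && ncol(gt) >= 2
  samples <- if (has_gt) colnames(gt)[-1] else
    sub("\\.vcf(\\.gz)?$", "", basename(path))
  info_af <- function(i) {
    m <- regmatches(fx$INFO[i], regexpr("(?:^|;)AF=([^;]+)", fx$INFO[i]))
    if (length(m) == 0) return(NA_character_)
    sub("^;?AF=", "", m)
  }
  snv_list <- list(); ind_list <- list()
  for (i in seq_len(nrow(fx))) {
    alts <- strsplit(fx$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- rep(NA_real_, length(alts))
    ia <- info_af(i)
    if (!is.na(ia)) {
      vals <- suppressWarnings(as.numeric(strsplit(ia, ",")[[1]]))
      afs[seq_along(vals)] <- vals
    }
    qual <- suppressWarnings(as.numeric(fx$QUAL[i]))
    pos <- as.integer(fx$POS[i])
    for (ai in seq_along(alts)) {
      if (has_gt) {
        fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
        af_field <- which(fmt %in% c("AF", "VAF"))[1]
        gt_field <- which(fmt == "GT")[1]
        for (s in seq_along(samples)) {
          cell <- gt[i, s + 1L]
          if (is.na(cell)) next
          parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
          gtv <- if (!is.na(gt_field)) parts[gt_field] else "."
          carries <- grepl(paste0("(^|[/|])", ai, "($|[/|])"), gtv)
          if (!carries) next
          vaf <- afs[ai]
          if (!is.na(af_field) && length(parts) >= af_field) {
            pv <- suppressWarnings(as.numeric(
              strsplit(parts[af_field], ",")[[1]]))
            if (length(pv) >= ai && !is.na(pv[ai])) vaf <- pv[ai]
            else if (length(pv) == 1 && !is.na(pv[1])) vaf <- pv[1]
          }
          rec <- row_to_records(samples[s], fx$CHROM[i], pos, fx$REF[i],
                                alts[ai], vaf, qual, i)
          snv_list[[length(snv_list) + 1L]] <- rec$snvs
          ind_list[[length(ind_list) + 1L]] <- rec$indels
        }
      } else {
        rec <- row_to_records(samples, fx$CHROM[i], pos, fx$REF[i],
                              alts[ai], afs[ai], qual, i)
        snv_list[[length(snv_list) + 1L]] <- rec$snvs
        ind_list[[length(ind_list) + 1L]] <- rec$indels
      }
    }
  }
  list(snvs = do.call(rbind, c(list(empty_snvs()), snv_list)),
       indels = do.call(rbind, c(list(empty_indels()), ind_list)))
}

#' Write a catalog to a MAF-like TSV
#'
#' One row per record; SNVs and indels share the column layout
#' `sample, chrom, pos, ref, alt, vaf, qual`. [read_catalog()] of the
#' written file reproduces the catalog.
#'
#' @param catalog list with `snvs` and/or `indels` data.frames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_catalog <- function(catalog, path) {
  snvs <- if (is.null(catalog$snvs)) empty_snvs() else validate_snvs(catalog$snvs)
  ind <- if (is.null(catalog$indels)) empty_indels() else
    validate_indels(catalog$indels)
  out <- rbind(
    data.frame(sample = snvs$sample_id, chrom = snvs$chrom, pos = snvs$pos,
               ref = snvs$ref, alt = snvs$alt, vaf = snvs$vaf,
               qual = snvs$qual, stringsAsFactors = FALSE),
    data.frame(sample = ind$sample_id, chrom = ind$chrom, pos = ind$pos,
               ref = ind$ref_allele, alt = ind$alt_allele, vaf = ind$vaf,
               qual = ind$qual, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Left-normalize indels against a reference
#'
#' Shifts every indel to the smallest position describing the identical
#' allele change (standard VCF left-alignment), so homopolymer and repeat
#' logic downstream is deterministic.
#'
#' @param indels validated indel data.frame
#' @param reference `ref_genome`
#' @return indel data.frame with updated `pos`, `ref_allele`, `alt_allele`
#' @export
left_normalize_indels <- function(indels, reference) {
  indels <- validate_indels(indels)
  if (nrow(indels) == 0) return(indels)
  seqs <- unclass(reference)
  for (i in seq_len(nrow(indels))) {
    ch <- indels$chrom[i]
    check_that(ch %in% names(seqs), "unknown chromosome: ", ch)
    sq <- seqs[[ch]]
    L <- indels$length[i]
    if (indels$kind[i] == "deletion") {
      # deleted span starts at s = pos + 1; shifting left by one keeps the
      # result identical iff ref[s - 1] == ref[s + L - 1]
      s <- indels$pos[i] + 1L
      while (s > 2L &&
             substr(sq, s - 1L, s - 1L) == substr(sq, s + L - 1L, s + L - 1L))
        s <- s - 1L
      pos <- s - 1L
      indels$pos[i] <- pos
      indels$ref_allele[i] <- substr(sq, pos, pos + L)
      indels$alt_allele[i] <- substr(sq, pos, pos)
    } else {
      # insertion of S after pos; shift left while ref[pos] == last base of S
      pos <- indels$pos[i]
      S <- substr(indels$alt_allele[i], 2L, L + 1L)
      while (pos > 1L && substr(sq, pos, pos) == substr(S, L, L)) {
        S <- paste0(substr(sq, pos, pos), substr(S, 1L, L - 1L))
        pos <- pos - 1L
      }
      indels$pos[i] <- pos
      anchor <- substr(sq, pos, pos)
      indels$ref_allele[i] <- anchor
      indels$alt_allele[i] <- paste0(anchor, S)
    }
  }
  indels
}

#' Read genomic intervals from BED
#'
#' BED is 0-based half-open; the returned `GRanges` uses the package's
#' 1-based inclusive convention (the conversion happens here and nowhere
#' else). Overlapping input intervals are preserved, not merged.
#'
#' @param path BED file
#' @param format only "bed" is supported
#' @return `GRanges` of intervals, names from the BED name column if present
#' @export
read_intervals <- function(path, format = "bed") {
  check_that(identical(tolower(format), "bed"), "unknown format tag: ", format)
  check_that(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    check_that(length(f) >= 3, "BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    check_that(!is.na(s) && !is.na(e), "BED line ", i, ": non-numeric bounds")
    check_that(s < e, "BED line ", i, ": start >= end")
  }
  gr <- rtracklayer::import(path, format = "BED")
  gr
}

#' Read a structural-variant catalog (BEDPE-like TSV)
#'
#' Tab-separated with 1-based breakpoint coordinates and columns
#' `sample_id, sv_type, chrom1, pos1, chrom2, pos2, junction_reads_variant,
#' junction_reads_total, blood_variant_reads` plus optional
#' `inserted_or_mh_seq` and `pass_filter` (caller-level PASS flag; e.g.
#' FALSE for LowQual/IMPRECISE calls).
#'
#' @param path input TSV
#' @return validated SV data.frame
#' @export
read_sv_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_svs(df)
}

#' Validate an SV data.frame
#' @param svs data.frame (see [read_sv_catalog()] for columns)
#' @return validated data.frame with optional columns filled
#' @export
validate_svs <- function(svs) {
  need <- c("sample_id", "sv_type", "chrom1", "pos1", "chrom2", "pos2",
            "junction_reads_variant", "junction_reads_total",
            "blood_variant_reads")
  miss <- setdiff(need, names(svs))
  check_that(length(miss) == 0, "svs missing column(s): ",
             paste(miss, collapse = ", "))
  if (!"inserted_or_mh_seq" %in% names(svs))
    svs$inserted_or_mh_seq <- NA_character_
  if (!"pass_filter" %in% names(svs)) svs$pass_filter <- TRUE
  svs$pos1 <- as.integer(svs$pos1); svs$pos2 <- as.integer(svs$pos2)
  check_that(all(svs$sv_type %in% c("DEL", "DUP", "INV", "TRA")),
             "sv_type must be DEL/DUP/INV/TRA")
  intra <- svs$sv_type != "TRA"
  check_that(all(svs$chrom1[intra] == svs$chrom2[intra]),
             "DEL/DUP/INV must have chrom1 == chrom2")
  check_that(all(svs$pos1[intra] < svs$pos2[intra]),
             "DEL/DUP/INV must have pos1 < pos2")
  check_that(all(svs$junction_reads_variant <= svs$junction_reads_total),
             "junction_reads_variant exceeds junction_reads_total")
  svs
}

#' Write a structural-variant catalog
#' @param svs validated SV data.frame
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_sv_catalog <- function(svs, path) {
  write.table(validate_svs(svs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id, donor_id, age, sex, race, cell_type, wga`.
#'
#' @param path input TSV
#' @return validated data.frame
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(df)
}

#' Validate sample metadata
#' @param meta data.frame of per-sample donor metadata
#' @return validated data.frame
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "donor_id", "age", "sex", "race", "cell_type", "wga")
  miss <- setdiff(need, names(meta))
  check_that(length(miss) == 0, "metadata missing column(s): ",
             paste(miss, collapse = ", "))
  check_that(all(meta$age > 0), "age must be > 0")
  check_that(all(meta$sex %in% c("M", "F")), "sex must be M or F")
  check_that(all(meta$race %in% c("White", "AfricanAmerican")),
             "race must be White or AfricanAmerican")
  check_that(all(meta$cell_type %in% c("fibroblast", "melanocyte")),
             "cell_type must be fibroblast or melanocyte")
  meta$wga <- as.logical(meta$wga)
  meta
}
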