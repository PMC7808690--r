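# Indel classification: replication-slippage homopolymer indels, >= 5 bp
# deletions with junction microhomology (end-joining scars), and templated
# insertions copied from adjacent sequence. All functions expect
# left-normalized, validated indels (see left_normalize_indels()).

# maximal run length of base `b` in `sq` containing or touching position i
run_length_at <- function(sq, i, b) {
  n <- nchar(sq)
  if (i < 1 || i > n || substr(sq, i, i) != b) return(0L)
  l <- i
  while (l > 1L && substr(sq, l - 1L, l - 1L) == b) l <- l - 1L
  r <- i
  while (r < n && substr(sq, r + 1L, r + 1L) == b) r <- r + 1L
  r - l + 1L
}

#' Classify a 1 bp indel as a homopolymer (slippage) indel
#'
#' A single-base insertion or deletion is a homopolymer indel when the
#' inserted/deleted base extends or shrinks a reference run of that base of
#' length >= `min_run`. The returned run length is measured on the
#' reference: for a deletion, the run containing the deleted base; for an
#' insertion, the run adjacent to the insertion point.
#'
#' @param indel one-row indel data.frame (left-normalized)
#' @param reference `ref_genome`
#' @param min_run minimum reference run length (default 2)
#' @return list with `is_homopolymer_1bp` and `homopolymer_run_length`
#' @export
classify_homopolymer <- function(indel, reference, min_run = 2) {
  sq <- unclass(reference)[[indel$chrom]]
  check_that(!is.null(sq), "unknown chromosome: ", indel$chrom)
  if (indel$length != 1L)
    return(list(is_homopolymer_1bp = FALSE, homopolymer_run_length = 0L))
  if (indel$kind == "deletion") {
    b <- substr(indel$ref_allele, 2L, 2L)
    run <- run_length_at(sq, indel$pos + 1L, b)
  } else {
    b <- substr(indel$alt_allele, 2L, 2L)
    # run adjacent to the insertion point (left of it after
    # left-normalization; check both sides for robustness)
    run <- max(run_length_at(sq, indel$pos, b),
               run_length_at(sq, indel$pos + 1L, b))
  }
  list(is_homopolymer_1bp = run >= min_run,
       homopolymer_run_length = as.integer(run))
}

#' Junction microhomology of a deletion
#'
#' Length of the identical sequence shared by the deletion and its junction:
#' the maximum of the longest common prefix of the deleted sequence with the
#' right flank and the longest common suffix with the left flank, capped at
#' the deletion length.
#'
#' @param indel one-row deletion data.frame
#' @param reference `ref_genome`
#' @return microhomology length (integer >= 0)
#' @export
junction_microhomology <- function(indel, reference) {
  check_that(indel$kind == "deletion", "microhomology is defined for deletions")
  sq <- unclass(reference)[[indel$chrom]]
  check_that(!is.null(sq), "unknown chromosome: ", indel$chrom)
  L <- indel$length
  s <- indel$pos + 1L            # first deleted base
  e <- indel$pos + L             # last deleted base
  deleted <- substr(sq, s, e)
  right <- substr(sq, e + 1L, min(nchar(sq), e + L))
  left <- substr(sq, max(1L, s - L), s - 1L)
  mh <- max(lcp_len(deleted, right), lcs_len(deleted, left))
  as.integer(min(mh, L))
}

#' Detect a templated (adjacent-copy) insertion
#'
#' An insertion of sequence `s` (length `L`) is `adjacent_copy` when `s`
#' equals the `L` reference bases immediately left or right of the insertion
#' point, and `adjacent_copy_with_mismatch` when the Hamming distance to a
#' flank is at most `max_mismatch` (only for insertions longer than 2 bp;
#' single-base and 2 bp templated insertions require an exact match). Ties
#' between the two sides report `left`.
#'
#' @param indel one-row insertion data.frame
#' @param reference `ref_genome`
#' @param max_mismatch mismatches tolerated for insertions > 2 bp (default 1)
#' @return list with `templated`, `template_side`, `mismatches`, `truncated`
#' @export
detect_templated_insertion <- function(indel, reference, max_mismatch = 1) {
  check_that(indel$kind == "insertion", "record is not an insertion")
  sq <- unclass(reference)[[indel$chrom]]
  check_that(!is.null(sq), "unknown chromosome: ", indel$chrom)
  L <- indel$length
  s <- substr(indel$alt_allele, 2L, L + 1L)
  left <- substr(sq, max(1L, indel$pos - L + 1L), indel$pos)
  right <- substr(sq, indel$pos + 1L, min(nchar(sq), indel$pos + L))
  truncated <- nchar(left) < L || nchar(right) < L
  # align the insertion to the end of the left flank and the start of the
  # right flank (the copied template abuts the insertion point); at a contig
  # edge only the available bases are compared and `truncated` is flagged
  mm_left <- if (nchar(left) == 0) Inf else {
    n <- min(nchar(left), L)
    a <- substr(s, L - n + 1L, L)
    b <- substr(left, nchar(left) - n + 1L, nchar(left))
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  mm_right <- if (nchar(right) == 0) Inf else {
    n <- min(nchar(right), L)
    a <- substr(s, 1L, n)
    b <- substr(right, 1L, n)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  side <- if (mm_left <= mm_right) "left" else "right"
  mm <- min(mm_left, mm_right)
  templated <- if (mm == 0) "adjacent_copy"
  else if (L > 2 && mm <= max_mismatch) "adjacent_copy_with_mismatch"
  else "none"
  list(templated = templated,
       template_side = if (templated == "none") "none" else side,
       mismatches = if (templated == "none") NA_integer_ else as.integer(mm),
       truncated = truncated)
}

#' Classify every indel of a catalog
#'
#' Runs [classify_homopolymer()], [junction_microhomology()] (deletions) and
#' [detect_templated_insertion()] (insertions) over a left-normalized
#' catalog.
#'
#' @param indels indel data.frame
#' @param reference `ref_genome`
#' @param min_run homopolymer minimum run (default 2)
#' @param max_mismatch templated-insertion mismatch tolerance (default 1)
#' @param normalize left-normalize first (default TRUE)
#' @return input data.frame with classification columns appended
#' @export
classify_indels <- function(indels, reference, min_run = 2, max_mismatch = 1,
                            normalize = TRUE) {
  indels <- validate_indels(indels)
  if (normalize && nrow(indels) > 0)
    indels <- left_normalize_indels(indels, reference)
  n <- nrow(indels)
  indels$is_homopolymer_1bp <- logical(n)
  indels$homopolymer_run_length <- integer(n)
  indels$is_deletion_ge5 <- indels$kind == "deletion" & indels$length >= 5
  indels$mh_length <- rep(NA_integer_, n)
  indels$templated <- rep(NA_character_, n)
  indels$template_side <- rep(NA_character_, n)
  indels$mismatches <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- indels[i, , drop = FALSE]
    hp <- classify_homopolymer(row, reference, min_run)
    indels$is_homopolymer_1bp[i] <- hp$is_homopolymer_1bp
    indels$homopolymer_run_length[i] <- hp$homopolymer_run_length
    if (row$kind == "deletion") {
      indels$mh_length[i] <- junction_microhomology(row, reference)
    } else {
      ti <- detect_templated_insertion(row, reference, max_mismatch)
      indels$templated[i] <- ti$templated
      indels$template_side[i] <- ti$template_side
      indels$mismatches[i] <- ti$mismatches
    }
  }
  indels
}

#' Per-sample indel summary
#'
#' @param classified output of [classify_indels()]
#' @param samples optional sample ids to report (zero rows included)
#' @return data.frame with per-sample counts: total, insertions, deletions,
#'   homopolymer 1 bp indels, deletions >= 5 bp, templated insertions
#' @export
summarize_indels <- function(classified, samples = NULL) {
  if (is.null(samples)) samples <- unique(classified$sample_id)
  out <- lapply(samples, function(s) {
    d <- classified[classified$sample_id == s, , drop = FALSE]
    data.frame(sample_id = s,
               total = nrow(d),
               ins = sum(d$kind == "insertion"),
               del = sum(d$kind == "deletion"),
               homopolymer_1bp = sum(d$is_homopolymer_1bp),
               deletions_ge5 = sum(d$is_deletion_ge5),
               templated = sum(d$templated %in%
                                 c("adjacent_copy",
                                   "adjacent_copy_with_mismatch")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
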