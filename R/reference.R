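# Reference genome access. Synthetic and test references are small, so the
# whole sequence set is held in memory as a named character vector; FASTA
# I/O goes through Biostrings.

#' Construct a reference genome object
#'
#' @param sequences named character vector of chromosome sequences
#'   (A/C/G/T/N, any case; stored uppercase)
#' @return object of class `ref_genome`
#' @export
ref_genome <- function(sequences) {
  check_that(is.character(sequences) && length(sequences) > 0,
             "sequences must be a non-empty character vector")
  check_that(!is.null(names(sequences)) && all(nzchar(names(sequences))),
             "every sequence must be named by its chromosome")
  check_that(!anyDuplicated(names(sequences)), "duplicated chromosome names")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  check_that(!any(bad), "non-ACGTN characters in sequence(s): ",
             paste(names(sequences)[bad], collapse = ", "))
  structure(sequences, class = "ref_genome")
}

#' Read a reference genome from FASTA
#' @param path path to a FASTA file
#' @return `ref_genome` object
#' @export
read_reference <- function(path) {
  check_that(file.exists(path), "no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ref_genome(seqs)
}

#' Write a reference genome to FASTA
#' @param ref `ref_genome`
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome with", length(x), "sequence(s):\n")
  for (nm in names(x)) cat(" ", nm, ":", nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Chromosome lengths of a reference
#' @param ref `ref_genome`
#' @return named integer vector
#' @export
seq_lengths <- function(ref) {
  setNames(nchar(unclass(ref)), names(ref))
}

# internal: fetch bases [start, end] 1-based inclusive, N-padded beyond ends
fetch_span <- function(ref, chrom, start, end) {
  seqs <- unclass(ref)
  check_that(chrom %in% names(seqs), "unknown chromosome: ", chrom)
  len <- nchar(seqs[[chrom]])
  left_pad <- max(0L, 1L - start)
  right_pad <- max(0L, end - len)
  core <- substr(seqs[[chrom]], max(1L, start), min(len, end))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Fetch the sequence context window around a position
#'
#' Returns the `2 * flank + 1` reference bases centred on `pos` (1-based).
#' Positions beyond the chromosome ends are padded with `N`.
#'
#' @param ref `ref_genome`
#' @param chrom chromosome name
#' @param pos 1-based centre position
#' @param flank number of bases on each side (default 20)
#' @param check_ref optional expected reference base at `pos`; a mismatch is
#'   an error (guards against catalog/reference mix-ups)
#' @return list with `chrom`, `pos`, `flank`, `sequence`
#' @export
fetch_context <- function(ref, chrom, pos, flank = 20L, check_ref = NULL) {
  check_that(length(pos) == 1L && pos >= 1L, "pos must be a single position >= 1")
  check_that(flank >= 0L, "flank must be >= 0")
  seqs <- unclass(ref)
  check_that(chrom %in% names(seqs), "unknown chromosome: ", chrom)
  check_that(pos <= nchar(seqs[[chrom]]),
             "pos ", pos, " beyond end of ", chrom)
  sq <- fetch_span(ref, chrom, pos - flank, pos + flank)
  if (!is.null(check_ref)) {
    mid <- substr(sq, flank + 1L, flank + 1L)
    check_that(identical(mid, toupper(check_ref)),
               "reference base at ", chrom, ":", pos, " is ", mid,
               " but record says ", check_ref)
  }
  list(chrom = chrom, pos = as.integer(pos), flank = as.integer(flank),
       sequence = sq)
}

# internal: vectorised window extraction for many positions on one genome.
# Returns character vector of windows (length 2*flank+1, N-padded).
fetch_windows <- function(ref, chrom, pos, flank = 20L) {
  if (length(pos) == 0L) return(character(0))
  seqs <- unclass(ref)
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    check_that(ch %in% names(seqs), "unknown chromosome: ", ch)
    idx <- which(chrom == ch)
    len <- nchar(seqs[[ch]])
    p <- pos[idx]
    check_that(all(p >= 1L & p <= len), "position outside ", ch)
    start <- p - flank
    end <- p + flank
    core <- substring(seqs[[ch]], pmax(1L, start), pmin(len, end))
    lp <- pmax(0L, 1L - start)
    rp <- pmax(0L, end - len)
    out[idx] <- paste0(strrep("N", lp), core, strrep("N", rp))
  }
  out
}

# internal: reverse-complement a whole reference (used by symmetry tests and
# available to users wanting strand checks)

#' Reverse complement every chromosome of a reference
#' @param ref `ref_genome`
#' @return `ref_genome` with each sequence reverse-complemented
#' @export
revcomp_reference <- function(ref) {
  ref_genome(setNames(revcomp(unclass(ref)), names(ref)))
}
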