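# Mutation-spectrum matrices and signature refitting: 96-channel SBS
# spectra with pyrimidine-strand normalization, 83-channel indel spectra,
# cosine similarity against reference signature catalogs and non-negative
# least-squares refitting.

#' The 96 SBS channel labels
#'
#' COSMIC ordering: substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each
#' with the 16 trinucleotide contexts in alphabetical order, written
#' `A[C>A]A`.
#'
#' @return character vector of 96 labels
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(l)
      paste0(l, "[", s, "]", vapply(bases, function(r) r, character(1)))))))
}

#' The 83 ID channel labels
#'
#' COSMIC-style ID83 scheme: 1 bp deletions/insertions split by
#' pyrimidine-normalised base (C/T) and homopolymer run length; longer
#' indels by length class (2, 3, 4, 5+) and the number of additional
#' adjacent copies of the indel sequence (repeat units, 0-5+); deletions
#' with no adjacent copy additionally by junction microhomology length.
#' Labels follow the `1:Del:C:0` convention: for 1 bp deletions the final
#' field is the reference run length minus one (0 = not in a run, 5 = run
#' of 6 or more); for 1 bp insertions it is the length of the adjacent run
#' of the inserted base (0-5+); for longer indels it is the repeat-unit or
#' microhomology count.
#'
#' @return character vector of 83 labels
#' @export
id83_channels <- function() {
  c(
    paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    paste0("2:Del:R:", 0:5), paste0("3:Del:R:", 0:5),
    paste0("4:Del:R:", 0:5), paste0("5:Del:R:", 0:5),
    paste0("2:Ins:R:", 0:5), paste0("3:Ins:R:", 0:5),
    paste0("4:Ins:R:", 0:5), paste0("5:Ins:R:", 0:5),
    "2:Del:M:1", paste0("3:Del:M:", 1:2), paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
}

#' SBS96 mutation spectrum matrix
#'
#' Assigns each SNV to one of the 96 trinucleotide channels after
#' pyrimidine-strand normalization (purine-reference records are reverse
#' complemented). Records whose trinucleotide context contains `N` are
#' dropped; the dropped count is available as `attr(x, "dropped")`.
#'
#' @param snvs SNV data.frame
#' @param reference `ref_genome`
#' @param samples optional sample ids fixing the column set/order
#' @return 96 x samples integer matrix with channel rownames
#' @export
sbs96 <- function(snvs, reference, samples = NULL) {
  snvs <- validate_snvs(snvs)
  if (is.null(samples)) samples <- unique(snvs$sample_id)
  chan <- sbs96_channels()
  m <- matrix(0L, nrow = 96, ncol = length(samples),
              dimnames = list(chan, samples))
  dropped <- 0L
  if (nrow(snvs) > 0) {
    win <- fetch_windows(reference, snvs$chrom, snvs$pos, flank = 1L)
    mid <- substr(win, 2L, 2L)
    check_that(all(mid == snvs$ref | mid == "N"),
               "reference base mismatch between catalog and reference")
    pur <- snvs$ref %in% c("A", "G")
    tri <- ifelse(pur, revcomp(win), win)
    alt <- ifelse(pur, comp_chr(snvs$alt), snvs$alt)
    ok <- !grepl("N", tri, fixed = TRUE)
    dropped <- sum(!ok)
    lab <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt, "]",
                  substr(tri, 3, 3))
    for (i in which(ok)) {
      s <- snvs$sample_id[i]
      if (!s %in% samples) next
      m[lab[i], s] <- m[lab[i], s] + 1L
    }
  }
  attr(m, "dropped") <- dropped
  m
}

#' Cosine similarity of two spectra
#' @param a,b equal-length non-negative numeric vectors
#' @return cosine similarity in \[0, 1\]
#' @export
cosine_sim <- function(a, b) {
  check_that(length(a) == length(b), "profiles differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  check_that(na > 0 && nb > 0, "cosine undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Refit a spectrum against a signature catalog
#'
#' Non-negative least squares: exposures minimise the squared
#' reconstruction error of the profile as a non-negative combination of
#' catalog signatures.
#'
#' @param profile numeric vector (or channels x samples matrix) of counts;
#'   names/rownames must match the catalog channels
#' @param catalog channels x signatures matrix, each column a probability
#'   vector
#' @return list with `exposures` (signatures x samples matrix) and
#'   `residual` (per-sample Euclidean reconstruction residual)
#' @export
refit <- function(profile, catalog) {
  if (is.vector(profile)) profile <- cbind(sample1 = profile)
  check_that(nrow(profile) == nrow(catalog),
             "profile and catalog channel counts differ")
  if (!is.null(rownames(profile)) && !is.null(rownames(catalog)))
    check_that(identical(rownames(profile), rownames(catalog)),
               "profile channels do not match catalog channels")
  ns <- ncol(profile)
  expo <- matrix(0, ncol(catalog), ns,
                 dimnames = list(colnames(catalog), colnames(profile)))
  resid <- numeric(ns)
  for (j in seq_len(ns)) {
    fit <- pracma::lsqnonneg(catalog, as.numeric(profile[, j]))
    expo[, j] <- fit$x
    resid[j] <- sqrt(max(fit$resid.norm, 0))
  }
  list(exposures = expo, residual = setNames(resid, colnames(profile)))
}

#' Read a signature catalog from TSV
#'
#' First column `channel`, remaining columns one probability vector per
#' signature (columns sum to 1 within 1e-6).
#'
#' @param path TSV path
#' @return channels x signatures numeric matrix
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_that(names(df)[1] == "channel", "first column must be 'channel'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  check_that(all(abs(colSums(m) - 1) < 1e-6),
             "signature columns must sum to 1")
  m
}

# number of additional adjacent exact copies of `S` around span [s, e] in sq
adjacent_copies <- function(sq, s, e, S) {
  L <- nchar(S)
  n <- nchar(sq)
  k <- 0L
  p <- e + 1L
  while (p + L - 1L <= n && substr(sq, p, p + L - 1L) == S) {
    k <- k + 1L; p <- p + L
  }
  p <- s - L
  while (p >= 1L && substr(sq, p, p + L - 1L) == S) {
    k <- k + 1L; p <- p - L
  }
  k
}

#' ID83 indel spectrum matrix
#'
#' Classifies each indel into the 83-channel scheme of [id83_channels()].
#' Indels are left-normalized first; indels whose classification window
#' contains ambiguous (`N`) bases are dropped with the count recorded in
#' `attr(x, "dropped")`.
#'
#' @param indels indel data.frame
#' @param reference `ref_genome`
#' @param samples optional sample ids fixing the column set/order
#' @return 83 x samples integer matrix
#' @export
indel83 <- function(indels, reference, samples = NULL) {
  indels <- validate_indels(indels)
  if (nrow(indels) > 0) indels <- left_normalize_indels(indels, reference)
  if (is.null(samples)) samples <- unique(indels$sample_id)
  chan <- id83_channels()
  m <- matrix(0L, nrow = 83, ncol = length(samples),
              dimnames = list(chan, samples))
  dropped <- 0L
  for (i in seq_len(nrow(indels))) {
    lab <- id83_channel_of(indels[i, , drop = FALSE], reference)
    if (is.na(lab)) { dropped <- dropped + 1L; next }
    s <- indels$sample_id[i]
    if (!s %in% samples) next
    m[lab, s] <- m[lab, s] + 1L
  }
  attr(m, "dropped") <- dropped
  m
}

#' ID83 channel of a single (left-normalized) indel
#' @param indel one-row indel data.frame
#' @param reference `ref_genome`
#' @return channel label, or `NA` if ambiguous reference bases prevent
#'   classification
#' @export
id83_channel_of <- function(indel, reference) {
  sq <- unclass(reference)[[indel$chrom]]
  check_that(!is.null(sq), "unknown chromosome: ", indel$chrom)
  L <- indel$length
  kind <- indel$kind
  if (kind == "deletion") {
    s <- indel$pos + 1L; e <- indel$pos + L
    S <- substr(sq, s, e)
  } else {
    S <- substr(indel$alt_allele, 2L, L + 1L)
    s <- indel$pos + 1L; e <- indel$pos  # empty reference span at the point
  }
  # classification window clipped to the chromosome (no N padding); only
  # genuinely ambiguous reference bases cause a drop
  win <- substr(sq, max(1L, s - 6L * L), min(nchar(sq), e + 6L * L))
  if (grepl("N", win, fixed = TRUE) || grepl("N", S, fixed = TRUE))
    return(NA_character_)
  if (L == 1L) {
    b <- S
    bn <- if (b %in% c("A", "G")) comp_chr(b) else b
    if (kind == "deletion") {
      run <- run_length_at(sq, s, b)
      return(paste0("1:Del:", bn, ":", min(run, 6L) - 1L))
    }
    run <- max(run_length_at(sq, indel$pos, b),
               run_length_at(sq, indel$pos + 1L, b))
    return(paste0("1:Ins:", bn, ":", min(run, 5L)))
  }
  lenc <- min(L, 5L)
  copies <- adjacent_copies(sq, s, e, S)
  if (kind == "insertion")
    return(paste0(lenc, ":Ins:R:", min(copies, 5L)))
  if (copies >= 1L)
    return(paste0(lenc, ":Del:R:", min(copies, 5L)))
  mh <- junction_microhomology(indel, reference)
  if (mh >= 1L) {
    cap <- if (lenc >= 5L) 5L else lenc - 1L
    return(paste0(lenc, ":Del:M:", min(mh, cap)))
  }
  paste0(lenc, ":Del:R:0")
}
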