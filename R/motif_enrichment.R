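# Knowledge-based trinucleotide-motif signature pipeline.
#
# For a motif such as yCn -> yTn the enrichment of mutations in the motif is
#
#   Enrichment = (Mutations_motif * Context_base) /
#                (Mutations_class * Context_motif)
#
# where Mutations_class counts all substitutions of the base-change class
# (e.g. all C->T), Mutations_motif those whose trinucleotide context matches
# the motif on either strand, and the Context terms count unmutated
# occurrences of the middle base (and its complement) inside +/- `flank`
# base windows around the class mutations, split by motif membership.
# Significance is a one-sided Fisher exact test on the corresponding 2x2
# table, corrected across samples by Benjamini-Hochberg; for samples with
# enrichment > 1 and q < alpha the minimum mutation load is
# Mutations_motif * (Enrichment - 1) / Enrichment.

#' Define a trinucleotide motif signature
#'
#' The motif is a 3-symbol IUPAC string whose middle symbol is the concrete
#' mutated base (conventionally capitalised, e.g. `"yCn"`); flanking symbols
#' may be degenerate. The reverse complement of the motif is always counted
#' as well.
#'
#' @param name signature label, e.g. `"yCn->yTn"`
#' @param motif 3-symbol IUPAC string, middle symbol a concrete base
#' @param to_base the base the middle base mutates to
#' @return object of class `motif_signature`
#' @export
motif_signature <- function(name, motif, to_base) {
  check_that(nchar(motif) == 3, "motif must have 3 symbols")
  sym <- toupper(strsplit(motif, "")[[1]])
  check_that(all(sym %in% names(IUPAC_SETS)),
             "motif symbols must be IUPAC codes")
  check_that(sym[2] %in% c("A", "C", "G", "T"),
             "middle motif symbol must be a concrete base")
  to_base <- toupper(to_base)
  check_that(to_base %in% c("A", "C", "G", "T") && to_base != sym[2],
             "to_base must be a base different from the middle base")
  structure(list(name = name, motif = motif, left = sym[1], mid = sym[2],
                 right = sym[3], from_base = sym[2], to_base = to_base),
            class = "motif_signature")
}

#' Built-in motif signatures
#'
#' The three motif-specific processes tracked in clonal skin lineages:
#' `nCg->nTg` (spontaneous deamination of methylated CpG cytosines, the core
#' of SBS1), `yCn->yTn` (UV photoproduct bypass, the core of SBS7b) and
#' `nTt->nCt` (UV-associated T->C changes).
#'
#' @return named list of [motif_signature()] objects
#' @export
builtin_signatures <- function() {
  list(
    `nCg->nTg` = motif_signature("nCg->nTg", "nCg", "T"),
    `yCn->yTn` = motif_signature("yCn->yTn", "yCn", "T"),
    `nTt->nCt` = motif_signature("nTt->nCt", "nTt", "C")
  )
}

#' Exclude complex (closely spaced) mutations
#'
#' Substitutions with another same-sample substitution less than
#' `min_spacing` bases away on the same chromosome likely arise from a
#' single translesion-synthesis event; both members of any close pair are
#' excluded from enrichment calculations.
#'
#' @param snvs SNV data.frame
#' @param min_spacing minimum spacing in bp (default 10; distance exactly
#'   `min_spacing` is kept)
#' @return SNV data.frame without complex mutations
#' @export
exclude_complex <- function(snvs, min_spacing = 10) {
  if (nrow(snvs) == 0) return(snvs)
  keep <- rep(TRUE, nrow(snvs))
  grp <- paste(snvs$sample_id, snvs$chrom, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    o <- idx[order(snvs$pos[idx])]
    if (length(o) < 2) next
    d <- diff(snvs$pos[o])
    close <- d < min_spacing
    bad <- unique(c(o[c(close, FALSE)], o[c(FALSE, close)]))
    keep[bad] <- FALSE
  }
  snvs[keep, , drop = FALSE]
}

# does a trinucleotide (l, c, r) match the motif on the forward / reverse
# strand? All arguments are vectors of single characters.
motif_match <- function(l, c, r, sig) {
  fwd <- c == sig$from_base & iupac_match(l, sig$left) &
    iupac_match(r, sig$right)
  rev <- c == comp_chr(sig$from_base) &
    iupac_match(r, iupac_comp(sig$left)) &
    iupac_match(l, iupac_comp(sig$right))
  fwd | rev
}

#' Count motif and base occurrences in context windows
#'
#' Given the context windows of all mutations of one base-change class
#' (each of length `2 * flank + 1`, centred on the mutated base), returns
#' the four counts of the enrichment equation. Reverse complements are
#' always counted: a centre matches if its trinucleotide matches the motif
#' on either strand, and context bases count occurrences of the middle base
#' and of its complement at non-centre positions. Centre (mutated)
#' positions are excluded from the context counts; `N` bases never count;
#' the outermost window position on each side (whose trinucleotide extends
#' beyond the window) is excluded from context counts as well.
#'
#' @param windows character vector of equal-length odd-width windows
#' @param signature [motif_signature()]
#' @param chrom,pos optional genomic coordinates of the window centres;
#'   required for `dedup`
#' @param dedup if TRUE, context bases shared by overlapping windows are
#'   counted once per genomic position instead of once per window
#' @return list with `mut_in_motif`, `mut_in_class`, `ctx_motif`,
#'   `ctx_base`, plus `ctx_motif_far`/`ctx_base_far` (context restricted to
#'   positions at least 2 bp from the mutated base)
#' @export
count_motif_and_base <- function(windows, signature, chrom = NULL,
                                 pos = NULL, dedup = FALSE) {
  if (length(windows) == 0)
    return(list(mut_in_motif = 0L, mut_in_class = 0L,
                ctx_motif = 0L, ctx_base = 0L,
                ctx_motif_far = 0L, ctx_base_far = 0L))
  w <- unique(nchar(windows))
  check_that(length(w) == 1 && w %% 2 == 1,
             "windows must share one odd length")
  check_that(!any(grepl("[^ACGTN]", windows)),
             "windows contain non-ACGTN symbols")
  if (dedup)
    check_that(!is.null(chrom) && !is.null(pos),
               "dedup requires chrom and pos of window centres")
  M <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
              nrow = length(windows), ncol = w, byrow = TRUE)
  ctr <- (w + 1L) / 2L
  from <- signature$from_base
  fromc <- comp_chr(from)
  base_m <- M == from | M == fromc
  motif_m <- matrix(FALSE, nrow(M), w)
  if (w >= 3) {
    inner <- 2:(w - 1L)
    motif_m[, inner] <- motif_match(M[, inner - 1L, drop = FALSE],
                                    M[, inner, drop = FALSE],
                                    M[, inner + 1L, drop = FALSE], signature)
    dim(motif_m) <- c(nrow(M), w)
  }
  mut_in_class <- length(windows)
  mut_in_motif <- sum(motif_m[, ctr])
  # context positions are the non-centre positions whose trinucleotide is
  # determinable within the window: the outermost two columns lack a
  # neighbour and are excluded (keeps degenerate motifs like nCn exactly at
  # enrichment 1). The "far" counts additionally drop the two positions
  # flanking the centre, whose motif status is constrained by the mutated
  # base itself (e.g. a G right after a mutated C is in nCg by
  # construction); they give an availability estimate free of that
  # near-centre structure, used by attributable_load().
  base_m[, c(1L, w)] <- FALSE
  near <- ctr + c(-1L, 0L, 1L)
  if (!dedup) {
    ctx_base <- sum(base_m[, -ctr])
    ctx_motif <- sum(motif_m[, -ctr] & base_m[, -ctr])
    ctx_base_far <- sum(base_m[, -near])
    ctx_motif_far <- sum(motif_m[, -near] & base_m[, -near])
  } else {
    # genomic coordinate of column j in window i: pos[i] + (j - ctr)
    offs <- matrix(rep(seq_len(w) - ctr, each = nrow(M)), nrow(M), w)
    keys <- matrix(paste(rep(chrom, w), pos + offs, sep = ":"), nrow(M), w)
    centers <- unique(keys[, ctr])
    nearkeys <- unique(as.vector(keys[, near]))
    bsel <- base_m; bsel[, ctr] <- FALSE
    msel <- motif_m & base_m; msel[, ctr] <- FALSE
    ctx_base <- length(setdiff(unique(keys[bsel]), centers))
    ctx_motif <- length(setdiff(unique(keys[msel]), centers))
    ctx_base_far <- length(setdiff(unique(keys[bsel]), nearkeys))
    ctx_motif_far <- length(setdiff(unique(keys[msel]), nearkeys))
  }
  list(mut_in_motif = as.integer(mut_in_motif),
       mut_in_class = as.integer(mut_in_class),
       ctx_motif = as.integer(ctx_motif),
       ctx_base = as.integer(ctx_base),
       ctx_motif_far = as.integer(ctx_motif_far),
       ctx_base_far = as.integer(ctx_base_far))
}

#' Motif enrichment ratio
#'
#' `(mut_in_motif * ctx_base) / (mut_in_class * ctx_motif)`. A zero
#' denominator is flagged, not an error: `Inf` when the numerator is
#' positive (motif context absent but motif mutations present), `NaN` when
#' the ratio is undefined (no class mutations or no context at all).
#'
#' @param mut_in_motif,mut_in_class,ctx_motif,ctx_base the four counts
#' @return enrichment ratio
#' @export
enrichment <- function(mut_in_motif, mut_in_class, ctx_motif, ctx_base) {
  check_that(all(c(mut_in_motif, mut_in_class, ctx_motif, ctx_base) >= 0),
             "counts must be non-negative")
  check_that(mut_in_motif <= mut_in_class, "mut_in_motif > mut_in_class")
  check_that(ctx_motif <= ctx_base, "ctx_motif > ctx_base")
  num <- mut_in_motif * ctx_base
  den <- mut_in_class * ctx_motif
  if (den == 0) return(if (num > 0) Inf else NaN)
  num / den
}

#' Fisher exact test for motif enrichment
#'
#' Tests the 2x2 table `[[mut_in_motif, mut_in_class - mut_in_motif],
#' [ctx_motif, ctx_base - ctx_motif]]`. One-sided toward enrichment by
#' default.
#'
#' @inheritParams enrichment
#' @param alternative "greater" (enrichment direction, default),
#'   "two.sided" or "less"
#' @return p-value
#' @export
enrichment_test <- function(mut_in_motif, mut_in_class, ctx_motif, ctx_base,
                            alternative = "greater") {
  tab <- matrix(c(mut_in_motif, mut_in_class - mut_in_motif,
                  ctx_motif, ctx_base - ctx_motif),
                nrow = 2, byrow = TRUE)
  check_that(all(tab >= 0), "negative cell in enrichment table")
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Benjamini-Hochberg correction
#'
#' Standard step-up BH q-values; the family is all samples tested for one
#' signature.
#'
#' @param p vector of p-values in \[0, 1\]
#' @return q-values, same order as `p`
#' @export
bh_correct <- function(p) {
  check_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Minimum mutation load of an enriched signature
#'
#' `mut_in_motif * (enrichment - 1) / enrichment` when `enrichment > 1` and
#' `q < alpha`; 0 otherwise. A conservative lower bound on the number of
#' mutations attributable to the motif-specific process.
#'
#' @param mut_in_motif motif mutation count
#' @param enrichment enrichment ratio
#' @param q BH-corrected p-value
#' @param alpha significance gate (default 0.05)
#' @return non-negative load estimate
#' @export
minimum_mutation_load <- function(mut_in_motif, enrichment, q, alpha = 0.05) {
  if (is.nan(enrichment) || is.na(q) || enrichment <= 1 || q >= alpha)
    return(0)
  if (is.infinite(enrichment)) return(as.numeric(mut_in_motif))
  mut_in_motif * (enrichment - 1) / enrichment
}

#' Availability-corrected attributable load
#'
#' Point estimate of the number of class mutations attributable to the
#' motif-specific process: `(mut_in_motif - mut_in_class * r) / (1 - r)`
#' with `r = ctx_motif / ctx_base` the motif availability among context
#' bases. Unlike the minimum load (which discounts in-motif process
#' mutations by the availability), this estimator is unbiased for a process
#' placing all its mutations in-motif over a uniform background. Gated like
#' the minimum load and clamped to `[0, mut_in_motif]`.
#'
#' @inheritParams enrichment
#' @param q BH-corrected p-value
#' @param alpha significance gate
#' @return non-negative load estimate
#' @export
attributable_load <- function(mut_in_motif, mut_in_class, ctx_motif,
                              ctx_base, q, alpha = 0.05) {
  e <- enrichment(mut_in_motif, mut_in_class, ctx_motif, ctx_base)
  if (is.nan(e) || is.na(q) || e <= 1 || q >= alpha) return(0)
  if (is.infinite(e)) return(as.numeric(mut_in_motif))
  r <- ctx_motif / ctx_base
  est <- (mut_in_motif - mut_in_class * r) / (1 - r)
  min(max(est, 0), mut_in_motif)
}

#' Count CC->TT dinucleotide substitutions
#'
#' Counts same-sample pairs of substitutions at adjacent positions forming
#' CC->TT on either strand (two adjacent C->T records, or two adjacent G->A
#' records read on the reverse complement). Each pair is counted once.
#'
#' @param snvs SNV data.frame
#' @return data.frame with `sample_id` and `cc_tt` count per sample
#' @export
count_cc_tt <- function(snvs) {
  samples <- unique(snvs$sample_id)
  n <- vapply(samples, function(s) {
    d <- snvs[snvs$sample_id == s, , drop = FALSE]
    tot <- 0L
    for (strand in list(c("C", "T"), c("G", "A"))) {
      dd <- d[d$ref == strand[1] & d$alt == strand[2], , drop = FALSE]
      if (nrow(dd) < 2) next
      keys <- paste(dd$chrom, dd$pos, sep = ":")
      nxt <- paste(dd$chrom, dd$pos + 1L, sep = ":")
      tot <- tot + sum(nxt %in% keys)
    }
    tot
  }, integer(1))
  data.frame(sample_id = samples, cc_tt = as.integer(n),
             stringsAsFactors = FALSE)
}

# records of the pyrimidine-normalised base-change class of a signature
class_records <- function(snvs, sig) {
  snvs[(snvs$ref == sig$from_base & snvs$alt == sig$to_base) |
         (snvs$ref == comp_chr(sig$from_base) &
            snvs$alt == comp_chr(sig$to_base)), , drop = FALSE]
}

#' Run the motif-enrichment panel over a clonal catalog
#'
#' Applies complex-mutation exclusion, builds +/- `flank` context windows
#' around every mutation of each signature's base-change class, computes
#' per-sample enrichment, one-sided Fisher p, BH q across samples within
#' each signature, minimum mutation load and the availability-corrected
#' attributable load, plus per-sample CC->TT dinucleotide counts (taken
#' from the unexcluded catalog, since CC->TT pairs are themselves
#' closely spaced).
#'
#' @param snvs clonal SNV data.frame
#' @param reference `ref_genome`
#' @param signatures list of [motif_signature()] (default
#'   [builtin_signatures()])
#' @param flank context half-width in bp (default 20)
#' @param min_spacing complex-mutation spacing (default 10)
#' @param alpha significance gate for load estimates (default 0.05)
#' @param alternative Fisher sidedness (default "greater")
#' @param dedup deduplicate context bases shared by overlapping windows
#' @return list of class `enrichment_panel` with `results` (one row per
#'   sample x signature) and `cc_tt` (per-sample dinucleotide counts)
#' @export
run_panel <- function(snvs, reference, signatures = builtin_signatures(),
                      flank = 20, min_spacing = 10, alpha = 0.05,
                      alternative = "greater", dedup = FALSE) {
  snvs <- validate_snvs(snvs)
  cc <- count_cc_tt(snvs)
  kept <- exclude_complex(snvs, min_spacing)
  samples <- unique(snvs$sample_id)
  rows <- list()
  for (sig in signatures) {
    per_sig <- lapply(samples, function(s) {
      d <- class_records(kept[kept$sample_id == s, , drop = FALSE], sig)
      win <- fetch_windows(reference, d$chrom, d$pos, flank)
      cnt <- count_motif_and_base(win, sig, chrom = d$chrom, pos = d$pos,
                                  dedup = dedup)
      e <- enrichment(cnt$mut_in_motif, cnt$mut_in_class, cnt$ctx_motif,
                      cnt$ctx_base)
      p <- enrichment_test(cnt$mut_in_motif, cnt$mut_in_class,
                           cnt$ctx_motif, cnt$ctx_base,
                           alternative = alternative)
      data.frame(sample_id = s, signature = sig$name,
                 mut_in_motif = cnt$mut_in_motif,
                 mut_in_class = cnt$mut_in_class,
                 ctx_motif = cnt$ctx_motif, ctx_base = cnt$ctx_base,
                 ctx_motif_far = cnt$ctx_motif_far,
                 ctx_base_far = cnt$ctx_base_far,
                 enrichment = e, p = p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_sig)
    df$q <- bh_correct(df$p)
    df$min_load <- mapply(minimum_mutation_load, df$mut_in_motif,
                          df$enrichment, df$q, MoreArgs = list(alpha = alpha))
    df$attributable_load <- mapply(attributable_load, df$mut_in_motif,
                                   df$mut_in_class, df$ctx_motif_far,
                                   df$ctx_base_far, df$q,
                                   MoreArgs = list(alpha = alpha))
    rows[[sig$name]] <- df
  }
  structure(list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 cc_tt = cc),
            class = "enrichment_panel")
}

#' @export
print.enrichment_panel <- function(x, ...) {
  cat("Motif enrichment panel:", length(unique(x$results$signature)),
      "signature(s) x", length(unique(x$results$sample_id)), "sample(s)\n")
  sig <- x$results[x$results$min_load > 0, ]
  cat(nrow(sig), "sample x signature pairs with significant enrichment\n")
  invisible(x)
}
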