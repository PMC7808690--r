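# Independent oracles, deliberately written with different primitives than
# the implementation they check.

# Fisher exact p for the 2x2 table [[a, b], [c, d]] by hypergeometric
# enumeration with choose() arithmetic
fisher_oracle <- function(a, b, c, d, alternative = "greater") {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  pa <- probs[xs == a]
  switch(alternative,
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]),
         two.sided = sum(probs[probs <= pa * (1 + 1e-7)]))
}

# two-sided exact Mann-Whitney p by full enumeration of group assignments
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- combn(length(pooled), n1, u_of)
  lo <- mean(all_u <= u_obs + 1e-9)
  hi <- mean(all_u >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# step-up BH directly from the defining formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- prev
  }
  q
}

# naive per-window position-by-position motif/base scan (flank-2..w-1
# context columns, centre excluded), using explicit reverse complementation
# of each trinucleotide
motif_count_oracle <- function(windows, motif, from_base) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), N = c("A", "C", "G", "T"))
  msym <- toupper(strsplit(motif, "")[[1]])
  match3 <- function(tri) {
    b <- strsplit(tri, "")[[1]]
    ok <- function(t3) all(vapply(1:3, function(i)
      t3[i] %in% sets[[msym[i]]], logical(1)))
    rc <- rev(chartr("ACGTN", "TGCAN", b))
    ok(b) || ok(rc)
  }
  mm <- 0L; cm <- 0L; cb <- 0L; cmf <- 0L; cbf <- 0L
  w <- nchar(windows[1]); ctr <- (w + 1) / 2
  fromc <- chartr("ACGT", "TGCA", from_base)
  for (win in windows) {
    for (j in 2:(w - 1)) {
      tri <- substr(win, j - 1, j + 1)
      bj <- substr(win, j, j)
      is_base <- bj %in% c(from_base, fromc)
      hit <- is_base && match3(tri)
      if (j == ctr) {
        if (hit) mm <- mm + 1L
      } else if (is_base) {
        cb <- cb + 1L
        if (hit) cm <- cm + 1L
        if (abs(j - ctr) > 1) {
          cbf <- cbf + 1L
          if (hit) cmf <- cmf + 1L
        }
      }
    }
  }
  list(mut_in_motif = mm, mut_in_class = length(windows),
       ctx_motif = cm, ctx_base = cb, ctx_motif_far = cmf,
       ctx_base_far = cbf)
}

# O(n^2) hotspot membership oracle: transitive closure over pairwise
# breakpoint distances, then the >= 2 SVs / >= 2 samples rule
hotspot_oracle <- function(svs, max_gap) {
  bp <- data.frame(sv = rep(seq_len(nrow(svs)), 2),
                   sample = rep(svs$sample_id, 2),
                   chrom = c(svs$chrom1, svs$chrom2),
                   pos = c(svs$pos1, svs$pos2))
  n <- nrow(bp)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (bp$chrom[i] == bp$chrom[j] &&
          abs(bp$pos[i] - bp$pos[j]) <= max_gap &&
          grp[i] != grp[j]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  in_hot <- rep(FALSE, nrow(svs))
  for (g in unique(grp)) {
    mem <- bp[grp == g, ]
    if (length(unique(mem$sv)) >= 2 && length(unique(mem$sample)) >= 2)
      in_hot[unique(mem$sv)] <- TRUE
  }
  in_hot
}

# independent SBS96 classifier built on Biostrings
sbs96_oracle_label <- function(tri, alt) {
  if (substr(tri, 2, 2) %in% c("A", "G")) {
    tri <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
    alt <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  }
  paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt, "]",
         substr(tri, 3, 3))
}
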