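# Shared fixture builders. Everything is generated in code; no binary data.

# fixed tiny reference for hand-checked examples
tiny_ref <- function() {
  ref_genome(c(chrA = "ACGTACGTACGTTTTTTACGCGCGTAGCTAGCTAACCGGTT",
               chrB = "TTTTCCCCGGGGAAAATTCGATCGATCG"))
}

# random reference with uniform base composition
random_ref <- function(len = 1e4, seed = 1, chroms = 1, gc = 0.5) {
  with_seed(seed, {
    seqs <- vapply(seq_len(chroms), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = ""), character(1))
    names(seqs) <- paste0("chr", seq_len(chroms))
    ref_genome(seqs)
  })
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

snv_df <- function(sample_id, chrom, pos, ref, alt, vaf = 0.5) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, vaf = vaf, stringsAsFactors = FALSE)
}

indel_df <- function(sample_id, chrom, pos, ref_allele, alt_allele,
                     qual = 90, vaf = 0.5) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref_allele = ref_allele, alt_allele = alt_allele, qual = qual,
             vaf = vaf, stringsAsFactors = FALSE)
}

sv_df <- function(sample_id, sv_type, chrom1, pos1, chrom2, pos2,
                  jv = 10, jt = 20, blood = 0) {
  data.frame(sample_id = sample_id, sv_type = sv_type, chrom1 = chrom1,
             pos1 = as.integer(pos1), chrom2 = chrom2,
             pos2 = as.integer(pos2), junction_reads_variant = jv,
             junction_reads_total = jt, blood_variant_reads = blood,
             stringsAsFactors = FALSE)
}

# mirror a catalog onto the reverse-complemented reference
mirror_snvs <- function(snvs, reference) {
  lens <- seq_lengths(reference)
  data.frame(sample_id = snvs$sample_id, chrom = snvs$chrom,
             pos = as.integer(lens[snvs$chrom] - snvs$pos + 1L),
             ref = chartr("ACGT", "TGCA", snvs$ref),
             alt = chartr("ACGT", "TGCA", snvs$alt),
             vaf = snvs$vaf, stringsAsFactors = FALSE)
}

# small fast sim config for end-to-end tests that do not need cohort scale
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, genome_length = 1.2e5, n_chromosomes = 2,
             n_donors = 6, n_fibroblasts = 8, n_melanocytes = 2,
             background_median = 150, uv_median = c(White = 80,
                                                    AfricanAmerican = 0),
             n_fragile_sites = 4, sv_max_gap = 1500, fragile_width = 1000,
             ...)
}
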