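# Builds the synthetic signature-catalog fixtures shipped under
# inst/extdata/. These are stand-ins constructed to have the qualitative
# channel concentrations of well-known processes (CpG deamination, clock-like
# flat, UV photoproduct bypass, oxidative damage; homopolymer slippage
# insertions/deletions, end-joining deletions) so that refitting and cosine
# tests need no external downloads. They are NOT the COSMIC matrices; users
# analysing real data should point refit()/cosine_sim() at the real files.
#
# Run from the package root:  Rscript data-raw/make_signature_fixtures.R

suppressMessages(pkgload::load_all(".", quiet = TRUE))

norm1 <- function(x) x / sum(x)

sbs <- sbs96_channels()
sub_of <- function(ch) substr(ch, 3, 5)
l5 <- substr(sbs, 1, 1)
r3 <- substr(sbs, 7, 7)

w_cpg <- ifelse(sub_of(sbs) == "C>T" & r3 == "G", 20, 0.2)
w_flat <- 1 + 0.5 * seq_along(sbs) %% 7 / 7
w_uv <- ifelse(sub_of(sbs) == "C>T" & l5 %in% c("C", "T"), 11, 0.15)
w_oxo <- ifelse(sub_of(sbs) == "C>A", 4.7, 0.25)

sbs_cat <- data.frame(channel = sbs,
                      SBS1_like = norm1(w_cpg),
                      SBS5_like = norm1(w_flat),
                      SBS7b_like = norm1(w_uv),
                      SBS18_like = norm1(w_oxo))

id <- id83_channels()
w_id1 <- ifelse(id %in% c("1:Ins:T:4", "1:Ins:T:5"), 30,
                ifelse(grepl("^1:Ins", id), 2, 0.05))
w_id2 <- ifelse(id %in% c("1:Del:T:4", "1:Del:T:5"), 30,
                ifelse(grepl("^1:Del", id), 2, 0.05))
w_id8 <- ifelse(grepl("^5:Del", id), 8, 0.1)

id_cat <- data.frame(channel = id,
                     ID1_like = norm1(w_id1),
                     ID2_like = norm1(w_id2),
                     ID8_like = norm1(w_id8))

fmt <- function(df, path) {
  df[-1] <- lapply(df[-1], function(x) formatC(x, digits = 10, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
fmt(sbs_cat, "inst/extdata/signatures_sbs96_synthetic.tsv")
fmt(id_cat, "inst/extdata/signatures_id83_synthetic.tsv")
cat("wrote inst/extdata fixtures\n")
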