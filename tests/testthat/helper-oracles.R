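# Independent oracles and small fixture builders used across the suite.

# Independently coded ensemble screening rule: a direct nested-if transcription
# of the published triage text, kept deliberately separate from the package's
# implementation so the two can be compared cell by cell.
oracle_screen_rule <- function(length_bp, topology, cat, dvf, dvfp, marvel,
                               catv, catf) {
  pres <- function(x) !is.na(x)
  min_len <- if (topology == "circular") 1500 else 5000
  if (length_bp < min_len) return("sub_length.none")
  kept <- pres(cat) ||
    (pres(dvf) && pres(dvfp) && dvf >= 0.7 && dvfp < 0.05) ||
    (pres(marvel) && marvel >= 70)
  if (!kept) return("rejected.none")
  if ((pres(cat) && cat %in% c(1, 2, 4, 5)) ||
      (pres(dvf) && dvf >= 0.9) ||
      (pres(marvel) && marvel >= 90)) return("viral.high_confidence")
  n <- 0
  if (pres(cat) && cat %in% c(3, 6)) n <- n + 1
  if (pres(dvf) && pres(dvfp) && dvf >= 0.7 && dvf < 0.9 && dvfp < 0.05) n <- n + 1
  if (pres(marvel) && marvel >= 70 && marvel < 90) n <- n + 1
  if ((pres(catv) && catv) || (pres(catf) && catf < 0.4)) n <- n + 1
  if (n >= 2) "viral.two_tool" else "rejected.none"
}

# one score record as classify_contig expects it
score_record <- function(length_bp = 6000, topology = "linear",
                         virsorter_category = NA, dvf_score = NA, dvf_p = NA,
                         marvel_prob = NA, cat_viral = NA,
                         cat_nonviral_gene_frac = NA,
                         contig_id = "c1") {
  list(contig_id = contig_id, length_bp = length_bp, topology = topology,
       virsorter_category = virsorter_category, dvf_score = dvf_score,
       dvf_p = dvf_p, marvel_prob = marvel_prob, cat_viral = cat_viral,
       cat_nonviral_gene_frac = cat_nonviral_gene_frac)
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_protein <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  hit <- runif(length(x)) < rate
  x[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(x, collapse = "")
}

# nucleotide cassette encoding a given number of non-stop codons behind an
# ATG, terminated by TAA, preceded by an in-frame TAA stop
plant_gene_cassette <- function(n_codons) {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  safe <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  body <- paste(sample(safe, n_codons - 1L, replace = TRUE), collapse = "")
  paste0("TAA", "ATG", body, "TAA")
}

# exhaustive enumeration oracle for the ANOSIM permutation distribution
anosim_r_stat <- function(d, groups) {
  d <- as.matrix(d)
  lower <- which(lower.tri(d))
  rd <- rank(d[lower])
  same <- (groups[row(d)[lower]] == groups[col(d)[lower]])
  m <- length(rd)
  (mean(rd[!same]) - mean(rd[same])) / (m / 2)
}
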