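test_that("six-frame ORF calling recovers planted genes with exact coordinates", {
  set.seed(19)
  cassette <- plant_gene_cassette(100)   # TAA + ATG + 99 codons + TAA
  prefix <- rand_dna(1501)               # shifts the cassette to frame 1
  genome <- paste0(prefix, cassette, rand_dna(1200))
  orfs <- call_orfs(c(g = genome))
  start0 <- nchar(prefix) + 3L           # 0-based start of the ATG
  hit <- orfs[orfs$start == start0 & orfs$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, start0 + 3L * 101L)  # stop codon included
  expect_equal(hit$length_aa, 100)
  expect_equal(substr(hit$aa_seq, 1, 1), "M")
  expect_false(grepl("\\*", hit$aa_seq))

  # reverse-strand gene: forward coordinates plus strand flag
  genome_rc <- paste0(rand_dna(900), revcomp(cassette), rand_dna(800))
  orfs_rc <- call_orfs(c(g = genome_rc))
  # the ORF (ATG..stop) maps to forward coordinates just after the 900-bp pad
  hit_rc <- orfs_rc[orfs_rc$strand == "-" & orfs_rc$start == 900, ]
  expect_equal(nrow(hit_rc), 1)
  expect_equal(hit_rc$end, 900 + 3 * 101)
  expect_equal(hit_rc$length_aa, 100)

  # an all-stop sequence yields nothing
  expect_equal(nrow(call_orfs(c(x = strrep("TAA", 400)))), 0)
})

test_that("greedy protein clustering groups families and splits strangers", {
  set.seed(23)
  fam_a <- rand_protein(150)
  fam_b <- rand_protein(220)
  fam_c <- rand_protein(90)
  orfs <- data.frame(
    orf_id = sprintf("o%02d", 1:9),
    genome_id = rep(c("g1", "g2", "g3"), 3),
    aa_seq = c(fam_a, mutate_protein(fam_a, 0.3), mutate_protein(fam_a, 0.3),
               fam_b, mutate_protein(fam_b, 0.3), mutate_protein(fam_b, 0.3),
               fam_c, mutate_protein(fam_c, 0.3), mutate_protein(fam_c, 0.3)),
    stringsAsFactors = FALSE)
  orfs$length_aa <- nchar(orfs$aa_seq)
  pcs <- cluster_proteins(orfs)
  expect_equal(pcs$n_pcs, 3)
  fam <- rep(c("A", "B", "C"), each = 3)
  grp <- split(pcs$membership$pc_id,
               fam[match(pcs$membership$orf_id, orfs$orf_id)])
  for (g in grp) expect_equal(length(unique(g)), 1)
  expect_equal(length(unique(vapply(grp, unique, character(1)))), 3)

  # two identical proteins share a PC; unrelated proteins do not
  two <- data.frame(orf_id = c("a", "b"), genome_id = c("x", "y"),
                    aa_seq = c(fam_a, fam_a), length_aa = nchar(fam_a),
                    stringsAsFactors = FALSE)
  expect_equal(cluster_proteins(two)$n_pcs, 1)
  far <- data.frame(orf_id = c("a", "b"), genome_id = c("x", "y"),
                    aa_seq = c(fam_a, rand_protein(150)),
                    length_aa = 150, stringsAsFactors = FALSE)
  expect_equal(cluster_proteins(far)$n_pcs, 2)
})

test_that("shared-PC significance is exact hypergeometric", {
  s <- pair_significance(character(0), character(0), 10)
  expect_equal(s$p, 1)
  expect_equal(s$weight, 0)

  s <- pair_significance(c("p1", "p2", "p3"), c("p1", "p2", "p3"), 10)
  expect_equal(s$p, 1 / 120, tolerance = 1e-12)
  expect_equal(s$weight, -log10(1 / 120), tolerance = 1e-9)

  s <- pair_significance(c("p1", "p2"), c("p1", "p9"), 6)
  expect_equal(s$p, 0.6, tolerance = 1e-12)
  expect_equal(s$weight, -log10(0.6), tolerance = 1e-9)

  # weight is monotone in the shared count
  p_by_c <- vapply(0:3, function(cc) {
    a <- paste0("s", 1:3)
    b <- c(if (cc > 0) a[seq_len(cc)], if (cc < 3) paste0("t", seq_len(3 - cc)))
    pair_significance(a, b, 20)$weight
  }, numeric(1))
  expect_true(all(diff(p_by_c) > 0))
})

test_that("viral clusters, outliers and singletons form a trichotomy", {
  # three planted genus groups with high intra-group PC overlap, none between
  presence <- list(
    a1 = paste0("A", 1:20), a2 = paste0("A", 3:22), a3 = paste0("A", 1:18),
    b1 = paste0("B", 1:15), b2 = paste0("B", 2:16), b3 = paste0("B", 1:14),
    c1 = paste0("C", 1:12), c2 = paste0("C", 1:10), c3 = paste0("C", 3:12),
    lone = paste0("L", 1:8))
  vc <- build_viral_clusters(presence)
  asn <- vc$assignments
  expect_equal(sort(unique(asn$class)), c("clustered", "singleton"))
  expect_equal(length(unique(na.omit(asn$vc_id))), 3)
  expect_equal(asn$class[asn$genome_id == "lone"], "singleton")
  by_vc <- split(asn$genome_id, asn$vc_id)
  expect_setequal(vapply(by_vc, function(g)
    length(unique(substr(g, 1, 1))), integer(1)), rep(1L, 3))

  # trichotomy: each genome exactly one class
  expect_true(all(asn$class %in% c("clustered", "outlier", "singleton")))

  # one weakly shared PC in a large universe: edge below sig_min -> outliers
  weak <- list(x = c(paste0("X", 1:3), "S1"), y = c(paste0("Y", 1:3), "S1"))
  weak_universe <- c(weak, list(z = paste0("Z", 1:40)))
  vcw <- build_viral_clusters(weak_universe, sig_min = 2.5)
  expect_true(all(vcw$assignments$class[vcw$assignments$genome_id %in%
                                          c("x", "y")] == "outlier"))

  # reference co-clustering flags VCs but leaves other relationships alone
  with_ref <- c(presence, list(ref1 = paste0("A", 5:20)))
  vcr <- build_viral_clusters(with_ref, reference_ids = "ref1")
  asn_r <- vcr$assignments
  a_vc <- unique(asn_r$vc_id[asn_r$genome_id %in% c("a1", "a2", "a3")])
  expect_length(a_vc, 1)
  expect_true(all(asn_r$shares_reference[asn_r$vc_id %in% a_vc]))
  expect_false(any(asn_r$shares_reference[asn_r$genome_id %in%
                                            c("b1", "b2", "b3", "c1", "c2", "c3")]))
  # non-reference relationships unchanged
  pairs_before <- setNames(asn$vc_id, asn$genome_id)
  pairs_after <- setNames(asn_r$vc_id, asn_r$genome_id)
  same_vc <- function(m, x, y) !is.na(m[x]) && !is.na(m[y]) && m[x] == m[y]
  for (pp in list(c("a1", "a2"), c("b1", "b3"), c("a1", "b1"), c("c1", "lone"))) {
    expect_equal(same_vc(pairs_before, pp[1], pp[2]),
                 same_vc(pairs_after, pp[1], pp[2]))
  }
})

test_that("two genomes sharing all their PCs form one VC", {
  presence <- list(u = paste0("P", 1:6), v = paste0("P", 1:6),
                   w = paste0("Q", 1:30))
  vc <- build_viral_clusters(presence)
  asn <- vc$assignments
  expect_equal(asn$class[asn$genome_id %in% c("u", "v")], rep("clustered", 2))
  expect_equal(asn$vc_id[asn$genome_id == "u"], asn$vc_id[asn$genome_id == "v"])
  expect_equal(asn$class[asn$genome_id == "w"], "singleton")
})
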