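test_that("prophage channel accepts only perfect full-length embeddings", {
  set.seed(29)
  host <- rand_dna(40000)
  virus <- rand_dna(8000)
  embedded <- paste0(substr(host, 1, 15000), virus, substr(host, 15001, 40000))
  calls <- find_prophage_links(c(v1 = virus), c(h1 = embedded))
  expect_equal(nrow(calls), 1)
  expect_true(calls$accepted)
  expect_equal(calls$identity_pct, 100)

  # a single substitution anywhere breaks the strict 100%/100% rule
  virus_mut <- mutate_seq(virus, n_sub = 1)
  expect_equal(nrow(find_prophage_links(c(v1 = virus_mut), c(h1 = embedded))), 0)

  # reverse-complement embeddings count
  embedded_rc <- paste0(substr(host, 1, 15000), revcomp(virus),
                        substr(host, 15001, 40000))
  calls_rc <- find_prophage_links(c(v1 = virus), c(h1 = embedded_rc))
  expect_true(calls_rc$accepted)

  # a co-assembled copy without host flanks is found but not accepted
  no_flank <- paste0(virus, substr(host, 1, 500))
  calls_nf <- find_prophage_links(c(v1 = virus), c(h1 = no_flank))
  expect_equal(nrow(calls_nf), 1)
  expect_false(calls_nf$accepted)
})

test_that("CRISPR arrays are recovered exactly from planted repeats", {
  set.seed(31)
  host <- rand_dna(10000)
  repeat_seq <- rand_dna(30)
  protos <- replicate(3, rand_dna(32))
  planted <- plant_crispr_array(host, protos, n_repeats = 4,
                                repeat_seq = repeat_seq, insert_pos = 5000)
  arrays <- detect_crispr_arrays(planted$seq, "h1")
  expect_length(arrays, 1)
  expect_equal(arrays[[1]]$repeat_seq, repeat_seq)
  expect_identical(arrays[[1]]$spacers$seq, unname(protos))
  expect_equal(arrays[[1]]$spacers$start, planted$truth$spacers$start)
  expect_equal(arrays[[1]]$start, planted$truth$array_start)
  expect_equal(arrays[[1]]$end, planted$truth$array_end)

  # the minimal array (2 repeats, 1 spacer) is detected
  one <- plant_crispr_array(host, protos[1], n_repeats = 2,
                            repeat_seq = repeat_seq, insert_pos = 3000)
  arr1 <- detect_crispr_arrays(one$seq, "h1")
  expect_length(arr1, 1)
  expect_equal(arr1[[1]]$spacers$seq, unname(protos[1]))

  # a clean random sequence has no arrays; fewer than 2 repeats is an error
  expect_length(detect_crispr_arrays(host, "h1"), 0)
  expect_error(plant_crispr_array(host, character(0), 1, repeat_seq, 100),
               "at least 2")
  # array span bookkeeping: 4 repeats + 3 spacers
  expect_equal(planted$truth$array_end - planted$truth$array_start,
               4L * 30L + 3L * 32L)
})

test_that("spacer matching is a pure function of mismatch count and length", {
  set.seed(37)
  virus <- rand_dna(20000)
  spacer <- substr(virus, 501, 532)         # 32 bp, exact
  arr <- list(list(host_id = "h1", start = 0, end = 100, repeat_seq = "x",
                   spacers = data.frame(seq = spacer, start = 0, end = 32,
                                        stringsAsFactors = FALSE)))
  hit <- match_spacers(arr, c(v1 = virus))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$identity_pct, 100)

  # 1 mismatch in 32 bp = 96.9% -> accepted; 2 mismatches = 93.75% -> not
  sp1 <- mutate_seq(spacer, n_sub = 1)
  arr[[1]]$spacers$seq <- sp1
  hit1 <- match_spacers(arr, c(v1 = virus))
  expect_equal(nrow(hit1), 1)
  expect_equal(hit1$identity_pct, 100 * 31 / 32, tolerance = 1e-9)

  sp2 <- mutate_seq(spacer, n_sub = 2)
  arr[[1]]$spacers$seq <- sp2
  expect_equal(nrow(match_spacers(arr, c(v1 = virus))), 0)

  # reverse-strand protospacers are found
  arr[[1]]$spacers$seq <- revcomp(spacer)
  expect_equal(nrow(match_spacers(arr, c(v1 = virus))), 1)
})

test_that("tRNA channel requires exact sharing plus prophage concordance", {
  host_trnas <- data.frame(host_id = c("h1", "h2"), trna_id = c("t1", "t1"),
                           stringsAsFactors = FALSE)
  virus_trnas <- data.frame(virus_id = "v1", trna_id = "t1",
                            stringsAsFactors = FALSE)
  pro <- data.frame(virus_id = "v1", host_id = "h1", channel = "prophage",
                    identity_pct = 100, length_bp = 1L, loglik = NA_real_,
                    p = NA_real_, accepted = TRUE, stringsAsFactors = FALSE)
  calls <- match_trnas(host_trnas, virus_trnas, pro)
  expect_equal(calls$accepted[calls$host_id == "h1"], TRUE)
  expect_equal(calls$accepted[calls$host_id == "h2"], FALSE)

  # a 1-mismatch tRNA is simply never located by the exact matcher
  set.seed(41)
  lib <- c(t1 = rand_dna(75))
  seq_with <- paste0(rand_dna(300), lib[["t1"]], rand_dna(300))
  expect_equal(nrow(find_trnas(seq_with, lib)), 1)
  lib_mut <- c(t1 = mutate_seq(lib[["t1"]], n_sub = 1))
  expect_equal(nrow(find_trnas(seq_with, lib_mut)), 0)
})

test_that("Markov host models have the closed-form smoothed probabilities", {
  m <- train_markov(strrep("A", 100), k = 1, pseudocount = 1,
                    both_strands = FALSE)
  # P(A) = (100 + 1) / (100 + 4)
  expect_equal(markov_loglik(m, "A"), log(101 / 104), tolerance = 1e-12)

  # each conditional distribution sums to 1
  m8 <- train_markov(rand_dna(5000), k = 3)
  p <- matrix(exp(m8$logp), ncol = 4, byrow = TRUE)
  expect_equal(rowSums(p), rep(1, 16), tolerance = 1e-12)

  # strand symmetry: training on seq+revcomp equals training on seq alone
  s <- rand_dna(3000)
  m_both <- train_markov(s, k = 4, both_strands = TRUE)
  m_cat <- train_markov(paste0(s, "NNNN", revcomp(s)), k = 4,
                        both_strands = FALSE)
  expect_equal(m_both$logp, m_cat$logp, tolerance = 1e-12)

  expect_error(train_markov("ACG", k = 8), "shorter")
})

test_that("k-mer channel applies the p~0 / weak-p-with-prophage rule", {
  set.seed(43)
  chains <- lapply(1:4, function(i) new_markov_chain(3))
  hosts <- vapply(chains, markov_generate, character(1), len = 30000)
  names(hosts) <- paste0("h", 1:4)
  models <- lapply(names(hosts), function(h) train_markov(hosts[[h]], h))
  nulls <- lapply(1:10, function(i)
    train_markov(markov_generate(new_markov_chain(3), 20000), paste0("d", i)))
  virus <- mutate_seq(markov_generate(chains[[2]], 20000), rate = 0.05)
  km <- score_kmer_channel(c(v1 = virus), models, nulls)
  expect_equal(km$host_id, "h2")       # parameter recovery
  expect_true(km$p >= 0 && km$p <= 1)

  # weak p alone is not accepted; with a concordant prophage call it is.
  # A decoy-like virus gives a moderate p against every candidate model.
  stranger <- markov_generate(new_markov_chain(3), 20000)
  weak <- score_kmer_channel(c(vx = stranger), models, nulls)
  expect_gt(weak$p, 1e-10)
  expect_false(weak$accepted)
  pro <- data.frame(virus_id = "vx", host_id = weak$host_id,
                    channel = "prophage", identity_pct = 100, length_bp = 1L,
                    loglik = NA_real_, p = NA_real_, accepted = TRUE,
                    stringsAsFactors = FALSE)
  with_pro <- score_kmer_channel(c(vx = stranger), models, nulls,
                                 prophage_calls = pro, p_weak = 1)
  expect_true(with_pro$accepted)

  expect_error(score_kmer_channel(c(v1 = virus), models[1], nulls), "at least 2")
  expect_error(score_kmer_channel(c(v1 = virus), models, nulls[1:5]),
               "at least 10")
})

test_that("consensus applies the channel priority and reports linkage", {
  calls <- rbind(
    data.frame(virus_id = "v1", host_id = "MAG2", channel = "kmer",
               identity_pct = NA, length_bp = NA, loglik = -1.3, p = 1e-12,
               accepted = TRUE),
    data.frame(virus_id = "v1", host_id = "MAG1", channel = "prophage",
               identity_pct = 100, length_bp = 8000, loglik = NA, p = NA,
               accepted = TRUE),
    data.frame(virus_id = "v2", host_id = "MAG3", channel = "crispr",
               identity_pct = 100, length_bp = 32, loglik = NA, p = NA,
               accepted = FALSE))
  out <- consensus_hosts(calls, virus_ids = c("v1", "v2", "v3"))
  expect_equal(nrow(out$consensus), 1)
  expect_equal(out$consensus$host_id, "MAG1")
  expect_equal(out$consensus$primary_channel, "prophage")
  expect_equal(out$consensus$channels, "kmer;prophage")
  expect_equal(out$fraction_linked, 1 / 3)
})

test_that("planted host links are recovered with perfect precision and recall", {
  cfg <- community_config(seed = 5)
  comm <- generate_community(cfg)
  truthv <- comm$truth$viral_status$contig_id[comm$truth$viral_status$viral]
  vs <- comm$contigs[truthv]
  tl <- comm$truth$host_links
  key <- function(df) paste(df$virus_id, df$host_id)

  pro <- find_prophage_links(vs, comm$host_bins)
  acc <- pro[pro$accepted, ]
  tp <- tl[tl$channel == "prophage", ]
  expect_setequal(key(acc), key(tp))   # precision = recall = 1

  arrays <- unlist(lapply(names(comm$host_bins), function(h)
    detect_crispr_arrays(comm$host_bins[[h]], h)), recursive = FALSE)
  cri <- match_spacers(arrays, vs)
  acc <- cri[cri$accepted, ]
  ta <- tl[tl$channel == "crispr", ]
  # recall: every planted (population, host) link is re-found
  expect_true(all(key(ta) %in% key(acc)))
  # precision at the population level: every hit points at a planted pair
  popof <- setNames(comm$truth$populations$population_id,
                    comm$truth$populations$member_id)
  hit_pop <- paste(popof[acc$virus_id], acc$host_id)
  expect_true(all(hit_pop %in% key(ta)))
})
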