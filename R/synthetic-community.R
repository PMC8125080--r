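# Seeded synthetic communities with planted ground truth. Hosts are sampled
# from independent order-3 Markov chains (Dirichlet-random transition rows),
# giving each host a distinct compositional signature; phages of a host are
# sampled from the same chain with extra substitution noise, which is exactly
# the assumption behind k-mer host prediction. Planted features (prophage
# insertions flanked by att repeats, CRISPR arrays targeting phages, shared
# tRNAs, lysogeny marker genes) make every downstream detector testable with
# exact truth tables. All truth coordinates are 0-based half-open.

#' Build a synthetic community configuration
#'
#' Defaults describe a desk-scale bulk-metagenome study: a handful of host
#' bins, a few dozen phage populations, three sample groups of five (one
#' control, two perturbed) with designated responder taxa.
#'
#' @param n_hosts number of host genome bins
#' @param n_phages number of viral populations
#' @param extra_members_per_population additional members per population,
#'   mutated copies of the representative at `within_population` rates
#' @param host_length_bp,phage_length_bp length ranges `c(min, max)`
#' @param host_markov_order order of the per-host Markov source
#' @param markov_alpha Dirichlet concentration of transition rows (smaller =
#'   better-separated host signatures)
#' @param phage_mutation_rates list with `from_host` (substitution rate
#'   applied to a phage drawn from its host's chain) and `within_population`
#'   (`c(min, max)` substitution-rate range between population members)
#' @param att_core_length_bp att core length range
#' @param crispr_repeat_bp,crispr_spacer_bp CRISPR repeat/spacer length ranges
#' @param crispr_spacer_mismatch substitutions applied to each spacer copy
#' @param trna_library named character vector of 70-90 bp tRNA sequences, or
#'   NULL to generate `n_trnas` random ones
#' @param n_trnas library size when generated
#' @param frac_confident_temperate fraction of populations planted as
#'   confident temperate (integrase + att pair + prophage insertion)
#' @param frac_candidate_temperate fraction planted with non-integrase
#'   lysogeny markers only
#' @param frac_circular fraction of non-temperate populations given a direct
#'   terminal repeat (circular topology)
#' @param frac_hosts_with_crispr fraction of hosts carrying a CRISPR array
#' @param n_cellular_contigs_per_host cellular (non-viral) screening
#'   negatives sampled from each host
#' @param cellular_contig_bp length range of cellular contigs
#' @param groups named integer vector: group label -> samples per group
#' @param responder_spec list of lists with `group`, `fold`, `n_features`;
#'   NULL for the default two-up/two-down design
#' @param sample_noise_sdlog lognormal sd of per-sample, per-feature
#'   abundance noise (inter-individual variation within groups)
#' @param depth_per_sample total read count per sample
#' @param score_config predictor score distributions, from
#'   [default_score_config()]
#' @param seed integer RNG seed; fixed seed implies byte-identical output
#' @return object of class `community_config`
#' @export
community_config <- function(n_hosts = 8L,
                             n_phages = 24L,
                             extra_members_per_population = 1L,
                             host_length_bp = c(50000L, 80000L),
                             phage_length_bp = c(15000L, 35000L),
                             host_markov_order = 3L,
                             markov_alpha = 1,
                             phage_mutation_rates = list(
                               from_host = 0.05,
                               within_population = c(0.01, 0.03)),
                             att_core_length_bp = c(12L, 16L),
                             crispr_repeat_bp = c(23L, 47L),
                             crispr_spacer_bp = c(26L, 50L),
                             crispr_spacer_mismatch = 0L,
                             trna_library = NULL,
                             n_trnas = 12L,
                             frac_confident_temperate = 0.2,
                             frac_candidate_temperate = 0.15,
                             frac_circular = 0.15,
                             frac_hosts_with_crispr = 0.75,
                             n_cellular_contigs_per_host = 2L,
                             cellular_contig_bp = c(6000L, 15000L),
                             groups = c(control = 5L, treatment1 = 5L,
                                        treatment2 = 5L),
                             responder_spec = NULL,
                             sample_noise_sdlog = 0.4,
                             depth_per_sample = 2e5,
                             score_config = default_score_config(),
                             seed = 1L) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(r <= 0) || r[2L] < r[1L])
      stop("invalid range for ", nm)
  }
  chk_range(host_length_bp, "host_length_bp")
  chk_range(phage_length_bp, "phage_length_bp")
  chk_range(att_core_length_bp, "att_core_length_bp")
  chk_range(crispr_repeat_bp, "crispr_repeat_bp")
  chk_range(crispr_spacer_bp, "crispr_spacer_bp")
  chk_range(cellular_contig_bp, "cellular_contig_bp")
  if (n_hosts < 1L) stop("need at least one host")
  if (n_phages < 0L) stop("n_phages must be >= 0")
  if (is.null(names(groups)) || any(groups < 2L))
    stop("groups must be named with >= 2 samples per group")
  if (depth_per_sample <= 0) stop("depth_per_sample must be positive")
  if (is.null(responder_spec)) {
    gl <- names(groups)[-1L]
    responder_spec <- list(
      list(group = gl[1L], fold = 8, n_features = 2L),
      list(group = gl[min(2L, length(gl))], fold = 0.125, n_features = 2L))
  }
  structure(as.list(environment()), class = "community_config")
}

#' Insert a prophage into a host sequence, flanked by att direct repeats
#'
#' The modified host contains `att_core` + `phage_seq` + `att_core` inserted
#' before the base at 0-based offset `insert_pos`, emulating site-specific
#' integration that leaves attL/attR hybrid sites as a direct repeat.
#'
#' @param host_seq host sequence (character scalar)
#' @param phage_seq phage sequence (non-empty)
#' @param att_core att core sequence; must not already occur in the host
#'   (ambiguity guard; an `att_ambiguity` error asks the caller to draw a
#'   new core)
#' @param insert_pos 0-based insertion offset within the host
#' @return list with `seq` (modified host) and `truth` (data.frame of
#'   0-based half-open attL/attR and phage coordinates)
#' @export
plant_prophage <- function(host_seq, phage_seq, att_core, insert_pos) {
  if (nchar(phage_seq) == 0L) stop("empty phage sequence")
  if (nchar(att_core) == 0L) stop("empty att core")
  if (insert_pos < 0L || insert_pos > nchar(host_seq))
    stop("insert_pos outside host")
  if (grepl(att_core, host_seq, fixed = TRUE)) {
    stop(structure(class = c("att_ambiguity", "error", "condition"),
                   list(message = "att core already occurs in host; regenerate",
                        call = sys.call())))
  }
  alen <- nchar(att_core); plen <- nchar(phage_seq)
  frag <- paste0(att_core, phage_seq, att_core)
  res <- apply_insertions(host_seq, data.frame(pos = insert_pos, frag = frag,
                                               stringsAsFactors = FALSE))
  s <- res$coords$start[1L]
  truth <- data.frame(attL_start = s, attL_end = s + alen,
                      phage_start = s + alen, phage_end = s + alen + plen,
                      attR_start = s + alen + plen,
                      attR_end = s + 2L * alen + plen)
  list(seq = res$seq, truth = truth)
}

#' Plant a CRISPR array into a host sequence
#'
#' The array is repeat + (spacer + repeat) x (n_repeats - 1), with spacers
#' copied from the protospacers (optionally with planted mismatches).
#'
#' @param host_seq host sequence
#' @param protospacers character vector of length `n_repeats - 1`
#' @param n_repeats number of repeat copies (>= 2)
#' @param repeat_seq the repeat sequence
#' @param insert_pos 0-based insertion offset
#' @param spacer_mismatch substitutions applied to each spacer copy
#' @return list with `seq` and `truth` (array span plus per-spacer 0-based
#'   half-open coordinates in the modified host)
#' @export
plant_crispr_array <- function(host_seq, protospacers, n_repeats, repeat_seq,
                               insert_pos, spacer_mismatch = 0L) {
  if (n_repeats < 2L) stop("a CRISPR array needs at least 2 repeats")
  if (length(protospacers) != n_repeats - 1L)
    stop("need exactly n_repeats - 1 protospacers")
  spacers <- vapply(protospacers, mutate_seq, character(1),
                    n_sub = spacer_mismatch, USE.NAMES = FALSE)
  frag <- paste0(repeat_seq, paste0(spacers, repeat_seq, collapse = ""))
  res <- apply_insertions(host_seq, data.frame(pos = insert_pos, frag = frag,
                                               stringsAsFactors = FALSE))
  s <- res$coords$start[1L]
  rlen <- nchar(repeat_seq)
  sp_start <- s + rlen + (seq_along(spacers) - 1L) * (rlen + nchar(spacers))
  truth <- list(array_start = s, array_end = s + nchar(frag),
                repeat_seq = repeat_seq,
                spacers = data.frame(seq = spacers, start = sp_start,
                                     end = sp_start + nchar(spacers),
                                     stringsAsFactors = FALSE))
  list(seq = res$seq, truth = truth)
}

#' Predictor score distributions for the score simulator
#'
#' @param mode "default" (noisy, realistic sparsity), "perfect" (true phages
#'   always VirSorter category 1, cellular contigs all-missing) or "none"
#'   (every channel missing for every contig)
#' @return list of per-label sampling parameters
#' @export
default_score_config <- function(mode = c("default", "perfect", "none")) {
  mode <- match.arg(mode)
  list(mode = mode)
}

#' Simulate per-contig predictor scores conditioned on true viral status
#'
#' True phages draw from viral-like distributions, cellular contigs from
#' cellular-like ones; every channel has a configurable missing-value
#' probability (missingness is the norm in real predictor output).
#'
#' @param contig_table data.frame with `contig_id`, `length_bp`, `topology`
#' @param viral_status logical vector (TRUE = truly viral), aligned to rows
#' @param score_config from [default_score_config()]
#' @param seed optional RNG seed
#' @return score table data.frame (one row per contig)
#' @export
simulate_tool_scores <- function(contig_table, viral_status,
                                 score_config = default_score_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(contig_table)
  stopifnot(length(viral_status) == n)
  vs_cat <- rep(NA_integer_, n); dvf <- rep(NA_real_, n)
  dvfp <- rep(NA_real_, n); mvl <- rep(NA_real_, n)
  catv <- rep(NA, n); catf <- rep(NA_real_, n)
  mode <- score_config$mode
  if (mode == "perfect") {
    vs_cat[viral_status] <- 1L
  } else if (mode == "default") {
    for (i in seq_len(n)) {
      if (viral_status[i]) {
        if (runif(1) < 0.85)
          vs_cat[i] <- sample(c(1L, 2L, 4L, 5L, 3L, 6L), 1L,
                              prob = c(.28, .28, .12, .12, .1, .1))
        if (runif(1) < 0.9) {
          dvf[i] <- rbeta(1, 8, 2)
          dvfp[i] <- runif(1, 0, 0.04)
        }
        if (runif(1) < 0.8) mvl[i] <- runif(1, 70, 100)
        if (runif(1) < 0.9) {
          catv[i] <- runif(1) < 0.8
          catf[i] <- runif(1, 0, 0.39)
        }
      } else {
        if (runif(1) < 0.05) vs_cat[i] <- sample(c(3L, 6L), 1L)
        if (runif(1) < 0.9) {
          dvf[i] <- rbeta(1, 2, 8)
          dvfp[i] <- runif(1, 0.05, 1)
        }
        if (runif(1) < 0.8) mvl[i] <- runif(1, 0, 69)
        if (runif(1) < 0.9) {
          catv[i] <- FALSE
          catf[i] <- runif(1, 0.41, 1)
        }
      }
    }
  }
  data.frame(contig_id = contig_table$contig_id,
             length_bp = contig_table$length_bp,
             topology = contig_table$topology,
             virsorter_category = vs_cat, dvf_score = dvf, dvf_p = dvfp,
             marvel_prob = mvl, cat_viral = catv,
             cat_nonviral_gene_frac = catf, stringsAsFactors = FALSE)
}

#' Multinomial count simulation from per-sample abundance profiles
#'
#' @param profiles features x samples matrix of expected proportions (each
#'   column sums to 1)
#' @param depth total counts per sample (scalar or per-sample vector)
#' @param seed optional RNG seed
#' @return integer count matrix of the same shape
#' @export
simulate_counts <- function(profiles, depth, seed = NULL) {
  if (any(depth <= 0)) stop("depth must be positive")
  stopifnot(all(abs(colSums(profiles) - 1) < 1e-8))
  if (!is.null(seed)) set.seed(seed)
  depth <- rep_len(depth, ncol(profiles))
  counts <- vapply(seq_len(ncol(profiles)), function(j) {
    rmultinom(1L, size = depth[j], prob = profiles[, j])[, 1L]
  }, integer(nrow(profiles)))
  dimnames(counts) <- dimnames(profiles)
  counts
}

# ---- internal pieces of generate_community ---------------------------------

.GENE_LABELS <- c("terminase large subunit", "major capsid protein",
                  "portal protein", "tail fiber protein",
                  "baseplate assembly protein", "DNA polymerase",
                  "holin", "endolysin", "hypothetical protein",
                  "tail sheath protein")
.CANDIDATE_MARKERS <- c("excisionase", "CI repressor",
                        "antirepressor protein", "ParA partition protein",
                        "ParB partition protein")

#' @keywords internal
.tile_genes <- function(L, tail_reserve = 2500L) {
  genes <- list()
  pos <- sample(180:260, 1L)   # leave a noncoding head for attL
  while (TRUE) {
    glen <- sample(600:1200, 1L)
    if (pos + glen > L - tail_reserve) break
    genes[[length(genes) + 1L]] <- data.frame(
      start = pos, end = pos + glen,
      strand = sample(c("+", "-"), 1L),
      label = sample(.GENE_LABELS, 1L), stringsAsFactors = FALSE)
    pos <- pos + glen + sample(80:150, 1L)
  }
  do.call(rbind, genes)
}

#' @keywords internal
.plant_att_on_contig <- function(seq, genes, core_range) {
  L <- nchar(seq)
  for (try in 1:20) {
    clen <- sample(core_range[1L]:core_range[2L], 1L)
    core <- rand_dna(clen)
    attL_start <- sample(20:60, 1L)                     # 0-based
    attR_start <- L - clen - sample(60:150, 1L)
    if (attL_start + clen > genes$start[1L]) next
    s2 <- seq
    substr(s2, attL_start + 1L, attL_start + clen) <- core
    substr(s2, attR_start + 1L, attR_start + clen) <- core
    n_occ <- length(gregexpr(core, s2, fixed = TRUE)[[1L]])
    if (n_occ == 2L) {
      return(list(seq = s2, core = core,
                  attL_start = attL_start, attL_end = attL_start + clen,
                  attR_start = attR_start, attR_end = attR_start + clen))
    }
  }
  stop("could not plant an unambiguous att core")
}

#' @keywords internal
.distinct_positions <- function(n, lo, hi, min_gap) {
  stopifnot(hi > lo)
  for (try in 1:50) {
    pos <- sort(sample(lo:hi, n))
    if (n < 2L || all(diff(pos) >= min_gap)) return(pos)
  }
  stop("could not place ", n, " insertions with gap ", min_gap)
}

#' Generate a seeded synthetic community with full ground truth
#'
#' @param config object from [community_config()]
#' @return object of class `virotrace_community`: a list with `contigs`
#'   (named character: phage contigs and cellular fragments), `contig_table`
#'   (`contig_id`, `length_bp` with circular DTR trimmed once, `topology`),
#'   `host_bins` (named character), `scores` (predictor table), `counts`
#'   (features x samples), `design` (`sample_id`, `group`), `annotations`
#'   (phage gene table, 0-based half-open), `trna_library`, and `truth`
#'   (viral status, population membership, host links with channel,
#'   lifestyle, planted-feature coordinates, expected abundance profiles,
#'   responders)
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  cfg <- config

  trna_library <- cfg$trna_library
  if (is.null(trna_library)) {
    trna_library <- setNames(
      vapply(seq_len(cfg$n_trnas), function(i) rand_dna(sample(70:90, 1L)),
             character(1)),
      sprintf("trna_%02d", seq_len(cfg$n_trnas)))
  }

  # hosts: one Markov chain each
  host_ids <- sprintf("MAG_%02d", seq_len(cfg$n_hosts))
  chains <- lapply(host_ids, function(h)
    new_markov_chain(cfg$host_markov_order, cfg$markov_alpha))
  names(chains) <- host_ids
  host_base <- setNames(vapply(host_ids, function(h) {
    markov_generate(chains[[h]], sample(cfg$host_length_bp[1L]:cfg$host_length_bp[2L], 1L))
  }, character(1)), host_ids)

  # phage populations
  n_p <- cfg$n_phages
  pop_ids <- if (n_p > 0L) sprintf("vp_%04d", seq_len(n_p)) else character(0)
  pop_host <- if (n_p > 0L) host_ids[((seq_len(n_p) - 1L) %% cfg$n_hosts) + 1L] else character(0)
  names(pop_host) <- pop_ids

  n_conf <- round(cfg$frac_confident_temperate * n_p)
  n_cand <- round(cfg$frac_candidate_temperate * n_p)
  lifestyle <- rep("lytic", n_p)
  if (n_p > 0L) {
    idx <- sample.int(n_p)
    lifestyle[idx[seq_len(n_conf)]] <- "confident_temperate"
    if (n_cand > 0L)
      lifestyle[idx[n_conf + seq_len(n_cand)]] <- "candidate_temperate"
  }
  names(lifestyle) <- pop_ids

  contigs <- character(0)
  contig_rows <- list(); ann_rows <- list(); feat_rows <- list()
  truth_pop <- list(); truth_links <- list(); truth_life <- list()
  pop_att_core <- setNames(rep(NA_character_, n_p), pop_ids)
  pop_trna <- setNames(rep(NA_character_, n_p), pop_ids)
  pop_seq <- setNames(rep(NA_character_, n_p), pop_ids)
  pop_genes <- list()

  add_contig <- function(id, seq, topology, length_bp) {
    contigs[[id]] <<- seq
    contig_rows[[length(contig_rows) + 1L]] <<- data.frame(
      contig_id = id, length_bp = length_bp, topology = topology,
      stringsAsFactors = FALSE)
  }

  for (j in seq_len(n_p)) {
    pid <- pop_ids[j]
    hid <- pop_host[j]
    plen <- sample(cfg$phage_length_bp[1L]:cfg$phage_length_bp[2L], 1L)
    pseq <- mutate_seq(markov_generate(chains[[hid]], plen),
                       rate = cfg$phage_mutation_rates$from_host)
    genes <- .tile_genes(plen)
    topo <- "linear"
    protected <- list()   # intervals (0-based half-open) shielded from member mutation
    if (lifestyle[j] == "confident_temperate") {
      genes$label[1L] <- "phage integrase"
      if (runif(1) < 0.5 && nrow(genes) > 1L) genes$label[2L] <- "excisionase"
      att <- .plant_att_on_contig(pseq, genes, cfg$att_core_length_bp)
      pseq <- att$seq
      pop_att_core[pid] <- att$core
      protected <- c(protected, list(c(att$attL_start, att$attL_end),
                                     c(att$attR_start, att$attR_end)))
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        contig_id = pid, feature_type = "att_pair", start = att$attL_start,
        end = att$attR_end, strand = "+", target_id = hid,
        detail = sprintf("core=%s;attL=%d-%d;attR=%d-%d", att$core,
                         att$attL_start, att$attL_end, att$attR_start,
                         att$attR_end),
        stringsAsFactors = FALSE)
      # shared tRNA in the noncoding tail (before attR)
      if (runif(1) < 0.7) {
        tid <- sample(names(trna_library), 1L)
        tr <- trna_library[[tid]]
        tpos <- plen - 2400L            # 0-based; tail is noncoding
        substr(pseq, tpos + 1L, tpos + nchar(tr)) <- tr
        pop_trna[pid] <- tid
        protected <- c(protected, list(c(tpos, tpos + nchar(tr))))
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          contig_id = pid, feature_type = "trna", start = tpos,
          end = tpos + nchar(tr), strand = "+", target_id = tid,
          detail = "planted on virus", stringsAsFactors = FALSE)
      }
    } else if (lifestyle[j] == "candidate_temperate") {
      gi <- sample(nrow(genes), 1L)
      genes$label[gi] <- sample(.CANDIDATE_MARKERS, 1L)
    } else if (runif(1) < cfg$frac_circular) {
      topo <- "circular"
    }
    pop_seq[pid] <- pseq
    pop_genes[[pid]] <- genes
    member_seqs <- c(setNames(list(pseq), pid))
    if (cfg$extra_members_per_population > 0L) {
      for (mmb in seq_len(cfg$extra_members_per_population)) {
        rate <- runif(1, cfg$phage_mutation_rates$within_population[1L],
                      cfg$phage_mutation_rates$within_population[2L])
        ms <- mutate_seq(pseq, rate = rate)
        # re-plant protected features so members keep exact att/tRNA copies
        for (iv in protected) {
          substr(ms, iv[1L] + 1L, iv[2L]) <- substr(pseq, iv[1L] + 1L, iv[2L])
        }
        member_seqs[[sprintf("%s_m%d", pid, mmb)]] <- ms
      }
    }
    dtr_len <- if (topo == "circular") sample(20:40, 1L) else 0L
    for (mid in names(member_seqs)) {
      mseq <- member_seqs[[mid]]
      eff_len <- nchar(mseq)
      if (topo == "circular") {
        # one DTR length per population: the terminal repeat is a feature of
        # the genome, and equal member lengths keep the representative first
        # in the length-descending, id-ascending clustering order
        mseq <- paste0(mseq, substr(mseq, 1L, dtr_len))
      }
      add_contig(mid, mseq, topo, eff_len)
      truth_pop[[length(truth_pop) + 1L]] <- data.frame(
        population_id = pid, member_id = mid, stringsAsFactors = FALSE)
      truth_life[[length(truth_life) + 1L]] <- data.frame(
        contig_id = mid, lifestyle = lifestyle[j], stringsAsFactors = FALSE)
      truth_links[[length(truth_links) + 1L]] <- data.frame(
        virus_id = mid, host_id = hid, channel = "kmer",
        stringsAsFactors = FALSE)
      g <- pop_genes[[pid]]
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        contig_id = mid, start = g$start, end = g$end, strand = g$strand,
        label = g$label, stringsAsFactors = FALSE)
    }
  }

  # host modifications: prophages (confident temperate reps), CRISPR arrays,
  # shared tRNAs
  host_bins <- host_base
  crispr_hosts <- host_ids[seq_len(round(cfg$frac_hosts_with_crispr * cfg$n_hosts))]
  for (hid in host_ids) {
    inserts <- list()
    pops_here <- pop_ids[pop_host == hid]
    conf_here <- pops_here[lifestyle[pops_here] == "confident_temperate"]
    for (pid in conf_here) {
      inserts[[length(inserts) + 1L]] <- list(
        type = "prophage", frag = paste0(pop_att_core[pid], pop_seq[pid],
                                         pop_att_core[pid]),
        pid = pid)
      if (!is.na(pop_trna[pid])) {
        inserts[[length(inserts) + 1L]] <- list(
          type = "trna", frag = trna_library[[pop_trna[pid]]],
          pid = pid, tid = pop_trna[pid])
      }
    }
    crispr_truth <- NULL
    if (hid %in% crispr_hosts && length(pops_here)) {
      targets <- pops_here[seq_len(min(3L, length(pops_here)))]
      rlen <- sample(cfg$crispr_repeat_bp[1L]:cfg$crispr_repeat_bp[2L], 1L)
      repeat_seq <- rand_dna(rlen)
      protos <- vapply(targets, function(pid) {
        slen <- sample(cfg$crispr_spacer_bp[1L]:cfg$crispr_spacer_bp[2L], 1L)
        s0 <- sample(nchar(pop_seq[pid]) - slen, 1L)
        substr(pop_seq[pid], s0 + 1L, s0 + slen)
      }, character(1))
      spacers <- vapply(protos, mutate_seq, character(1),
                        n_sub = cfg$crispr_spacer_mismatch, USE.NAMES = FALSE)
      frag <- paste0(repeat_seq, paste0(spacers, repeat_seq, collapse = ""))
      inserts[[length(inserts) + 1L]] <- list(type = "crispr", frag = frag,
                                              targets = targets,
                                              repeat_seq = repeat_seq,
                                              spacers = spacers)
    }
    if (!length(inserts)) next
    L <- nchar(host_bins[[hid]])
    pos <- .distinct_positions(length(inserts), 2500L, L - 2500L, 3000L)
    ins_df <- data.frame(pos = pos,
                         frag = vapply(inserts, `[[`, character(1), "frag"),
                         idx = seq_along(inserts), stringsAsFactors = FALSE)
    res <- apply_insertions(host_bins[[hid]], ins_df)
    host_bins[hid] <- res$seq
    for (r in seq_len(nrow(res$coords))) {
      ins <- inserts[[res$coords$idx[r]]]
      st <- res$coords$start[r]; en <- res$coords$end[r]
      if (ins$type == "prophage") {
        alen <- nchar(pop_att_core[ins$pid])
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          contig_id = hid, feature_type = "prophage",
          start = st + alen, end = en - alen, strand = "+",
          target_id = ins$pid,
          detail = sprintf("attL=%d-%d;attR=%d-%d", st, st + alen,
                           en - alen, en),
          stringsAsFactors = FALSE)
        truth_links[[length(truth_links) + 1L]] <- data.frame(
          virus_id = ins$pid, host_id = hid, channel = "prophage",
          stringsAsFactors = FALSE)
      } else if (ins$type == "trna") {
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          contig_id = hid, feature_type = "trna", start = st, end = en,
          strand = "+", target_id = ins$tid, detail = "planted on host",
          stringsAsFactors = FALSE)
        truth_links[[length(truth_links) + 1L]] <- data.frame(
          virus_id = ins$pid, host_id = hid, channel = "trna",
          stringsAsFactors = FALSE)
      } else if (ins$type == "crispr") {
        rlen <- nchar(ins$repeat_seq)
        sp_start <- st + rlen + cumsum(c(0L, head(nchar(ins$spacers), -1L) + rlen))
        for (sj in seq_along(ins$targets)) {
          feat_rows[[length(feat_rows) + 1L]] <- data.frame(
            contig_id = hid, feature_type = "crispr_spacer",
            start = sp_start[sj], end = sp_start[sj] + nchar(ins$spacers[sj]),
            strand = "+", target_id = ins$targets[sj],
            detail = sprintf("repeat=%s", ins$repeat_seq),
            stringsAsFactors = FALSE)
          truth_links[[length(truth_links) + 1L]] <- data.frame(
            virus_id = ins$targets[sj], host_id = hid, channel = "crispr",
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # cellular screening negatives from the unmodified host backbones
  for (hid in host_ids) {
    for (fi in seq_len(cfg$n_cellular_contigs_per_host)) {
      flen <- sample(cfg$cellular_contig_bp[1L]:cfg$cellular_contig_bp[2L], 1L)
      s0 <- sample(nchar(host_base[[hid]]) - flen, 1L)
      add_contig(sprintf("%s_frag%d", hid, fi),
                 substr(host_base[[hid]], s0 + 1L, s0 + flen),
                 "linear", flen)
    }
  }

  contig_table <- do.call(rbind, contig_rows)
  rownames(contig_table) <- NULL
  truth_pop <- if (length(truth_pop)) do.call(rbind, truth_pop) else
    data.frame(population_id = character(0), member_id = character(0))
  viral_status <- data.frame(
    contig_id = contig_table$contig_id,
    viral = contig_table$contig_id %in% truth_pop$member_id,
    stringsAsFactors = FALSE)

  scores <- simulate_tool_scores(contig_table, viral_status$viral,
                                 cfg$score_config,
                                 seed = (cfg$seed %% 1000000L) * 101L + 17L)

  # abundance: features are population representatives plus hosts
  features <- c(pop_ids, host_ids)
  design <- data.frame(
    sample_id = unlist(lapply(names(cfg$groups), function(g)
      sprintf("%s_s%d", g, seq_len(cfg$groups[[g]])))),
    group = rep(names(cfg$groups), cfg$groups), stringsAsFactors = FALSE)
  base <- rlnorm(length(features), meanlog = 0, sdlog = 1)
  names(base) <- features
  responders <- list()
  if (n_p > 0L) {
    avail <- pop_ids
    for (rs in cfg$responder_spec) {
      nf <- min(rs$n_features, length(avail))
      if (nf == 0L) next
      picked <- sample(avail, nf)
      avail <- setdiff(avail, picked)
      responders[[length(responders) + 1L]] <- data.frame(
        feature_id = picked, group = rs$group, fold = rs$fold,
        stringsAsFactors = FALSE)
    }
  }
  responders <- if (length(responders)) do.call(rbind, responders) else
    data.frame(feature_id = character(0), group = character(0),
               fold = numeric(0), stringsAsFactors = FALSE)
  profiles <- vapply(seq_len(nrow(design)), function(si) {
    w <- base * rlnorm(length(base), meanlog = 0, sdlog = cfg$sample_noise_sdlog)
    hit <- responders[responders$group == design$group[si], , drop = FALSE]
    if (nrow(hit)) w[hit$feature_id] <- w[hit$feature_id] * hit$fold
    w / sum(w)
  }, numeric(length(features)))
  dimnames(profiles) <- list(features, design$sample_id)
  counts <- simulate_counts(profiles, cfg$depth_per_sample,
                            seed = (cfg$seed %% 1000000L) * 103L + 29L)

  feature_lengths <- setNames(
    c(if (n_p > 0L) nchar(pop_seq[pop_ids]) else integer(0),
      nchar(host_bins[host_ids])), features)

  annotations <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(contig_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), label = character(0),
               stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  planted <- if (length(feat_rows)) do.call(rbind, feat_rows) else
    data.frame(contig_id = character(0), feature_type = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               target_id = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  rownames(planted) <- NULL
  host_links <- if (length(truth_links)) unique(do.call(rbind, truth_links)) else
    data.frame(virus_id = character(0), host_id = character(0),
               channel = character(0), stringsAsFactors = FALSE)
  rownames(host_links) <- NULL
  truth_life <- if (length(truth_life)) do.call(rbind, truth_life) else
    data.frame(contig_id = character(0), lifestyle = character(0),
               stringsAsFactors = FALSE)
  rownames(truth_life) <- NULL

  structure(list(
    config = cfg, contigs = contigs, contig_table = contig_table,
    host_bins = host_bins, scores = scores, counts = counts, design = design,
    annotations = annotations, trna_library = trna_library,
    feature_lengths = feature_lengths,
    truth = list(viral_status = viral_status, populations = truth_pop,
                 host_links = host_links, lifestyle = truth_life,
                 planted = planted, profiles = profiles,
                 responders = responders, pop_host = pop_host)),
    class = "virotrace_community")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
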