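# End-to-end orchestration: simulate -> screen -> cluster -> network -> host
# -> lifestyle -> stats, behind one configuration, with a machine-readable
# run report. Every stochastic stage is seeded from the community seed, so a
# fixed configuration is fully deterministic.

#' Run the full virome pipeline on a synthetic community
#'
#' Stages run in dependency order: community generation, ensemble viral
#' screening, population clustering (viral contigs only), gene-sharing
#' genus clustering of population representatives, four-channel host
#' prediction, lifestyle classification, and the ecology statistics layer on
#' RPKM abundances. Any stage list can be switched off via `stages`.
#'
#' @param config community configuration from [community_config()]
#' @param outdir optional directory: stage outputs are written as
#'   FASTA/TSV/JSON files
#' @param stages character vector of stages to run after generation; any of
#'   "screen", "cluster", "network", "host", "lifestyle", "stats"
#' @param n_perm permutations for the ANOSIM test
#' @param n_null_hosts decoy Markov hosts for the k-mer channel null model
#' @param kmer_k word size of the host Markov models
#' @return object of class `virotrace_run`: list with `community`, per-stage
#'   results, and `report` (the run report, see [run_report()])
#' @export
run_pipeline <- function(config, outdir = NULL,
                         stages = c("screen", "cluster", "network", "host",
                                    "lifestyle", "stats"),
                         n_perm = 199L, n_null_hosts = 12L, kmer_k = 8L) {
  t0 <- Sys.time()
  community <- generate_community(config)
  res <- list(community = community)

  if ("screen" %in% stages) {
    res$screen <- screen_table(community$scores, community$contig_table$contig_id)
  }

  viral_ids <- character(0)
  if (!is.null(res$screen)) {
    viral_ids <- res$screen$decisions$contig_id[res$screen$decisions$status == "viral"]
  }
  viral_seqs <- community$contigs[viral_ids]

  if ("cluster" %in% stages) {
    res$populations <- if (length(viral_seqs)) greedy_cluster(viral_seqs) else
      data.frame(population_id = character(0), member_id = character(0),
                 representative = logical(0), ani_pct = numeric(0),
                 af_pct = numeric(0), length_bp = integer(0))
  }

  if ("network" %in% stages && !is.null(res$populations) &&
      nrow(res$populations)) {
    reps <- res$populations$member_id[res$populations$representative]
    orfs <- call_orfs(viral_seqs[reps])
    if (nrow(orfs)) {
      pcs <- cluster_proteins(orfs)
      res$network <- build_viral_clusters(pcs$presence)
      res$network$pcs <- pcs
    }
  }

  if ("host" %in% stages) {
    set.seed((config$seed %% 1000000L) * 107L + 41L)
    pro <- find_prophage_links(viral_seqs, community$host_bins)
    arrays <- list()
    for (h in names(community$host_bins)) {
      arrays <- c(arrays, detect_crispr_arrays(
        community$host_bins[[h]], host_id = h,
        repeat_bp = config$crispr_repeat_bp,
        spacer_bp = config$crispr_spacer_bp))
    }
    cri <- match_spacers(arrays, viral_seqs)
    host_trnas <- do.call(rbind, lapply(names(community$host_bins), function(h) {
      tr <- find_trnas(community$host_bins[[h]], community$trna_library)
      if (nrow(tr)) cbind(host_id = h, tr, stringsAsFactors = FALSE) else NULL
    }))
    virus_trnas <- do.call(rbind, lapply(names(viral_seqs), function(v) {
      tr <- find_trnas(viral_seqs[[v]], community$trna_library)
      if (nrow(tr)) cbind(virus_id = v, tr, stringsAsFactors = FALSE) else NULL
    }))
    trn <- if (!is.null(host_trnas) && !is.null(virus_trnas)) {
      match_trnas(host_trnas, virus_trnas, pro)
    } else .empty_host_calls()
    models <- lapply(names(community$host_bins), function(h)
      train_markov(community$host_bins[[h]], host_id = h, k = kmer_k))
    null_models <- lapply(seq_len(n_null_hosts), function(i) {
      ch <- new_markov_chain(config$host_markov_order, config$markov_alpha)
      train_markov(markov_generate(ch, 50000L),
                   host_id = sprintf("decoy_%02d", i), k = kmer_k)
    })
    kmr <- if (length(viral_seqs) && length(models) >= 2L) {
      score_kmer_channel(viral_seqs, models, null_models, prophage_calls = pro)
    } else .empty_host_calls()
    calls <- rbind(pro, cri, trn, kmr)
    res$host <- list(calls = calls, arrays = arrays,
                     consensus = consensus_hosts(calls, names(viral_seqs)))
  }

  if ("lifestyle" %in% stages) {
    ann <- community$annotations[community$annotations$contig_id %in% viral_ids, ,
                                 drop = FALSE]
    res$lifestyle <- classify_lifestyles(viral_seqs, ann)
  }

  if ("stats" %in% stages) {
    rpkmm <- rpkm_matrix(community$counts,
                         community$feature_lengths[rownames(community$counts)])
    logm <- log_transform(rpkmm)
    d <- bray_curtis(logm)
    groups <- setNames(community$design$group,
                       community$design$sample_id)[colnames(d)]
    gl <- names(config$groups)
    res$stats <- list(
      rpkm = rpkmm,
      bray_curtis = d,
      pcoa = pcoa_ordination(d),
      anosim = anosim_test(d, groups, n_perm = n_perm,
                           seed = (config$seed %% 1000000L) * 109L + 7L),
      shannon = apply(community$counts, 2L, shannon),
      wilcoxon = wilcoxon_bh(rpkmm, community$design),
      volcano = lapply(setNames(gl[-1L], gl[-1L]), function(g)
        t_volcano(logm, community$design, c(gl[1L], g))),
      heatmap = zscore_hclust(logm))
  }

  res$report <- run_report(res, wall_time = as.numeric(Sys.time() - t0, units = "secs"))
  if (!is.null(outdir)) write_run_outputs(res, outdir)
  class(res) <- "virotrace_run"
  res
}

#' Assemble the machine-readable run report
#'
#' @param res stage results from [run_pipeline()]
#' @param wall_time elapsed seconds
#' @return list of per-stage record counts, parameter echo, and seed
#' @export
run_report <- function(res, wall_time = NA_real_) {
  cfg <- res$community$config
  rep_counts <- list(seed = cfg$seed,
                     n_contigs = nrow(res$community$contig_table))
  if (!is.null(res$screen)) {
    s <- as.list(res$screen$summary)
    s$n_contigs <- NULL
    rep_counts <- c(rep_counts, s)
  }
  if (!is.null(res$populations)) {
    rep_counts$n_populations <- sum(res$populations$representative)
    rep_counts$n_population_members <- nrow(res$populations)
  }
  if (!is.null(res$network)) {
    cl <- res$network$assignments$class
    rep_counts$n_vcs <- length(unique(stats::na.omit(res$network$assignments$vc_id)))
    rep_counts$n_clustered <- sum(cl == "clustered")
    rep_counts$n_outlier <- sum(cl == "outlier")
    rep_counts$n_singleton <- sum(cl == "singleton")
  }
  if (!is.null(res$host)) {
    rep_counts$n_host_linked <- nrow(res$host$consensus$consensus)
    rep_counts$fraction_host_linked <- res$host$consensus$fraction_linked
  }
  if (!is.null(res$lifestyle)) {
    lc <- res$lifestyle$calls$call
    rep_counts$n_confident_temperate <- sum(lc == "confident_temperate")
    rep_counts$n_candidate_temperate <- sum(lc == "candidate_temperate")
    rep_counts$n_no_evidence <- sum(lc == "no_evidence")
  }
  if (!is.null(res$stats)) {
    rep_counts$anosim_R <- res$stats$anosim$R
    rep_counts$anosim_p <- res$stats$anosim$p
    rep_counts$n_sig_wilcoxon <- sum(res$stats$wilcoxon$q < 0.05, na.rm = TRUE)
    rep_counts$n_sig_volcano <- sum(vapply(res$stats$volcano, function(v)
      sum(v$q < 0.05, na.rm = TRUE), numeric(1)))
  }
  rep_counts$wall_time_s <- wall_time
  rep_counts$params <- list(
    min_linear_bp = 5000L, min_circular_bp = 1500L,
    ani_min = 95, af_min = 80, spacer_id_min = 95, kmer_k = 8L,
    fdr_alpha = 0.05)
  rep_counts
}

#' Percentage helper used in summary accounting
#' @param part,whole counts
#' @param digits decimal places for the printed percentage
#' @return `100 * part / whole`, rounded to `digits`
#' @export
pct_of <- function(part, whole, digits = 1L) {
  stopifnot(whole > 0)
  round(100 * part / whole, digits)
}

#' Write all stage outputs of a pipeline run to a directory
#' @param res `virotrace_run`-style list from [run_pipeline()]
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_run_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  comm <- res$community
  write_fasta(comm$contigs, file.path(outdir, "contigs.fasta"))
  write_fasta(comm$host_bins, file.path(outdir, "host_bins.fasta"))
  write_tsv(comm$scores, file.path(outdir, "scores.tsv"))
  write_tsv(comm$design, file.path(outdir, "design.tsv"))
  write_tsv(data.frame(feature_id = rownames(comm$counts), comm$counts,
                       check.names = FALSE), file.path(outdir, "counts.tsv"))
  write_tsv(comm$truth$planted, file.path(outdir, "truth_features.tsv"))
  write_tsv(comm$truth$host_links, file.path(outdir, "truth_host_links.tsv"))
  if (!is.null(res$screen))
    write_tsv(res$screen$decisions, file.path(outdir, "screen_decisions.tsv"))
  if (!is.null(res$populations))
    write_tsv(res$populations, file.path(outdir, "populations.tsv"))
  if (!is.null(res$network)) {
    write_tsv(res$network$assignments, file.path(outdir, "vc_assignments.tsv"))
    write_tsv(res$network$edges, file.path(outdir, "vc_edges.tsv"))
  }
  if (!is.null(res$host)) {
    write_tsv(res$host$calls, file.path(outdir, "host_calls.tsv"))
    write_tsv(res$host$consensus$consensus, file.path(outdir, "host_consensus.tsv"))
  }
  if (!is.null(res$lifestyle)) {
    write_tsv(res$lifestyle$calls, file.path(outdir, "lifestyle.tsv"))
    write_tsv(res$lifestyle$att_pairs, file.path(outdir, "att_pairs.tsv"))
  }
  if (!is.null(res$stats)) {
    write_tsv(data.frame(feature_id = rownames(res$stats$rpkm), res$stats$rpkm,
                         check.names = FALSE), file.path(outdir, "rpkm.tsv"))
    write_tsv(res$stats$wilcoxon, file.path(outdir, "wilcoxon.tsv"))
    write_newick(res$stats$heatmap$hclust, file.path(outdir, "heatmap_rows.nwk"))
  }
  jsonlite::write_json(res$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
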