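# Genus-level grouping of viral genomes by shared protein content: six-frame
# ORF calling, greedy protein clustering (a deterministic analogue of
# MMseqs2-style clustering at 30% identity / 70% centroid coverage),
# hypergeometric significance of shared protein clusters between genome
# pairs, and connected-component viral clusters (VCs) with a
# clustered / outlier / singleton trichotomy.

#' Call ORFs by a six-frame scan
#'
#' Deterministic simplified gene caller: in all six frames, every
#' stop-to-stop segment contributes at most one ORF, from its first ATG to
#' the stop codon (standard genetic code), kept when the translated product
#' is at least `min_aa` residues. Coordinates are 0-based half-open on the
#' forward strand; the stop codon is included in the interval.
#'
#' @param genomes named character vector of nucleotide sequences
#' @param min_aa minimum protein length in residues (stop excluded)
#' @return data.frame with `orf_id`, `genome_id`, `start`, `end`, `strand`,
#'   `aa_seq`, `length_aa`
#' @export
call_orfs <- function(genomes, min_aa = 60L) {
  stopifnot(!is.null(names(genomes)))
  rows <- list()
  for (gid in names(genomes)) {
    g <- genomes[[gid]]
    L <- nchar(g)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") g else revcomp(g)
      for (frame in 0:2) {
        nt_len <- ((L - frame) %/% 3L) * 3L
        if (nt_len < 3L) next
        sub <- substr(s, frame + 1L, frame + nt_len)
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                 no.init.codon = TRUE))
        stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"))
        if (length(stops) < 2L) next
        for (si in seq_len(length(stops) - 1L)) {
          seg_from <- stops[si] + 1L
          seg_to <- stops[si + 1L] - 1L      # aa positions, stop excluded
          if (seg_to - seg_from + 1L < min_aa) next
          seg <- substr(aa, seg_from, seg_to)
          m <- regexpr("M", seg, fixed = TRUE)
          if (m < 0L) next
          aa_start <- seg_from + as.integer(m) - 1L
          n_aa <- seg_to - aa_start + 1L
          if (n_aa < min_aa) next
          # 0-based half-open in the scanned strand, stop codon included
          b <- frame + 3L * (aa_start - 1L)
          e <- frame + 3L * (stops[si + 1L])
          if (strand == "+") {
            start <- b; end <- e
          } else {
            start <- L - e; end <- L - b
          }
          rows[[length(rows) + 1L]] <- data.frame(
            genome_id = gid, start = start, end = end, strand = strand,
            aa_seq = substr(aa, aa_start, seg_to), length_aa = n_aa,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(orf_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), aa_seq = character(0),
                      length_aa = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id, out$start, out$strand), , drop = FALSE]
  out <- cbind(orf_id = sprintf("%s_orf%04d", out$genome_id,
                                stats::ave(seq_len(nrow(out)), out$genome_id,
                                           FUN = seq_along)),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @keywords internal
.aa_kmers <- function(p, k = 4L) unique(kmer_strings(p, k))

#' Greedy protein clustering into protein clusters (PCs)
#'
#' Proteins are sorted by length descending (ties by id); each protein joins
#' the first centroid it matches at `id_min` identity over `cov_min` of the
#' centroid's length (local alignment, BLOSUM62), otherwise it founds a new
#' PC. Candidate centroids are pre-filtered by shared amino-acid 4-mers, so
#' unrelated proteins are never aligned.
#'
#' @param orfs data.frame from [call_orfs()] (needs `orf_id`, `genome_id`,
#'   `aa_seq`)
#' @param id_min minimum fractional identity over aligned columns
#' @param cov_min minimum fraction of the centroid covered by the alignment
#' @param min_shared_kmers prefilter: candidate centroids must share at least
#'   this many distinct 4-mers with the query
#' @return list with `membership` (orf_id, genome_id, pc_id), `presence`
#'   (named list: genome_id -> character vector of PC ids) and `n_pcs`
#' @export
cluster_proteins <- function(orfs, id_min = 0.30, cov_min = 0.70,
                             min_shared_kmers = 2L) {
  stopifnot(nrow(orfs) >= 1L)
  ord <- order(-orfs$length_aa, orfs$orf_id)
  orfs <- orfs[ord, , drop = FALSE]
  kmer_env <- new.env(hash = TRUE, parent = emptyenv())
  centroids <- character(0)
  pc_of <- integer(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    p <- orfs$aa_seq[i]
    km <- .aa_kmers(p)
    hits <- unlist(lapply(km, function(w) kmer_env[[w]]), use.names = FALSE)
    assigned <- 0L
    if (length(hits)) {
      tab <- table(hits)
      cand <- sort(as.integer(names(tab)[tab >= min_shared_kmers]))
      if (length(cand)) {
        # one vectorized alignment call against all candidate centroids
        alns <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(centroids[cand]), Biostrings::AAString(p),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = 10, gapExtension = 0.5)
        cov <- IRanges::width(Biostrings::pattern(alns)@range) /
          nchar(centroids[cand])
        idy <- Biostrings::pid(alns, type = "PID2") / 100
        ok <- which(idy >= id_min & cov >= cov_min)
        if (length(ok)) assigned <- cand[ok[1L]]
      }
    }
    if (assigned == 0L) {
      centroids <- c(centroids, p)
      assigned <- length(centroids)
      for (w in km) kmer_env[[w]] <- c(kmer_env[[w]], assigned)
    }
    pc_of[i] <- assigned
  }
  pc_ids <- sprintf("PC_%05d", pc_of)
  membership <- data.frame(orf_id = orfs$orf_id, genome_id = orfs$genome_id,
                           pc_id = pc_ids, stringsAsFactors = FALSE)
  membership <- membership[order(membership$orf_id), , drop = FALSE]
  rownames(membership) <- NULL
  presence <- lapply(split(pc_ids, orfs$genome_id), function(x) sort(unique(x)))
  list(membership = membership, presence = presence, n_pcs = length(centroids))
}

#' Hypergeometric significance of shared protein clusters
#'
#' Probability of two genomes sharing at least `c` PCs when one holds
#' `|pcs_a|` of the `n_universe` PCs and the other draws `|pcs_b|` of them
#' at random.
#'
#' @param pcs_a,pcs_b character vectors of PC ids held by each genome
#' @param n_universe total number of distinct PCs across all genomes
#' @return list with `shared`, `p` (upper-tail hypergeometric probability)
#'   and `weight` (-log10 p)
#' @export
pair_significance <- function(pcs_a, pcs_b, n_universe) {
  na <- length(unique(pcs_a)); nb <- length(unique(pcs_b))
  stopifnot(na <= n_universe, nb <= n_universe)
  c_shared <- length(intersect(pcs_a, pcs_b))
  p <- phyper(c_shared - 1L, na, n_universe - na, nb, lower.tail = FALSE)
  list(shared = c_shared, p = p, weight = -log10(p))
}

#' Build genus-level viral clusters from PC presence profiles
#'
#' Edges connect genome pairs whose shared-PC significance weight
#' (-log10 hypergeometric p) reaches `sig_min`; VCs are connected components
#' of size >= 2. Genomes sharing no PC with any other genome are singletons;
#' genomes with shared PCs but no retained edge (or alone in their component)
#' are outliers. VCs containing a reference genome are flagged.
#'
#' @param presence named list (genome_id -> character vector of PC ids), as
#'   produced by [cluster_proteins()]
#' @param sig_min minimum edge weight (default 1.0, i.e. p <= 0.1)
#' @param reference_ids genome ids regarded as references for the
#'   `shares_reference` flag
#' @return list with `assignments` (genome_id, vc_id, class,
#'   shares_reference) and `edges` (a, b, shared, p, weight)
#' @export
build_viral_clusters <- function(presence, sig_min = 1.0,
                                 reference_ids = character(0)) {
  gids <- names(presence)
  n_universe <- length(unique(unlist(presence)))
  # inverted index: pc -> genomes, to enumerate only pairs that share a PC
  pc2g <- split(rep(gids, lengths(presence)), unlist(presence))
  pairs <- unique(do.call(rbind, lapply(pc2g, function(gs) {
    if (length(gs) < 2L) return(NULL)
    t(combn(sort(gs), 2L))
  })))
  has_share <- unique(as.vector(pairs))
  edges <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    edges <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      sig <- pair_significance(presence[[pairs[r, 1L]]],
                               presence[[pairs[r, 2L]]], n_universe)
      data.frame(a = pairs[r, 1L], b = pairs[r, 2L], shared = sig$shared,
                 p = sig$p, weight = sig$weight, stringsAsFactors = FALSE)
    }))
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        shared = integer(0), p = numeric(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  kept <- edges[edges$weight >= sig_min, , drop = FALSE]
  g <- igraph::graph_from_data_frame(kept[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = gids))
  comp <- igraph::components(g)
  memb <- comp$membership[gids]
  vc_comp <- which(comp$csize >= 2L)
  vc_label <- setNames(rep(NA_character_, comp$no), seq_len(comp$no))
  if (length(vc_comp)) {
    # stable VC numbering by first member in input order
    first_member <- vapply(vc_comp, function(cc) min(match(gids[memb == cc], gids)),
                           integer(1))
    vc_comp <- vc_comp[order(first_member)]
    vc_label[as.character(vc_comp)] <- sprintf("VC_%04d", seq_along(vc_comp))
  }
  vc_id <- unname(vc_label[as.character(memb)])
  class <- ifelse(!is.na(vc_id), "clustered",
                  ifelse(gids %in% has_share, "outlier", "singleton"))
  ref_vcs <- unique(vc_id[gids %in% reference_ids & !is.na(vc_id)])
  shares_reference <- !is.na(vc_id) & vc_id %in% ref_vcs
  assignments <- data.frame(genome_id = gids, vc_id = vc_id, class = class,
                            shares_reference = shares_reference,
                            stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(assignments = assignments, edges = edges, n_universe = n_universe)
}
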