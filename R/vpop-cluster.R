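# Species-level clustering of viral genomes into populations at >=95% average
# nucleotide identity (ANI) over >=80% of the shorter genome (aligned
# fraction, AF). The ANI engine chains exact k-mer anchors on shared
# diagonals into ungapped local segments and scores identity over each
# segment; reverse-complement homology counts. It is oracle-checked against
# full global alignment on small pairs in the test suite.

#' @keywords internal
.anchor_segments <- function(ra, rb, ka, kb, k, max_gap = 1000L, min_seg_id = 70) {
  m <- match(kb, ka)
  j <- which(!is.na(m))
  if (!length(j)) return(NULL)
  i <- m[j]
  d <- i - j
  ord <- order(d, j)
  j <- j[ord]; d <- d[ord]
  # split anchor chains at diagonal changes and at large gaps along a diagonal
  brk <- c(TRUE, diff(d) != 0L | diff(j) > max_gap)
  run <- cumsum(brk)
  segs <- NULL
  la <- length(ra); lb <- length(rb)
  for (r in unique(run)) {
    idx <- which(run == r)
    dd <- d[idx[1L]]
    jb1 <- j[idx[1L]]
    jb2 <- j[idx[length(idx)]] + k - 1L
    # extend outward while bases keep matching
    while (jb1 > 1L && jb1 + dd > 1L && ra[jb1 + dd - 1L] == rb[jb1 - 1L]) jb1 <- jb1 - 1L
    while (jb2 < lb && jb2 + dd < la && ra[jb2 + dd + 1L] == rb[jb2 + 1L]) jb2 <- jb2 + 1L
    len <- jb2 - jb1 + 1L
    nm <- .match_count(ra, rb, jb1 + dd, jb1, len)
    if (100 * nm / len >= min_seg_id) {
      segs <- rbind(segs, c(diag = dd, jb = jb1, len = len, nmatch = nm))
    }
  }
  segs
}

#' @keywords internal
.ani_af_one_strand <- function(ra, rb, ka, kb, k) {
  segs <- .anchor_segments(ra, rb, ka, kb, k)
  la <- length(ra); lb <- length(rb)
  short_len <- min(la, lb)
  if (is.null(segs)) return(list(ani = 0, af = 0, aligned = 0L))
  segs <- segs[order(-segs[, "nmatch"]), , drop = FALSE]
  covered <- logical(short_len)
  tot_cols <- 0L; tot_match <- 0L
  for (r in seq_len(nrow(segs))) {
    jb <- segs[r, "jb"]; len <- segs[r, "len"]; dd <- segs[r, "diag"]
    # interval in the coordinates of the shorter sequence
    s1 <- if (la <= lb) jb + dd else jb
    span <- s1:(s1 + len - 1L)
    span <- span[span >= 1L & span <= short_len]
    if (!length(span)) next
    if (mean(covered[span]) > 0.2) next  # mostly redundant with a better segment
    covered[span] <- TRUE
    tot_cols <- tot_cols + len
    tot_match <- tot_match + segs[r, "nmatch"]
  }
  if (tot_cols == 0L) return(list(ani = 0, af = 0, aligned = 0L))
  list(ani = unname(100 * tot_match / tot_cols),
       af = 100 * sum(covered) / short_len,
       aligned = sum(covered))
}

#' Pairwise ANI and aligned fraction between two genomes
#'
#' ANI is the percent identity over aligned columns of accepted ungapped
#' local segments (both strands of `b` are tried; the strand with the larger
#' aligned extent wins). AF is the fraction of the shorter sequence covered
#' by accepted segments, in percent.
#'
#' @param a,b nucleotide sequences (character scalars)
#' @param k anchor word size
#' @return list with `ani_pct` and `af_pct`
#' @export
pairwise_ani_af <- function(a, b, k = 15L) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  ra <- charToRaw(a)
  ka <- kmer_strings(a, k)
  fw <- .ani_af_one_strand(ra, charToRaw(b), ka, kmer_strings(b, k), k)
  brc <- revcomp(b)
  rv <- .ani_af_one_strand(ra, charToRaw(brc), ka, kmer_strings(brc, k), k)
  best <- if (rv$aligned > fw$aligned) rv else fw
  list(ani_pct = best$ani, af_pct = best$af)
}

#' @keywords internal
.genome_index <- function(s, k) {
  list(raw = charToRaw(s), kmers = kmer_strings(s, k),
       rc_raw = NULL, rc_kmers = NULL, seq = s, len = nchar(s))
}

#' @keywords internal
.ani_af_indexed <- function(idx_a, idx_b, k) {
  fw <- .ani_af_one_strand(idx_a$raw, idx_b$raw, idx_a$kmers, idx_b$kmers, k)
  if (is.null(idx_b$rc_raw)) {
    rc <- revcomp(idx_b$seq)
    idx_b$rc_raw <- charToRaw(rc)
    idx_b$rc_kmers <- kmer_strings(rc, k)
  }
  rv <- .ani_af_one_strand(idx_a$raw, idx_b$rc_raw, idx_a$kmers, idx_b$rc_kmers, k)
  best <- if (rv$aligned > fw$aligned) rv else fw
  list(ani_pct = best$ani, af_pct = best$af, idx_b = idx_b)
}

#' Greedy longest-first clustering into viral populations
#'
#' Genomes are sorted by length descending (ties broken by id, ascending);
#' each genome joins the first existing representative it matches at
#' `ani_min`/`af_min` (both thresholds inclusive), otherwise it seeds a new
#' population. The ordering canonicalizes the partition, so shuffling the
#' input does not change it.
#'
#' @param genomes named character vector of nucleotide sequences
#' @param ani_min minimum ANI in percent
#' @param af_min minimum aligned fraction of the shorter genome in percent
#' @param k anchor word size for the ANI engine
#' @return data.frame with `population_id`, `member_id`, `representative`
#'   (logical), `ani_pct`, `af_pct` (vs the representative), `length_bp`
#' @export
greedy_cluster <- function(genomes, ani_min = 95.0, af_min = 80.0, k = 15L) {
  stopifnot(length(genomes) > 0L, !is.null(names(genomes)))
  if (anyDuplicated(names(genomes))) stop("duplicate genome ids")
  ord <- order(-nchar(genomes), names(genomes))
  genomes <- genomes[ord]
  ids <- names(genomes)
  rep_idx <- list()   # genome index objects for representatives
  rep_ids <- character(0)
  rows <- vector("list", length(genomes))
  for (g in seq_along(genomes)) {
    idx_g <- .genome_index(genomes[[g]], k)
    assigned <- FALSE
    for (r in seq_along(rep_ids)) {
      hit <- .ani_af_indexed(rep_idx[[r]], idx_g, k)
      idx_g <- hit$idx_b
      if (hit$ani_pct >= ani_min && hit$af_pct >= af_min) {
        rows[[g]] <- data.frame(population_id = rep_ids[r], member_id = ids[g],
                                representative = FALSE, ani_pct = hit$ani_pct,
                                af_pct = hit$af_pct, length_bp = idx_g$len,
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_ids <- c(rep_ids, ids[g])
      rep_idx[[length(rep_ids)]] <- idx_g
      rows[[g]] <- data.frame(population_id = ids[g], member_id = ids[g],
                              representative = TRUE, ani_pct = 100,
                              af_pct = 100, length_bp = idx_g$len,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag populations as novel or known against a reference genome set
#'
#' A population is "known" iff its representative meets the same ANI/AF
#' criterion against any reference genome; otherwise it is novel.
#'
#' @param populations membership table from [greedy_cluster()]
#' @param genomes named character vector holding at least the representatives
#' @param reference_genomes named character vector (possibly empty)
#' @inheritParams greedy_cluster
#' @return data.frame with `population_id` and `novelty` ("novel"/"known")
#' @export
novelty_vs_reference <- function(populations, genomes, reference_genomes,
                                 ani_min = 95.0, af_min = 80.0, k = 15L) {
  reps <- populations$member_id[populations$representative]
  ref_idx <- lapply(reference_genomes, .genome_index, k = k)
  novelty <- vapply(reps, function(rid) {
    idx_r <- .genome_index(genomes[[rid]], k)
    for (ri in seq_along(ref_idx)) {
      hit <- .ani_af_indexed(ref_idx[[ri]], idx_r, k)
      idx_r <- hit$idx_b
      if (hit$ani_pct >= ani_min && hit$af_pct >= af_min) return("known")
    }
    "novel"
  }, character(1))
  data.frame(population_id = populations$population_id[populations$representative],
             novelty = unname(novelty), stringsAsFactors = FALSE)
}
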