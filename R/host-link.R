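# Virus-host prediction through four channels, each with its own acceptance
# rule, plus a priority-based consensus:
#   prophage — the whole viral contig occurs verbatim (either strand) inside
#     a host bin, with >=1 kb of host flanking sequence on at least one side
#     (the flank requirement distinguishes integration from co-assembly);
#   crispr   — a host CRISPR spacer matches the virus full-length, ungapped,
#     at >=95% identity;
#   trna     — an exactly shared full-length tRNA, only accepted when the
#     same (virus, host) pair also has an accepted prophage call;
#   kmer     — order-(k-1) Markov likelihood with a Gaussian null fitted to
#     decoy-host scores; accepted at p ~ 0 alone, or p < 0.05 with a
#     concordant prophage call.

.empty_host_calls <- function() {
  data.frame(virus_id = character(0), host_id = character(0),
             channel = character(0), identity_pct = numeric(0),
             length_bp = integer(0), loglik = numeric(0), p = numeric(0),
             accepted = logical(0), stringsAsFactors = FALSE)
}

#' Prophage channel: exact full-length embedding of a virus in a host bin
#'
#' @param virus_seqs named character vector of viral contig sequences
#' @param host_bins named character vector of host bin sequences
#' @param min_flank_bp minimum host flanking sequence on at least one side
#'   for a hit to be accepted as an integrated prophage
#' @return HostCall data.frame (one row per virus x host with a hit);
#'   `identity_pct` is always 100 for a hit, `length_bp` the virus length
#' @export
find_prophage_links <- function(virus_seqs, host_bins, min_flank_bp = 1000L) {
  rows <- list()
  for (v in names(virus_seqs)) {
    vs <- virus_seqs[[v]]
    vr <- revcomp(vs)
    for (h in names(host_bins)) {
      hs <- host_bins[[h]]
      st <- as.integer(regexpr(vs, hs, fixed = TRUE))
      if (st < 0L) st <- as.integer(regexpr(vr, hs, fixed = TRUE))
      if (st < 0L) next
      en <- st + nchar(vs) - 1L
      flank_l <- st - 1L
      flank_r <- nchar(hs) - en
      rows[[length(rows) + 1L]] <- data.frame(
        virus_id = v, host_id = h, channel = "prophage", identity_pct = 100,
        length_bp = nchar(vs), loglik = NA_real_, p = NA_real_,
        accepted = (flank_l >= min_flank_bp || flank_r >= min_flank_bp),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_host_calls())
  do.call(rbind, rows)
}

#' Detect CRISPR arrays by exact-repeat seeding
#'
#' Finds runs of two or more identical repeat copies (length within
#' `repeat_bp`) separated by spacer gaps within `spacer_bp`. Seeds are
#' duplicated words of length `min(repeat_bp)`; runs are chained when
#' consecutive seed starts are compatible with one repeat plus one spacer,
#' then the repeat is extended to its maximal common length. Repeats must be
#' exact copies (no degenerate repeats).
#'
#' @param host_seq host sequence (character scalar)
#' @param host_id id recorded on the result
#' @param repeat_bp integer vector `c(min, max)` repeat length range
#' @param spacer_bp integer vector `c(min, max)` spacer length range
#' @param min_repeats minimum number of repeat copies (>= 2)
#' @return list of arrays; each is a list with `host_id`, `start`, `end`
#'   (0-based half-open span of the array), `repeat_seq` and `spacers`
#'   (data.frame seq/start/end)
#' @export
detect_crispr_arrays <- function(host_seq, host_id = "host",
                                 repeat_bp = c(23L, 47L),
                                 spacer_bp = c(26L, 50L),
                                 min_repeats = 2L) {
  stopifnot(min_repeats >= 2L, nchar(host_seq) > 0L)
  k <- repeat_bp[1L]
  n <- nchar(host_seq)
  if (n < 2L * k + spacer_bp[1L]) return(list())
  words <- kmer_strings(host_seq, k)
  dup <- unique(words[duplicated(words)])
  if (!length(dup)) return(list())
  # candidate seed-start differences: repeat + spacer
  d_min <- repeat_bp[1L] + spacer_bp[1L]
  d_max <- repeat_bp[2L] + spacer_bp[2L]
  cands <- list()
  for (w in dup) {
    pos <- which(words == w)           # 1-based starts of the seed
    d <- diff(pos)
    # chain consecutive occurrences with plausible periods
    ok <- d >= d_min & d <= d_max
    if (!any(ok)) next
    runs <- rle(ok)
    idx_end <- cumsum(runs$lengths)
    for (r in which(runs$values)) {
      from <- if (r == 1L) 1L else idx_end[r - 1L] + 1L
      chain <- pos[from:(idx_end[r] + 1L)]
      if (length(chain) < min_repeats) next
      # maximal repeat length common to all copies
      gap_min <- min(diff(chain))
      cap <- min(repeat_bp[2L], gap_min - spacer_bp[1L])
      L <- k
      while (L < cap) {
        nxt <- substring(host_seq, chain, chain + L)
        if (length(unique(nxt)) > 1L) break
        L <- L + 1L
      }
      spacer_len <- diff(chain) - L
      if (any(spacer_len < spacer_bp[1L] | spacer_len > spacer_bp[2L])) next
      rep_seq <- substr(host_seq, chain[1L], chain[1L] + L - 1L)
      sp_start <- head(chain, -1L) + L           # 1-based
      sp_end <- tail(chain, -1L) - 1L
      spacers <- data.frame(
        seq = substring(host_seq, sp_start, sp_end),
        start = sp_start - 1L, end = sp_end,     # 0-based half-open
        stringsAsFactors = FALSE)
      cands[[length(cands) + 1L]] <- list(
        host_id = host_id, start = chain[1L] - 1L,
        end = chain[length(chain)] + L - 1L,
        repeat_seq = rep_seq, spacers = spacers,
        n_copies = length(chain))
    }
  }
  if (!length(cands)) return(list())
  # greedy selection: longest chains first, so a coincidentally extended seed
  # (e.g. one base beyond a repeat) cannot shadow the full array
  pri <- order(-vapply(cands, `[[`, integer(1), "n_copies"),
               -vapply(cands, function(a) a$end - a$start, integer(1)),
               vapply(cands, `[[`, integer(1), "start"))
  masked <- logical(n)
  arrays <- list()
  for (a in cands[pri]) {
    span <- (a$start + 1L):a$end
    if (any(masked[span])) next
    masked[span] <- TRUE
    a$n_copies <- NULL
    arrays[[length(arrays) + 1L]] <- a
  }
  arrays[order(vapply(arrays, `[[`, integer(1), "start"))]
}

#' CRISPR channel: match array spacers against viral contigs
#'
#' A spacer hit is accepted iff it aligns full-length, ungapped, on either
#' strand, with identity >= `id_min` (i.e. at most floor((1 - id_min/100) * L)
#' mismatches over its whole length L).
#'
#' @param arrays list of arrays from [detect_crispr_arrays()] (possibly from
#'   several hosts)
#' @param virus_seqs named character vector of viral contig sequences
#' @param id_min minimum percent identity over the whole spacer
#' @return HostCall data.frame; `identity_pct` is the identity of the best
#'   placement, `length_bp` the spacer length
#' @export
match_spacers <- function(arrays, virus_seqs, id_min = 95.0) {
  if (!length(arrays) || !length(virus_seqs)) return(.empty_host_calls())
  vset <- Biostrings::DNAStringSet(virus_seqs)
  rows <- list()
  for (arr in arrays) {
    for (si in seq_len(nrow(arr$spacers))) {
      sp <- arr$spacers$seq[si]
      L <- nchar(sp)
      max_mm <- floor((1 - id_min / 100) * L)
      for (pat in c(sp, revcomp(sp))) {
        hits <- Biostrings::vmatchPattern(pat, vset, max.mismatch = max_mm,
                                          with.indels = FALSE)
        nh <- lengths(hits)
        for (vi in which(nh > 0L)) {
          v <- names(virus_seqs)[vi]
          rng <- hits[[vi]][1L]
          frag <- substr(virus_seqs[[vi]], Biostrings::start(rng),
                         Biostrings::end(rng))
          mm <- sum(charToRaw(frag) != charToRaw(pat))
          rows[[length(rows) + 1L]] <- data.frame(
            virus_id = v, host_id = arr$host_id, channel = "crispr",
            identity_pct = 100 * (L - mm) / L, length_bp = L,
            loglik = NA_real_, p = NA_real_, accepted = TRUE,
            stringsAsFactors = FALSE)
        }
        if (pat == revcomp(sp) && sp == revcomp(sp)) break
      }
    }
  }
  if (!length(rows)) return(.empty_host_calls())
  out <- do.call(rbind, rows)
  # collapse duplicate (virus, host) spacer hits to the best one
  key <- paste(out$virus_id, out$host_id)
  out <- out[order(key, -out$identity_pct), , drop = FALSE]
  out <- out[!duplicated(paste(out$virus_id, out$host_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate tRNA library members in a sequence by exact matching
#'
#' Covariance-model scanning is out of scope; tRNAs are located as exact,
#' full-length occurrences of user-supplied library sequences (either
#' strand).
#'
#' @param seq sequence to scan (character scalar)
#' @param trna_library named character vector of tRNA sequences (70-90 bp)
#' @return data.frame with `trna_id`, `start`, `end` (0-based half-open),
#'   `strand`
#' @export
find_trnas <- function(seq, trna_library) {
  rows <- list()
  subj <- Biostrings::DNAString(seq)
  for (tid in names(trna_library)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") trna_library[[tid]] else revcomp(trna_library[[tid]])
      hit <- Biostrings::matchPattern(pat, subj)
      if (length(hit) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        trna_id = tid, start = Biostrings::start(hit)[1L] - 1L,
        end = Biostrings::end(hit)[1L], strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(trna_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' tRNA channel: exactly shared tRNAs, gated on prophage concordance
#'
#' A (virus, host) pair is accepted iff they carry an identical full-length
#' tRNA (same library member, located by exact matching) AND the same pair
#' has an accepted prophage call.
#'
#' @param host_trnas data.frame with `host_id`, `trna_id` (one row per
#'   located host tRNA)
#' @param virus_trnas data.frame with `virus_id`, `trna_id`
#' @param prophage_calls HostCall data.frame from [find_prophage_links()]
#' @return HostCall data.frame
#' @export
match_trnas <- function(host_trnas, virus_trnas, prophage_calls) {
  if (!nrow(host_trnas) || !nrow(virus_trnas)) return(.empty_host_calls())
  hits <- merge(virus_trnas[, c("virus_id", "trna_id")],
                host_trnas[, c("host_id", "trna_id")], by = "trna_id")
  if (!nrow(hits)) return(.empty_host_calls())
  hits <- unique(hits[, c("virus_id", "host_id", "trna_id")])
  pro_ok <- prophage_calls[prophage_calls$accepted, c("virus_id", "host_id")]
  key <- paste(hits$virus_id, hits$host_id)
  ok <- key %in% paste(pro_ok$virus_id, pro_ok$host_id)
  out <- data.frame(virus_id = hits$virus_id, host_id = hits$host_id,
                    channel = "trna", identity_pct = 100,
                    length_bp = NA_integer_, loglik = NA_real_, p = NA_real_,
                    accepted = ok, stringsAsFactors = FALSE)
  out <- out[order(out$virus_id, out$host_id), , drop = FALSE]
  out <- out[!duplicated(paste(out$virus_id, out$host_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train an order-(k-1) Markov model of a host genome
#'
#' Transition log-probabilities are estimated from k-mer counts with an
#' additive pseudocount; by default both strands are counted, so the model
#' is strand-symmetric.
#'
#' @param host_seq host sequence (character scalar)
#' @param host_id id stored on the model
#' @param k word size (model order is k - 1)
#' @param pseudocount additive smoothing count (> 0 so every k-mer is
#'   scoreable)
#' @param both_strands train on the sequence plus its reverse complement
#' @return object of class `markov_host_model` with the log-probability
#'   vector over all 4^k words
#' @export
train_markov <- function(host_seq, host_id = "host", k = 8L, pseudocount = 1,
                         both_strands = TRUE) {
  if (nchar(host_seq) < k) stop("sequence shorter than k")
  stopifnot(pseudocount > 0)
  cnt <- as.numeric(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(host_seq), width = k))
  if (both_strands) {
    cnt <- cnt + as.numeric(Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(Biostrings::DNAString(host_seq)), width = k))
  }
  # words are in lexicographic order with the last base varying fastest:
  # rows of the k-mer count matrix are (k-1)-mer contexts
  m <- matrix(cnt + pseudocount, ncol = 4L, byrow = TRUE)
  logp <- log(m / rowSums(m))
  structure(list(host_id = host_id, k = as.integer(k),
                 logp = as.numeric(t(logp))), class = "markov_host_model")
}

#' Mean per-base log-likelihood of a virus under a host Markov model
#' @param model object from [train_markov()]
#' @param virus_seq viral sequence (character scalar)
#' @return numeric scalar (natural log per scored base)
#' @export
markov_loglik <- function(model, virus_seq) {
  stopifnot(inherits(model, "markov_host_model"))
  if (nchar(virus_seq) < model$k) stop("virus shorter than k")
  vc <- as.numeric(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(virus_seq), width = model$k))
  sum(vc * model$logp) / sum(vc)
}

#' k-mer channel: score viruses against host Markov models
#'
#' For each virus the best-scoring candidate host is taken; a one-sided
#' Gaussian p-value is computed from the virus's scores against decoy (null)
#' host models. A call is accepted iff p <= `p_zero_eps` (the operational
#' reading of "p = 0"), or p < `p_weak` with a concordant accepted prophage
#' call for the same pair.
#'
#' @param virus_seqs named character vector of viral contigs
#' @param models list of candidate host models from [train_markov()] (>= 2)
#' @param null_models list of decoy host models (>= 10)
#' @param prophage_calls optional HostCall data.frame used for the weak-p
#'   consistency rule
#' @param p_zero_eps strong acceptance threshold
#' @param p_weak weak acceptance threshold (needs prophage concordance)
#' @return HostCall data.frame (one row per virus: its best host)
#' @export
score_kmer_channel <- function(virus_seqs, models, null_models,
                               prophage_calls = NULL,
                               p_zero_eps = 1e-10, p_weak = 0.05) {
  if (length(models) < 2L) stop("need at least 2 candidate host models")
  if (length(null_models) < 10L) stop("need at least 10 null (decoy) models")
  pro_keys <- character(0)
  if (!is.null(prophage_calls) && nrow(prophage_calls)) {
    acc <- prophage_calls[prophage_calls$accepted, , drop = FALSE]
    pro_keys <- paste(acc$virus_id, acc$host_id)
  }
  ks <- vapply(c(models, null_models), `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("all models must share the same k")
  k <- ks[1L]
  rows <- lapply(names(virus_seqs), function(v) {
    # virus k-mer counts computed once, dotted with every model
    vc <- as.numeric(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(virus_seqs[[v]]), width = k))
    nk <- sum(vc)
    sc <- vapply(models, function(m) sum(vc * m$logp) / nk, numeric(1))
    null_sc <- vapply(null_models, function(m) sum(vc * m$logp) / nk, numeric(1))
    best <- which.max(sc)
    mu <- mean(null_sc); s <- sd(null_sc)
    p <- if (s == 0) as.numeric(sc[best] <= mu) else
      pnorm(sc[best], mean = mu, sd = s, lower.tail = FALSE)
    host <- models[[best]]$host_id
    accepted <- (p <= p_zero_eps) ||
      (p < p_weak && paste(v, host) %in% pro_keys)
    data.frame(virus_id = v, host_id = host, channel = "kmer",
               identity_pct = NA_real_, length_bp = nchar(virus_seqs[[v]]),
               loglik = sc[best], p = p, accepted = accepted,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(.empty_host_calls())
  do.call(rbind, rows)
}

#' Consensus host prediction across channels
#'
#' Accepted calls are grouped per virus; the primary host is the one backed
#' by the highest-priority channel (prophage > crispr > trna > kmer, ties on
#' host id broken ascending). All supporting channels are retained as
#' provenance.
#'
#' @param calls HostCall data.frame (rows from any subset of channels)
#' @param virus_ids universe of viruses for the linked-fraction statistic
#'   (defaults to the viruses present in `calls`)
#' @return list with `consensus` (virus_id, host_id, primary_channel,
#'   channels, n_channels) and `fraction_linked`
#' @export
consensus_hosts <- function(calls, virus_ids = NULL) {
  prio <- c(prophage = 1L, crispr = 2L, trna = 3L, kmer = 4L)
  acc <- calls[calls$accepted, , drop = FALSE]
  if (is.null(virus_ids)) virus_ids <- unique(calls$virus_id)
  if (!nrow(acc)) {
    cons <- data.frame(virus_id = character(0), host_id = character(0),
                       primary_channel = character(0), channels = character(0),
                       n_channels = integer(0), stringsAsFactors = FALSE)
    return(list(consensus = cons, fraction_linked = 0))
  }
  acc$prio <- prio[acc$channel]
  cons <- do.call(rbind, lapply(split(acc, acc$virus_id), function(d) {
    d <- d[order(d$prio, d$host_id), , drop = FALSE]
    data.frame(virus_id = d$virus_id[1L], host_id = d$host_id[1L],
               primary_channel = d$channel[1L],
               channels = paste(sort(unique(d$channel)), collapse = ";"),
               n_channels = length(unique(d$channel)),
               stringsAsFactors = FALSE)
  }))
  rownames(cons) <- NULL
  list(consensus = cons,
       fraction_linked = nrow(cons) / max(1L, length(virus_ids)))
}
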