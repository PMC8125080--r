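# Temperate/lytic lifestyle classification of viral contigs from lysogeny
# marker genes (integrase/site-specific recombinase, excisionase,
# repressor/antirepressor, ParA/B) and attL/attR attachment-site detection.
# A contig is a confident temperate phage when it carries an integrase AND a
# pair of identical direct-repeat att cores in noncoding sequence; any marker
# alone makes it a candidate temperate phage.

.MARKER_PATTERNS <- list(
  integrase = "integrase|site[- ]specific recombinase",
  excisionase = "excisionase",
  antirepressor = "anti[- ]?repressor",
  repressor = "repressor",
  parAB = "\\bpar\\s*[ab]\\b"
)

#' Map gene labels to lysogeny marker categories
#'
#' Case-insensitive keyword matching: integrase / site-specific recombinase,
#' excisionase, repressor, antirepressor (matched before repressor), and
#' ParA/ParB. Everything else is "other".
#'
#' @param annotations data.frame with `contig_id` and `label`
#' @return data.frame `annotations` plus a `category` column
#' @export
classify_markers <- function(annotations) {
  lab <- tolower(annotations$label)
  category <- rep("other", length(lab))
  # antirepressor must win over the plain "repressor" keyword
  for (cat in c("integrase", "excisionase", "antirepressor", "parAB", "repressor")) {
    hit <- grepl(.MARKER_PATTERNS[[cat]], lab, perl = TRUE) & category == "other"
    if (cat == "repressor") hit <- hit & !grepl(.MARKER_PATTERNS$antirepressor, lab, perl = TRUE)
    category[hit] <- cat
  }
  cbind(annotations, category = category, stringsAsFactors = FALSE)
}

#' Marker category sets per contig
#' @param annotations data.frame with `contig_id` and `label`
#' @return named list: contig_id -> character vector of marker categories
#'   present (excluding "other")
#' @export
marker_sets <- function(annotations) {
  ann <- classify_markers(annotations)
  ann <- ann[ann$category != "other", , drop = FALSE]
  lapply(split(ann$category, ann$contig_id), function(x) sort(unique(x)))
}

#' Find attL/attR direct-repeat pairs on a viral contig
#'
#' Searches for exact direct repeats of core length >= `min_core` whose two
#' copies (i) both lie entirely in noncoding sequence (not overlapping any
#' annotated gene), (ii) are separated by at least `min_sep_frac` of the
#' contig length, and (iii) each sit within `max_end_dist` of a contig end or
#' of an integrase gene. Returns nothing when the contig carries no integrase
#' annotation, since att sites are only meaningful next to an integration
#' module.
#'
#' @param contig_seq contig sequence (character scalar)
#' @param annotations data.frame with `start`, `end` (0-based half-open) and
#'   `label` for genes on this contig
#' @param contig_id id recorded on results
#' @param min_core minimum exact repeat core length (bp)
#' @param min_sep_frac minimum separation between copies as a fraction of
#'   contig length
#' @param max_end_dist maximum distance (bp) from a copy to a contig end or
#'   integrase gene
#' @return data.frame with `contig_id`, `attL_start`, `attL_end`,
#'   `attR_start`, `attR_end` (0-based half-open), `core_seq`, `core_len`
#' @export
find_att_pairs <- function(contig_seq, annotations, contig_id = "contig",
                           min_core = 12L, min_sep_frac = 0.5,
                           max_end_dist = 2000L) {
  empty <- data.frame(contig_id = character(0), attL_start = integer(0),
                      attL_end = integer(0), attR_start = integer(0),
                      attR_end = integer(0), core_seq = character(0),
                      core_len = integer(0), stringsAsFactors = FALSE)
  ann <- classify_markers(annotations)
  integ <- ann[ann$category == "integrase", , drop = FALSE]
  if (!nrow(integ)) return(empty)
  L <- nchar(contig_seq)
  coding <- logical(L)
  for (i in seq_len(nrow(ann))) {
    if (ann$end[i] > ann$start[i]) coding[(ann$start[i] + 1L):ann$end[i]] <- TRUE
  }
  near <- logical(L)  # positions within max_end_dist of an end or an integrase
  near[seq_len(min(L, max_end_dist))] <- TRUE
  near[max(1L, L - max_end_dist + 1L):L] <- TRUE
  for (i in seq_len(nrow(integ))) {
    lo <- max(1L, integ$start[i] - max_end_dist + 1L)
    hi <- min(L, integ$end[i] + max_end_dist)
    near[lo:hi] <- TRUE
  }
  # candidate seed starts: min_core window fully noncoding and in a near zone
  n_seed <- L - min_core + 1L
  if (n_seed < 1L) return(empty)
  ok_nc <- !coding
  # a window starting at p (1-based) spans p..p+min_core-1
  win_ok <- vapply(seq_len(n_seed), function(p) {
    near[p] && all(ok_nc[p:(p + min_core - 1L)])
  }, logical(1))
  cand <- which(win_ok)
  if (length(cand) < 2L) return(empty)
  words <- substring(contig_seq, cand, cand + min_core - 1L)
  rawseq <- charToRaw(contig_seq)
  min_sep <- ceiling(min_sep_frac * L)
  pairs <- list()
  by_word <- split(cand, words)
  for (pos in by_word) {
    if (length(pos) < 2L) next
    for (ii in seq_len(length(pos) - 1L)) {
      for (jj in (ii + 1L):length(pos)) {
        p1 <- pos[ii]; p2 <- pos[jj]
        if (p2 - p1 < min_sep) next
        # extend the exact repeat maximally while staying noncoding
        s1 <- p1; s2 <- p2; e1 <- p1 + min_core - 1L
        while (s1 > 1L && s2 > p1 + min_core - 1L &&
               rawseq[s1 - 1L] == rawseq[s2 - 1L] &&
               ok_nc[s1 - 1L] && ok_nc[s2 - 1L]) {
          s1 <- s1 - 1L; s2 <- s2 - 1L
        }
        clen <- min_core + (p1 - s1)
        e1 <- s1 + clen - 1L
        while (e1 < s2 - 1L && s2 + clen <= L &&
               rawseq[e1 + 1L] == rawseq[s2 + clen] &&
               ok_nc[e1 + 1L] && ok_nc[s2 + clen]) {
          clen <- clen + 1L; e1 <- e1 + 1L
        }
        pairs[[length(pairs) + 1L]] <- data.frame(
          contig_id = contig_id, attL_start = s1 - 1L, attL_end = s1 - 1L + clen,
          attR_start = s2 - 1L, attR_end = s2 - 1L + clen,
          core_seq = substr(contig_seq, s1, s1 + clen - 1L), core_len = clen,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  # seeds inside the same extended repeat collapse to one pair
  out <- out[!duplicated(out[, c("attL_start", "attR_start", "core_len")]), , drop = FALSE]
  out <- out[order(-out$core_len, out$attL_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lifestyle verdict for one contig
#'
#' `confident_temperate` iff an integrase marker is present AND at least one
#' att pair was found; `candidate_temperate` iff any lysogeny marker category
#' is present (and the contig is not confident); otherwise `no_evidence`.
#'
#' @param contig_id contig id
#' @param markers character vector of marker categories present
#' @param att_pairs data.frame from [find_att_pairs()]
#' @return data.frame with `contig_id`, `call`, `evidence`
#' @export
classify_lifestyle <- function(contig_id, markers, att_pairs) {
  has_att <- !is.null(att_pairs) && nrow(att_pairs) > 0L
  ev <- markers
  if (has_att) ev <- c(ev, "att_pair")
  call <- if ("integrase" %in% markers && has_att) {
    "confident_temperate"
  } else if (length(markers) > 0L) {
    "candidate_temperate"
  } else {
    "no_evidence"
  }
  data.frame(contig_id = contig_id, call = call,
             evidence = paste(ev, collapse = ";"), stringsAsFactors = FALSE)
}

#' Lifestyle classification for a set of contigs
#'
#' @param contig_seqs named character vector of viral contigs
#' @param annotations data.frame with `contig_id`, `start`, `end`, `strand`,
#'   `label` (0-based half-open coordinates)
#' @param ... passed to [find_att_pairs()]
#' @return list with `calls` (contig_id, call, evidence) and `att_pairs`
#' @export
classify_lifestyles <- function(contig_seqs, annotations, ...) {
  msets <- marker_sets(annotations)
  calls <- list(); atts <- list()
  for (cid in names(contig_seqs)) {
    ann <- annotations[annotations$contig_id == cid, , drop = FALSE]
    ap <- find_att_pairs(contig_seqs[[cid]], ann, contig_id = cid, ...)
    mk <- if (cid %in% names(msets)) msets[[cid]] else character(0)
    calls[[cid]] <- classify_lifestyle(cid, mk, ap)
    if (nrow(ap)) atts[[cid]] <- ap
  }
  att_pairs <- if (length(atts)) do.call(rbind, atts) else
    find_att_pairs("A", data.frame(contig_id = character(0), start = integer(0),
                                   end = integer(0), label = character(0)))
  rownames(att_pairs) <- NULL
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(contig_id = character(0), call = character(0),
               evidence = character(0), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, att_pairs = att_pairs)
}
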