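# Two-tier ensemble triage of contigs into viral / rejected / sub_length
# verdicts from a per-contig predictor score table (VirSorter-style category,
# DeepVirFinder-style score and p, MARVEL-style probability, CAT-style
# annotation summary). Missing predictor values never satisfy a criterion and
# never raise an error: real predictor output is sparse.

#' Validate one predictor score record
#' @keywords internal
.validate_score_record <- function(rec) {
  need <- c("contig_id", "length_bp", "topology")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("score record missing fields: ", paste(miss, collapse = ", "))
  if (is.na(rec$length_bp) || rec$length_bp <= 0) stop("length_bp must be positive")
  if (!rec$topology %in% c("linear", "circular")) stop("topology must be linear or circular")
  ok_range <- function(x, lo, hi) is.na(x) || (x >= lo && x <= hi)
  if (!is.na(.na_num(rec$virsorter_category)) &&
      !(rec$virsorter_category %in% 1:6)) stop("virsorter_category must be in 1..6")
  if (!ok_range(.na_num(rec$dvf_score), 0, 1)) stop("dvf_score out of [0,1]")
  if (!ok_range(.na_num(rec$dvf_p), 0, 1)) stop("dvf_p out of [0,1]")
  if (!ok_range(.na_num(rec$marvel_prob), 0, 100)) stop("marvel_prob out of [0,100]")
  if (!ok_range(.na_num(rec$cat_nonviral_gene_frac), 0, 1)) stop("cat_nonviral_gene_frac out of [0,1]")
  invisible(TRUE)
}

.na_num <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
.na_lgl <- function(x) if (is.null(x) || length(x) == 0L) NA else as.logical(x)

#' Classify a single contig from its predictor evidence
#'
#' Applies a length/topology gate (linear >= 5 kb or circular >= 1.5 kb),
#' then a keep gate (any VirSorter category 1-6, DeepVirFinder score >= 0.7
#' with p < 0.05, or MARVEL probability >= 70), then a two-tier call:
#' tier `high_confidence` for VirSorter categories 1/2/4/5, DVF >= 0.9, or
#' MARVEL >= 90; tier `two_tool` when at least two weaker signals agree
#' (VirSorter 3/6; DVF in [0.7, 0.9) with p < 0.05; MARVEL in [70, 90);
#' CAT viral or < 40% of genes classified non-viral). CAT support alone never
#' satisfies the keep gate. Missing values satisfy nothing.
#'
#' @param record a one-row data.frame or named list with fields `contig_id`,
#'   `length_bp`, `topology`, and optionally `virsorter_category`,
#'   `dvf_score`, `dvf_p`, `marvel_prob`, `cat_viral`,
#'   `cat_nonviral_gene_frac` (absent or NA when a predictor gave no call)
#' @param min_linear_bp,min_circular_bp length gates
#' @return data.frame with `contig_id`, `status` (viral/rejected/sub_length),
#'   `tier` (high_confidence/two_tool/none) and `evidence`
#'   (semicolon-joined criterion tokens)
#' @export
classify_contig <- function(record, min_linear_bp = 5000L, min_circular_bp = 1500L) {
  rec <- as.list(record)
  .validate_score_record(rec)
  cat_v <- .na_lgl(rec$cat_viral)
  vs <- .na_num(rec$virsorter_category)
  dvf <- .na_num(rec$dvf_score)
  dvfp <- .na_num(rec$dvf_p)
  mvl <- .na_num(rec$marvel_prob)
  catf <- .na_num(rec$cat_nonviral_gene_frac)

  out <- function(status, tier, ev) {
    data.frame(contig_id = rec$contig_id, status = status, tier = tier,
               evidence = paste(ev, collapse = ";"), stringsAsFactors = FALSE)
  }

  min_len <- if (rec$topology == "circular") min_circular_bp else min_linear_bp
  if (rec$length_bp < min_len) return(out("sub_length", "none", character(0)))

  isTRUE2 <- function(x) !is.na(x) && x
  keep_vs <- isTRUE2(vs >= 1 & vs <= 6)
  keep_dvf <- isTRUE2(dvf >= 0.7) && isTRUE2(dvfp < 0.05)
  keep_mvl <- isTRUE2(mvl >= 70)
  if (!(keep_vs || keep_dvf || keep_mvl)) return(out("rejected", "none", character(0)))

  # Tier 1: any single strong signal
  t1 <- character(0)
  if (isTRUE2(vs %in% c(1, 2, 4, 5))) t1 <- c(t1, sprintf("virsorter_cat%d", vs))
  if (isTRUE2(dvf >= 0.9)) t1 <- c(t1, "dvf_ge0.9")
  if (isTRUE2(mvl >= 90)) t1 <- c(t1, "marvel_ge90")
  if (length(t1)) return(out("viral", "high_confidence", t1))

  # Tier 2: at least two weaker tool signals
  t2 <- character(0)
  if (isTRUE2(vs %in% c(3, 6))) t2 <- c(t2, sprintf("virsorter_cat%d", vs))
  if (isTRUE2(dvf >= 0.7) && isTRUE2(dvf < 0.9) && isTRUE2(dvfp < 0.05)) t2 <- c(t2, "dvf_0.7_0.9")
  if (isTRUE2(mvl >= 70) && isTRUE2(mvl < 90)) t2 <- c(t2, "marvel_70_90")
  if (isTRUE2(cat_v) || isTRUE2(catf < 0.40)) t2 <- c(t2, "cat_support")
  if (length(t2) >= 2L) return(out("viral", "two_tool", t2))
  out("rejected", "none", character(0))
}

#' Screen a whole score table
#'
#' @param score_table data.frame with one row per contig (schema of
#'   [classify_contig()])
#' @param contig_ids optional character vector of expected contig ids; every
#'   score row must match one (unmatched rows are an error)
#' @return list with `decisions` (one row per contig) and `summary`
#'   (counts of viral contigs overall and at >= 5 kb / >= 10 kb)
#' @export
screen_table <- function(score_table, contig_ids = NULL) {
  if (nrow(score_table) == 0L) {
    dec <- data.frame(contig_id = character(0), status = character(0),
                      tier = character(0), evidence = character(0),
                      stringsAsFactors = FALSE)
    return(list(decisions = dec,
                summary = c(n_contigs = 0L, n_viral = 0L,
                            n_viral_ge5kb = 0L, n_viral_ge10kb = 0L)))
  }
  if (anyDuplicated(score_table$contig_id))
    stop("duplicate contig_id in score table")
  if (!is.null(contig_ids)) {
    bad <- setdiff(score_table$contig_id, contig_ids)
    if (length(bad))
      stop("score rows with no matching contig: ", paste(bad, collapse = ", "))
  }
  dec <- do.call(rbind, lapply(seq_len(nrow(score_table)), function(i) {
    classify_contig(score_table[i, , drop = FALSE])
  }))
  viral <- dec$status == "viral"
  len <- score_table$length_bp
  list(decisions = dec,
       summary = c(n_contigs = nrow(dec),
                   n_viral = sum(viral),
                   n_viral_ge5kb = sum(viral & len >= 5000),
                   n_viral_ge10kb = sum(viral & len >= 10000)))
}

#' Detect circular topology by direct terminal repeat
#'
#' A contig is called circular when its first `min_dtr_bp` bases recur
#' exactly as a suffix of the sequence.
#'
#' @param seq character scalar
#' @param min_dtr_bp minimum direct terminal repeat length
#' @return "circular" or "linear"
#' @export
detect_circularity <- function(seq, min_dtr_bp = 20L) {
  n <- nchar(seq)
  if (n < 2L * min_dtr_bp) return("linear")
  pre <- substr(seq, 1L, min_dtr_bp)
  suf <- substr(seq, n - min_dtr_bp + 1L, n)
  if (pre == suf) "circular" else "linear"
}

#' Contig length with the direct terminal repeat trimmed once
#'
#' For circular contigs the terminal repeat is counted once, so the length
#' used by the screening gate does not double-count the DTR. The repeat is
#' extended from `min_dtr_bp` to its maximal length before trimming.
#'
#' @inheritParams detect_circularity
#' @return integer effective length
#' @export
effective_length <- function(seq, min_dtr_bp = 20L) {
  n <- nchar(seq)
  if (detect_circularity(seq, min_dtr_bp) == "linear") return(n)
  L <- min_dtr_bp
  while (L < n %/% 2L &&
         substr(seq, 1L, L + 1L) == substr(seq, n - L, n)) {
    L <- L + 1L
  }
  n - L
}
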