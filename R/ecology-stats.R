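# Abundance normalization and the community statistics layer: RPKM,
# Bray-Curtis dissimilarity, log2(x+1) transform, PCoA (classical scaling),
# ANOSIM with a seeded permutation test, Shannon diversity, pairwise Wilcoxon
# with Benjamini-Hochberg correction, between/within-group dissimilarity
# extraction, Welch-t volcano statistics, and z-score hierarchical
# clustering. Matrices are features x samples throughout.

#' Reads per kilobase per million mapped reads
#'
#' rpkm = count * 1e9 / (length_bp * total_mapped).
#'
#' @param count mapped read count(s) for the feature
#' @param length_bp feature length(s) in bp (> 0)
#' @param total_mapped total mapped reads in the sample (> 0)
#' @return numeric RPKM value(s)
#' @export
rpkm <- function(count, length_bp, total_mapped) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  count * 1e9 / (length_bp * total_mapped)
}

#' RPKM-normalize a count matrix
#' @param counts features x samples count matrix
#' @param lengths_bp per-feature lengths (named or in row order)
#' @param totals per-sample total mapped reads (defaults to column sums)
#' @return RPKM matrix of the same shape
#' @export
rpkm_matrix <- function(counts, lengths_bp, totals = colSums(counts)) {
  stopifnot(nrow(counts) == length(lengths_bp), ncol(counts) == length(totals))
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts))) {
    lengths_bp <- lengths_bp[rownames(counts)]
  }
  sweep(sweep(counts, 1, lengths_bp, "/"), 2, totals, "/") * 1e9
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(a, b) = sum|a_i - b_i| / sum(a_i + b_i), computed between the columns of
#' a features x samples matrix (vegan's vegdist underneath). A pair of
#' all-zero samples gets distance 0 with a warning.
#'
#' @param m non-negative features x samples matrix
#' @return symmetric sample x sample distance matrix with zero diagonal
#' @export
bray_curtis <- function(m) {
  if (any(m < 0)) stop("Bray-Curtis needs non-negative abundances")
  # vegdist warns about empty rows itself; the NaN cells it produces for
  # all-zero pairs are handled (and warned about) below
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(m), method = "bray")))
  if (any(!is.finite(d))) {
    warning("all-zero sample pair(s); their Bray-Curtis distance is set to 0")
    d[!is.finite(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' log2(x + pseudocount) transform
#' @param m non-negative matrix
#' @param pseudocount value added before the log (default 1)
#' @return transformed matrix
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (any(m < 0)) stop("negative values in abundance matrix")
  log2(m + pseudocount)
}

#' Principal-coordinate analysis (classical scaling)
#'
#' Double-centered Gram eigendecomposition of a distance matrix. Axes with
#' non-positive eigenvalues are dropped from the coordinates; the full
#' eigenvalue spectrum is reported.
#'
#' @param d symmetric distance matrix with zero diagonal
#' @return list with `points` (samples x axes), `eig` (all eigenvalues) and
#'   `negative` (number of negative eigenvalues)
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  sc <- suppressWarnings(cmdscale(as.dist(d), k = n - 1L, eig = TRUE))
  eig <- sc$eig
  keep <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  pts <- sc$points[, seq_along(keep), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_along(keep))
  list(points = pts, eig = eig, negative = sum(eig < 0))
}

#' @keywords internal
.anosim_r <- function(rank_d, within) {
  m <- length(rank_d)
  (mean(rank_d[!within]) - mean(rank_d[within])) / (m / 2)
}

#' ANOSIM: analysis of similarities with a seeded permutation test
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2), with M the
#' number of pairwise distances. The p-value uses the add-one estimator
#' (1 + #{permuted R >= observed}) / (1 + n_perm) over seeded label
#' permutations, so p is never reported as 0.
#'
#' @param d symmetric sample distance matrix (dimnames = sample ids)
#' @param groups factor/character of group labels in column order of `d`
#' @param n_perm number of label permutations
#' @param seed RNG seed for the permutations (optional)
#' @return list with `R`, `p`, `n_perm`
#' @export
anosim_test <- function(d, groups, n_perm = 999L, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs at least two samples")
  n <- nrow(d)
  lower <- which(lower.tri(d))
  rank_d <- rank(d[lower])
  pair_i <- row(d)[lower]; pair_j <- col(d)[lower]
  obs <- .anosim_r(rank_d, groups[pair_i] == groups[pair_j])
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]
    if (.anosim_r(rank_d, gp[pair_i] == gp[pair_j]) >= obs) ge <- ge + 1L
  }
  list(R = obs, p = (1 + ge) / (1 + n_perm), n_perm = n_perm)
}

#' PERMANOVA pseudo-F alternative (vegan::adonis2 wrapper)
#'
#' Provided alongside [anosim_test()] because ordination group tests in this
#' field are reported under both names; the two statistics are not
#' interchangeable.
#'
#' @inheritParams anosim_test
#' @return list with `F`, `R2`, `p`
#' @export
permanova_test <- function(d, groups, n_perm = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(group = factor(groups))
  fit <- vegan::adonis2(as.dist(d) ~ group, data = df, permutations = n_perm)
  list(F = fit$F[1L], R2 = fit$R2[1L], p = fit$`Pr(>F)`[1L])
}

#' Shannon diversity index (natural log)
#' @param x non-negative abundance vector, not all zero
#' @return H = -sum p_i ln p_i over nonzero entries
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("negative abundances")
  if (sum(x) == 0) stop("all-zero abundance vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' @keywords internal
.contrast_pairs <- function(groups, contrasts) {
  if (is.null(contrasts)) {
    gl <- sort(unique(as.character(groups)))
    contrasts <- combn(gl, 2L, simplify = FALSE)
  }
  contrasts
}

#' Pairwise Wilcoxon rank-sum tests with BH correction
#'
#' Two-sided rank-sum test per feature and contrast (exact when the combined
#' n is small and untied, normal approximation with midranks otherwise,
#' following `wilcox.test`); q-values are BH step-up adjusted within each
#' contrast family. Constant features get p = 1.
#'
#' @param m features x samples abundance matrix
#' @param design data.frame with `sample_id` and `group` (sample order need
#'   not match; matched by `sample_id` against colnames)
#' @param contrasts list of 2-vectors of group labels; default all pairs
#' @return data.frame with `feature_id`, `contrast`, `statistic`, `p`, `q`,
#'   `direction` (group enriched by mean difference)
#' @export
wilcoxon_bh <- function(m, design, contrasts = NULL) {
  grp <- setNames(as.character(design$group), design$sample_id)[colnames(m)]
  if (any(is.na(grp))) stop("unlabeled samples in matrix")
  contrasts <- .contrast_pairs(grp, contrasts)
  out <- list()
  for (ct in contrasts) {
    i1 <- which(grp == ct[1L]); i2 <- which(grp == ct[2L])
    if (length(i1) < 2L || length(i2) < 2L) stop("each group needs >= 2 samples")
    res <- t(apply(m, 1L, function(x) {
      a <- x[i1]; b <- x[i2]
      if (length(unique(c(a, b))) == 1L) return(c(NA_real_, 1))
      w <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
      c(unname(w$statistic), w$p.value)
    }))
    q <- p.adjust(res[, 2L], method = "BH")
    md <- rowMeans(m[, i2, drop = FALSE]) - rowMeans(m[, i1, drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      feature_id = rownames(m), contrast = paste(ct, collapse = "_vs_"),
      statistic = res[, 1L], p = res[, 2L], q = q,
      direction = ifelse(md > 0, ct[2L], ifelse(md < 0, ct[1L], "none")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Between- or within-group dissimilarity values
#'
#' @param d symmetric sample distance matrix (dimnames = sample ids)
#' @param design data.frame with `sample_id`, `group`
#' @param mode "between" (needs `g1`, `g2`: |g1| x |g2| values) or "within"
#'   (needs `g1`: choose(|g1|, 2) values)
#' @param g1,g2 group labels
#' @return numeric vector of dissimilarities
#' @export
group_dissimilarities <- function(d, design, mode = c("between", "within"),
                                  g1, g2 = NULL) {
  mode <- match.arg(mode)
  d <- as.matrix(d)
  grp <- setNames(as.character(design$group), design$sample_id)
  if (!g1 %in% grp) stop("unknown group: ", g1)
  s1 <- design$sample_id[design$group == g1]
  if (mode == "between") {
    if (is.null(g2) || !g2 %in% grp) stop("unknown group: ", g2)
    s2 <- design$sample_id[design$group == g2]
    as.vector(d[s1, s2])
  } else {
    dd <- d[s1, s1]
    dd[lower.tri(dd)]
  }
}

#' Welch t-test volcano statistics per feature
#'
#' Two-sample Welch t-tests on a (log-transformed) abundance matrix for one
#' contrast, BH-adjusted. The effect is the mean difference (second group
#' minus first); features constant in both groups get p = 1 when the means
#' are equal.
#'
#' @param m features x samples matrix (typically log2(RPKM + 1))
#' @param design data.frame with `sample_id`, `group`
#' @param contrast length-2 character vector of group labels
#' @return data.frame with `feature_id`, `contrast`, `effect`, `statistic`,
#'   `p`, `q`, `direction`
#' @export
t_volcano <- function(m, design, contrast) {
  stopifnot(length(contrast) == 2L)
  grp <- setNames(as.character(design$group), design$sample_id)[colnames(m)]
  i1 <- which(grp == contrast[1L]); i2 <- which(grp == contrast[2L])
  if (length(i1) < 2L || length(i2) < 2L) stop("each group needs >= 2 samples")
  res <- t(apply(m, 1L, function(x) {
    a <- x[i1]; b <- x[i2]
    eff <- mean(b) - mean(a)
    tt <- tryCatch(t.test(b, a, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      c(eff, NA_real_, if (eff == 0) 1 else 0)
    } else {
      c(eff, unname(tt$statistic), tt$p.value)
    }
  }))
  q <- p.adjust(res[, 3L], method = "BH")
  out <- data.frame(feature_id = rownames(m),
                    contrast = paste(contrast, collapse = "_vs_"),
                    effect = res[, 1L], statistic = res[, 2L], p = res[, 3L],
                    q = q,
                    direction = ifelse(res[, 1L] > 0, contrast[2L],
                                       ifelse(res[, 1L] < 0, contrast[1L], "none")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Row z-score normalization with hierarchical clustering
#'
#' Rows are centered and scaled to unit variance (constant rows become
#' all-zero with a warning); rows are then clustered with complete-linkage
#' agglomeration on Euclidean distances.
#'
#' @param m features x samples matrix with >= 2 rows
#' @return list with `z` (normalized matrix), `hclust` and `order`
#'   (deterministic leaf order)
#' @export
zscore_hclust <- function(m) {
  stopifnot(nrow(m) >= 2L)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  if (any(s == 0)) {
    warning("constant row(s) z-scored to all zero")
    s[s == 0] <- 1
  }
  z <- (m - mu) / s
  hc <- hclust(dist(z, method = "euclidean"), method = "complete")
  list(z = z, hclust = hc, order = hc$order)
}
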