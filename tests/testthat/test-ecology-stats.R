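test_that("RPKM follows its closed form and is linear in counts", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(57, 4500, 23.5e6), 0.539, tolerance = 1e-3)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "total")
  expect_equal(rpkm(20, 1000, 1e6), 2 * rpkm(10, 1000, 1e6))

  cnt <- matrix(c(10, 90, 40, 60), nrow = 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
  rk <- rpkm_matrix(cnt, c(f1 = 1000, f2 = 2000), totals = c(1e6, 1e6))
  expect_equal(rk["f1", "s1"], 10)
  expect_equal(rk["f2", "s2"], 30)
})

test_that("Bray-Curtis distances match hand arithmetic and stay in [0,1]", {
  m <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 4 / 12, tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0))

  ident <- cbind(x = c(5, 1), y = c(5, 1))
  expect_equal(bray_curtis(ident)["x", "y"], 0)
  disjoint <- cbind(x = c(5, 0), y = c(0, 3))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  set.seed(53)
  big <- matrix(rlnorm(200), nrow = 20)
  colnames(big) <- paste0("s", 1:10)
  db <- bray_curtis(big)
  expect_true(all(db >= 0 & db <= 1))
  expect_equal(db, t(db))

  zz <- cbind(a = c(0, 0), b = c(0, 0))
  expect_warning(dz <- bray_curtis(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("log2 pseudocount transform hits exact powers", {
  m <- matrix(c(0, 1, 7, 15), 2)
  expect_equal(log_transform(m), matrix(c(0, 1, 3, 4), 2))
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("PCoA embeds Euclidean distances exactly", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 4
  d["b", "c"] <- d["c", "b"] <- 5
  ord <- pcoa_ordination(d)
  got <- as.matrix(dist(ord$points))
  expect_equal(got["a", "b"], 3, tolerance = 1e-6)
  expect_equal(got["a", "c"], 4, tolerance = 1e-6)
  expect_equal(got["b", "c"], 5, tolerance = 1e-6)
  # eigenvalue sum equals the trace of the centered Gram matrix
  n <- 3
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (d^2) %*% J
  expect_equal(sum(ord$eig), sum(diag(G)), tolerance = 1e-8)

  # identical samples land on coincident coordinates
  m <- cbind(s1 = c(1, 2), s2 = c(1, 2), s3 = c(4, 1))
  dd <- bray_curtis(m)
  oo <- pcoa_ordination(dd)
  expect_equal(oo$points["s1", ], oo$points["s2", ], tolerance = 1e-9)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ANOSIM matches exhaustive enumeration on a separable design", {
  # two groups of 3 in perfect separation
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- rep(c("A", "B"), each = 3)
  res <- anosim_test(d, groups, n_perm = 999, seed = 1)
  expect_equal(res$R, 1)
  # enumeration oracle: 20 ordered labelings, 2 reach R = 1
  combs <- combn(6, 3)
  r_all <- apply(combs, 2, function(ix) {
    g <- rep("B", 6); g[ix] <- "A"
    anosim_r_stat(d, g)
  })
  expect_equal(mean(r_all >= 1), 0.1)
  expect_lt(abs(res$p - 0.1), 0.03)

  # agreement with the reference implementation on the R statistic
  veg <- vegan::anosim(as.dist(d), grouping = factor(groups), permutations = 0)
  expect_equal(res$R, unname(veg$statistic), tolerance = 1e-12)

  # all-equal distances: R = 0 by rank symmetry
  deq <- matrix(1, 6, 6); diag(deq) <- 0
  dimnames(deq) <- dimnames(d)
  expect_equal(anosim_test(deq, groups, n_perm = 99, seed = 1)$R, 0)

  expect_error(anosim_test(d, c("A", rep("B", 5)), 99), "at least two")
})

test_that("Shannon diversity has its closed forms", {
  expect_equal(shannon(rep(2, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")
  # agreement with the reference implementation
  set.seed(59)
  x <- rlnorm(30)
  expect_equal(shannon(x), unname(vegan::diversity(x, "shannon")),
               tolerance = 1e-12)
})

test_that("Wilcoxon/BH results match exact enumeration and hand BH", {
  m <- rbind(extreme = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             flat = rep(1, 10))
  colnames(m) <- paste0("s", 1:10)
  design <- data.frame(sample_id = paste0("s", 1:10),
                       group = rep(c("g1", "g2"), each = 5))
  res <- wilcoxon_bh(m, design)
  expect_equal(res$p[res$feature_id == "extreme"], 2 / 252, tolerance = 1e-12)
  expect_equal(res$p[res$feature_id == "flat"], 1)
  expect_equal(res$direction[res$feature_id == "extreme"], "g2")

  # BH step-up against the hand computation
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.4), "BH"), c(0.02, 0.4))
})

test_that("between/within dissimilarity extraction counts comparisons", {
  set.seed(61)
  m <- matrix(rlnorm(15 * 30), nrow = 30)
  colnames(m) <- paste0("s", 1:15)
  design <- data.frame(sample_id = paste0("s", 1:15),
                       group = rep(c("lam", "t4", "t10"), each = 5))
  d <- bray_curtis(m)
  btw <- group_dissimilarities(d, design, "between", "lam", "t4")
  expect_length(btw, 25)
  win <- group_dissimilarities(d, design, "within", "lam")
  expect_length(win, 10)
  # 2-group partition identity on off-diagonal entries
  two <- design[design$group != "t10", ]
  d2 <- d[two$sample_id, two$sample_id]
  all_off <- sort(d2[lower.tri(d2)])
  parts <- sort(c(group_dissimilarities(d2, two, "between", "lam", "t4"),
                  group_dissimilarities(d2, two, "within", "lam"),
                  group_dissimilarities(d2, two, "within", "t4")))
  expect_equal(length(parts), length(all_off))
  expect_equal(sort(parts), all_off, tolerance = 1e-12)
  expect_error(group_dissimilarities(d, design, "within", "nope"), "unknown")
})

test_that("t volcano flips sign under label swap and handles degeneracy", {
  set.seed(67)
  m <- matrix(rnorm(50 * 10), nrow = 50,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:10)))
  design <- data.frame(sample_id = paste0("s", 1:10),
                       group = rep(c("a", "b"), each = 5))
  r1 <- t_volcano(m, design, c("a", "b"))
  r2 <- t_volcano(m, design, c("b", "a"))
  expect_equal(r1$effect, -r2$effect)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)

  const <- rbind(f1 = rep(3, 10))
  colnames(const) <- paste0("s", 1:10)
  rc <- t_volcano(const, design, c("a", "b"))
  expect_equal(rc$p, 1)
})

test_that("null and responder behaviour of the volcano is calibrated", {
  set.seed(71)
  n_seeds <- 40
  fpr <- numeric(n_seeds)
  hit <- logical(n_seeds)
  design <- data.frame(sample_id = paste0("s", 1:10),
                       group = rep(c("a", "b"), each = 5))
  for (i in seq_len(n_seeds)) {
    base <- rlnorm(60)
    prof <- vapply(1:10, function(j) {
      w <- base * rlnorm(60, 0, 0.4)
      w / sum(w)
    }, numeric(60))
    rownames(prof) <- paste0("f", 1:60)
    colnames(prof) <- design$sample_id
    counts <- simulate_counts(prof, 2e5)
    lm0 <- log_transform(rpkm_matrix(counts, rep(1000, 60)))
    fpr[i] <- mean(t_volcano(lm0, design, c("a", "b"))$q < 0.05, na.rm = TRUE)

    # planted 8x responder in group b
    prof2 <- prof
    prof2["f1", 6:10] <- prof2["f1", 6:10] * 8
    prof2 <- sweep(prof2, 2, colSums(prof2), "/")
    counts2 <- simulate_counts(prof2, 2e5)
    lm2 <- log_transform(rpkm_matrix(counts2, rep(1000, 60)))
    r <- t_volcano(lm2, design, c("a", "b"))
    hit[i] <- r$q[r$feature_id == "f1"] < 0.05 && r$direction[r$feature_id == "f1"] == "b"
  }
  expect_lte(mean(fpr), 0.05)
  expect_gte(mean(hit), 0.95)
})

test_that("z-score rows are standardized and duplicated rows merge first", {
  set.seed(73)
  m <- matrix(rnorm(8 * 6), nrow = 8,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:6)))
  m[2, ] <- m[1, ]          # duplicated profile
  out <- zscore_hclust(m)
  expect_equal(unname(rowMeans(out$z)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(out$z, 1, sd)), rep(1, 8), tolerance = 1e-12)
  expect_equal(sort(out$hclust$merge[1, ]), c(-2, -1))

  # constant rows become all-zero with a warning
  mc <- rbind(m, f9 = rep(2, 6))
  expect_warning(outc <- zscore_hclust(mc), "constant")
  expect_equal(unname(outc$z["f9", ]), rep(0, 6))

  # three planted row profiles are recovered at k = 3
  prof <- rbind(
    matrix(rep(c(5, 5, 0, 0, 0, 0), each = 4), nrow = 4, byrow = FALSE),
    matrix(rep(c(0, 0, 5, 5, 0, 0), each = 4), nrow = 4, byrow = FALSE),
    matrix(rep(c(0, 0, 0, 0, 5, 5), each = 4), nrow = 4, byrow = FALSE))
  prof <- prof + matrix(rnorm(nrow(prof) * 6, 0, 0.2), ncol = 6)
  rownames(prof) <- paste0("r", 1:12)
  oc <- zscore_hclust(prof)
  k3 <- cutree(oc$hclust, k = 3)
  expect_equal(mclust::adjustedRandIndex(k3, rep(1:3, each = 4)), 1)
})

test_that("PERMANOVA wrapper agrees directionally with ANOSIM", {
  pts <- c(0, 0.3, 0.5, 8, 8.2, 8.4)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- rep(c("A", "B"), each = 3)
  pm <- permanova_test(d, groups, n_perm = 199, seed = 3)
  expect_gt(pm$F, 1)
  expect_lt(pm$p, 0.2)
  expect_true(pm$R2 > 0 && pm$R2 < 1)
})
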