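test_that("per-tissue mean and median are computed over the right samples", {
  v <- matrix(c(1, 3, 0,
                0, 0, 9), 2, 3, byrow = TRUE)
  em <- make_em(rbind(v, 0), tissue = c("A", "A", "B"))
  s <- summarize_by_tissue(em)
  gA <- s[s$gene_id == "g1" & s$tissue == "A", ]
  expect_equal(gA$mean_fpkm, 2)
  expect_equal(gA$median_fpkm, 2)
  expect_equal(gA$n_samples, 2)
  # single-sample tissue: mean = median = the value
  gB <- s[s$gene_id == "g2" & s$tissue == "B", ]
  expect_equal(gB$mean_fpkm, 9)
  expect_equal(gB$median_fpkm, 9)

  em2 <- make_em(matrix(c(0, 0, 9), 1), tissue = rep("A", 3))
  s2 <- summarize_by_tissue(em2)
  expect_equal(s2$mean_fpkm, 3)
  expect_equal(s2$median_fpkm, 0)
})

test_that("summaries are invariant to sample order within a tissue", {
  set.seed(7)
  for (i in 1:5) {
    v <- matrix(stats::rexp(40), 5, 8)
    tissue <- rep(c("A", "B"), each = 4)
    em <- make_em(v, tissue)
    perm <- c(sample(1:4), sample(5:8))
    emp <- make_em(v[, perm], tissue[perm], genes = rownames(em$values))
    s1 <- summarize_by_tissue(em)
    s2 <- summarize_by_tissue(emp)
    expect_equal(summary_matrix(s1, "mean"), summary_matrix(s2, "mean"))
    expect_equal(summary_matrix(s1, "median"), summary_matrix(s2, "median"))
  }
})

test_that("activity report counts detected and inactive genes per tissue", {
  v <- matrix(c(0.2, 0.4,
                5, 6,
                0, 0), 3, 2, byrow = TRUE)
  em <- make_em(v, tissue = c("A", "A"))
  rep <- activity_report(em)
  expect_equal(rep$n_detected, 2)
  expect_equal(rep$n_inactive, 1)
  expect_equal(rep$fraction_inactive, 0.5)

  # exactly 1.0 in one sample -> active (strict < 1 rule)
  em2 <- make_em(matrix(c(1.0, 0.2), 1), tissue = c("A", "A"))
  expect_equal(activity_report(em2)$n_inactive, 0)

  # everything active
  em3 <- make_em(matrix(c(2, 3, 4, 5), 2), tissue = c("A", "A"))
  expect_equal(activity_report(em3)$fraction_inactive, 0)

  # fractions bounded; detected + never-expressed = total
  set.seed(11)
  v4 <- matrix(stats::rexp(60) * stats::rbinom(60, 1, 0.7), 10, 6)
  em4 <- make_em(v4, rep(c("A", "B"), each = 3))
  r4 <- activity_report(em4)
  expect_true(all(r4$fraction_inactive >= 0 & r4$fraction_inactive <= 1))
  for (t in r4$tissue) {
    sub <- em4$values[, tissue_samples(em4, t)]
    never <- sum(rowSums(sub > 0) == 0)
    expect_equal(r4$n_detected[r4$tissue == t] + never, nrow(sub))
  }
})

test_that("replicate filter keeps genes with enough positive samples in one tissue", {
  # one positive sample in each of three tissues: dropped at min_samples = 2
  v <- matrix(0, 2, 6)
  v[1, c(1, 3, 5)] <- 5
  v[2, 1:2] <- 5   # two positives in tissue A: kept
  em <- make_em(v, rep(c("A", "B", "C"), each = 2))
  kept <- filter_min_expressed_samples(em, 2)
  expect_identical(rownames(kept$values), "g2")

  # min_samples = 1 is exactly the all-zero-gene filter
  v2 <- rbind(v, 0)
  em2 <- make_em(v2, rep(c("A", "B", "C"), each = 2))
  k1 <- filter_min_expressed_samples(em2, 1)
  expect_identical(rownames(k1$values), c("g1", "g2"))

  # idempotence
  expect_identical(filter_min_expressed_samples(kept, 2)$values, kept$values)

  # empty result warns
  em3 <- make_em(matrix(0, 1, 2), c("A", "A"))
  expect_warning(out <- filter_min_expressed_samples(em3, 1), "empty")
  expect_equal(nrow(out$values), 0)
})

test_that("tissue clustering groups correlated tissues first", {
  # construct vectors in log space so the transform is exactly inverted
  set.seed(3)
  base <- stats::rnorm(50, 5, 2)
  la <- base
  lb <- base + stats::rnorm(50, 0, 0.1)       # ~identical to A
  lc <- sample(base) + stats::rnorm(50, 0, 2) # unrelated
  m <- cbind(A = 2^la - 1, B = 2^lb - 1, C = 2^lc - 1)
  m[m < 0] <- 0
  rownames(m) <- paste0("g", 1:50)
  cl <- tissue_correlation_clustering(summary_from_means(m))
  expect_gt(cl$correlation["A", "B"], cl$correlation["A", "C"])
  first <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  expect_match(cl$newick, "^\\(")

  # identical tissue vectors: r exactly 1; doubled copy: r ~ 1 after log
  m2 <- cbind(A = m[, 1], B = m[, 1], C = 2 * m[, 1])
  cl2 <- tissue_correlation_clustering(summary_from_means(m2))
  expect_equal(cl2$correlation["A", "B"], 1)
  expect_gt(cl2$correlation["A", "C"], 0.99)

  # constant tissue excluded with a warning
  m3 <- cbind(A = m[, 1], B = m[, 2], D = rep(2, 50))
  expect_warning(cl3 <- tissue_correlation_clustering(summary_from_means(m3)),
                 "D")
  expect_true(all(is.na(cl3$correlation["D", ])))
})

test_that("sample PCA separates distinct tissue groups", {
  set.seed(21)
  g <- 200
  a <- matrix(2^(stats::rnorm(g * 4, 6, 0.3)), g)
  b <- matrix(2^(stats::rnorm(g * 4, 6, 0.3)), g)
  shift <- sample(g, 80)
  b[shift, ] <- b[shift, ] * 8
  em <- make_em(cbind(a, b), rep(c("A", "B"), each = 4))
  pca <- sample_pca(em)
  pc1 <- pca$scores[, 1]
  expect_true(all(sign(pc1[1:4]) != sign(pc1[5:8])))
  expect_lte(sum(pca$var_explained), 1 + 1e-12)

  # duplicated sample gets identical scores
  v <- em$values
  v2 <- cbind(v, dup = v[, 1])
  em2 <- ExpressionMatrix(v2, design = c(em$design, dup = "A"))
  p2 <- sample_pca(em2)
  expect_equal(unname(p2$scores["s1", ]), unname(p2$scores["dup", ]))

  # too few genes after filtering is an error
  em3 <- make_em(matrix(0.5, 3, 4), rep("A", 4))
  expect_error(sample_pca(em3), "fewer than 2 genes")
})

test_that("biotype composition is a faithful group-by", {
  ann <- data.frame(gene_id = paste0("g", 1:4),
                    biotype = c("protein_coding", "protein_coding",
                                "lncRNA", "lncRNA"))
  comp <- biotype_composition(c("g1", "g2", "g3", "g9"), ann)
  expect_equal(comp$n[comp$biotype == "protein_coding"], 2L)
  expect_equal(comp$n[comp$biotype == "unannotated"], 1L)
  expect_equal(sum(comp$fraction), 1)
})
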