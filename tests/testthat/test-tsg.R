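test_that("the three criteria evaluate as quoted on literal means", {
  m <- rbind(g1 = c(30, 1, 1, 1),
             g2 = c(9, 3, 3, 3),
             g3 = c(5, 5, 5, 5))
  colnames(m) <- paste0("t", 1:4)
  tsg <- detect_tsg(summary_from_means(m))
  r1 <- tsg[tsg$gene_id == "g1" & tsg$tissue == "t1", ]
  expect_true(r1$crit_top && r1$crit_sum && r1$crit_fold && r1$is_tsg)
  expect_equal(r1$sum_other_means, 3)
  expect_equal(r1$max_other_mean, 1)
  # g2: sum criterion passes (9 > 4.5) but fold fails (9 > 9 is false)
  r2 <- tsg[tsg$gene_id == "g2" & tsg$tissue == "t1", ]
  expect_true(r2$crit_sum)
  expect_false(r2$crit_fold)
  expect_false(r2$is_tsg)
  # constant gene can never pass the fold criterion
  expect_false(any(tsg$is_tsg[tsg$gene_id == "g3"]))
})

test_that("genes with zero mean everywhere emit no candidate row", {
  m <- rbind(g1 = c(10, 0), g2 = c(0, 0))
  colnames(m) <- c("t1", "t2")
  tsg <- detect_tsg(summary_from_means(m))
  expect_false("g2" %in% tsg$gene_id)
  expect_equal(nrow(tsg[tsg$gene_id == "g1", ]), 1L)
})

test_that("detection agrees with the brute-force oracle on random matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- random_mean_matrix(50, 6)
    got <- detect_tsg(summary_from_means(m))
    want <- oracle_tsg(m)
    key <- function(d) paste(d$gene_id, d$tissue)
    got <- got[order(key(got)), ]
    want <- want[order(key(want)), ]
    expect_identical(key(got), key(want))
    expect_identical(got$crit_top, want$crit_top)
    expect_identical(got$crit_sum, want$crit_sum)
    expect_identical(got$crit_fold, want$crit_fold)
    expect_identical(got$is_tsg, want$is_tsg)
  }
})

test_that("a gene is specific to at most one tissue", {
  for (seed in 11:30) {
    set.seed(seed)
    m <- random_mean_matrix(40, 5, zero_frac = 0.4)
    tsg <- detect_tsg(summary_from_means(m))
    per_gene <- tapply(tsg$is_tsg, tsg$gene_id, sum)
    expect_true(all(per_gene <= 1))
  }
})

test_that("particular TSGs are silent outside their target tissue", {
  m <- rbind(g1 = c(30, 0.2, 0.1, 0.5),
             g2 = c(30, 2, 0.1, 0.5))
  colnames(m) <- paste0("t", 1:4)
  s <- summary_from_means(m)
  tsg <- detect_particular_tsg(detect_tsg(s), s)
  expect_true(tsg$is_particular[tsg$gene_id == "g1" & tsg$tissue == "t1"])
  r2 <- tsg[tsg$gene_id == "g2" & tsg$tissue == "t1", ]
  expect_true(r2$is_tsg)
  expect_false(r2$is_particular)
  # particular set is a subset of the TSG set, on random input too
  set.seed(31)
  m2 <- random_mean_matrix(60, 6, zero_frac = 0.5)
  s2 <- summary_from_means(m2)
  t2 <- detect_particular_tsg(detect_tsg(s2), s2)
  expect_true(all(!t2$is_particular | t2$is_tsg))
})

test_that("raising fold shrinks TSG calls; raising the silence threshold grows particulars", {
  set.seed(41)
  m <- random_mean_matrix(80, 6, zero_frac = 0.3)
  s <- summary_from_means(m)
  t3 <- detect_tsg(s, fold = 3)
  t5 <- detect_tsg(s, fold = 5)
  called <- function(d) paste(d$gene_id, d$tissue)[d$is_tsg]
  expect_true(all(called(t5) %in% called(t3)))

  p1 <- detect_particular_tsg(t3, s, silence_threshold = 1)
  p2 <- detect_particular_tsg(t3, s, silence_threshold = 4)
  part <- function(d) paste(d$gene_id, d$tissue)[d$is_particular]
  expect_true(all(part(p1) %in% part(p2)))
})

test_that("per-tissue counts conserve totals", {
  empty <- detect_tsg(summary_from_means(
    matrix(0, 1, 2, dimnames = list("g1", c("t1", "t2")))))
  expect_equal(nrow(tsg_counts_by_tissue(empty)), 0L)

  m <- rbind(g1 = c(30, 1, 1), g2 = c(40, 0.1, 0.2), g3 = c(1, 1, 50))
  colnames(m) <- paste0("t", 1:3)
  s <- summary_from_means(m)
  tsg <- detect_particular_tsg(detect_tsg(s), s)
  cts <- tsg_counts_by_tissue(tsg)
  expect_equal(sum(cts$n_tsg), sum(tsg$is_tsg))
  expect_equal(sum(cts$n_particular), sum(tsg$is_particular))
  expect_gte(sum(cts$n_tsg), sum(cts$n_particular))

  top <- top_particular_tsg(tsg, n = 1)
  expect_equal(nrow(top), 1L)
  expect_equal(top$gene_id, "g2")
})
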