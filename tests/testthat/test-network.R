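test_that("network expression filter honors its two modes", {
  # g1: > 1 in all samples of tissue A only; g2: < 1 everywhere;
  # g3: > 1 in all samples of both tissues
  v <- rbind(c(5, 6, 0.5, 2),
             c(0.5, 0.6, 0.2, 0.3),
             c(4, 5, 6, 7))
  em <- make_em(v, c("A", "A", "B", "B"))
  def <- filter_for_network(em, mode = "any_tissue", min_genes = 1)
  expect_setequal(rownames(def$values), c("g1", "g3"))
  strict <- filter_for_network(em, mode = "all_tissues", min_genes = 1)
  expect_identical(rownames(strict$values), "g3")
  expect_true(all(rownames(strict$values) %in% rownames(def$values)))
  expect_error(filter_for_network(em, min_genes = 10), "mode")
})

test_that("scale-free fit index recognizes a planted power law", {
  set.seed(17)
  kk <- 1:100
  k <- sample(kk, 3000, replace = TRUE, prob = kk^-2) +
    stats::runif(3000, 0, 0.2)
  sf <- scale_free_fit(k)
  expect_gte(sf$fit, 0.9)
  expect_lt(sf$slope, 0)
  expect_lte(sf$fit, 1)
  # independent check of the regression via closed-form slope/R^2
  brk <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- as.numeric(tapply(k, bin, mean))
  mids <- (brk[-1] + brk[-11]) / 2
  kmean[is.na(kmean) | kmean == 0] <- mids[is.na(kmean) | kmean == 0]
  x <- log10(kmean); y <- log10(freq + 1e-9)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- slope^2 * sum((x - mean(x))^2) / sum((y - mean(y))^2)
  expect_equal(sf$slope, slope, tolerance = 1e-10)
  expect_equal(sf$fit, -sign(slope) * r2, tolerance = 1e-10)
  # anti-scale-free degrees score poorly
  expect_lt(scale_free_fit(stats::rnorm(3000, 50, 2))$fit, 0.9)
})

test_that("soft-threshold selection reports fits and degenerates loudly", {
  set.seed(23)
  lexpr <- matrix(stats::rnorm(200 * 20), 200,
                  dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
  pick <- suppressWarnings(pick_soft_threshold(lexpr))
  expect_equal(nrow(pick$fit_table), 20L)
  expect_true(pick$beta %in% pick$fit_table$beta)
  expect_equal(pick$rsq, pick$fit_table$fit[pick$fit_table$beta == pick$beta])
  expect_true(all(pick$fit_table$fit <= 1, na.rm = TRUE))
  # when no candidate crosses the target, fall back to the maximal fit
  got_warning <- FALSE
  pick2 <- withCallingHandlers(
    pick_soft_threshold(lexpr, network_config(rsq_target = 0.999)),
    warning = function(w) {
      got_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  expect_true(got_warning)
  ft <- pick2$fit_table
  expect_equal(pick2$rsq, max(ft$fit, na.rm = TRUE))
  # two-gene network: the degree distribution cannot be binned
  expect_error(suppressWarnings(
    pick_soft_threshold(lexpr[1:2, ])), "undefined|bins")
})

test_that("topological overlap matches hand values and the triple loop", {
  a2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("g1", "g2"), c("g1", "g2")))
  t2 <- topological_overlap(a2)
  expect_equal(t2["g1", "g2"], 0.4)
  expect_equal(diag(t2), c(g1 = 1, g2 = 1))

  a3 <- matrix(1, 3, 3) - diag(3)
  dimnames(a3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_true(all(abs(topological_overlap(a3)[upper.tri(a3)] - 1) < 1e-12))

  z <- matrix(0, 3, 3, dimnames = dimnames(a3))
  expect_true(all(topological_overlap(z)[upper.tri(z)] == 0))

  bad <- a3; bad[1, 2] <- 0.2
  expect_error(topological_overlap(bad), "symmetric")

  set.seed(29)
  for (i in 1:5) {
    a <- matrix(stats::runif(900), 30)
    a <- (a + t(a)) / 2; diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:30), paste0("g", 1:30))
    tom <- topological_overlap(a)
    expect_lt(max(abs(tom - oracle_tom(a))), 1e-10)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("module detection recovers planted TOM blocks exactly", {
  set.seed(37)
  g <- 120
  tom <- matrix(0, g, g)
  tom[1:60, 1:60] <- 0.6
  tom[61:120, 61:120] <- 0.6
  tom <- tom + matrix(stats::runif(g * g, 0, 0.01), g)
  tom <- (tom + t(tom)) / 2; diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:g), paste0("g", 1:g))
  mods <- detect_modules(tom, network_config())
  expect_length(mods$modules, 2)
  truth <- rep(c(1, 2), each = 60)
  expect_equal(mclust::adjustedRandIndex(mods$assignment, truth), 1)
  # assigned modules partition the assigned genes
  all_assigned <- unlist(mods$modules)
  expect_false(any(duplicated(all_assigned)))
  expect_setequal(c(all_assigned, mods$unassigned), rownames(tom))
  # impossible module size: everything unassigned, with a warning
  expect_warning(
    none <- detect_modules(tom, network_config(min_module_size = 500)),
    "min_module_size")
  expect_length(none$modules, 0)
  expect_length(none$unassigned, g)
})

test_that("module eigengene is the leading standardized component", {
  set.seed(43)
  profile <- stats::rnorm(12)
  expr <- outer(stats::runif(8, 0.5, 2), profile) +
    matrix(stats::rnorm(96, 0, 1e-6), 8)
  dimnames(expr) <- list(paste0("g", 1:8), paste0("s", 1:12))
  eg <- module_eigengene(expr)
  zp <- scale(profile)[, 1]; zp <- zp / sqrt(sum(zp^2))
  expect_equal(abs(stats::cor(eg$eigengene, zp)), 1, tolerance = 1e-6)
  expect_equal(eg$var_explained, 1, tolerance = 1e-6)
  expect_equal(sqrt(sum(eg$eigengene^2)), 1)
  # sign convention: mean correlation with member genes is positive
  expect_gte(mean(stats::cor(t(expr), eg$eigengene)), 0)

  expr2 <- rbind(expr, g9 = rep(3, 12))
  expect_warning(eg2 <- module_eigengene(expr2), "zero-variance")
  expect_equal(eg2$n_genes_used, 8)
  expect_error(module_eigengene(expr[1, , drop = FALSE]), ">= 2")
})

test_that("eigengene merging collapses duplicated modules and only those", {
  set.seed(47)
  s <- 20
  latent1 <- stats::rnorm(s)
  latent2 <- stats::rnorm(s)
  mk <- function(latent, n, noise) {
    t(sapply(seq_len(n), function(i)
      stats::runif(1, 0.8, 1.2) * latent + stats::rnorm(s, 0, noise)))
  }
  lexpr <- rbind(mk(latent1, 10, 0.05), mk(latent1, 10, 0.05),
                 mk(latent2, 10, 0.05))
  dimnames(lexpr) <- list(paste0("g", 1:30), paste0("s", 1:s))
  mods <- structure(list(
    modules = list(M1 = paste0("g", 1:10), M2 = paste0("g", 11:20),
                   M3 = paste0("g", 21:30)),
    assignment = stats::setNames(rep(c("M1", "M2", "M3"), each = 10),
                                 paste0("g", 1:30)),
    unassigned = character(0)), class = "module_set")
  merged <- merge_close_modules(mods, lexpr, network_config())
  expect_length(merged$modules, 2)
  expect_lte(length(merged$modules), length(mods$modules))
  sizes <- sort(vapply(merged$modules, length, integer(1)))
  expect_equal(unname(sizes), c(10L, 20L))
  # the two copies of latent1 ended up together
  a <- merged$assignment
  expect_equal(length(unique(a[paste0("g", 1:20)])), 1L)
  expect_false(unique(a[paste0("g", 1:20)]) == unique(a[paste0("g", 21:30)]))
})

test_that("module-tissue association matches the t-transform oracle", {
  s <- 24
  design <- stats::setNames(rep(c("A", "B", "C"), each = 8),
                            paste0("s", 1:s))
  ind <- as.numeric(design == "A")
  e1 <- scale(ind)[, 1]; e1 <- e1 / sqrt(sum(e1^2))
  # orthogonal-to-indicator eigengene: alternate within groups
  e2 <- rep(c(1, -1), s / 2); e2 <- e2 / sqrt(sum(e2^2))
  mods <- structure(list(
    modules = list(M1 = "gx", M2 = "gy"),
    assignment = c(gx = "M1", gy = "M2"), unassigned = character(0),
    eigengenes = matrix(c(e1, e2), ncol = 2,
                        dimnames = list(names(design), c("M1", "M2")))),
    class = "module_set")
  tt <- module_trait_association(mods, design)
  r1 <- tt[tt$module_id == "M1" & tt$tissue == "A", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_true(r1$is_tissue_specific)
  r2 <- tt[tt$module_id == "M2" & tt$tissue == "A", ]
  expect_equal(r2$r, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1, tolerance = 1e-12)
  expect_true(all(tt$r >= -1 & tt$r <= 1))
  # p agrees with the incomplete-beta form of the t CDF
  for (i in seq_len(nrow(tt))) {
    if (abs(tt$r[i]) < 1 - 1e-9)
      expect_equal(tt$p[i], oracle_cor_p(tt$r[i], s), tolerance = 1e-10)
  }
})

test_that("hub calling respects GS/MM thresholds and module scope", {
  set.seed(53)
  s <- 30
  design <- stats::setNames(rep(c("A", "B", "C"), each = 10),
                            paste0("s", 1:s))
  ind <- as.numeric(design == "A")
  lexpr <- rbind(hub1 = ind * 4 + stats::rnorm(s, 0, 0.05),
                 hub2 = ind * 3 + stats::rnorm(s, 0, 0.05),
                 noise1 = stats::rnorm(s), noise2 = stats::rnorm(s))
  colnames(lexpr) <- names(design)
  eg <- module_eigengene(lexpr[c("hub1", "hub2"), ])
  mods <- structure(list(
    modules = list(M1 = c("hub1", "hub2")),
    assignment = c(hub1 = "M1", hub2 = "M1",
                   noise1 = "grey", noise2 = "grey"),
    unassigned = c("noise1", "noise2"),
    eigengenes = matrix(eg$eigengene, ncol = 1,
                        dimnames = list(names(design), "M1"))),
    class = "module_set")
  tt <- module_trait_association(mods, design)
  hubs <- call_hub_genes(mods, lexpr, design, tt)
  expect_setequal(hubs$gene_id, c("hub1", "hub2"))
  expect_true(all(hubs$is_hub))
  expect_true(all(abs(hubs$gs) > 0.2 & abs(hubs$mm) > 0.8))
  # no tissue-specific module: empty table with warning
  tt0 <- tt; tt0$is_tissue_specific <- FALSE
  expect_warning(h0 <- call_hub_genes(mods, lexpr, design, tt0),
                 "tissue-specific")
  expect_equal(nrow(h0), 0L)
})

test_that("uncorrelated genes are almost never hubs", {
  set.seed(59)
  s <- 30
  design <- stats::setNames(rep(c("A", "B", "C"), each = 10),
                            paste0("s", 1:s))
  ind <- as.numeric(design == "A")
  eigengene <- scale(ind + stats::rnorm(s, 0, 0.1))[, 1]
  hits <- 0L
  for (i in 1:200) {
    g <- stats::rnorm(s)
    if (abs(stats::cor(g, ind)) > 0.2 && abs(stats::cor(g, eigengene)) > 0.8)
      hits <- hits + 1L
  }
  expect_lte(hits / 200, 0.05)
})

test_that("the full network stage is deterministic and internally consistent", {
  syn <- generate_synthetic_expression(
    synth_config(n_tissues = 4, n_hkg = 30, n_tsg = 40, n_modules = 2,
                 module_size = 35, n_background = 80, n_inactive = 20,
                 seed = 5))
  net1 <- suppressWarnings(build_coexpression_network(syn$matrix))
  net2 <- suppressWarnings(build_coexpression_network(syn$matrix))
  expect_identical(net1$modules$assignment, net2$modules$assignment)
  expect_identical(net1$trait_table, net2$trait_table)
  expect_identical(net1$hub_table, net2$hub_table)
  expect_true(all(net1$hub_table$gene_id %in%
                    unlist(net1$modules$modules)))
  # hub genes only come from tissue-specific modules
  ts_mods <- net1$trait_table$module_id[net1$trait_table$is_tissue_specific]
  expect_true(all(net1$hub_table$module_id %in% ts_mods))
})
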