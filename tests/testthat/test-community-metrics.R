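test_that("rarefaction drops shallow samples and subsamples exactly", {
  m <- rbind(s1 = c(60L, 40L, 0L), s2 = c(10L, 10L, 10L),
             s3 = c(100L, 25L, 25L))
  colnames(m) <- c("t1", "t2", "t3")
  ft <- feature_table(m)
  expect_message(r <- rarefy(ft, 100, seed = 1), "s2")
  expect_setequal(attr(r, "dropped_samples"), "s2")
  expect_equal(rownames(r), c("s1", "s3"))
  expect_equal(unname(r["s1", ]), c(60L, 40L, 0L))  # depth == row sum
  expect_true(all(rowSums(r) == 100))
  expect_error(rarefy(ft, 0), "depth")
})

test_that("rarefied counts never exceed the originals (property)", {
  for (seed in 1:5) {
    ft <- tiny_table(seed, n_samples = 5, n_taxa = 12, lambda = 30)
    depth <- min(rowSums(ft)) - 5L
    r <- rarefy(ft, depth, seed = seed)
    expect_true(all(unclass(r) <= unclass(ft)[rownames(r), ]))
    expect_true(all(rowSums(r) == depth))
    expect_identical(unclass(rarefy(ft, depth, seed = seed)), unclass(r))
  }
})

test_that("alpha diversity matches direct summation and handles edge cases", {
  m <- rbind(uniform = c(10L, 10L, 10L, 10L),
             single = c(100L, 0L, 0L, 0L),
             hand = c(1L, 2L, 3L, 0L))
  colnames(m) <- paste0("t", 1:4)
  a <- alpha_metrics(feature_table(m))
  expect_equal(a$richness, c(4L, 1L, 3L))
  expect_equal(a$pielou[1], 1)
  expect_equal(a$shannon[2], 0)
  expect_true(is.na(a$pielou[2]))
  p <- c(1, 2, 3) / 6
  expect_equal(a$shannon[3], -sum(p * log(p)))
  # cross-check against vegan on a random table
  ft <- tiny_table(7)
  expect_equal(alpha_metrics(ft)$shannon,
               unname(vegan::diversity(unclass(ft), index = "shannon")))
})

test_that("Bray-Curtis matches hand arithmetic and handles zero pairs", {
  m <- rbind(a = c(6L, 0L, 2L), b = c(2L, 2L, 0L), c = c(6L, 0L, 2L),
             d = c(0L, 5L, 0L))
  colnames(m) <- paste0("t", 1:3)
  d <- as.matrix(bray_curtis(feature_table(m)))
  expect_equal(d["a", "b"], 8 / 12)
  expect_equal(d["a", "c"], 0)          # identical rows
  expect_equal(d["c", "d"], 1)          # disjoint supports
  z <- rbind(a = c(0L, 0L), b = c(0L, 0L), c = c(1L, 1L))
  colnames(z) <- c("t1", "t2")
  expect_warning(dz <- bray_curtis(feature_table(z)), "all-zero|All-zero")
  expect_equal(as.matrix(dz)["a", "b"], 0)
})

test_that("weighted UniFrac reproduces branch-by-branch hand computation", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  m <- rbind(s1 = c(10L, 0L, 0L), s2 = c(0L, 0L, 7L), s3 = c(10L, 0L, 0L))
  colnames(m) <- c("A", "B", "C")
  d <- as.matrix(weighted_unifrac(feature_table(m), tree))
  expect_equal(d["s1", "s2"], 4)        # path A -> C: 1 + 1 + 2
  expect_equal(d["s1", "s3"], 0)        # identical samples
  bad <- m
  colnames(bad) <- c("A", "B", "Z")
  expect_error(weighted_unifrac(feature_table(bad), tree), "Z")
})

test_that("raw weighted UniFrac on a unit star tree is L1 on proportions", {
  n_taxa <- 6
  star <- ape::stree(n_taxa, type = "star", tip.label = paste0("t", 1:n_taxa))
  star$edge.length <- rep(1, nrow(star$edge))
  ft <- tiny_table(3, n_samples = 4, n_taxa = n_taxa)
  colnames(ft) <- paste0("t", 1:n_taxa)
  d <- as.matrix(weighted_unifrac(feature_table(unclass(ft)), star))
  p <- unclass(ft) / rowSums(ft)
  l1 <- as.matrix(stats::dist(p, method = "manhattan"))
  expect_equal(d, l1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("weighted UniFrac agrees with an independent implementation and is metric-valid", {
  skip_if_not_installed("phyloseq")
  for (seed in 1:3) {
    ft <- tiny_table(seed, n_samples = 5, n_taxa = 8, lambda = 15)
    tree <- gen_tree(colnames(ft), seed = seed + 50)
    for (norm in c(TRUE, FALSE)) {
      ours <- as.matrix(weighted_unifrac(feature_table(unclass(ft)), tree,
                                         normalized = norm))
      ph <- as.matrix(phyloseq::UniFrac(
        phyloseq::phyloseq(phyloseq::otu_table(unclass(ft),
                                               taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tree)),
        weighted = TRUE, normalized = norm))
      expect_equal(ours, ph[rownames(ours), colnames(ours)],
                   tolerance = 1e-10)
    }
    # symmetry, zero diagonal, triangle inequality
    d <- as.matrix(weighted_unifrac(feature_table(unclass(ft)), tree))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("beta-dispersion equals direct geometry on Euclidean input", {
  pts <- cbind(c(0, 1, 2, 5, 6, 7, 6), c(0, 0, 1, 2, 3, 3, 2))
  rownames(pts) <- paste0("s", 1:7)
  grp <- c("g1", "g1", "g1", "g2", "g2", "g2", "g2")
  bd <- beta_dispersion(stats::dist(pts), grp)
  cent <- rbind(g1 = colMeans(pts[1:3, ]), g2 = colMeans(pts[4:7, ]))
  direct <- sqrt(rowSums((pts - cent[grp, ])^2))
  expect_equal(bd$dist_to_centroid, unname(direct), tolerance = 1e-8)
  # doubling distances doubles every distance to centroid
  bd2 <- beta_dispersion(stats::dist(pts) * 2, grp)
  expect_equal(bd2$dist_to_centroid, 2 * bd$dist_to_centroid,
               tolerance = 1e-8)
  # identical members collapse to zero
  same_m <- rbind(s1 = c(5L, 5L), s2 = c(5L, 5L),
                  s3 = c(1L, 9L), s4 = c(1L, 9L))
  colnames(same_m) <- c("t1", "t2")
  same <- feature_table(same_m)
  bd0 <- suppressWarnings(beta_dispersion(bray_curtis(same),
                                          c("a", "a", "b", "b")))
  expect_equal(bd0$dist_to_centroid, rep(0, 4), tolerance = 1e-12)
  expect_warning(beta_dispersion(stats::dist(pts), c(grp[-7], "solo")),
                 "singleton|Singleton|Skipping")
})

test_that("functional-group subsetting partitions counts and reports shares", {
  ft <- tiny_table(9, n_samples = 4, n_taxa = 10)
  tax <- tibble::tibble(taxon_id = colnames(ft),
                        order = rep(c("o1", "o2"), 5),
                        ammonia_oxidizer = c(rep(TRUE, 3), rep(FALSE, 7)),
                        diazotroph = FALSE, glomeromycota = FALSE)
  sub <- subset_functional_group(ft, tax, "ammonia_oxidizer")
  expect_equal(ncol(sub$table), 3)
  expect_equal(sub$relative_abundance$relative_abundance,
               unname(rowSums(unclass(ft)[, 1:3]) / rowSums(ft)))
  # union of flagged and unflagged sub-tables reconstitutes the parent
  anti <- unclass(ft)[, !tax$ammonia_oxidizer, drop = FALSE]
  rebuilt <- cbind(unclass(sub$table), anti)[, colnames(ft)]
  expect_identical(rebuilt, unclass(ft))
  expect_error(subset_functional_group(ft, tax, "nope"), "not defined")
  tax0 <- dplyr::mutate(tax, ammonia_oxidizer = FALSE)
  expect_warning(subset_functional_group(ft, tax0, "ammonia_oxidizer"),
                 "no taxa")
  # 10 of 1000 reads flagged -> 0.01
  one <- feature_table(matrix(c(10L, 990L), 1, 2,
                              dimnames = list("s1", c("t1", "t2"))))
  tax1 <- tibble::tibble(taxon_id = c("t1", "t2"),
                         ammonia_oxidizer = c(TRUE, FALSE),
                         diazotroph = FALSE, glomeromycota = FALSE)
  expect_equal(subset_functional_group(one, tax1, "ammonia_oxidizer")$
                 relative_abundance$relative_abundance, 0.01)
})

test_that("rank aggregation conserves totals and never raises richness", {
  ft <- tiny_table(13, n_samples = 5, n_taxa = 12)
  tax <- tibble::tibble(taxon_id = colnames(ft),
                        order = c(rep("o1", 4), rep("o2", 4),
                                  rep(NA_character_, 4)))
  agg <- aggregate_to_rank(ft, tax, "order")
  expect_setequal(colnames(agg), c("o1", "o2", "unclassified"))
  expect_equal(rowSums(agg), rowSums(ft))
  expect_identical(aggregate_to_rank(ft, tax, "asv"), ft)
  expect_true(all(alpha_metrics(agg)$richness <= alpha_metrics(ft)$richness))
  two <- feature_table(matrix(c(3L, 4L), 1, 2,
                              dimnames = list("s1", c("a", "b"))))
  tax2 <- tibble::tibble(taxon_id = c("a", "b"), order = "same")
  expect_equal(unname(unclass(aggregate_to_rank(two, tax2, "order"))[1, 1]), 7L)
})
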