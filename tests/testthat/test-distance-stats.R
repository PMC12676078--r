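test_that("Gower centering recovers the centered inner-product matrix", {
  set.seed(1)
  X <- matrix(rnorm(8 * 3), 8, 3)
  G <- gower_center(stats::dist(X))
  Xc <- scale(X, scale = FALSE)
  expect_equal(G, tcrossprod(Xc), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(G))), 1e-8 * max(abs(G)))
  expect_equal(gower_center(matrix(0, 4, 4)), matrix(0, 4, 4))
  # McArdle-Anderson identity: trace(G) = (1/n) sum_{i<j} d^2
  for (seed in 1:4) {
    set.seed(seed)
    d <- stats::dist(matrix(rnorm(6 * 4), 6, 4))
    expect_equal(sum(diag(gower_center(d))), sum(d^2) / 6, tolerance = 1e-8)
  }
})

test_that("PCoA reconstructs Euclidean configurations and reports eigenvalues", {
  set.seed(2)
  pts <- cbind(runif(7), runif(7))
  d <- stats::dist(pts)
  p <- rhizoadapt::pcoa(d)
  expect_equal(as.matrix(stats::dist(p$coordinates)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(p$values), sum(diag(gower_center(d))), tolerance = 1e-8)
  # duplicate samples land on coincident coordinates
  pts2 <- rbind(pts, pts[1, ])
  p2 <- rhizoadapt::pcoa(stats::dist(pts2))
  expect_equal(p2$coordinates[8, ], p2$coordinates[1, ], tolerance = 1e-8)
})

test_that("PERMANOVA pseudo-F equals the classical one-way ANOVA F", {
  set.seed(3)
  y <- rnorm(18)
  g <- rep(letters[1:3], each = 6)
  pa <- permanova(stats::dist(y), data.frame(genotype = g), "genotype",
                  n_perm = 99, seed = 1)
  f_aov <- stats::anova(stats::lm(y ~ g))[["F value"]][1]
  expect_equal(pa$statistic[1], f_aov, tolerance = 1e-8)
  expect_equal(sum(pa$R2[1:2]), 1, tolerance = 1e-8)
  expect_equal(sum(pa$df[1:2]), 17)
})

test_that("PERMANOVA permutation p matches exhaustive enumeration at n = 6", {
  set.seed(4)
  y <- c(rnorm(3), rnorm(3, 2))
  g <- rep(c("a", "b"), each = 3)
  d <- stats::dist(y)
  perms <- do.call(rbind, combinat_perms(6))
  pa <- permanova(d, data.frame(genotype = g), "genotype",
                  permutations = perms)
  # independent oracle: classical F recomputed for every relabeling of y
  f_of <- function(yy) stats::anova(stats::lm(yy ~ g))[["F value"]][1]
  f_obs <- f_of(y)
  f_all <- apply(perms, 1, function(p) f_of(y[p]))
  p_exact <- (1 + sum(f_all >= f_obs - 1e-12)) / (1 + nrow(perms))
  expect_equal(pa$p_value[1], p_exact, tolerance = 1e-12)
})

test_that("PERMANOVA agrees with adonis2 and is invariant to reordering", {
  ft <- tiny_table(5, n_samples = 12, n_taxa = 20, lambda = 12)
  meta <- data.frame(genotype = rep(letters[1:4], 3),
                     block = rep(LETTERS[1:3], each = 4))
  d <- bray_curtis(ft)
  pa <- permanova(d, meta, c("genotype", "block"), n_perm = 99, seed = 1)
  ad <- vegan::adonis2(d ~ genotype + block, data = meta,
                       permutations = 99, by = "terms")
  expect_equal(pa$R2[1:2], ad$R2[1:2], tolerance = 1e-8)
  expect_equal(pa$statistic[1:2], ad$F[1:2], tolerance = 1e-8)
  # consistent sample reordering leaves R2 unchanged
  ord <- sample(12)
  d2 <- stats::as.dist(as.matrix(d)[ord, ord])
  pa2 <- permanova(d2, meta[ord, ], c("genotype", "block"),
                   n_perm = 99, seed = 1)
  expect_equal(pa2$R2, pa$R2, tolerance = 1e-8)
  # aliased term errors with its name
  meta$dup <- meta$genotype
  expect_error(permanova(d, meta, c("genotype", "dup"), n_perm = 99),
               "dup")
})

test_that("dbMEM bases are orthonormal, match pcnm, and track transects", {
  x1 <- seq(0, 10, length.out = 16)
  d <- stats::dist(cbind(x1, 0))
  mb <- dbmem(d)
  expect_true(all(mb$values > 0))
  expect_equal(crossprod(mb$vectors), diag(ncol(mb$vectors)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(abs(cor(mb$vectors[, 1], x1)), 0.8)
  pc <- vegan::pcnm(d)
  expect_equal(abs(cor(mb$vectors[, 1], pc$vectors[, 1])), 1,
               tolerance = 1e-8)
  expect_equal(ncol(mb$vectors), ncol(pc$vectors))
  mb_broad <- dbmem(d, keep = "broad")
  expect_lt(ncol(mb_broad$vectors), ncol(mb$vectors))
  expect_error(dbmem(stats::dist(matrix(1, 5, 2))), "coincident")
})

test_that("SSR Hamming distance is the mismatch share over non-missing loci", {
  ssr <- tibble::tibble(genotype = c("g1", "g2", "g3"),
                        l1 = c(1L, 1L, 2L),
                        l2 = c(2L, 3L, NA),
                        l3 = c(1L, 2L, 1L),
                        l4 = c(4L, 4L, 4L))
  h <- as.matrix(hamming_distance(ssr))
  expect_equal(h["g1", "g2"], 2 / 4)
  expect_equal(h["g1", "g3"], 1 / 3)  # l2 missing for g3
  expect_equal(h, t(h))
})

test_that("dbRDA equals direct multivariate regression on Euclidean input", {
  set.seed(6)
  Y <- matrix(rnorm(15 * 4), 15, 4)
  X <- data.frame(a = rnorm(15), b = rnorm(15))
  fit <- rhizoadapt::dbrda(stats::dist(Y), X)
  Yc <- scale(Y, scale = FALSE)
  Q <- qr.Q(qr(cbind(1, scale(as.matrix(X)))))
  r2 <- sum((tcrossprod(Q) %*% Yc)^2) / sum(Yc^2)
  expect_equal(fit$constrained / fit$total, r2, tolerance = 1e-8)
  # predictor orthogonal to the data explains ~nothing
  X0 <- data.frame(z = rep(c(-1, 1), length.out = 15))
  Yb <- Yc - tcrossprod(scale(X0$z) / sqrt(sum(scale(X0$z)^2))) %*% Yc
  fit0 <- rhizoadapt::dbrda(stats::dist(Yb), X0)
  expect_lt(fit0$constrained / fit0$total, 1e-8)
})

test_that("conditioned dbRDA decomposes inertia and matches capscale", {
  set.seed(7)
  Y <- matrix(rnorm(18 * 5), 18, 5)
  X <- data.frame(a = rnorm(18), b = rnorm(18))
  cond <- matrix(rnorm(18 * 2), 18, 2)
  fit <- rhizoadapt::dbrda(stats::dist(Y), X, condition = cond)
  expect_equal(fit$conditioned + fit$constrained + fit$unconstrained,
               fit$total, tolerance = 1e-8)
  vf <- vegan::capscale(stats::dist(Y) ~ a + b + Condition(cond), data = X)
  # capscale reports inertia scaled by 1/(n-1)
  expect_equal(fit$conditioned / 17, vf$pCCA$tot.chi, tolerance = 1e-6)
  expect_equal(fit$constrained / 17, vf$CCA$tot.chi, tolerance = 1e-6)
  # predictor duplicated in the condition is dropped with a warning
  expect_warning(rhizoadapt::dbrda(stats::dist(Y),
                                   data.frame(a = cond[, 1]),
                                   condition = cond),
                 "collinear")
})

test_that("over-conditioning on the response's own full MEM-like basis
           leaves no constrained inertia", {
  set.seed(8)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  d <- stats::dist(Y)
  full_basis <- rhizoadapt::pcoa(d)$vectors[, 1:11]
  fit <- rhizoadapt::dbrda(d, data.frame(x = rnorm(12)),
                           condition = full_basis)
  expect_lt(fit$constrained / fit$total, 1e-8)
})

test_that("forward selection honors alpha limits and the seed", {
  set.seed(9)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  d <- stats::dist(Y)
  cand <- data.frame(x1 = rnorm(20), x2 = rnorm(20), x3 = rnorm(20))
  all_in <- forward_select(d, cand, alpha = 1, n_perm = 99, seed = 1)
  expect_setequal(all_in$selected, names(cand))
  none <- forward_select(d, cand, alpha = 1e-6, n_perm = 99, seed = 1)
  expect_length(none$selected, 0)
  s1 <- forward_select(d, cand, alpha = 0.5, n_perm = 99, seed = 2)
  s2 <- forward_select(d, cand, alpha = 0.5, n_perm = 99, seed = 2)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$steps, s2$steps)
})

test_that("genotype-level matrices expand to samples by membership", {
  pan <- gen_panel(5, seed = 51)
  ssr <- gen_ssr(pan, seed = 52)
  meta <- tibble::tibble(sample_id = paste0("s", 1:10),
                         genotype = rep(pan$genotype, 2))
  cb <- condition_basis(pan, ssr, meta)
  expect_equal(nrow(cb), 10)
  mem <- dbmem(geographic_distance(pan))
  ex <- expand_to_samples(mem, meta$genotype)
  expect_equal(ex[1, ], ex[6, ])  # same genotype, same row
  expect_error(expand_to_samples(mem, c("G01", "nope")), "missing")
})
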