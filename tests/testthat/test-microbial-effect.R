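test_that("the microbial effect is the (live - sterile)/sterile ratio", {
  tt <- tibble::tibble(
    genotype = rep("G1", 8),
    nitrogen = rep(c("low", "high"), each = 4),
    microbe = rep(c("live", "live", "sterile", "sterile"), 2),
    height = c(12, 12, 10, 10, 15, 15, 15, 15))
  est <- compute_microbial_effect(tt, "height")
  expect_equal(est$me[est$glasshouse_n == "low"], 0.2)
  expect_equal(est$me[est$glasshouse_n == "high"], 0)  # equal means
  # scale invariance
  tt2 <- dplyr::mutate(tt, height = height * 3.7)
  expect_equal(compute_microbial_effect(tt2, "height")$me, est$me)
})

test_that("thin cells are dropped and me >= -1 whenever live means are valid", {
  pan <- gen_panel(40, seed = 81)
  tt <- gen_experiment2_traits(pan, seed = 82)
  # remove all but one live plant in one genotype x nitrogen cell
  cell <- tt$genotype == tt$genotype[1] & tt$nitrogen == "low" &
    tt$microbe == "live"
  tt_thin <- tt[!(cell & seq_len(nrow(tt)) != which(cell)[1]), ]
  expect_warning(est <- compute_microbial_effect(tt_thin, "height"),
                 "replicates")
  expect_false(any(est$genotype == tt$genotype[1] &
                     est$glasshouse_n == "low"))
  est_all <- compute_microbial_effect(tt, "height")
  expect_true(all(est_all$me >= -1))
})

test_that("delta-method propagation matches hand arithmetic", {
  est <- fake_me_estimates(12, 10, 0.5, 0.4)
  out <- propagate_me_uncertainty(est, method = "delta")
  expect_equal(out$me_se, sqrt(0.25 / 100 + 144 * 0.16 / 1e4),
               tolerance = 1e-12)
  expect_equal(out$me_se, 0.0693, tolerance = 1e-3)
})

test_that("zero cell SEs propagate to zero me_se under both methods", {
  est <- fake_me_estimates(c(12, 9), c(10, 10), c(0, 0), c(0, 0))
  expect_equal(propagate_me_uncertainty(est, "delta")$me_se, c(0, 0))
  expect_equal(propagate_me_uncertainty(est, "montecarlo", seed = 1)$me_se,
               c(0, 0))
})

test_that("delta and Monte-Carlo SEs agree within 5% at small CVs", {
  withr::with_seed(42, {
    k <- 100
    sterile <- runif(k, 5, 50)
    live <- sterile * runif(k, 0.8, 1.4)
    est <- fake_me_estimates(live, sterile,
                             live_se = live * runif(k, 0.02, 0.10),
                             sterile_se = sterile * runif(k, 0.02, 0.10))
  })
  d <- propagate_me_uncertainty(est, "delta")$me_se
  m <- propagate_me_uncertainty(est, "montecarlo", n_draws = 20000,
                                seed = 2)$me_se
  expect_lt(max(abs(m - d) / d), 0.05)
})

test_that("a large sterile-mean CV triggers the heavy-tail warning", {
  est <- fake_me_estimates(12, 10, 0.5, 4)
  expect_warning(propagate_me_uncertainty(est, "delta"), "heavy-tailed")
})

test_that("reaction norms are ordinary least squares on the predictor", {
  est <- fake_me_estimates(c(10, 20, 30), c(10, 10, 10), rep(0.1, 3),
                           rep(0.1, 3))
  # me = 0, 1, 2 against x = 0, 1, 2 -> slope 1, intercept 0
  x <- setNames(c(0, 1, 2), est$genotype)
  rn <- fit_reaction_norm(est, x)
  expect_equal(rn$slope, 1, tolerance = 1e-12)
  expect_equal(rn$intercept, 0, tolerance = 1e-12)
  expect_error(fit_reaction_norm(est, setNames(c(1, 1, 1), est$genotype)),
               "Constant")
  # permuted x has a null-centered slope
  pan <- gen_panel(40, seed = 83)
  slopes <- vapply(1:20, function(i) {
    tt <- gen_experiment2_traits(pan, seed = 840 + i)
    est_i <- compute_microbial_effect(tt, "height")
    low <- est_i[est_i$glasshouse_n == "low", ]
    set.seed(850 + i)
    xp <- setNames(sample(pan$soil_nitrogen_z, nrow(low)), low$genotype)
    fit_reaction_norm(low, xp)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("reaction norms recover the generator slope within 2 SE", {
  pan <- gen_panel(40, seed = 85)
  hits_low <- hits_high <- 0
  n_sim <- 50
  for (i in seq_len(n_sim)) {
    tt <- gen_experiment2_traits(pan, seed = 860 + i)
    est <- compute_microbial_effect(tt, "height")
    x <- setNames(pan$soil_nitrogen_z, pan$genotype)[unique(est$genotype)]
    rn_l <- fit_reaction_norm(est[est$glasshouse_n == "low", ], x)
    rn_h <- fit_reaction_norm(est[est$glasshouse_n == "high", ], x)
    hits_low <- hits_low + (abs(rn_l$slope - (-0.15)) <= 2 * rn_l$se_slope)
    hits_high <- hits_high + (abs(rn_h$slope - 0.15) <= 2 * rn_h$se_slope)
  }
  expect_gte(hits_low / n_sim, 0.85)
  expect_gte(hits_high / n_sim, 0.85)
})

test_that("certain slope differences attain the minimum p-value", {
  est <- dplyr::bind_rows(
    fake_me_estimates(c(10, 20, 30, 25), c(10, 10, 10, 10), 0, 0, "low"),
    fake_me_estimates(c(30, 20, 10, 15), c(10, 10, 10, 10), 0, 0, "high"))
  est$me_se <- 0
  x <- setNames(c(0, 1, 2, 3), unique(est$genotype))
  sc <- slope_difference_test(est, x, n_sim = 1999, seed = 1)
  expect_equal(sc$p_value, 2 / 2000)
})

test_that("the slope-difference p decreases with the planted difference", {
  pan <- gen_panel(40, seed = 87)
  hist_n <- setNames(pan$soil_nitrogen_z, pan$genotype)
  mean_p <- vapply(c(0, 0.08, 0.25), function(delta) {
    spec <- trait_effect_spec(me_slope_low = -delta / 2,
                              me_slope_high = delta / 2)
    mean(vapply(1:12, function(i) {
      tt <- gen_experiment2_traits(pan, spec, seed = 880 + i)
      est <- propagate_me_uncertainty(compute_microbial_effect(tt, "height"),
                                      "montecarlo", n_draws = 1000,
                                      seed = 890 + i)
      slope_difference_test(est, hist_n, n_sim = 1000, seed = 895 + i)$p_value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_p) < 0))
})

test_that("slope tests are reproducible and demand shared genotypes", {
  pan <- gen_panel(40, seed = 89)
  tt <- gen_experiment2_traits(pan, seed = 90)
  est <- propagate_me_uncertainty(compute_microbial_effect(tt, "height"),
                                  "montecarlo", seed = 1)
  x <- setNames(pan$soil_nitrogen_z, pan$genotype)
  s1 <- slope_difference_test(est, x, n_sim = 1000, seed = 7)
  s2 <- slope_difference_test(est, x, n_sim = 1000, seed = 7)
  expect_equal(s1$p_value, s2$p_value)
  expect_equal(s1$delta, s2$delta)
  few <- est[est$genotype %in% unique(est$genotype)[1:2], ]
  expect_error(slope_difference_test(few, x, n_sim = 1000), "3 genotypes")
})

test_that("microbiome traits act as genotype-level predictors", {
  pan <- gen_panel(40, seed = 91)
  tt <- gen_experiment2_traits(pan, seed = 92)
  est <- propagate_me_uncertainty(compute_microbial_effect(tt, "height"),
                                  "montecarlo", seed = 1)
  genos <- unique(est$genotype)
  # richness proxy decreasing in soil N, as the community generator plants
  z <- setNames(pan$soil_nitrogen_z, pan$genotype)[genos]
  rich <- 25 + (12 - 25) * (z - min(z)) / diff(range(z)) +
    withr::with_seed(93, rnorm(length(z), 0, 0.8))
  sc <- me_vs_microbiome(est, setNames(rich, genos), n_sim = 1000, seed = 2,
                         predictor = "diazotroph_richness")
  # planted: ME decreases with soil N under low N; richness decreases with
  # soil N; so ME rises with richness under low N and falls under high N
  expect_gt(sc$slope_low, 0)
  expect_lt(sc$slope_high, 0)
  # affine rescaling of x rescales slopes and leaves p unchanged
  sc2 <- me_vs_microbiome(est, setNames(3 + 2 * rich, genos), n_sim = 1000,
                          seed = 2, predictor = "rescaled")
  expect_equal(sc2$slope_low, sc$slope_low / 2, tolerance = 1e-10)
  expect_equal(sc2$p_value, sc$p_value)
  expect_error(me_vs_microbiome(est, setNames(rich[-1], genos[-1]),
                                n_sim = 1000), "missing")
  expect_error(me_vs_microbiome(est, setNames(rep(1, length(genos)), genos),
                                n_sim = 1000), "Constant")
})
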