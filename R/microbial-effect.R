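as_genotype_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else if (!is.null(names(x))) {
    x
  } else {
    abort("Predictor must be a named vector or a (genotype, value) table.")
  }
}

#' Per-genotype microbial effect on a plant trait
#'
#' The microbial effect is the response ratio
#' `ME = (live_mean - sterile_mean) / sterile_mean`, computed from raw
#' genotype cell means within each glasshouse nitrogen level. ME > 0
#' means the live inoculum increased the trait; ME >= -1 whenever the
#' live mean is non-negative. Cells with fewer than `min_reps` live or
#' sterile plants are dropped with a warning; a sterile mean <= 0 flags
#' the estimate unusable.
#'
#' @param traits A trait table with `genotype`, `nitrogen`, `microbe`
#'   and the trait column.
#' @param trait Trait column name (`"height"` or `"biomass"`).
#' @param min_reps Minimum live and sterile replicates per cell.
#' @return A tibble of class `me_estimates`: one row per genotype x
#'   glasshouse nitrogen level with cell means, standard errors of the
#'   means, replicate counts, `me` and `usable`.
#' @export
compute_microbial_effect <- function(traits, trait = "height",
                                     min_reps = 2L) {
  check_columns(traits, c("genotype", "nitrogen", "microbe", trait),
                "Trait table")
  cells <- traits |>
    dplyr::group_by(.data$genotype, .data$nitrogen, .data$microbe) |>
    dplyr::summarise(mean = mean(.data[[trait]]),
                     se = sd(.data[[trait]]) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "microbe",
                       values_from = c("mean", "se", "n"))
  for (col in c("mean_live", "mean_sterile", "se_live", "se_sterile",
                "n_live", "n_sterile")) {
    if (!col %in% names(cells)) cells[[col]] <- NA_real_
  }
  short <- is.na(cells$n_live) | is.na(cells$n_sterile) |
    cells$n_live < min_reps | cells$n_sterile < min_reps
  if (any(short)) {
    warn(sprintf("Dropping %d genotype x nitrogen cell(s) with < %d live or sterile replicates.",
                 sum(short), min_reps))
    cells <- cells[!short, ]
  }
  out <- tibble::tibble(
    genotype = cells$genotype,
    glasshouse_n = cells$nitrogen,
    trait = trait,
    live_mean = cells$mean_live, sterile_mean = cells$mean_sterile,
    live_se = cells$se_live, sterile_se = cells$se_sterile,
    n_live = cells$n_live, n_sterile = cells$n_sterile,
    me = (cells$mean_live - cells$mean_sterile) / cells$mean_sterile,
    usable = cells$mean_sterile > 0)
  if (any(!out$usable)) {
    warn(sprintf("Sterile mean <= 0 for %d estimate(s); flagged unusable.",
                 sum(!out$usable)))
  }
  class(out) <- c("me_estimates", class(out))
  out
}

#' Propagate uncertainty from cell means to the microbial effect
#'
#' Adds a standard error `me_se` to each estimate. The Monte-Carlo
#' method (default; more faithful for a ratio) draws cell means from
#' normal(mean, se), redrawing sterile means below `0.05 x sterile_mean`,
#' and takes the SD of the simulated ratios. The delta method uses
#' `Var(ME) = Var(L)/S^2 + L^2 Var(S)/S^4` assuming independent cell
#' means. A sterile-mean coefficient of variation above 0.33 triggers a
#' heavy-tail warning.
#'
#' @param estimates A [compute_microbial_effect()] tibble.
#' @param method `"montecarlo"` or `"delta"`.
#' @param n_draws Monte-Carlo draws per estimate (>= 1000).
#' @param seed Integer seed.
#' @return The estimates with an added `me_se` column.
#' @export
propagate_me_uncertainty <- function(estimates,
                                     method = c("montecarlo", "delta"),
                                     n_draws = 2000, seed = NULL) {
  method <- match.arg(method)
  cv <- estimates$sterile_se / estimates$sterile_mean
  if (any(cv > 0.33, na.rm = TRUE)) {
    warn("Sterile-mean CV > 0.33 for some estimates; the ratio distribution is heavy-tailed.")
  }
  if (method == "delta") {
    v <- estimates$live_se^2 / estimates$sterile_mean^2 +
      estimates$live_mean^2 * estimates$sterile_se^2 / estimates$sterile_mean^4
    estimates$me_se <- sqrt(v)
    return(estimates)
  }
  if (n_draws < 1000) abort("Monte-Carlo propagation needs n_draws >= 1000.")
  estimates$me_se <- local_seed_eval(seed, vapply(seq_len(nrow(estimates)), function(i) {
    L <- rnorm(n_draws, estimates$live_mean[i], estimates$live_se[i])
    S <- rnorm(n_draws, estimates$sterile_mean[i], estimates$sterile_se[i])
    floor_s <- 0.05 * estimates$sterile_mean[i]
    for (tries in 1:100) {
      bad <- S <= floor_s
      if (!any(bad)) break
      S[bad] <- rnorm(sum(bad), estimates$sterile_mean[i],
                      estimates$sterile_se[i])
    }
    S[S <= floor_s] <- floor_s
    sd((L - S) / S)
  }, numeric(1)))
  estimates
}

#' Ordinary least-squares reaction norm of the microbial effect
#'
#' Fits `me ~ x` across genotypes within one glasshouse nitrogen level.
#' Unweighted by default (matching ordinary fitted lines);
#' `weighted = TRUE` uses inverse-variance weights from `me_se`.
#'
#' @param estimates `me_estimates` rows for a single glasshouse level
#'   (usable only).
#' @param x Per-genotype predictor: named vector or (genotype, value)
#'   table. Panel environment predictors are already standardized
#'   (`soil_nitrogen_z`); set `standardize = TRUE` to z-score a raw
#'   predictor.
#' @param weighted Inverse-variance weighting (needs `me_se`).
#' @param standardize Z-score `x` before fitting.
#' @return A list of class `reaction_norm`: `slope`, `intercept`,
#'   `se_slope`, `n`.
#' @export
fit_reaction_norm <- function(estimates, x, weighted = FALSE,
                              standardize = FALSE) {
  xv <- as_genotype_vector(x)
  est <- estimates[estimates$usable %||% TRUE, ]
  est <- est[est$genotype %in% names(xv), ]
  if (nrow(est) < 3) abort("Need >= 3 genotypes with usable estimates.")
  if (length(unique(est$glasshouse_n)) > 1) {
    abort("Fit one glasshouse nitrogen level at a time.")
  }
  xi <- xv[est$genotype]
  if (sd(xi) == 0) abort("Constant predictor.")
  if (standardize) xi <- zscore(xi)
  w <- if (weighted) 1 / pmax(est$me_se, 1e-8)^2 else rep(1, nrow(est))
  fit <- stats::lm(est$me ~ xi, weights = w)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 se_slope = sm$coefficients[2, 2],
                 n = nrow(est)),
            class = "reaction_norm")
}

# Closed-form OLS slope weights for x (slope = w %*% y).
slope_weights <- function(x) {
  xc <- x - mean(x)
  xc / sum(xc^2)
}

#' Simulation-based comparison of reaction-norm slopes between nitrogen
#' environments
#'
#' Parametric bootstrap of the slope difference: each genotype's
#' microbial effect is perturbed as `me* ~ normal(me, me_se)`
#' independently in both glasshouse nitrogen environments, both reaction
#' norms are refit, and `delta* = slope_high* - slope_low*` is recorded.
#' The two-sided p-value is `2 min(Pr(delta* <= 0), Pr(delta* >= 0))`
#' with the `(1 + b) / (1 + n_sim)` convention, capped at 1.
#'
#' @param estimates `me_estimates` with `me_se` (both glasshouse levels).
#' @param x Per-genotype predictor (named vector or table); see
#'   [fit_reaction_norm()].
#' @param n_sim Number of simulations (>= 1000).
#' @param seed Integer seed.
#' @param predictor Label stored on the result.
#' @return An object of class `slope_comparison`: observed `slope_low`,
#'   `slope_high` (with simulation SEs), `delta`, `p_value`, `n_sim`,
#'   quantiles of the simulated delta, and the genotype set used.
#' @export
slope_difference_test <- function(estimates, x, n_sim = 2000, seed = NULL,
                                  predictor = "historic_soil_n") {
  if (n_sim < 1000) abort("Use n_sim >= 1000.")
  if (!"me_se" %in% names(estimates)) {
    abort("Run propagate_me_uncertainty() first (me_se required).")
  }
  xv <- as_genotype_vector(x)
  est <- estimates[(estimates$usable %||% TRUE) &
                     estimates$genotype %in% names(xv), ]
  low <- est[est$glasshouse_n == "low", ]
  high <- est[est$glasshouse_n == "high", ]
  shared <- intersect(low$genotype, high$genotype)
  if (length(shared) < 3) abort("Fewer than 3 genotypes shared between environments.")
  low <- low[match(shared, low$genotype), ]
  high <- high[match(shared, high$genotype), ]
  xi <- xv[shared]
  if (sd(xi) == 0) abort("Constant predictor.")
  w <- slope_weights(xi)

  slope_low <- sum(w * low$me)
  slope_high <- sum(w * high$me)
  delta_obs <- slope_high - slope_low

  sims <- local_seed_eval(seed, {
    g <- length(shared)
    draw_low <- matrix(rnorm(n_sim * g, rep(low$me, each = n_sim),
                             rep(low$me_se, each = n_sim)), n_sim, g)
    draw_high <- matrix(rnorm(n_sim * g, rep(high$me, each = n_sim),
                              rep(high$me_se, each = n_sim)), n_sim, g)
    cbind(low = drop(draw_low %*% w), high = drop(draw_high %*% w))
  })
  delta_sim <- sims[, "high"] - sims[, "low"]
  p_le <- (1 + sum(delta_sim <= 0)) / (1 + n_sim)
  p_ge <- (1 + sum(delta_sim >= 0)) / (1 + n_sim)
  p <- min(1, 2 * min(p_le, p_ge))

  structure(list(predictor = predictor,
                 slope_low = slope_low, slope_high = slope_high,
                 se_low = sd(sims[, "low"]), se_high = sd(sims[, "high"]),
                 delta = delta_obs, p_value = p, n_sim = n_sim,
                 sim_quantiles = quantile(delta_sim,
                                          c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 genotypes = shared, x = xi,
                 estimates = dplyr::bind_rows(low, high)),
            class = "slope_comparison")
}

#' Microbial effect against a microbiome trait of the genotype
#'
#' Treats a community characteristic measured in the common-garden
#' experiment (e.g. per-genotype diazotroph richness or ammonia-oxidizer
#' relative abundance) as a conserved genotype trait and runs the same
#' slope-difference machinery with it as the predictor.
#'
#' @param estimates `me_estimates` with `me_se`.
#' @param microbiome_trait Per-genotype value (named vector or table);
#'   must be available, and non-constant, for every genotype used.
#' @param predictor Label stored on the result.
#' @inheritParams slope_difference_test
#' @return A `slope_comparison`.
#' @export
me_vs_microbiome <- function(estimates, microbiome_trait, n_sim = 2000,
                             seed = NULL, predictor = "microbiome_trait") {
  xv <- as_genotype_vector(microbiome_trait)
  missing <- setdiff(unique(estimates$genotype), names(xv))
  if (length(missing)) {
    abort(sprintf("Microbiome trait missing for genotype(s): %s",
                  paste(missing, collapse = ", ")))
  }
  slope_difference_test(estimates, xv, n_sim = n_sim, seed = seed,
                        predictor = predictor)
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison> predictor: %s (%d genotypes, %d sims)\n",
              x$predictor, length(x$genotypes), x$n_sim))
  cat(sprintf("  slope(low N)  = %8.4f (se %.4f)\n", x$slope_low, x$se_low))
  cat(sprintf("  slope(high N) = %8.4f (se %.4f)\n", x$slope_high, x$se_high))
  cat(sprintf("  delta = %.4f, p = %.4g\n", x$delta, x$p_value))
  invisible(x)
}
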