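signif_code <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p <= 0.001 ~ "***", p <= 0.01 ~ "**",
                   p <= 0.05 ~ "*", p <= 0.1 ~ "+", TRUE ~ "")
}

trait_fixed_terms <- c("hist_n", "microbe", "glasshouse_n",
                       "hist_n:microbe", "hist_n:glasshouse_n",
                       "microbe:glasshouse_n", "hist_n:microbe:glasshouse_n")

prepare_trait_frame <- function(traits, response) {
  need <- c(response, "soil_nitrogen_z", "microbe", "nitrogen", "genotype", "block")
  check_columns(traits, need, "Trait table")
  df <- data.frame(
    y = traits[[response]],
    hist_n = zscore(traits$soil_nitrogen_z, allow_constant = TRUE),
    microbe = factor(traits$microbe, levels = c("sterile", "live")),
    glasshouse_n = factor(traits$nitrogen, levels = c("low", "high")),
    genotype = factor(traits$genotype),
    block = factor(traits$block))
  if (anyNA(df)) abort("Missing values in model columns are not allowed.")
  df
}

#' Fit the crossed nitrogen-by-microbe trait model
#'
#' Mixed model of a plant trait on the historic nitrogen environment
#' (continuous, standardized), glasshouse microbe treatment, glasshouse
#' nitrogen treatment and all their interactions, with genotype and block
#' random intercepts. Gaussian responses are fit by REML, binary
#' responses (tillering) by maximum-likelihood logistic regression. A
#' zero-variance random effect is reported through the `singular` flag
#' and retained, not dropped: replicates within a genotype are
#' pseudoreplicates and the term encodes the design regardless of its
#' estimated variance.
#'
#' @param traits A trait table (see [read_traits()] /
#'   [gen_experiment2_traits()]); historic nitrogen is taken from the
#'   `soil_nitrogen_z` column.
#' @param response Trait column name (`"height"`, `"biomass"`,
#'   `"tillering"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return An object of class `trait_model` wrapping the lme4 fit, with
#'   `singular` flag and the model frame.
#' @export
fit_trait_model <- function(traits, response,
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  df <- prepare_trait_frame(traits, response)
  if (family == "binomial" && !all(df$y %in% c(0, 1))) {
    abort("Binomial family requires a 0/1 response.")
  }
  form <- y ~ hist_n * microbe * glasshouse_n + (1 | genotype) + (1 | block)
  fit <- suppressMessages(suppressWarnings(
    if (family == "gaussian") lme4::lmer(form, df, REML = TRUE)
    else lme4::glmer(form, df, family = stats::binomial())))
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    abort(paste("Mixed-model optimizer failed:",
                paste(unlist(fit@optinfo$message), collapse = "; ")))
  }
  # Gradient-tolerance notes from lme4's convergence checker are retained
  # on the object; they are near-universal for singular null fits and do
  # not indicate optimizer failure.
  structure(list(fit = fit, family = family, response = response,
                 frame = df, singular = lme4::isSingular(fit),
                 checks = unlist(fit@optinfo$conv$lme4$messages)),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %s (%s)%s\n", x$response, x$family,
              if (x$singular) " [singular random-effect fit]" else ""))
  print(x$fit)
  invisible(x)
}

# Indices of fixed coefficients belonging to each model term.
term_assign <- function(fit) {
  X <- lme4::getME(fit, "X")
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(stats::formula(fit, fixed.only = TRUE)),
                 "term.labels")
  list(X = X, assign = asgn, labels = labels)
}

#' Per-term ANOVA table for a trait model
#'
#' Gaussian models report F statistics (sequential Type-I decomposition,
#' or marginal Wald F) with denominator degrees of freedom `n - rank(X)`:
#' no fixed term is nested in a random factor here, so the containment
#' denominator is the residual stratum. Binomial models report
#' likelihood-ratio chi-squared statistics from sequential refits
#' (`type = "sequential"`) or marginal Wald chi-squared
#' (`type = "marginal"`). Interactions always enter after their
#' lower-order terms (marginality is enforced by the fixed term order).
#'
#' @param model A [fit_trait_model()] result.
#' @param type `"sequential"` (default) or `"marginal"`.
#' @return A tibble of class `trait_anova`: `term`, `df`, `statistic`,
#'   `p_value`, `signif`, with the singular-fit flag as an attribute.
#' @export
anova_table <- function(model, type = c("sequential", "marginal")) {
  type <- match.arg(type)
  fit <- model$fit
  ta <- term_assign(fit)
  n <- nrow(ta$X)
  ddf <- n - qr(ta$X)$rank

  if (model$family == "gaussian") {
    if (type == "sequential") {
      a <- stats::anova(fit)
      out <- tibble::tibble(term = rownames(a),
                            df = a[, "npar"] %||% a[, "Df"],
                            statistic = a[, "F value"])
    } else {
      out <- purrr::map_dfr(seq_along(ta$labels), function(k) {
        idx <- which(ta$assign == k)
        b <- lme4::fixef(fit)[idx]
        V <- as.matrix(stats::vcov(fit))[idx, idx, drop = FALSE]
        tibble::tibble(term = ta$labels[k], df = length(idx),
                       statistic = drop(crossprod(b, solve(V, b))) / length(idx))
      })
    }
    out$p_value <- pf(out$statistic, out$df, ddf, lower.tail = FALSE)
  } else {
    if (type == "sequential") {
      df0 <- model$frame
      fits <- vector("list", length(ta$labels) + 1)
      rhs <- "1"
      fits[[1]] <- suppressMessages(
        lme4::glmer(as.formula(paste("y ~", rhs, "+ (1|genotype) + (1|block)")),
                    df0, family = stats::binomial()))
      for (k in seq_along(ta$labels)) {
        rhs <- paste(rhs, "+", ta$labels[k])
        fits[[k + 1]] <- suppressMessages(
          lme4::glmer(as.formula(paste("y ~", rhs, "+ (1|genotype) + (1|block)")),
                      df0, family = stats::binomial()))
      }
      ll <- vapply(fits, function(f) as.numeric(logLik(f)), numeric(1))
      npar <- vapply(fits, function(f) attr(logLik(f), "df"), numeric(1))
      out <- tibble::tibble(term = ta$labels,
                            df = diff(npar),
                            statistic = pmax(0, 2 * diff(ll)))
    } else {
      out <- purrr::map_dfr(seq_along(ta$labels), function(k) {
        idx <- which(ta$assign == k)
        b <- lme4::fixef(fit)[idx]
        V <- as.matrix(stats::vcov(fit))[idx, idx, drop = FALSE]
        tibble::tibble(term = ta$labels[k], df = length(idx),
                       statistic = drop(crossprod(b, solve(V, b))))
      })
    }
    out$p_value <- pchisq(out$statistic, out$df, lower.tail = FALSE)
  }
  out$signif <- signif_code(out$p_value)
  class(out) <- c("trait_anova", class(out))
  attr(out, "singular") <- model$singular
  attr(out, "residual_df") <- ddf
  attr(out, "type") <- type
  out
}

#' Mixed model of a microbiome metric on a historic-environment variable
#'
#' Fits `metric ~ z(env) + (1 | genotype) + (1 | block)` and reports the
#' slope (per standardized environment unit), its standard error, and an
#' F test against residual degrees of freedom. This is the analysis
#' behind the diversity-vs-environment panels (e.g. diazotroph richness
#' decreasing with historic soil nitrogen).
#'
#' @param data Per-sample tibble containing the metric, `genotype`,
#'   `block`, and the environment column (genotype-level, expanded to
#'   samples).
#' @param response Metric column name.
#' @param env Environment column name.
#' @return A list of class `env_metric_fit`: `slope`, `se`, `statistic`,
#'   `p_value`, `singular`, `table` (tidy per-term tibble).
#' @export
fit_env_diversity_model <- function(data, response, env) {
  check_columns(data, c(response, env, "genotype", "block"),
                "Metric table")
  y <- data[[response]]
  if (sd(y, na.rm = TRUE) == 0) abort("Constant metric; nothing to model.")
  df <- data.frame(y = y, env_z = zscore(data[[env]], allow_constant = FALSE),
                   genotype = factor(data$genotype),
                   block = factor(data$block))
  df <- df[complete.cases(df), ]
  fit <- suppressMessages(lme4::lmer(y ~ env_z + (1 | genotype) + (1 | block),
                                     df, REML = TRUE))
  b <- lme4::fixef(fit)[["env_z"]]
  se <- sqrt(as.matrix(stats::vcov(fit))["env_z", "env_z"])
  ddf <- nrow(df) - 2L
  fstat <- (b / se)^2
  p <- pf(fstat, 1, ddf, lower.tail = FALSE)
  structure(list(slope = b, se = se, statistic = fstat, p_value = p,
                 singular = lme4::isSingular(fit), fit = fit,
                 table = tibble::tibble(term = "env_z", df = 1,
                                        statistic = fstat, p_value = p,
                                        signif = signif_code(p))),
            class = "env_metric_fit")
}

#' @export
print.env_metric_fit <- function(x, ...) {
  cat(sprintf("<env_metric_fit> slope %.4g (se %.3g), F = %.3g, p = %.3g%s\n",
              x$slope, x$se, x$statistic, x$p_value,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}
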