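#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.permanova <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @exportS3Method generics::glance
glance.permanova <- function(x, ...) {
  terms <- x$term[!x$term %in% c("Residual", "Total")]
  tibble::tibble(n_terms = length(terms),
                 R2_model = sum(x$R2[match(terms, x$term)]),
                 n_perm = attr(x, "n_perm"))
}

#' @exportS3Method generics::tidy
tidy.dbrda_fit <- function(x, ...) {
  if (nrow(x$terms %||% tibble::tibble()) == 0) {
    return(tibble::tibble(term = character(0), SumOfSqs = numeric(0),
                          R2 = numeric(0)))
  }
  x$terms
}

#' @exportS3Method generics::glance
glance.dbrda_fit <- function(x, ...) {
  tibble::tibble(total = x$total, conditioned = x$conditioned,
                 constrained = x$constrained,
                 unconstrained = x$unconstrained,
                 constrained_prop = x$constrained / x$total,
                 n_selected = length(x$selected))
}

#' @exportS3Method generics::tidy
tidy.trait_model <- function(x, ...) {
  b <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
  tibble::tibble(term = names(b), estimate = unname(b), std_error = unname(se))
}

#' @exportS3Method generics::glance
glance.trait_model <- function(x, ...) {
  tibble::tibble(response = x$response, family = x$family,
                 n = nrow(x$frame), singular = x$singular,
                 logLik = as.numeric(logLik(x$fit)))
}

#' @exportS3Method generics::tidy
tidy.reaction_norm <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std_error = c(NA_real_, x$se_slope))
}

#' @exportS3Method generics::tidy
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(term = c("slope_low", "slope_high", "delta"),
                 estimate = c(x$slope_low, x$slope_high, x$delta),
                 std_error = c(x$se_low, x$se_high, NA_real_),
                 p_value = c(NA_real_, NA_real_, x$p_value))
}

#' @exportS3Method generics::glance
glance.slope_comparison <- function(x, ...) {
  tibble::tibble(predictor = x$predictor, delta = x$delta,
                 p_value = x$p_value, n_genotypes = length(x$genotypes),
                 n_sim = x$n_sim)
}

#' @exportS3Method generics::tidy
tidy.rhizo_pcoa <- function(x, n_axes = 2, ...) {
  k <- min(n_axes, ncol(x$coordinates))
  coords <- x$coordinates[, seq_len(k), drop = FALSE]
  colnames(coords) <- sprintf("axis%d", seq_len(k))
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids),
                   tibble::as_tibble(coords))
}

#' @exportS3Method generics::glance
glance.rhizo_pcoa <- function(x, ...) {
  pos <- x$values[x$values > 0]
  tibble::tibble(n_positive = length(pos),
                 n_negative = sum(x$values < 0),
                 prop_axis1 = pos[1] / sum(pos),
                 prop_axis2 = if (length(pos) > 1) pos[2] / sum(pos) else NA_real_)
}

#' @exportS3Method generics::tidy
tidy.env_metric_fit <- function(x, ...) x$table
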