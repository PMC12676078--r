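#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats sd var rnorm runif rbinom rgamma rmultinom quantile
#'   setNames complete.cases coef pf pchisq logLik model.matrix as.dist
#'   as.formula dist cor
#' @importFrom utils head combn
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
# NULL the global stream is used as-is.
local_seed_eval <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and a small offset, kept < 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% 2147483611L
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# z-score a numeric vector; constant vectors are an error unless allow0.
zscore <- function(x, allow_constant = FALSE) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    abort("Cannot standardize a constant (zero-variance) variable.")
  }
  (x - mean(x)) / s
}

# Great-circle distance matrix (km) from lon/lat in decimal degrees.
# Haversine with Earth radius 6371 km.
haversine_dist <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  r <- 6371
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lon)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dphi <- phi - phi[i]
    dlam <- lam - lam[i]
    a <- sin(dphi / 2)^2 + cos(phi[i]) * cos(phi) * sin(dlam / 2)^2
    d[i, ] <- 2 * r * asin(pmin(1, sqrt(a)))
  }
  d
}

# Format a numeric data frame deterministically for file output.
write_stamped_tsv <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# rhizoadapt %s",
                     as.character(utils::packageVersion("rhizoadapt"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_plain_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
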