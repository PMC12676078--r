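#' Gower-centered inner-product matrix of a distance matrix
#'
#' G = -1/2 J D^2 J with J = I - 11'/n the centering projector and D^2 the
#' elementwise squared distances. This is the common core of PCoA,
#' PERMANOVA and dbRDA: for Euclidean distances of points X, G equals the
#' centered X X'.
#'
#' @param dm A [stats::dist] or symmetric matrix.
#' @return A symmetric matrix with (numerically) zero row/column sums.
#' @export
gower_center <- function(dm) {
  d <- as.matrix(dm)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("Distance matrix must be symmetric.")
  n <- nrow(d)
  a <- -0.5 * d^2
  rs <- rowMeans(a)
  a - outer(rs, rep(1, n)) - outer(rep(1, n), rs) + mean(a)
}

# Hat (orthogonal projection) matrix onto the column space of X.
hat_matrix <- function(X) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered matrix. Negative eigenvalues
#' (non-Euclidean distances) are retained and reported; coordinates are
#' returned on the positive (real) axes only.
#'
#' @param dm A [stats::dist].
#' @return An object of class `rhizo_pcoa`: `values` (all eigenvalues),
#'   `vectors` (orthonormal eigenvectors), `coordinates` (samples x
#'   positive axes, scaled by sqrt(eigenvalue)), `sample_ids`.
#' @export
pcoa <- function(dm) {
  G <- gower_center(dm)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  ids <- attr(dm, "Labels") %||% rownames(as.matrix(dm))
  rownames(coords) <- ids
  structure(list(values = e$values, vectors = e$vectors,
                 coordinates = coords, sample_ids = ids),
            class = "rhizo_pcoa")
}

# Sequential (Type-I) partition of trace(G) over design terms.
# Returns list(df, ss, ss_res, df_res, hats) for reuse under permutation.
sequential_partition <- function(G, data, terms) {
  n <- nrow(G)
  X <- matrix(1, n, 1)
  hats <- list()
  df <- integer(length(terms))
  rank_prev <- 1L
  H_prev <- hat_matrix(X)
  for (k in seq_along(terms)) {
    v <- data[[terms[k]]]
    if (is.null(v)) abort(sprintf("Design term `%s` not found.", terms[k]))
    Xk <- if (is.numeric(v)) matrix(as.numeric(v), n, 1)
          else model.matrix(~ f - 1, data.frame(f = factor(v)))
    X <- cbind(X, Xk)
    qrX <- qr(X)
    if (qrX$rank == rank_prev) {
      abort(sprintf("Term `%s` is aliased with earlier terms (rank-deficient design).",
                    terms[k]))
    }
    df[k] <- qrX$rank - rank_prev
    rank_prev <- qrX$rank
    hats[[k]] <- hat_matrix(X)
  }
  ss <- numeric(length(terms))
  prev <- H_prev
  for (k in seq_along(terms)) {
    ss[k] <- sum(hats[[k]] * G) - sum(prev * G)
    prev <- hats[[k]]
  }
  ss_total <- sum(diag(G))
  list(df = df, ss = ss, ss_res = ss_total - sum(hats[[length(terms)]] * G),
       df_res = n - rank_prev, ss_total = ss_total, hats = hats,
       H0 = H_prev)
}

# Genotype/block R-squareds without permutation (used by calibration).
design_r2 <- function(dm, data, terms) {
  part <- sequential_partition(gower_center(dm), data, terms)
  setNames(part$ss / part$ss_total, terms)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Sequential (Type-I) sums of squares via hat-matrix projections of the
#' Gower-centered matrix (SS(term) = trace(H G) increments), pseudo-F per
#' term, and permutation p-values under free relabeling of samples with
#' the (1 + b) / (1 + n_perm) convention.
#'
#' @param dm A [stats::dist].
#' @param data Data frame of design variables, rows aligned with the
#'   samples of `dm`.
#' @param terms Character vector of term names, in model order (order
#'   matters for sequential SS).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @param permutations Optional integer matrix (one permutation per row)
#'   overriding random permutations, e.g. an exhaustive enumeration.
#' @return A tibble of class `permanova`: per-term `df`, `SumOfSqs`,
#'   `R2`, `statistic` (pseudo-F), `p_value`, plus Residual and Total rows.
#' @export
permanova <- function(dm, data, terms, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  if (is.null(permutations) && n_perm < 99) abort("Use at least 99 permutations.")
  G <- gower_center(dm)
  n <- nrow(G)
  if (nrow(data) != n) abort("Design rows must match the distance matrix.")
  part <- sequential_partition(G, data, terms)
  if (part$df_res <= 0) abort("No residual degrees of freedom.")
  f_obs <- (part$ss / part$df) / (part$ss_res / part$df_res)

  perms <- permutations %||% local_seed_eval(seed, t(replicate(n_perm, sample.int(n))))
  n_perm <- nrow(perms)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- perms[b, ]
    Gp <- G[p, p]
    prev <- sum(part$H0 * Gp)
    tot <- sum(diag(Gp))
    last <- sum(part$hats[[length(terms)]] * Gp)
    ss_res_p <- tot - last
    cum <- prev
    for (k in seq_along(terms)) {
      cur <- sum(part$hats[[k]] * Gp)
      ss_k <- cur - cum
      cum <- cur
      f_p <- (ss_k / part$df[k]) / (ss_res_p / part$df_res)
      if (f_p >= f_obs[k] - 1e-12) exceed[k] <- exceed[k] + 1
    }
  }
  p_val <- (1 + exceed) / (1 + n_perm)

  out <- tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(part$df, part$df_res, n - 1L),
    SumOfSqs = c(part$ss, part$ss_res, part$ss_total),
    R2 = c(part$ss, part$ss_res, part$ss_total) / part$ss_total,
    statistic = c(f_obs, NA, NA),
    p_value = c(p_val, NA, NA))
  class(out) <- c("permanova", class(out))
  attr(out, "n_perm") <- n_perm
  out
}

# Prim's minimum spanning tree; returns the longest MST edge weight.
mst_longest_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  longest <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  longest
}

#' Moran eigenvector map basis from a distance matrix
#'
#' Distances beyond the truncation threshold are replaced by 4x the
#' threshold; the truncated matrix is decomposed by principal coordinates
#' and the orthonormal eigenvectors with positive eigenvalues are
#' retained as spatial (or genetic) eigenfunctions.
#'
#' @param dm A [stats::dist] (geographic or genetic, e.g. SSR Hamming).
#' @param truncation `"mst"` (default: longest edge of the minimum
#'   spanning tree) or a positive numeric threshold.
#' @param source Label recorded on the basis (`"geographic"`,
#'   `"genetic"`, ...).
#' @param keep `"positive"` (all positive-eigenvalue eigenvectors) or
#'   `"broad"` (positive eigenvectors whose eigenvalue exceeds the mean
#'   positive eigenvalue -- the broad-scale eigenfunctions). Conditioning
#'   a model for genotype-level predictors on the full positive basis
#'   from two sources can span the whole between-genotype space and alias
#'   every predictor; the broad subset controls autocorrelation without
#'   saturating those degrees of freedom.
#' @return An object of class `mem_basis`: `vectors` (orthonormal),
#'   `values`, `threshold`, `source`.
#' @export
dbmem <- function(dm, truncation = "mst", source = "geographic",
                  keep = c("positive", "broad")) {
  keep <- match.arg(keep)
  d <- as.matrix(dm)
  if (nrow(d) < 4) abort("Need at least 4 points for a MEM basis.")
  if (max(d) == 0) abort("All points are coincident.")
  thr <- if (identical(truncation, "mst")) mst_longest_edge(d)
         else assert_scalar_number(truncation, "truncation", lower = 1e-12)
  dstar <- d
  dstar[dstar > thr] <- 4 * thr
  diag(dstar) <- 0
  e <- eigen(gower_center(dstar), symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  sel <- e$values > tol
  if (keep == "broad") sel <- sel & e$values > mean(e$values[sel])
  vec <- e$vectors[, sel, drop = FALSE]
  colnames(vec) <- sprintf("MEM%d", seq_len(ncol(vec)))
  rownames(vec) <- attr(dm, "Labels") %||% rownames(d)
  structure(list(vectors = vec, values = e$values[sel], threshold = thr,
                 source = source),
            class = "mem_basis")
}

#' Pairwise Hamming distance from an SSR marker matrix
#'
#' Proportion of mismatching loci among pairwise non-missing loci.
#'
#' @param ssr Tibble from [read_ssr()] / [gen_ssr()] (`genotype` +
#'   locus columns).
#' @return A [stats::dist] over genotypes.
#' @export
hamming_distance <- function(ssr) {
  loci <- as.matrix(ssr[, -1, drop = FALSE])
  n <- nrow(loci)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(loci[i, ]) & !is.na(loci[j, ])
      m[i, j] <- m[j, i] <- if (any(ok)) mean(loci[i, ok] != loci[j, ok]) else 0
    }
  }
  new_dist(m, ssr$genotype, "hamming")
}

#' Great-circle distance matrix for a genotype panel
#'
#' Haversine distances (Earth radius 6371 km) between the genotypes'
#' historic collection coordinates.
#'
#' @param panel Genotype panel with `genotype`, `lon`, `lat`.
#' @return A [stats::dist] over genotypes, in km.
#' @export
geographic_distance <- function(panel) {
  new_dist(haversine_dist(panel$lon, panel$lat), panel$genotype, "geographic")
}

#' Expand a genotype-level matrix to sample level
#'
#' @param m Matrix (or `mem_basis`) with genotype row names.
#' @param genotype Character vector: genotype of each sample.
#' @return Matrix with one row per sample.
#' @export
expand_to_samples <- function(m, genotype) {
  if (inherits(m, "mem_basis")) m <- m$vectors
  idx <- match(genotype, rownames(m))
  if (anyNA(idx)) abort("Sample genotype(s) missing from the genotype-level matrix.")
  out <- m[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combined spatial + genetic conditioning block for a sample set
#'
#' Builds the geographic (haversine) and genetic (SSR Hamming) Moran
#' eigenvector bases at genotype level and expands them to samples.
#'
#' @param panel Genotype panel.
#' @param ssr SSR marker tibble.
#' @param metadata Sample metadata (uses `genotype`).
#' @return Samples x eigenvectors numeric matrix.
#' @export
condition_basis <- function(panel, ssr, metadata) {
  geo <- dbmem(geographic_distance(panel), source = "geographic", keep = "broad")
  gen <- dbmem(hamming_distance(ssr), source = "genetic", keep = "broad")
  cbind(geo = expand_to_samples(geo, metadata$genotype),
        gen = expand_to_samples(gen, metadata$genotype))
}

# Standardize predictor columns to zero mean / unit variance (factors are
# expanded to centered dummies).
predictor_matrix <- function(predictors, n) {
  if (is.null(dim(predictors))) predictors <- data.frame(x = predictors)
  cols <- lapply(names(predictors), function(nm) {
    v <- predictors[[nm]]
    if (is.numeric(v)) {
      matrix(zscore(v), ncol = 1, dimnames = list(NULL, nm))
    } else {
      mm <- model.matrix(~ f - 1, data.frame(f = factor(v)))
      colnames(mm) <- paste0(nm, seq_len(ncol(mm)))
      scale(mm, scale = FALSE)
    }
  })
  X <- do.call(cbind, cols)
  if (nrow(X) != n) abort("Predictor rows must match the distance matrix.")
  X
}

#' Distance-based redundancy analysis with optional conditioning
#'
#' Partials the Gower matrix and predictors on the condition block, then
#' projects the residualized matrix onto the residualized predictor
#' space. Reports the inertia decomposition (conditioned + constrained +
#' unconstrained = total) and marginal per-variable statistics.
#'
#' @param dm A [stats::dist].
#' @param predictors Data frame of predictors (numeric predictors are
#'   standardized).
#' @param condition Optional samples x k numeric matrix (e.g. MEM
#'   eigenvectors) partialled out before fitting.
#' @return An object of class `dbrda_fit` with elements `total`,
#'   `conditioned`, `constrained`, `unconstrained`, `eigenvalues`,
#'   `terms` (marginal tibble), `selected`.
#' @export
dbrda <- function(dm, predictors, condition = NULL) {
  G <- gower_center(dm)
  n <- nrow(G)
  X <- predictor_matrix(predictors, n)
  total <- sum(diag(G))
  if (!is.null(condition)) {
    C <- cbind(1, as.matrix(condition))
    qc <- qr(C)
    if (qc$rank < ncol(C)) {
      C <- C[, qc$pivot[seq_len(qc$rank)], drop = FALSE]
    }
    Hc <- hat_matrix(C)
    R <- diag(n) - Hc
    Gr <- R %*% G %*% R
    Xr <- R %*% X
    conditioned <- total - sum(diag(Gr))
  } else {
    Gr <- G
    Xr <- scale(X, scale = FALSE)
    conditioned <- 0
    Hc <- hat_matrix(matrix(1, n, 1))
  }
  dropped <- character(0)
  # columns absorbed by the condition (residual norm ~ 0 after projection)
  dead <- colSums(Xr^2) < 1e-8 * n
  if (any(dead)) {
    dropped <- colnames(Xr)[dead]
    Xr <- Xr[, !dead, drop = FALSE]
  }
  qx <- qr(Xr)
  if (ncol(Xr) && qx$rank < ncol(Xr)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- c(dropped, colnames(Xr)[-keep])
    Xr <- Xr[, keep, drop = FALSE]
  }
  if (length(dropped)) {
    warn(sprintf("Predictor(s) collinear with the condition dropped: %s",
                 paste(dropped, collapse = ", ")))
  }
  if (!ncol(Xr)) {
    return(structure(list(total = total, conditioned = conditioned,
                          constrained = 0,
                          unconstrained = total - conditioned,
                          eigenvalues = numeric(0),
                          terms = tibble::tibble(term = character(0),
                                                 SumOfSqs = numeric(0),
                                                 R2 = numeric(0)),
                          selected = character(0), dropped = dropped,
                          n = n),
                     class = "dbrda_fit"))
  }
  Hx <- hat_matrix(Xr)
  constrained <- sum(Hx * Gr)
  unconstrained <- sum(diag(Gr)) - constrained
  ev <- eigen(Hx %*% Gr %*% Hx, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[seq_len(min(qr(Xr)$rank, length(ev)))]

  # marginal SS of each variable given the others (and the condition)
  marg <- purrr::map_dfr(colnames(Xr), function(nm) {
    others <- Xr[, setdiff(colnames(Xr), nm), drop = FALSE]
    Hr <- if (ncol(others)) hat_matrix(others) else matrix(0, n, n)
    ss <- constrained - sum(Hr * Gr)
    tibble::tibble(term = nm, SumOfSqs = ss,
                   R2 = ss / total)
  })
  structure(list(total = total, conditioned = conditioned,
                 constrained = constrained, unconstrained = unconstrained,
                 eigenvalues = ev, terms = marg,
                 selected = colnames(Xr), dropped = dropped, n = n),
            class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cat("<dbrda_fit>\n")
  cat(sprintf("  inertia: total %.4g = conditioned %.4g + constrained %.4g + unconstrained %.4g\n",
              x$total, x$conditioned, x$constrained, x$unconstrained))
  cat(sprintf("  constrained proportion: %.4f\n", x$constrained / x$total))
  if (length(x$selected)) cat("  terms:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Permutation forward selection of dbRDA predictors
#'
#' Iteratively adds the candidate with the smallest permutation p-value
#' for its marginal addition, permuting the residualized Gower matrix
#' under the current reduced model (condition + already-selected terms);
#' stops when the best p exceeds `alpha` or no candidates remain. The
#' final model's sequential variance partition over the selected terms is
#' reported.
#'
#' @param dm A [stats::dist].
#' @param candidates Data frame of candidate predictors (standardized
#'   internally).
#' @param condition Optional conditioning matrix (see [dbrda()]).
#' @param alpha Entry threshold for the permutation p-value.
#' @param n_perm Permutations per marginal test.
#' @param seed Integer seed.
#' @param groups Optional exchangeability blocks (e.g. genotype of each
#'   sample). Genotype-level candidates are constant across a genotype's
#'   replicates, and replicate communities are correlated within
#'   genotype; free sample permutation would treat the replicates as
#'   independent and grossly overstate significance, so when `groups` is
#'   given the candidate scores are permuted across groups instead.
#' @return A `dbrda_fit` for the selected model, with `$selected` (in
#'   entry order) and `$steps` (per-step F and p) added; if nothing is
#'   selected, a null fit with empty `$selected`.
#' @export
forward_select <- function(dm, candidates, condition = NULL, alpha = 0.05,
                           n_perm = 199, seed = NULL, groups = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  G <- gower_center(dm)
  n <- nrow(G)
  X <- predictor_matrix(candidates, n)
  gi <- if (is.null(groups)) seq_len(n) else as.integer(factor(groups))
  n_g <- max(gi)
  base_cond <- if (is.null(condition)) matrix(1, n, 1)
               else cbind(1, as.matrix(condition))
  local_seed_eval(seed, {
    remaining <- colnames(X)
    selected <- character(0)
    steps <- list()
    repeat {
      if (!length(remaining)) break
      C <- cbind(base_cond, X[, selected, drop = FALSE])
      qc <- qr(C)
      C <- C[, qc$pivot[seq_len(qc$rank)], drop = FALSE]
      R <- diag(n) - hat_matrix(C)
      Gr <- R %*% G %*% R
      df_res <- n - qr(C)$rank - 1L
      if (df_res <= 0) break
      perms <- t(replicate(n_perm, sample.int(n_g)))
      tr_g <- sum(diag(Gr))
      # Permuting candidate scores (within exchangeability blocks) is
      # equivalent to permuting Gr's rows/cols, so all permutation
      # statistics come from one matmul.
      res <- purrr::map_dfr(remaining, function(nm) {
        xr <- drop(R %*% X[, nm])
        xss <- sum(xr^2)
        if (xss < 1e-10) return(tibble::tibble(term = nm, statistic = NA_real_,
                                               p_value = NA_real_))
        ss_obs <- drop(crossprod(xr, Gr %*% xr)) / xss
        f_obs <- ss_obs / ((tr_g - ss_obs) / df_res)
        xr_g <- vapply(seq_len(n_g), function(g) xr[match(g, gi)], numeric(1))
        Y <- matrix(0, n, n_perm)
        for (k in seq_len(n_perm)) Y[, k] <- xr_g[perms[k, ]][gi]
        Y <- R %*% Y  # residualize permuted scores like the observed ones
        yss <- colSums(Y^2)
        ssp <- colSums(Y * (Gr %*% Y)) / pmax(yss, 1e-12)
        fp <- ssp / ((tr_g - ssp) / df_res)
        tibble::tibble(term = nm, statistic = f_obs,
                       p_value = (1 + sum(fp >= f_obs - 1e-12)) / (1 + n_perm))
      })
      res <- dplyr::filter(res, !is.na(.data$p_value))
      if (!nrow(res)) break
      best <- res[order(res$p_value, -res$statistic), ][1, ]
      if (best$p_value > alpha) break
      selected <- c(selected, best$term)
      remaining <- setdiff(remaining, best$term)
      steps[[length(steps) + 1]] <- best
    }
    if (length(selected)) {
      fit <- dbrda(dm, as.data.frame(candidates)[, selected, drop = FALSE],
                   condition = condition)
    } else {
      fit <- structure(list(total = sum(diag(G)), conditioned = NA_real_,
                            constrained = 0, unconstrained = NA_real_,
                            eigenvalues = numeric(0),
                            terms = tibble::tibble(), selected = character(0),
                            dropped = character(0), n = n),
                       class = "dbrda_fit")
    }
    fit$selected <- selected
    fit$steps <- if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(term = character(0), statistic = numeric(0),
                     p_value = numeric(0))
    fit
  })
}
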