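#' Rarefy a feature table to a fixed depth
#'
#' Samples with total count below `depth` are dropped (and reported via a
#' message and the `"dropped_samples"` attribute); the remaining samples
#' are subsampled once, without replacement, to exactly `depth` reads.
#'
#' @param table A [feature_table()].
#' @param depth Target depth (> 0).
#' @param seed Integer seed for the single subsampling draw.
#' @return A rarefied [feature_table()] with attribute `dropped_samples`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  assert_scalar_number(depth, "depth", lower = 1)
  depth <- as.integer(depth)
  totals <- rowSums(table)
  drop <- rownames(table)[totals < depth]
  if (length(drop)) {
    inform(sprintf("Dropping %d sample(s) below depth %d: %s",
                   length(drop), depth, paste(drop, collapse = ", ")))
  }
  keep <- table[totals >= depth, , drop = FALSE]
  if (nrow(keep) == 0) abort("No samples at or above the rarefaction depth.")
  out <- local_seed_eval(seed, {
    t(apply(keep, 1, function(cts) {
      if (sum(cts) == depth) return(as.integer(cts))
      reads <- rep.int(seq_along(cts), cts)
      tabulate(sample(reads, depth, replace = FALSE), nbins = length(cts))
    }))
  })
  dimnames(out) <- dimnames(keep)
  res <- feature_table(out)
  attr(res, "dropped_samples") <- drop
  res
}

#' Per-sample alpha diversity
#'
#' Richness (taxa with positive count), Shannon entropy H = -sum p log p
#' (natural log) and Pielou evenness H / log(richness). Pielou is `NA`
#' (undefined) when richness < 2; H is 0 when richness <= 1.
#'
#' @param table A [feature_table()].
#' @return A tibble: `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
alpha_metrics <- function(table) {
  purrr::map_dfr(seq_len(nrow(table)), function(i) {
    cts <- table[i, ]
    pos <- cts[cts > 0]
    rich <- length(pos)
    h <- if (rich <= 1) 0 else { p <- pos / sum(pos); -sum(p * log(p)) }
    tibble::tibble(sample_id = rownames(table)[i],
                   richness = rich,
                   shannon = h,
                   pielou = if (rich >= 2) h / log(rich) else NA_real_)
  })
}

new_dist <- function(m, ids, metric) {
  dimnames(m) <- list(ids, ids)
  d <- as.dist(m)
  attr(d, "metric") <- metric
  d
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i). A pair of all-zero
#' samples is defined as distance 0 (with a warning).
#'
#' @param table A [feature_table()] (or numeric matrix, samples in rows).
#' @return A [stats::dist] with attribute `metric = "braycurtis"`.
#' @export
bray_curtis <- function(table) {
  if (nrow(table) < 2) abort("Need at least 2 samples.")
  d <- vegan::vegdist(unclass(table), method = "bray")
  m <- as.matrix(d)
  if (anyNA(m)) {
    warn("All-zero sample pair(s); their Bray-Curtis distance is set to 0.")
    m[is.na(m)] <- 0
  }
  new_dist(m, rownames(table), "braycurtis")
}

#' Weighted UniFrac distance matrix
#'
#' Classic weighted UniFrac: for each branch b with length l_b, let A_b
#' and B_b be the fractions of each sample's total count descending from
#' b; the raw distance is sum_b l_b |A_b - B_b|. With
#' `normalized = TRUE` the sum is divided by sum_b l_b (A_b + B_b).
#' Every taxon in the table must be a leaf of the tree (extra leaves are
#' pruned); a table taxon missing from the tree is an error.
#'
#' @param table A [feature_table()].
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param normalized Use the normalized variant (default raw).
#' @return A [stats::dist] with attribute `metric = "wunifrac"`.
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  validate_tree(tree)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing)) {
    abort(sprintf("Taxa absent from the tree: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  extra <- setdiff(tree$tip.label, colnames(table))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)

  n <- nrow(table)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # proportions per sample at each tip, accumulated up the tree
  prop <- matrix(0, n, n_node)
  totals <- rowSums(table)
  if (any(totals == 0)) abort("All-zero sample(s); cannot form proportions.")
  prop[, seq_len(n_tip)] <- unclass(table)[, tree$tip.label, drop = FALSE] / totals
  for (e in ape::postorder(tree)) { # children edges precede parent edges

    parent <- tree$edge[e, 1]
    childn <- tree$edge[e, 2]
    prop[, parent] <- prop[, parent] + prop[, childn]
  }
  # each edge e carries the proportion of its child subtree
  child_prop <- prop[, tree$edge[, 2], drop = FALSE]
  len <- tree$edge.length
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- abs(child_prop[i, ] - child_prop[j, ])
      num <- sum(len * diffs)
      if (normalized) {
        den <- sum(len * (child_prop[i, ] + child_prop[j, ]))
        num <- if (den > 0) num / den else 0
      }
      m[i, j] <- m[j, i] <- num
    }
  }
  new_dist(m, rownames(table), if (normalized) "wunifrac_norm" else "wunifrac")
}

#' Distance to group centroid (beta-dispersion)
#'
#' Embeds the distance matrix by principal coordinates (keeping real and
#' imaginary axes) and computes each sample's distance to its group
#' centroid with Anderson's correction, sqrt(real^2 - imaginary^2) floored
#' at 0. Singleton groups are skipped with a warning.
#'
#' @param dm A [stats::dist].
#' @param groups Grouping vector aligned with the samples of `dm` (e.g.
#'   genotype).
#' @return A tibble: `sample_id`, `group`, `dist_to_centroid`, with the
#'   per-group means as `attr(, "group_means")`.
#' @export
beta_dispersion <- function(dm, groups) {
  ids <- attr(dm, "Labels")
  groups <- as.character(groups)
  stopifnot(length(groups) == attr(dm, "Size"))
  singletons <- names(which(table(groups) < 2))
  if (length(singletons)) {
    warn(sprintf("Skipping singleton group(s): %s",
                 paste(singletons, collapse = ", ")))
    keep <- !groups %in% singletons
    dm <- as.dist(as.matrix(dm)[keep, keep])
    ids <- ids[keep]
    groups <- groups[keep]
  }
  bd <- vegan::betadisper(dm, groups, type = "centroid")
  out <- tibble::tibble(sample_id = ids, group = groups,
                        dist_to_centroid = as.numeric(bd$distances))
  attr(out, "group_means") <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_dist = mean(.data$dist_to_centroid),
                     n = dplyr::n(), .groups = "drop")
  out
}

#' Subset a functional group from a feature table
#'
#' Returns the sub-table of taxa carrying the given taxonomy flag plus
#' each sample's flagged relative abundance, computed against the total
#' counts of the parent table (before subsetting).
#'
#' @param table A [feature_table()].
#' @param taxonomy Taxonomy tibble with logical flag columns.
#' @param flag Flag name: `"ammonia_oxidizer"`, `"diazotroph"` or
#'   `"glomeromycota"`.
#' @return A list: `table` (flagged sub-table) and `relative_abundance`
#'   (tibble `sample_id`, `relative_abundance`).
#' @export
subset_functional_group <- function(table, taxonomy, flag) {
  if (!flag %in% names(taxonomy)) {
    abort(sprintf("Flag `%s` is not defined in the taxonomy.", flag))
  }
  flagged <- taxonomy$taxon_id[which(taxonomy[[flag]])]
  flagged <- intersect(colnames(table), flagged)
  if (!length(flagged)) {
    warn(sprintf("Flag `%s` matches no taxa in the table.", flag))
  }
  sub <- unclass(table)[, flagged, drop = FALSE]
  totals <- rowSums(table)
  ra <- ifelse(totals > 0, rowSums(sub) / totals, NA_real_)
  list(table = if (length(flagged)) feature_table(sub) else sub,
       relative_abundance = tibble::tibble(sample_id = rownames(table),
                                           relative_abundance = as.numeric(ra)))
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Column-sums ASVs sharing the same label at `rank`; ASVs without a
#' label at that rank are pooled into `"unclassified"`. `rank = "asv"`
#' returns the table unchanged.
#'
#' @param table A [feature_table()].
#' @param taxonomy Taxonomy tibble with a column named `rank`.
#' @param rank Rank column name (e.g. `"order"`, `"genus"`) or `"asv"`.
#' @return A [feature_table()] of merged lineages.
#' @export
aggregate_to_rank <- function(table, taxonomy, rank) {
  if (identical(rank, "asv")) return(table)
  if (!rank %in% names(taxonomy)) {
    abort(sprintf("Rank `%s` is not present in the taxonomy.", rank))
  }
  labels <- taxonomy[[rank]][match(colnames(table), taxonomy$taxon_id)]
  labels[is.na(labels)] <- "unclassified"
  groups <- split(seq_len(ncol(table)), labels)
  out <- vapply(groups, function(idx) {
    as.integer(rowSums(unclass(table)[, idx, drop = FALSE]))
  }, integer(nrow(table)))
  if (nrow(table) == 1L) out <- matrix(out, nrow = 1, dimnames = list(rownames(table), names(groups)))
  rownames(out) <- rownames(table)
  feature_table(out)
}
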