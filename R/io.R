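env_vars <- c("soil_nitrogen", "soil_phosphorus", "cec", "ph",
              "mean_annual_temp", "precip_spring", "precip_summer",
              "precip_fall", "mean_annual_precip")

flag_vars <- c("ammonia_oxidizer", "diazotroph", "glomeromycota")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_levels <- function(x, allowed, column) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), allowed)
  if (length(bad)) {
    abort(sprintf("Column `%s` has unknown level(s) %s; allowed: %s",
                  column, paste(bad, collapse = ", "),
                  paste(allowed, collapse = ", ")))
  }
  invisible(x)
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `genotype`, `block`; the treatment columns
#' `nitrogen` (`low`/`high`) and `microbe` (`live`/`sterile`) are optional
#' and validated against their declared level sets when present.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read_plain_tsv(path)
  check_columns(df, c("sample_id", "genotype", "block"), "Sample metadata")
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("Duplicated sample id(s): %s",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]),
                        collapse = ", ")))
  }
  if ("nitrogen" %in% names(df)) check_levels(df$nitrogen, c("low", "high"), "nitrogen")
  if ("microbe" %in% names(df)) check_levels(df$microbe, c("live", "sterile"), "microbe")
  dplyr::mutate(df, dplyr::across(dplyr::any_of(c("sample_id", "genotype", "block")),
                                  as.character))
}

#' Read a genotype panel
#'
#' One row per genotype with collection coordinates (`lon`, `lat`, decimal
#' degrees), `elevation` (m) and the historic-environment covariates
#' (soil nitrogen, soil phosphorus, CEC, pH, mean annual temperature and
#' the precipitation variables). The environment vector must be complete.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per genotype, with a standardized
#'   `soil_nitrogen_z` column added if absent.
#' @export
read_panel <- function(path) {
  df <- read_plain_tsv(path)
  check_columns(df, c("genotype", "lon", "lat", "elevation", env_vars),
                "Genotype panel")
  if (anyDuplicated(df$genotype)) abort("Genotype ids must be unique.")
  num <- c("lon", "lat", "elevation", env_vars)
  incomplete <- !complete.cases(df[num]) |
    !apply(df[num], 1, function(r) all(is.finite(as.numeric(r))))
  if (any(incomplete)) {
    abort(sprintf("Incomplete environment vector for genotype(s): %s",
                  paste(df$genotype[incomplete], collapse = ", ")))
  }
  df <- dplyr::mutate(df, genotype = as.character(.data$genotype))
  if (!"soil_nitrogen_z" %in% names(df)) {
    df$soil_nitrogen_z <- zscore(df$soil_nitrogen)
  }
  df
}

#' Read an SSR marker matrix
#'
#' First column `genotype`, remaining columns integer allele codes per
#' locus; missing calls are encoded as `NA`.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per genotype.
#' @export
read_ssr <- function(path) {
  df <- read_plain_tsv(path)
  check_columns(df, "genotype", "SSR matrix")
  if (ncol(df) < 2L) abort("SSR matrix needs at least one locus column.")
  if (nrow(df) < 2L) abort("SSR matrix needs at least two genotypes.")
  loci <- as.matrix(df[, -1, drop = FALSE])
  if (any(loci[!is.na(loci)] != round(loci[!is.na(loci)]))) {
    abort("SSR allele codes must be integers (NA for missing).")
  }
  dplyr::mutate(df, genotype = as.character(.data$genotype))
}

#' Read a plant-trait table
#'
#' One row per plant from the crossed nitrogen-by-microbe experiment:
#' `plant_id`, `genotype`, `block`, `nitrogen` (`low`/`high`), `microbe`
#' (`live`/`sterile`), `height` (cm), `biomass` (g), `tillering` (0/1).
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per plant.
#' @export
read_traits <- function(path) {
  df <- read_plain_tsv(path)
  check_columns(df, c("plant_id", "genotype", "block", "nitrogen", "microbe",
                      "height", "biomass", "tillering"), "Trait table")
  if (anyDuplicated(df$plant_id)) abort("plant_id must be unique (one row per plant).")
  check_levels(df$nitrogen, c("low", "high"), "nitrogen")
  check_levels(df$microbe, c("live", "sterile"), "microbe")
  check_levels(df$tillering, c("0", "1"), "tillering")
  bad <- with(df, !is.finite(height) | !is.finite(biomass) |
                height <= 0 | biomass <= 0)
  if (any(bad)) {
    abort(sprintf("Non-finite or non-positive trait value(s) for plant(s): %s",
                  paste(df$plant_id[bad], collapse = ", ")))
  }
  dplyr::mutate(df,
                dplyr::across(c("plant_id", "genotype", "block", "nitrogen",
                                "microbe"), as.character),
                tillering = as.integer(.data$tillering))
}

#' Read a taxonomy table
#'
#' One row per taxon with rank labels (`domain` ... `genus`) and logical
#' functional-group flags (`ammonia_oxidizer`, `diazotroph`,
#' `glomeromycota`); absent flag columns are treated as all-FALSE.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per taxon.
#' @export
read_taxonomy <- function(path) {
  df <- read_plain_tsv(path)
  check_columns(df, "taxon_id", "Taxonomy table")
  if (anyDuplicated(df$taxon_id)) abort("taxon_id must be unique.")
  for (fl in flag_vars) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE
    df[[fl]] <- as.logical(df[[fl]])
  }
  dplyr::mutate(df, taxon_id = as.character(.data$taxon_id))
}

#' Read a rooted phylogeny with branch lengths
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree; leaves are matched case-sensitively to
#'   taxon ids downstream.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(sprintf("Unparseable newick: %s",
                                                     conditionMessage(e))))
  if (is.null(tree)) abort("Unparseable newick file.")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length)) {
    abort("Tree has no branch lengths; lengths are required for weighted UniFrac.")
  }
  if (any(tree$edge.length < 0)) abort("Negative branch length in tree.")
  if (anyDuplicated(tree$tip.label)) abort("Duplicate leaf names in tree.")
  tree
}

#' Write a tidy table to TSV with a version/seed header
#'
#' @param df A data frame.
#' @param path Output path.
#' @param seed Optional integer recorded in the file header.
#' @export
write_table_tsv <- function(df, path, seed = NULL) {
  write_stamped_tsv(df, path, seed = seed)
}
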