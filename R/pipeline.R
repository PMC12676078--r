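default_config <- function() {
  list(seed = 1L, out_dir = "rhizoadapt_run",
       n_genotypes = 40L, n_replicates = 5L,
       n_trait_genotypes = 10L, n_trait_replicates = 10L,
       depth_16s = 1000L, depth_nifh = 500L,
       n_perm = 999L, n_sim = 2000L, alpha = 0.05,
       propagation = "montecarlo")
}

#' Build a pipeline run configuration
#'
#' @param ... Overrides of the documented defaults: `seed`, `out_dir`,
#'   design sizes (`n_genotypes`, `n_replicates`, `n_trait_genotypes`,
#'   `n_trait_replicates`), rarefaction depths (`depth_16s`,
#'   `depth_nifh`), `n_perm`, `n_sim`, `alpha`, `propagation`
#'   (`"montecarlo"`/`"delta"`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    warn(sprintf("Ignoring unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
    over <- over[setdiff(names(over), unknown)]
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Unknown keys produce a warning (not an error); missing keys fall back
#' to the documented defaults.
#'
#' @param path Path to a text file with one `key = value` per line
#'   (`#` comments allowed).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) abort(sprintf("Malformed config line(s): %s",
                              paste(lines[bad], collapse = "; ")))
  vals <- lapply(kv, `[[`, 2)
  names(vals) <- vapply(kv, `[[`, 1, FUN.VALUE = character(1))
  defaults <- default_config()
  for (nm in intersect(names(vals), names(defaults))) {
    if (is.numeric(defaults[[nm]])) vals[[nm]] <- as.numeric(vals[[nm]])
  }
  do.call(run_config, vals)
}

write_json_out <- function(x, path, seed) {
  x$seed <- as.integer(seed)
  x$package_version <- as.character(utils::packageVersion("rhizoadapt"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the stages in order -- simulate, rarefy, diversity metrics,
#' PERMANOVA, conditioned dbRDA with forward selection, trait mixed
#' models, microbial-effect tests -- and writes per-stage TSV/JSON
#' outputs (each stamped with the seed and package version) into
#' `config$out_dir`. Deterministic: a fixed seed reproduces the bundle
#' byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- "simulate"
  result <- tryCatch({
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    seed <- config$seed

    bundle <- simulate_study(seed,
                             n_genotypes = config$n_genotypes,
                             n_replicates = config$n_replicates,
                             n_trait_genotypes = config$n_trait_genotypes,
                             n_trait_replicates = config$n_trait_replicates)
    write_table_tsv(bundle$panel, out("panel.tsv"), seed)
    write_table_tsv(bundle$ssr, out("ssr.tsv"), seed)
    write_table_tsv(bundle$metadata, out("metadata.tsv"), seed)
    write_feature_table(bundle$table_16s, out("features_16s.tsv"), seed)
    write_feature_table(bundle$table_nifh, out("features_nifh.tsv"), seed)
    write_table_tsv(bundle$taxonomy_16s, out("taxonomy_16s.tsv"), seed)
    write_table_tsv(bundle$taxonomy_nifh, out("taxonomy_nifh.tsv"), seed)
    ape::write.tree(bundle$tree_16s, out("tree_16s.nwk"))
    write_table_tsv(bundle$traits, out("traits.tsv"), seed)
    write_json_out(list(truth_16s = bundle$truth_16s["group_ra_target"],
                        truth_nifh = bundle$truth_nifh["richness_target"],
                        trait_truth = attr(bundle$traits, "truth")),
                   out("truth.json"), seed)

    stage <- "rarefy"
    ft16 <- rarefy(bundle$table_16s, config$depth_16s,
                   seed = child_seed(seed, 21))
    ftn <- rarefy(bundle$table_nifh, config$depth_nifh,
                  seed = child_seed(seed, 22))
    meta16 <- bundle$metadata[match(rownames(ft16), bundle$metadata$sample_id), ]
    metan <- bundle$metadata_nifh[match(rownames(ftn),
                                        bundle$metadata_nifh$sample_id), ]

    stage <- "metrics"
    alpha16 <- alpha_metrics(ft16)
    alphan <- alpha_metrics(ftn)
    write_table_tsv(alpha16, out("alpha_16s.tsv"), seed)
    write_table_tsv(alphan, out("alpha_nifh.tsv"), seed)
    d16_bc <- bray_curtis(ft16)
    d16_wu <- weighted_unifrac(ft16, bundle$tree_16s)
    dn_bc <- bray_curtis(ftn)
    disp <- beta_dispersion(dn_bc, metan$genotype)
    write_table_tsv(disp, out("dispersion.tsv"), seed)
    ao <- subset_functional_group(ft16, bundle$taxonomy_16s, "ammonia_oxidizer")
    write_table_tsv(ao$relative_abundance, out("group_ra.tsv"), seed)

    stage <- "permanova"
    pa <- dplyr::bind_rows(
      dplyr::mutate(tidy(permanova(d16_bc, meta16, c("genotype", "block"),
                                   n_perm = config$n_perm,
                                   seed = child_seed(seed, 31))),
                    marker = "16s", metric = "braycurtis"),
      dplyr::mutate(tidy(permanova(d16_wu, meta16, c("genotype", "block"),
                                   n_perm = config$n_perm,
                                   seed = child_seed(seed, 32))),
                    marker = "16s", metric = "wunifrac"),
      dplyr::mutate(tidy(permanova(dn_bc, metan, c("genotype", "block"),
                                   n_perm = config$n_perm,
                                   seed = child_seed(seed, 33))),
                    marker = "nifh", metric = "braycurtis"))
    write_table_tsv(pa, out("permanova.tsv"), seed)

    stage <- "dbrda"
    cond <- condition_basis(bundle$panel, bundle$ssr, meta16)
    cand <- as.data.frame(bundle$panel[match(meta16$genotype,
                                             bundle$panel$genotype),
                                       c(env_vars, "elevation")])
    sel <- forward_select(d16_bc, cand, condition = cond,
                          alpha = config$alpha, n_perm = config$n_perm,
                          seed = child_seed(seed, 41))
    write_json_out(list(selected = sel$selected,
                        steps = sel$steps,
                        inertia = as.list(glance(sel))),
                   out("dbrda.json"), seed)

    stage <- "env_models"
    richn <- dplyr::left_join(alphan, metan, by = "sample_id") |>
      dplyr::left_join(bundle$panel[c("genotype", "soil_nitrogen_z")],
                       by = "genotype")
    fit_rich <- fit_env_diversity_model(richn, "richness", "soil_nitrogen_z")
    ra16 <- dplyr::left_join(ao$relative_abundance, meta16, by = "sample_id") |>
      dplyr::left_join(bundle$panel[c("genotype", "soil_nitrogen_z")],
                       by = "genotype")
    fit_ra <- fit_env_diversity_model(ra16, "relative_abundance",
                                      "soil_nitrogen_z")
    write_json_out(list(
      diazotroph_richness = list(slope = fit_rich$slope, se = fit_rich$se,
                                 p_value = fit_rich$p_value),
      ao_relative_abundance = list(slope = fit_ra$slope, se = fit_ra$se,
                                   p_value = fit_ra$p_value)),
      out("env_models.json"), seed)

    stage <- "traits"
    anovas <- list()
    for (resp in c("height", "biomass")) {
      m <- fit_trait_model(bundle$traits, resp, "gaussian")
      anovas[[resp]] <- anova_table(m)
      write_table_tsv(anovas[[resp]], out(sprintf("anova_%s.tsv", resp)), seed)
    }
    m_till <- fit_trait_model(bundle$traits, "tillering", "binomial")
    anovas$tillering <- anova_table(m_till)
    write_table_tsv(anovas$tillering, out("anova_tillering.tsv"), seed)

    stage <- "mefx"
    hist_n <- setNames(bundle$panel$soil_nitrogen_z, bundle$panel$genotype)
    rich_by_geno <- richn |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(value = mean(.data$richness), .groups = "drop")
    ra_by_geno <- ra16 |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(value = mean(.data$relative_abundance),
                       .groups = "drop")
    mefx <- list()
    for (tr in c("height", "biomass")) {
      est <- compute_microbial_effect(bundle$traits, tr) |>
        propagate_me_uncertainty(method = config$propagation,
                                 n_draws = max(1000, config$n_sim),
                                 seed = child_seed(seed, 51))
      sc_env <- slope_difference_test(est, hist_n, n_sim = config$n_sim,
                                      seed = child_seed(seed, 52),
                                      predictor = "historic_soil_n")
      sc_rich <- me_vs_microbiome(est, rich_by_geno, n_sim = config$n_sim,
                                  seed = child_seed(seed, 53),
                                  predictor = "diazotroph_richness")
      sc_ra <- me_vs_microbiome(est, ra_by_geno, n_sim = config$n_sim,
                                seed = child_seed(seed, 54),
                                predictor = "ao_relative_abundance")
      mefx[[tr]] <- list(historic_soil_n = glance(sc_env),
                         diazotroph_richness = glance(sc_rich),
                         ao_relative_abundance = glance(sc_ra))
      write_json_out(list(estimates = est,
                          tests = lapply(mefx[[tr]], as.list)),
                     out(sprintf("mefx_%s.json", tr)), seed)
    }

    cfg_echo <- unclass(config)
    cfg_echo$out_dir <- NULL  # path varies between hosts; not part of the result
    write_json_out(list(config = cfg_echo, stages_completed = TRUE),
                   out("run_info.json"), seed)
    list(bundle = bundle, alpha_16s = alpha16, alpha_nifh = alphan,
         permanova = pa, dispersion = disp, forward_selection = sel,
         env_models = list(richness = fit_rich, ao_ra = fit_ra),
         anova = anovas, mefx = mefx)
  }, error = function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
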