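# Shared fixtures, built in code at test time.

tiny_table <- function(seed = 1, n_samples = 6, n_taxa = 10, lambda = 8) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("t%02d", seq_len(n_taxa))))
    feature_table(m)
  })
}

null_community_spec <- function(n_taxa = 60, depth = 300, ...) {
  community_effect_spec(n_taxa = n_taxa, genotype_sd = 0, env_beta = 0,
                        block_sd = 0, depth = depth, ...)
}

null_trait_spec <- function(...) {
  trait_effect_spec(nitrogen_effect = 0, microbe_effect = 0,
                    me_slope_low = 0, me_slope_high = 0,
                    genotype_sd = 0, block_sd = 0, residual_sd = 0.12, ...)
}

# All n! permutations of 1..n as a list of integer vectors (n <= 7).
combinat_perms <- function(n) {
  perm_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perm_of(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  perm_of(seq_len(n))
}

# ME estimate rows with chosen means/SEs, for propagation tests.
fake_me_estimates <- function(live_mean, sterile_mean, live_se, sterile_se,
                              glasshouse_n = "low") {
  k <- length(live_mean)
  out <- tibble::tibble(
    genotype = sprintf("G%02d", seq_len(k)),
    glasshouse_n = rep(glasshouse_n, length.out = k),
    trait = "height",
    live_mean = live_mean, sterile_mean = sterile_mean,
    live_se = live_se, sterile_se = sterile_se,
    n_live = 7L, n_sterile = 7L,
    me = (live_mean - sterile_mean) / sterile_mean,
    usable = sterile_mean > 0)
  class(out) <- c("me_estimates", class(out))
  out
}
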