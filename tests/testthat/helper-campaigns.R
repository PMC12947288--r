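# Shared fixtures for the test suite: small synthetic campaigns and record
# tables built in code.

small_spec <- function(seed = 11, ...) {
  defaults <- list(
    n_reaction_types = 3, transformations_per_type = 5,
    reactions_per_transformation = 20, seed = seed,
    reagent_vocabulary = list(
      ligand = c(L1 = 1.5, L2 = 0.5, L3 = 0, L4 = 0, L5 = -0.3),
      base = c(B1 = 0.8, B2 = 0, B3 = 0)
    )
  )
  do.call(synthetic_campaign_spec, utils::modifyList(defaults, list(...)))
}

# Conditions of the planted-winner recovery study: one role, one clearly
# superior ligand at +1.5 noise SDs, six transformations of ~24 reactions.
recovery_spec <- function(seed) {
  synthetic_campaign_spec(
    n_reaction_types = 1, transformations_per_type = 6,
    reactions_per_transformation = 24,
    reagent_vocabulary = list(
      ligand = c(GOOD = 1.5, L2 = 0, L3 = 0, L4 = 0, L5 = 0, L6 = 0)
    ),
    noise_model = "lognormal", noise_sd = 8, hit_sparsity = 1,
    seed = seed
  )
}

pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))

# Tiny hand-written record table: 2 transformations, known outcomes.
toy_records <- function() {
  tibble::tibble(
    reaction_id = sprintf("r%02d", 1:8),
    transformation_id = rep(c("T1", "T2"), each = 4),
    reaction_type = "RT01",
    electrophile_class = rep(c("ArBr", "ArCl"), each = 4),
    nucleophile_class = "sec-amine",
    ligand = c("A", "A", "B", "B", "A", "B", "B", "A"),
    outcome_area_pct = c(50, 30, 20, 0, 80, 60, 20, 0)
  )
}
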