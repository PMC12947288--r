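#' Specify a synthetic HTE campaign
#'
#' Builds a validated specification for the synthetic reaction-campaign
#' generator.  The generator emulates the statistical structure of real HTE
#' screening collections: many transformations per reaction type, on the
#' order of a hundred reactions per transformation sampled at ~3
#' time/temperature points each, positively skewed non-normal outcome
#' distributions, sparse hits, and reagent effects shared across
#' transformations — with the ground truth (latent reagent effects, hit
#' status per transformation) recorded in a ledger so that recovery can be
#' verified.
#'
#' @param n_reaction_types number of reaction types; default 42.
#' @param transformations_per_type transformations (substrate pairs) per
#'   type; default 14.
#' @param reactions_per_transformation mean reactions per transformation
#'   (Poisson-distributed, floor 2); default 113.
#' @param reagent_vocabulary named list: role -> named numeric vector of
#'   latent effect sizes in units of the noise SD.  Default vocabulary
#'   plants one clearly superior reagent per role (+1.5 SD) and one mildly
#'   good one (+0.5 SD) among neutral alternatives.
#' @param difficulty_range range (min, max) of the per-transformation
#'   baseline outcome offset in area percent; default c(1, 6).
#' @param noise_model `"lognormal"` (default; right-skewed, emulating
#'   sparse-hit screening data), `"truncated_normal"`, or `"zero_inflated"`.
#' @param noise_sd scale of the outcome noise in area percent; also the unit
#'   in which reagent effects are expressed.  Default 8.
#' @param zero_inflation probability of a hard-zero outcome under the
#'   zero-inflated model; default 0.3.
#' @param hit_sparsity fraction of transformations with at least one outcome
#'   above 10 area percent (the plate-filter criterion); default 0.8.
#' @param samples_per_reaction sampling points per reaction; default 3.
#' @param seed integer seed fixing the full campaign bit-for-bit.
#' @return a validated `campaign_spec` list.
#' @export
synthetic_campaign_spec <- function(n_reaction_types = 42,
                                    transformations_per_type = 14,
                                    reactions_per_transformation = 113,
                                    reagent_vocabulary = default_vocabulary(),
                                    difficulty_range = c(1, 6),
                                    noise_model = c("lognormal", "truncated_normal",
                                                    "zero_inflated"),
                                    noise_sd = 8,
                                    zero_inflation = 0.3,
                                    hit_sparsity = 0.8,
                                    samples_per_reaction = 3,
                                    seed = 1) {
  noise_model <- match.arg(noise_model)
  spec <- list(
    n_reaction_types = n_reaction_types,
    transformations_per_type = transformations_per_type,
    reactions_per_transformation = reactions_per_transformation,
    reagent_vocabulary = reagent_vocabulary,
    difficulty_range = difficulty_range,
    noise_model = noise_model,
    noise_sd = noise_sd,
    zero_inflation = zero_inflation,
    hit_sparsity = hit_sparsity,
    samples_per_reaction = samples_per_reaction,
    seed = seed
  )
  validate_campaign_spec(spec)
  class(spec) <- "campaign_spec"
  spec
}

#' Default synthetic reagent vocabulary
#'
#' Ligand, base and solvent vocabularies with one planted superior reagent
#' per role.  Effects are in units of the campaign's noise SD; the best
#' reagent per role is the one with the maximal effect.
#'
#' @return named list role -> named numeric effect vector.
#' @export
default_vocabulary <- function() {
  list(
    ligand  = c(L01 = 1.5, L02 = 0.5, L03 = 0, L04 = 0, L05 = 0, L06 = 0,
                L07 = 0, L08 = -0.3, L09 = 0, L10 = 0, L11 = 0, L12 = 0),
    base    = c(B1 = 1.5, B2 = 0.4, B3 = 0, B4 = 0, B5 = 0, B6 = -0.2),
    solvent = c(S1 = 0.8, S2 = 0, S3 = 0, S4 = 0, S5 = -0.2)
  )
}

validate_campaign_spec <- function(spec) {
  fail <- function(field, why) {
    stop("Invalid campaign spec field '", field, "': ", why, call. = FALSE)
  }
  pos_int <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1) {
      fail(field, "must be a positive integer")
    }
  }
  for (f in c("n_reaction_types", "transformations_per_type",
              "reactions_per_transformation", "samples_per_reaction")) {
    pos_int(f)
  }
  if (spec$samples_per_reaction > 5) {
    fail("samples_per_reaction", "at most 5 time/temperature points are supported")
  }
  if (!is.numeric(spec$seed) || length(spec$seed) != 1 || !is.finite(spec$seed)) {
    fail("seed", "must be a finite number")
  }
  if (!is.list(spec$reagent_vocabulary) || length(spec$reagent_vocabulary) == 0 ||
      is.null(names(spec$reagent_vocabulary)) ||
      !all(names(spec$reagent_vocabulary) %in% REAGENT_ROLES)) {
    fail("reagent_vocabulary", "must be a named list keyed by reagent role")
  }
  for (role in names(spec$reagent_vocabulary)) {
    v <- spec$reagent_vocabulary[[role]]
    if (!is.numeric(v) || length(v) < 1 || is.null(names(v)) || !all(is.finite(v))) {
      fail("reagent_vocabulary", paste0("role '", role,
           "' needs a named vector of finite effects"))
    }
  }
  if (!is.numeric(spec$difficulty_range) || length(spec$difficulty_range) != 2 ||
      spec$difficulty_range[1] > spec$difficulty_range[2]) {
    fail("difficulty_range", "must be (min, max) with min <= max")
  }
  if (!is.numeric(spec$noise_sd) || spec$noise_sd < 0) {
    fail("noise_sd", "must be >= 0")
  }
  for (f in c("hit_sparsity", "zero_inflation")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) fail(f, "must be in [0, 1]")
  }
  invisible(spec)
}

# Per-transformation substream seed: one shared stream per campaign, split by
# counter, so adding a transformation never perturbs the others.
stream_seed <- function(seed, counter) {
  (abs(as.integer(seed)) * 8191L + counter * 7L) %% 2147483629L
}

draw_noise <- function(n, spec) {
  if (spec$noise_sd == 0) return(rep(0, n))
  switch(spec$noise_model,
    lognormal = {
      # sdlog 0.9 gives strong right skew; scaled so sd(eps) = noise_sd
      sdlog <- 0.9
      raw <- rlnorm(n, meanlog = 0, sdlog = sdlog)
      raw_sd <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
      (raw - exp(sdlog^2 / 2)) / raw_sd * spec$noise_sd
    },
    truncated_normal = pmax(rnorm(n, mean = 0, sd = spec$noise_sd),
                            -spec$noise_sd),
    zero_inflated = {
      eps <- rlnorm(n, meanlog = 0, sdlog = 0.9)
      eps <- (eps - exp(0.405)) / sqrt((exp(0.81) - 1) * exp(0.81)) * spec$noise_sd
      zero <- runif(n) < spec$zero_inflation
      eps[zero] <- -Inf  # forces the outcome to clamp at 0
      eps
    }
  )
}

SAMPLE_TIMES <- c("1h", "4h", "18h", "24h", "48h")
SAMPLE_TEMPS <- c("25C", "50C", "80C", "100C", "120C")

#' Generate a synthetic HTE campaign
#'
#' Simulates a full campaign under a [synthetic_campaign_spec()]: for every
#' transformation, reagents are drawn per role from the vocabulary and the
#' final outcome is `clamp(offset + sum(role effects) * noise_sd + noise,
#' 0, 100)`.  Each reaction additionally gets a monotone-rise-then-plateau
#' multi-sample product series whose maximum equals the final outcome, so
#' the sample-collapse step has nontrivial work to do.  Hit sparsity is
#' controlled per transformation: a `hit` transformation is guaranteed at
#' least one outcome above 10 area percent, a non-hit one is capped below.
#'
#' @param spec a `campaign_spec`.
#' @return list with:
#'   `dataset` (an `hte_dataset` of the generated reactions),
#'   `ledger` (tibble of latent effects: `role`, `reagent`, `effect`,
#'   `is_best`),
#'   `transform_info` (per-transformation bookkeeping: classes, hit flag,
#'   offset, reaction count), and
#'   `samples` (per-sampling product percents feeding
#'   [generate_peak_tables()]).
#' @export
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec") || is.list(spec))
  validate_campaign_spec(spec)
  # the generator manages its own per-transformation RNG streams; leave the
  # caller's RNG state untouched
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", old_seed, envir = globalenv()))
  vocab <- spec$reagent_vocabulary
  roles <- names(vocab)
  k <- spec$samples_per_reaction

  counter <- 0L
  all_rec <- vector("list", spec$n_reaction_types * spec$transformations_per_type)
  all_samp <- vector("list", length(all_rec))
  tinfo <- vector("list", length(all_rec))

  for (ty in seq_len(spec$n_reaction_types)) {
    type_name <- sprintf("RT%02d", ty)
    for (tr in seq_len(spec$transformations_per_type)) {
      counter <- counter + 1L
      set.seed(stream_seed(spec$seed, counter))
      tid <- sprintf("%s_T%03d", type_name, tr)
      n_rxn <- max(2L, rpois(1, spec$reactions_per_transformation))
      offset <- runif(1, spec$difficulty_range[1], spec$difficulty_range[2])
      is_hit <- runif(1) < spec$hit_sparsity
      e_class <- sample(paste0("E", 1:4), 1)
      n_class <- sample(paste0("N", 1:5), 1)

      assigned <- lapply(roles, function(r) {
        sample(names(vocab[[r]]), n_rxn, replace = TRUE)
      })
      names(assigned) <- roles
      effect_sum <- Reduce(`+`, lapply(roles, function(r) {
        unname(vocab[[r]][assigned[[r]]])
      }))
      outcome <- offset + effect_sum * spec$noise_sd + draw_noise(n_rxn, spec)
      outcome <- pmin(pmax(outcome, 0), 100)

      if (is_hit) {
        if (max(outcome) <= 10) {
          imax <- which.max(outcome)
          outcome[imax] <- 10 + runif(1, 0.5, 5)
        }
      } else {
        outcome <- pmin(outcome, 9.5)
      }

      # monotone rise to the outcome, then plateau/slight decay
      peak_at <- sample(seq(ceiling(k / 2), k), n_rxn, replace = TRUE)
      samp <- lapply(seq_len(n_rxn), function(i) {
        f <- outcome[i]
        p <- peak_at[i]
        g <- numeric(k)
        if (p > 1) g[seq_len(p - 1)] <- sort(runif(p - 1, 0.2, 0.95))
        g[p] <- 1
        if (p < k) g[(p + 1):k] <- runif(k - p, 0.85, 0.999)
        tibble::tibble(
          reaction_id = sprintf("%s_R%04d", tid, i),
          sample_id = sprintf("%s_R%04d_s%d", tid, i, seq_len(k)),
          sample_index = seq_len(k),
          time = SAMPLE_TIMES[seq_len(k)],
          temperature = SAMPLE_TEMPS[pmin(seq_len(k), length(SAMPLE_TEMPS))],
          product_pct = f * g
        )
      })
      samp <- dplyr::bind_rows(samp)

      argmax_label <- samp |>
        dplyr::group_by(.data$reaction_id) |>
        dplyr::summarise(
          sampling_profile = paste0(
            .data$time[which.max(.data$product_pct)], "/",
            .data$temperature[which.max(.data$product_pct)]
          ),
          .groups = "drop"
        )

      rec <- tibble::tibble(
        reaction_id = sprintf("%s_R%04d", tid, seq_len(n_rxn)),
        transformation_id = tid,
        reaction_type = type_name,
        electrophile_class = e_class,
        nucleophile_class = n_class,
        outcome_area_pct = outcome,
        n_samples = k
      )
      for (r in roles) rec[[r]] <- assigned[[r]]
      rec <- dplyr::left_join(rec, argmax_label, by = "reaction_id")

      all_rec[[counter]] <- rec
      all_samp[[counter]] <- samp
      tinfo[[counter]] <- tibble::tibble(
        transformation_id = tid, reaction_type = type_name,
        electrophile_class = e_class, nucleophile_class = n_class,
        n_reactions = n_rxn, is_hit = is_hit, offset = offset
      )
    }
  }

  ledger <- dplyr::bind_rows(lapply(roles, function(r) {
    tibble::tibble(
      role = r, reagent = names(vocab[[r]]), effect = unname(vocab[[r]]),
      is_best = unname(vocab[[r]]) == max(vocab[[r]])
    )
  }))

  list(
    dataset = as_hte_dataset(dplyr::bind_rows(all_rec)),
    ledger = ledger,
    transform_info = dplyr::bind_rows(tinfo),
    samples = dplyr::bind_rows(all_samp)
  )
}

#' Generate raw peak tables consistent with a campaign
#'
#' Inverts the area-percent normalization: for each sampling point of each
#' reaction it emits a product and a starting-material peak whose raw areas
#' renormalize exactly to the sample's product percent, plus
#' internal-standard, reagent and injection peaks that the normalization
#' must discard.  All raw areas of a sample share a random positive scale
#' factor, exercising the scale invariance of the normalization.
#'
#' @param campaign result of [generate_campaign()].
#' @param seed seed for the nuisance-peak scale factors; defaults to the
#'   campaign seed semantics (pass the spec seed for reproducibility).
#' @return long-format peak-table tibble (`sample_id`, `reaction_id`,
#'   `peak_class`, `raw_area`, `time`, `temperature`).
#' @export
generate_peak_tables <- function(campaign, seed = 0) {
  samp <- campaign$samples
  n <- nrow(samp)
  scale <- with_preserved_seed(seed, runif(n, 0.5, 20))
  per_sample <- tibble::tibble(
    sample_id = rep(samp$sample_id, each = 5),
    reaction_id = rep(samp$reaction_id, each = 5),
    peak_class = rep(c("product", "starting_material", "internal_standard",
                       "reagent", "injection"), times = n),
    raw_area = as.vector(rbind(
      samp$product_pct * scale,
      (100 - samp$product_pct) * scale,
      25 * scale,
      7 * scale,
      2 * scale
    )),
    time = rep(samp$time, each = 5),
    temperature = rep(samp$temperature, each = 5)
  )
  per_sample
}

#' Write a synthetic campaign to disk
#'
#' Emits the dataset CSV (readable by [read_dataset()]), the ground-truth
#' ledger CSV, and the per-transformation bookkeeping CSV.
#'
#' @param campaign result of [generate_campaign()].
#' @param dir output directory, created if needed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    dataset = file.path(dir, "dataset.csv"),
    ledger = file.path(dir, "ledger.csv"),
    transform_info = file.path(dir, "transform_info.csv")
  )
  write_dataset(campaign$dataset, paths[["dataset"]])
  readr::write_csv(campaign$ledger, paths[["ledger"]])
  readr::write_csv(campaign$transform_info, paths[["transform_info"]])
  invisible(paths)
}
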