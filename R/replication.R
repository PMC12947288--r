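#' Candidate locations of the published HTE dataset
#'
#' The 66,000-reaction published dataset is distributed through its authors'
#' repository and is not bundled with this package.  When a copy is placed at
#' one of these conventional locations, [replicate_published_diagnostics()]
#' and the dataset-replication checks can run against it.
#'
#' @param dir optional directory to search first.
#' @return the first existing candidate path, or `NA_character_`.
#' @export
published_dataset_path <- function(dir = NULL) {
  candidates <- c(
    if (!is.null(dir)) file.path(dir, "hte_dataset.csv"),
    file.path("data", "hte_dataset.csv"),
    file.path(Sys.getenv("HOME"), "hte_dataset.csv")
  )
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

#' Recompute the headline diagnostics of a published-scale dataset
#'
#' Runs the full diagnostic pipeline on a dataset file and returns the
#' quantities a published HTE collection is characterized by: total reaction
#' count, number of reaction types, number of types with more than 1,000
#' reactions, mean reactions per transformation, median per-type skewness,
#' and whether every reaction type fails the Shapiro-Wilk normality test at
#' `alpha`.
#'
#' @param path dataset CSV path (see [published_dataset_path()]).
#' @param schema column schema; see [default_schema()].
#' @param alpha normality-test significance level; default 0.05.
#' @return list of the diagnostic quantities plus the full
#'   `hte_diagnostics` object under `$diagnostics`.
#' @export
replicate_published_diagnostics <- function(path, schema = default_schema(),
                                            alpha = 0.05) {
  ds <- read_dataset(path, schema = schema)
  diag <- dataset_diagnostics(ds)
  pt <- diag$per_type
  list(
    n_reactions = diag$global$n_reactions,
    n_reaction_types = diag$global$n_reaction_types,
    n_types_over_1000 = sum(pt$n_reactions > 1000),
    mean_reactions_per_transformation =
      diag$global$mean_reactions_per_transformation,
    median_skewness = diag$global$median_skewness,
    all_types_nonnormal = all(pt$shapiro_p < alpha, na.rm = TRUE),
    diagnostics = diag
  )
}

#' Precatalyst-vs-ligand worked comparison
#'
#' For one ligand with several precatalysts, computes each precatalyst's
#' median rank statistic individually (per-catalyst mode, support filter
#' relaxed so thinly supported precatalysts are visible) and the pooled
#' ligand-level statistic, within one slice.  This is the analysis that
#' shows why ligand pooling matters: a precatalyst that excels in only two
#' transformations is hidden by the default support filter, yet pulls the
#' pooled ligand score up.
#'
#' @param x an `hte_dataset` or records data frame.
#' @param ligand ligand name whose precatalysts are compared.
#' @param catalog catalyst catalog; see [read_catalyst_catalog()].
#' @param ... slice filters and options passed to [rank_reagents()]
#'   (e.g. `reaction_type`, `nucleophile_class`, `n_top`).
#' @return list with `per_catalyst` (ranking rows of the ligand's
#'   precatalysts, any support) and `pooled` (the ligand's pooled ranking
#'   row).
#' @export
ligand_pooling_comparison <- function(x, ligand, catalog, ...) {
  cats <- catalog$catalyst[catalog$ligand == ligand]
  per_cat <- rank_reagents(x, role = "catalyst", pooling = "per_catalyst",
                           min_transformations = 1, ...)
  pooled <- rank_reagents(x, role = "catalyst", pooling = "ligand_pooled",
                          catalog = catalog, min_transformations = 1, ...)
  list(
    per_catalyst = per_cat[per_cat$reagent %in% cats, , drop = FALSE],
    pooled = pooled[pooled$reagent == ligand, , drop = FALSE]
  )
}
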