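#' Per-transformation z-scores
#'
#' The z-score of a reaction is `(x - mu) / sigma`, where `x` is the
#' reaction's normalized product area percent and `mu`, `sigma` are the mean
#' and standard deviation of all outcomes of the same chemical transformation
#' (substrate pair).  A hit among many failures thereby scores higher than an
#' equal-area hit in a transformation full of hits, making outcomes
#' comparable across transformations.
#'
#' By default `sigma` is the population standard deviation (divide by N): the
#' transformation's reactions are the entire frame of reference, not a sample
#' from a larger population.  `sd_type = "sample"` switches to the n-1
#' convention.
#'
#' Transformations where `sigma` is 0 (all outcomes equal) or that hold a
#' single reaction carry no discriminating information: every z is set to 0
#' and the records are flagged `degenerate`, which excludes them from
#' ranking.
#'
#' @param x an `hte_dataset` or records data frame.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return the records tibble with added columns `z` and `degenerate`.
#' @export
compute_zscores <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  rec <- as_hte_records(x)
  sd_fun <- if (sd_type == "population") pop_sd else stats::sd
  rec |>
    dplyr::group_by(.data$transformation_id) |>
    dplyr::mutate(
      .n = dplyr::n(),
      .mu = mean(.data$outcome_area_pct),
      .sigma = if (.data$.n[1] < 2) 0 else sd_fun(.data$outcome_area_pct),
      degenerate = .data$.n < 2 | .data$.sigma == 0,
      z = ifelse(.data$degenerate, 0,
                 (.data$outcome_area_pct - .data$.mu) / .data$.sigma)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".n", -".mu", -".sigma")
}

#' Pool z-scores of one reagent across transformations
#'
#' Selects the z-scores over which a reagent's rank statistic is computed.
#' With scope `"per_transformation"` (the default, matching the published
#' boxplots: "top five hits per transformation"), the up-to-`n_top` highest
#' z-scores of the reagent's reactions are taken within each transformation
#' that contains it and pooled.  With scope `"global"`, the `n_top` highest
#' z-scores across all of the reagent's reactions are taken.  Negative
#' z-scores are eligible: top-n means highest, not positive.
#'
#' Ties at the top-n boundary are broken deterministically by sorting on
#' (z descending, reaction_id ascending) and taking exactly n.
#'
#' @param zscores data frame with columns `transformation_id`, `reaction_id`,
#'   `z` — the z-scored reactions containing one reagent.
#' @param n_top number of top z-scores to keep (per transformation or
#'   globally, by scope); default 5.
#' @param topn_scope `"per_transformation"` or `"global"`.
#' @return numeric vector of pooled z-scores.
#' @export
select_top_n <- function(zscores, n_top = 5,
                         topn_scope = c("per_transformation", "global")) {
  select_top_rows(zscores, n_top, match.arg(topn_scope))$z
}

# As select_top_n(), but returning the selected rows (z plus identifiers),
# for callers that need per-point metadata (e.g. boxplot hover labels).
select_top_rows <- function(zscores, n_top = 5,
                            topn_scope = c("per_transformation", "global")) {
  topn_scope <- match.arg(topn_scope)
  stopifnot(n_top >= 1)
  zs <- tibble::as_tibble(zscores)
  zs <- zs[order(-zs$z, zs$reaction_id), , drop = FALSE]
  if (topn_scope == "global") {
    return(utils::head(zs, n_top))
  }
  zs |>
    dplyr::group_by(.data$transformation_id) |>
    dplyr::slice_head(n = n_top) |>
    dplyr::ungroup()
}

#' Relabel records by pooling mode
#'
#' Determines the reagent label each reaction is ranked under.
#' `per_catalyst` uses the role's name unchanged; `ligand_pooled` (for the
#' catalyst role) replaces each precatalyst by its parent ligand via the
#' catalog, so all precatalysts of one ligand are treated as equivalent;
#' `combination` joins two roles into a composite key (e.g.
#' `"Cs2CO3∥toluene"` for base-solvent pairs).  Catalysts absent from the
#' catalog keep their own name (and are reported), so pooling stays
#' auditable.
#'
#' @param x an `hte_dataset` or records data frame.
#' @param role reagent role to rank (`ligand`, `catalyst`, `base`, `solvent`,
#'   `additive`).
#' @param pooling one of `"per_catalyst"`, `"ligand_pooled"`,
#'   `"combination"`.
#' @param catalog catalyst catalog (required for `ligand_pooled`); see
#'   [read_catalyst_catalog()].
#' @param combo_roles length-2 character vector of roles joined in
#'   `combination` mode; default base + solvent.
#' @return records tibble with an added `reagent` column (NA where the
#'   reaction does not use the role).
#' @export
pool_reagents <- function(x, role = "ligand",
                          pooling = c("per_catalyst", "ligand_pooled", "combination"),
                          catalog = NULL, combo_roles = c("base", "solvent")) {
  pooling <- match.arg(pooling)
  rec <- as_hte_records(x)
  if (pooling == "combination") {
    stopifnot(length(combo_roles) == 2, all(combo_roles %in% REAGENT_ROLES))
    a <- rec[[combo_roles[1]]]
    b <- rec[[combo_roles[2]]]
    rec$reagent <- ifelse(is.na(a) | is.na(b), NA_character_,
                          paste(a, b, sep = COMBO_SEP))
    return(rec)
  }
  stopifnot(role %in% REAGENT_ROLES)
  rec$reagent <- rec[[role]]
  if (pooling == "ligand_pooled") {
    if (is.null(catalog)) stop("ligand_pooled mode needs a catalog", call. = FALSE)
    mapped <- suppressMessages(
      map_catalyst_to_ligand(rec$reagent, catalog, sentinel = NA_character_)
    )
    unmapped <- is.na(mapped) & !is.na(rec$reagent)
    if (any(unmapped)) {
      message("Catalyst(s) not in catalog, ranked under their own name: ",
              paste(unique(rec$reagent[unmapped]), collapse = ", "))
    }
    rec$reagent <- dplyr::coalesce(mapped, rec$reagent)
  }
  rec
}

#' Rank reagents by the median of their pooled top-n z-scores
#'
#' The reagent rank statistic: pool the top-n z-scores of reactions
#' containing each reagent (see [select_top_n()]) and take their median.
#' The median rather than the mean limits the influence of single-outlier
#' reactions; a large `n_top` favors reagents that perform robustly under
#' many conditions, a small one rewards extraordinary one-off performance.
#' Reagents present in fewer than `min_transformations` transformations
#' within the active slice are hidden from display (kept in the result with
#' `displayed = FALSE`), which stops rarely-used reagents from topping the
#' list on thin evidence.
#'
#' The slice is filtered first (reaction type, functional-group classes),
#' then the plate-inclusion filter is applied, then z-scores are computed
#' within each surviving transformation over all of its reactions.
#' Degenerate transformations (single reaction, or zero spread) contribute
#' no z-scores.
#'
#' @param x an `hte_dataset` or records data frame.
#' @param role reagent role to rank.
#' @param reaction_type optional reaction type(s) to slice on.
#' @param electrophile_class,nucleophile_class optional functional-group
#'   class set(s) to slice on.
#' @param pooling,catalog,combo_roles see [pool_reagents()].
#' @param n_top number of top z-scores pooled per reagent; default 5.
#' @param min_transformations minimum transformation support for display;
#'   default 5, counted within the active slice.
#' @param topn_scope `"per_transformation"` (default) or `"global"`; see
#'   [select_top_n()].
#' @param sd_type z-score standard-deviation convention; see
#'   [compute_zscores()].
#' @param plate_threshold area-percent threshold of the plate filter.
#' @param apply_plate_filter set FALSE if the data were already filtered.
#' @return a `reagent_ranking` tibble, ordered by `rank_score` descending
#'   (ties: larger `n_transformations` first, then name), with columns
#'   `reagent`, `rank_score`, `n_transformations`, `n_reactions`,
#'   `displayed`, and the list column `pooled_z`.  An empty slice returns a
#'   zero-row result with a message naming the filter that emptied it.
#' @export
rank_reagents <- function(x, role = "ligand",
                          reaction_type = NULL,
                          electrophile_class = NULL,
                          nucleophile_class = NULL,
                          pooling = c("per_catalyst", "ligand_pooled", "combination"),
                          catalog = NULL, combo_roles = c("base", "solvent"),
                          n_top = 5, min_transformations = 5,
                          topn_scope = c("per_transformation", "global"),
                          sd_type = c("population", "sample"),
                          plate_threshold = 10,
                          apply_plate_filter = TRUE) {
  pooling <- match.arg(pooling)
  topn_scope <- match.arg(topn_scope)
  sd_type <- match.arg(sd_type)
  stopifnot(n_top >= 1, min_transformations >= 1)
  rec <- as_hte_records(x)

  empty_result <- function(filter_name) {
    message("Empty slice after filter: ", filter_name)
    out <- tibble::tibble(
      reagent = character(), rank_score = numeric(),
      n_transformations = integer(), n_reactions = integer(),
      displayed = logical(), pooled_z = list(), pooled_ids = list()
    )
    attr(out, "emptied_by") <- filter_name
    class(out) <- c("reagent_ranking", class(out))
    out
  }

  for (f in c("reaction_type", "electrophile_class", "nucleophile_class")) {
    keep_vals <- switch(f,
      reaction_type = reaction_type,
      electrophile_class = electrophile_class,
      nucleophile_class = nucleophile_class
    )
    if (!is.null(keep_vals)) {
      rec <- rec[rec[[f]] %in% keep_vals, , drop = FALSE]
      if (nrow(rec) == 0) return(empty_result(f))
    }
  }

  if (apply_plate_filter) {
    rec <- included_records(rec, threshold = plate_threshold)
    rec <- rec[rec$included, , drop = FALSE]
    if (nrow(rec) == 0) return(empty_result("plate_filter"))
  }

  zrec <- compute_zscores(rec, sd_type = sd_type)
  zrec <- zrec[!zrec$degenerate, , drop = FALSE]
  if (nrow(zrec) == 0) return(empty_result("degenerate_transformations"))

  zrec <- pool_reagents(zrec, role = role, pooling = pooling,
                        catalog = catalog, combo_roles = combo_roles)
  zrec <- zrec[!is.na(zrec$reagent), , drop = FALSE]
  if (nrow(zrec) == 0) return(empty_result(paste0("role:", role)))

  out <- zrec |>
    dplyr::group_by(.data$reagent) |>
    dplyr::summarise(
      n_transformations = dplyr::n_distinct(.data$transformation_id),
      n_reactions = dplyr::n(),
      pooled = list(select_top_rows(
        dplyr::pick("transformation_id", "reaction_id", "z"),
        n_top = n_top, topn_scope = topn_scope
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pooled_z = lapply(.data$pooled, function(p) p$z),
      pooled_ids = lapply(.data$pooled, function(p) p$reaction_id),
      rank_score = vapply(.data$pooled_z, stats::median, numeric(1)),
      displayed = .data$n_transformations >= min_transformations
    ) |>
    dplyr::arrange(dplyr::desc(.data$rank_score),
                   dplyr::desc(.data$n_transformations), .data$reagent) |>
    dplyr::select("reagent", "rank_score", "n_transformations",
                  "n_reactions", "displayed", "pooled_z", "pooled_ids")

  attr(out, "query") <- list(
    role = role, pooling = pooling, combo_roles = combo_roles,
    reaction_type = reaction_type, electrophile_class = electrophile_class,
    nucleophile_class = nucleophile_class, n_top = n_top,
    min_transformations = min_transformations, topn_scope = topn_scope,
    sd_type = sd_type, plate_threshold = plate_threshold
  )
  class(out) <- c("reagent_ranking", class(out))
  out
}

#' @export
print.reagent_ranking <- function(x, n = 10, ...) {
  q <- attr(x, "query")
  if (!is.null(q)) {
    cat("<reagent_ranking> role=", q$role, " pooling=", q$pooling,
        " n_top=", q$n_top, " min_transformations=", q$min_transformations,
        " scope=", q$topn_scope, "\n", sep = "")
  }
  shown <- x[x$displayed, , drop = FALSE]
  cat(nrow(shown), "displayed of", nrow(x), "reagents\n")
  df <- utils::head(as.data.frame(shown[, c("reagent", "rank_score",
                                            "n_transformations", "n_reactions")]), n)
  df$rank_score <- round(df$rank_score, 2)  # display only; stored full precision
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a ranking as CSV
#'
#' Writes the displayed reagents (by default) with rank scores at full
#' precision in stable order, so repeated runs are byte-identical.
#'
#' @param ranking a `reagent_ranking`.
#' @param path output CSV path.
#' @param displayed_only drop hidden reagents; default TRUE.
#' @return `path`, invisibly.
#' @export
export_ranking <- function(ranking, path, displayed_only = TRUE) {
  out <- ranking
  if (displayed_only) out <- out[out$displayed, , drop = FALSE]
  readr::write_csv(
    as.data.frame(out[, c("reagent", "rank_score", "n_transformations", "n_reactions")]),
    path
  )
  invisible(path)
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Dataset diagnostics
#'
#' Summaries that characterize an HTE collection: per reaction type the
#' reaction and transformation counts, the adjusted Fisher-Pearson sample
#' skewness of the outcome distribution, and a Shapiro-Wilk normality
#' p-value; globally the median per-type skewness and the mean number of
#' reactions per transformation.  HTE outcome distributions are typically
#' strongly right-skewed (sparse hits over many failures) and non-normal,
#' which is why the package uses z-scores only for normalization, never for
#' probabilistic inference.
#'
#' Shapiro-Wilk is valid for 3-5000 observations; larger types are
#' subsampled to `shapiro_cap` with a fixed seed so the report is
#' reproducible.  Types with fewer than 3 outcomes report `NA` skewness.
#'
#' @param x an `hte_dataset` or records data frame.
#' @param shapiro_cap maximum sample size passed to the test; default 4999.
#' @param shapiro_seed seed for the subsample; default 0.
#' @return an `hte_diagnostics` list: `per_type` tibble
#'   (`reaction_type`, `n_reactions`, `n_transformations`, `skewness`,
#'   `shapiro_p`) and `global` list (`n_reactions`, `n_transformations`,
#'   `n_reaction_types`, `median_skewness`,
#'   `mean_reactions_per_transformation`).
#' @export
dataset_diagnostics <- function(x, shapiro_cap = 4999, shapiro_seed = 0) {
  rec <- as_hte_records(x)
  shapiro_p <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) > shapiro_cap) {
      v <- with_preserved_seed(shapiro_seed, sample(v, shapiro_cap))
    }
    if (length(v) < 3 || pop_sd(v) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  per_type <- rec |>
    dplyr::group_by(.data$reaction_type) |>
    dplyr::summarise(
      n_reactions = dplyr::n(),
      n_transformations = dplyr::n_distinct(.data$transformation_id),
      skewness = sample_skewness(.data$outcome_area_pct),
      shapiro_p = shapiro_p(.data$outcome_area_pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_reactions))
  out <- list(
    per_type = per_type,
    global = list(
      n_reactions = nrow(rec),
      n_transformations = dplyr::n_distinct(rec$transformation_id),
      n_reaction_types = nrow(per_type),
      median_skewness = stats::median(per_type$skewness, na.rm = TRUE),
      mean_reactions_per_transformation =
        nrow(rec) / dplyr::n_distinct(rec$transformation_id)
    )
  )
  class(out) <- "hte_diagnostics"
  out
}

#' @export
print.hte_diagnostics <- function(x, ...) {
  g <- x$global
  cat("<hte_diagnostics>\n",
      "  reactions: ", g$n_reactions,
      "  transformations: ", g$n_transformations,
      "  reaction types: ", g$n_reaction_types, "\n",
      "  median per-type skewness: ", round(g$median_skewness, 2), "\n",
      "  mean reactions per transformation: ",
      round(g$mean_reactions_per_transformation, 1), "\n", sep = "")
  print(utils::head(as.data.frame(x$per_type), 10), row.names = FALSE)
  invisible(x)
}
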