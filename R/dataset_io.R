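#' Default column schema for HTE reaction datasets
#'
#' Maps the canonical record fields used throughout the package to the column
#' headers expected in a CSV file.  The schema is configurable because
#' published HTE exports differ in their headers; pass a modified copy of this
#' mapping (or a YAML file with the same keys read via [read_schema()]) to
#' [read_dataset()].
#'
#' Canonical fields: `reaction_id`, `transformation_id`, `reaction_type`,
#' `electrophile_class`, `nucleophile_class`, the reagent roles `ligand`,
#' `catalyst`, `base`, `solvent`, `additive`, the outcome
#' `outcome_area_pct` (normalized product area percent in \[0, 100\]),
#' `n_samples` (number of time/temperature samplings collapsed into the
#' outcome) and the optional `sampling_profile` label.
#'
#' @return named character vector: canonical field -> column name.
#' @export
default_schema <- function() {
  c(
    reaction_id        = "reaction_id",
    transformation_id  = "transformation_id",
    reaction_type      = "reaction_type",
    electrophile_class = "electrophile_class",
    nucleophile_class  = "nucleophile_class",
    ligand             = "ligand",
    catalyst           = "catalyst",
    base               = "base",
    solvent            = "solvent",
    additive           = "additive",
    outcome_area_pct   = "outcome_area_pct",
    n_samples          = "n_samples",
    sampling_profile   = "sampling_profile"
  )
}

#' Read a schema mapping from a YAML file
#'
#' @param path YAML file with `field: column` pairs; fields absent from the
#'   file keep their [default_schema()] column names.
#' @return named character vector usable as `schema` in [read_dataset()].
#' @export
read_schema <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  schema <- default_schema()
  bad <- setdiff(names(user), names(schema))
  if (length(bad) > 0) {
    stop("Unknown schema field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  schema[names(user)] <- vapply(user, as.character, character(1))
  schema
}

# Fields that must exist as columns in the input file.
MANDATORY_FIELDS <- c("transformation_id", "reaction_type", "outcome_area_pct")

#' Read and validate an HTE reaction dataset
#'
#' Reads a delimited file of one-reaction-per-row records, validates each row
#' against the record invariants, and returns the accepted records together
#' with a rejects report.  Malformed rows are never silently dropped: each
#' rejected row appears in the report with the reason for rejection.
#'
#' Validation rules: `outcome_area_pct` must be numeric in \[0, 100\];
#' `transformation_id` and `reaction_type` must be non-empty; at least one
#' reagent role must be filled.  Reagent names are canonicalized with
#' [clean_reagent_name()] on read.
#'
#' @param path path to the delimited file (header row required).
#' @param schema named character vector mapping canonical fields to column
#'   names; see [default_schema()].  Mandatory fields whose columns are absent
#'   raise an error naming the column.
#' @param delim field delimiter, default comma.
#' @return an `hte_dataset`: list with `records` (tibble of accepted
#'   records in canonical columns), `rejects` (tibble with a `reason`
#'   column), and `schema`.
#' @export
read_dataset <- function(path, schema = default_schema(), delim = ",") {
  if (!file.exists(path)) stop("Dataset file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- schema[MANDATORY_FIELDS][!schema[MANDATORY_FIELDS] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("Mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  build_dataset(raw, schema)
}

# Shared row-validation core for read_dataset() and as_hte_dataset().
build_dataset <- function(raw, schema = default_schema()) {
  present <- schema[schema %in% names(raw)]
  rec <- tibble::as_tibble(raw)[, unname(present), drop = FALSE]
  names(rec) <- names(present)

  # fill optional fields
  n <- nrow(rec)
  if (!"reaction_id" %in% names(rec)) rec$reaction_id <- sprintf("rxn_%06d", seq_len(n))
  rec$reaction_id <- as.character(rec$reaction_id)
  for (f in c("electrophile_class", "nucleophile_class", "sampling_profile")) {
    if (!f %in% names(rec)) rec[[f]] <- NA_character_
  }
  for (role in REAGENT_ROLES) {
    if (!role %in% names(rec)) rec[[role]] <- NA_character_
    rec[[role]] <- dplyr::na_if(clean_reagent_name(rec[[role]]), "")
  }
  if (!"n_samples" %in% names(rec)) rec$n_samples <- 1L
  rec$n_samples <- suppressWarnings(as.integer(rec$n_samples))
  rec$n_samples[is.na(rec$n_samples)] <- 1L
  rec$outcome_area_pct <- suppressWarnings(as.numeric(rec$outcome_area_pct))

  reason <- rep(NA_character_, n)
  blank <- function(x) is.na(x) | trimws(as.character(x)) == ""
  has_reagent <- rowSums(!is.na(as.matrix(rec[REAGENT_ROLES]))) > 0
  bad_outcome <- is.na(rec$outcome_area_pct) |
    rec$outcome_area_pct < 0 | rec$outcome_area_pct > 100
  reason[blank(rec$transformation_id)] <- "empty transformation_id"
  reason[is.na(reason) & blank(rec$reaction_type)] <- "empty reaction_type"
  reason[is.na(reason) & bad_outcome] <- "outcome_area_pct outside [0, 100]"
  reason[is.na(reason) & !has_reagent] <- "no reagent assigned in any role"

  keep <- is.na(reason)
  rejects <- rec[!keep, , drop = FALSE]
  rejects$reason <- reason[!keep]

  canonical <- c(
    "reaction_id", "transformation_id", "reaction_type",
    "electrophile_class", "nucleophile_class", REAGENT_ROLES,
    "outcome_area_pct", "n_samples", "sampling_profile"
  )
  records <- rec[keep, canonical, drop = FALSE]
  structure(
    list(records = records, rejects = tibble::as_tibble(rejects), schema = schema),
    class = "hte_dataset"
  )
}

#' Coerce a data frame of reaction records to an `hte_dataset`
#'
#' Applies the same validation as [read_dataset()] to an in-memory table.
#'
#' @param x data frame with (a subset of) the canonical columns.
#' @param schema optional schema if `x` uses non-canonical column names.
#' @return an `hte_dataset`.
#' @export
as_hte_dataset <- function(x, schema = default_schema()) {
  if (inherits(x, "hte_dataset")) return(x)
  build_dataset(tibble::as_tibble(x), schema)
}

# Accept either an hte_dataset or a bare records table.
as_hte_records <- function(x) {
  if (inherits(x, "hte_dataset")) x$records else tibble::as_tibble(x)
}

#' @export
print.hte_dataset <- function(x, ...) {
  r <- x$records
  cat("<hte_dataset> ", nrow(r), " reactions, ",
      dplyr::n_distinct(r$transformation_id), " transformations, ",
      dplyr::n_distinct(r$reaction_type), " reaction types; ",
      nrow(x$rejects), " rejected rows\n", sep = "")
  invisible(x)
}

#' Write an HTE dataset (and its rejects report) back to CSV
#'
#' Accepted records are written under the dataset's schema column names, so
#' that `read_dataset(write_dataset(x))` round-trips every field.
#'
#' @param x an `hte_dataset` or records data frame.
#' @param path output CSV path for the records.
#' @param rejects_path optional CSV path for the rejects report.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, rejects_path = NULL, delim = ",") {
  ds <- as_hte_dataset(x)
  out <- ds$records
  present <- ds$schema[names(ds$schema) %in% names(out)]
  out <- out[, names(present), drop = FALSE]
  names(out) <- unname(present)
  readr::write_delim(out, path, delim = delim, na = "")
  if (!is.null(rejects_path)) {
    readr::write_delim(ds$rejects, rejects_path, delim = delim, na = "")
  }
  invisible(path)
}

#' Per-transformation summary of a dataset
#'
#' @param x an `hte_dataset` or records data frame.
#' @return tibble with one row per transformation: reaction type, record
#'   count, and the maximum outcome (the quantity the plate filter tests).
#' @export
transformation_summary <- function(x) {
  as_hte_records(x) |>
    dplyr::group_by(.data$transformation_id, .data$reaction_type) |>
    dplyr::summarise(
      n_reactions = dplyr::n(),
      max_outcome = max(.data$outcome_area_pct),
      .groups = "drop"
    )
}

#' Electrophile-nucleophile coverage matrix
#'
#' Counts reactions of one reaction type for each combination of functional
#' group classes, the tabulation shown as a heat-map matrix in HTE coverage
#' reports.  Classes can be excluded (e.g. classes with negligible counts).
#'
#' @param x an `hte_dataset` or records data frame.
#' @param reaction_type the reaction type to tabulate.
#' @param row_axis,col_axis record fields giving the row/column classes;
#'   defaults electrophile x nucleophile.
#' @param exclude character vector of class labels dropped from both axes.
#' @return tibble: one row per row-axis class, one column per col-axis class,
#'   integer counts (0 where a combination is absent).  Unknown reaction type
#'   yields an empty table with a warning.
#' @export
coverage_matrix <- function(x, reaction_type,
                            row_axis = "electrophile_class",
                            col_axis = "nucleophile_class",
                            exclude = character()) {
  rec <- as_hte_records(x)
  rec <- rec[rec$reaction_type == reaction_type, , drop = FALSE]
  if (nrow(rec) == 0) {
    warning("No reactions of type '", reaction_type, "' in dataset", call. = FALSE)
    return(tibble::tibble(!!row_axis := character()))
  }
  rec <- rec[!(rec[[row_axis]] %in% exclude) & !(rec[[col_axis]] %in% exclude), ]
  counts <- rec |>
    dplyr::count(.data[[row_axis]], .data[[col_axis]]) |>
    tidyr::pivot_wider(
      names_from = dplyr::all_of(col_axis),
      values_from = "n", values_fill = 0L
    ) |>
    dplyr::arrange(.data[[row_axis]])
  counts[, c(row_axis, sort(setdiff(names(counts), row_axis)))]
}

#' Read a catalyst-to-ligand catalog
#'
#' The catalog is an editable TSV with columns `catalyst` and `ligand`
#' (optionally `precatalyst_class`), one row per precatalyst.  It drives
#' ligand pooling: all precatalysts of one ligand are treated as equivalent.
#'
#' @param path TSV file path.
#' @return tibble with `catalyst`, `ligand` (and `precatalyst_class` if
#'   present), names canonicalized.
#' @export
read_catalyst_catalog <- function(path) {
  cat <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (!all(c("catalyst", "ligand") %in% names(cat))) {
    stop("Catalog must have columns 'catalyst' and 'ligand'", call. = FALSE)
  }
  cat$catalyst <- clean_reagent_name(cat$catalyst)
  cat$ligand <- clean_reagent_name(cat$ligand)
  if (anyDuplicated(cat$catalyst)) {
    stop("Catalog maps some catalyst to more than one ligand", call. = FALSE)
  }
  cat
}

#' Map precatalyst names to their parent ligand
#'
#' @param catalyst_name character vector of precatalyst names.
#' @param catalog catalog tibble from [read_catalyst_catalog()].
#' @param sentinel label returned for catalysts absent from the catalog.
#' @return character vector of ligand names; unmapped entries carry
#'   `sentinel` and are reported via a single message.
#' @export
#' @examples
#' catalog <- tibble::tibble(
#'   catalyst = c("SPhos Pd(allyl)OTf", "SPhos Pd(crotyl)Cl"),
#'   ligand = c("SPhos", "SPhos")
#' )
#' map_catalyst_to_ligand("SPhos Pd(allyl)OTf", catalog)
map_catalyst_to_ligand <- function(catalyst_name, catalog, sentinel = "unmapped") {
  key <- clean_reagent_name(catalyst_name)
  out <- catalog$ligand[match(key, catalog$catalyst)]
  unmapped <- is.na(out) & !is.na(key)
  if (any(unmapped)) {
    message("Unmapped catalyst(s): ",
            paste(unique(key[unmapped]), collapse = ", "))
    out[unmapped] <- sentinel
  }
  out
}
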