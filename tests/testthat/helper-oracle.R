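# Independent brute-force transcription of the ranking definitions, written
# with plain loops over the record table.  Used as the oracle against
# rank_reagents(); deliberately shares no code with the implementation.

oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

oracle_rank <- function(records, role = "ligand", n_top = 5,
                        min_transformations = 5,
                        topn_scope = "per_transformation",
                        sd_type = "population",
                        plate_threshold = 10) {
  df <- as.data.frame(records)

  # plate filter: keep transformations whose best outcome exceeds threshold
  keep_tid <- character()
  for (tid in unique(df$transformation_id)) {
    if (max(df$outcome_area_pct[df$transformation_id == tid]) > plate_threshold) {
      keep_tid <- c(keep_tid, tid)
    }
  }
  df <- df[df$transformation_id %in% keep_tid, , drop = FALSE]
  if (nrow(df) == 0) return(NULL)

  # z-scores within each transformation; drop degenerate frames
  df$z <- NA_real_
  drop_tid <- character()
  for (tid in unique(df$transformation_id)) {
    idx <- which(df$transformation_id == tid)
    x <- df$outcome_area_pct[idx]
    mu <- sum(x) / length(x)
    sigma <- if (sd_type == "population") {
      sqrt(sum((x - mu)^2) / length(x))
    } else if (length(x) >= 2) {
      sqrt(sum((x - mu)^2) / (length(x) - 1))
    } else 0
    if (length(x) < 2 || sigma == 0) {
      drop_tid <- c(drop_tid, tid)
    } else {
      df$z[idx] <- (x - mu) / sigma
    }
  }
  df <- df[!df$transformation_id %in% drop_tid, , drop = FALSE]
  if (nrow(df) == 0) return(NULL)

  df <- df[!is.na(df[[role]]), , drop = FALSE]
  res <- list()
  for (rg in unique(df[[role]])) {
    sub <- df[df[[role]] == rg, , drop = FALSE]
    if (topn_scope == "global") {
      sub <- sub[order(-sub$z, sub$reaction_id), , drop = FALSE]
      pooled <- head(sub$z, n_top)
    } else {
      pooled <- numeric()
      for (tid in unique(sub$transformation_id)) {
        st <- sub[sub$transformation_id == tid, , drop = FALSE]
        st <- st[order(-st$z, st$reaction_id), , drop = FALSE]
        pooled <- c(pooled, head(st$z, n_top))
      }
    }
    res[[rg]] <- data.frame(
      reagent = rg,
      rank_score = oracle_median(pooled),
      n_transformations = length(unique(sub$transformation_id)),
      n_reactions = nrow(sub),
      displayed = length(unique(sub$transformation_id)) >= min_transformations
    )
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$rank_score, -out$n_transformations, out$reagent), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random micro-campaign: <=5 transformations x <=20 reactions, small reagent
# vocabulary, occasional duplicate outcomes to exercise ties.
random_micro_campaign <- function() {
  n_t <- sample(1:5, 1)
  recs <- lapply(seq_len(n_t), function(t) {
    n_r <- sample(2:20, 1)
    outcome <- round(runif(n_r, 0, 40), sample(0:2, 1))  # rounding makes ties
    tibble::tibble(
      reaction_id = sprintf("T%d_R%02d", t, seq_len(n_r)),
      transformation_id = paste0("T", t),
      reaction_type = "RTX",
      ligand = sample(LETTERS[1:5], n_r, replace = TRUE),
      outcome_area_pct = outcome
    )
  })
  dplyr::bind_rows(recs)
}
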