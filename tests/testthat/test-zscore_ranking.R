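test_that("z-scores standardize each transformation (population sigma default)", {
  rec <- tibble::tibble(
    reaction_id = as.character(1:5), transformation_id = "T1",
    reaction_type = "BH", ligand = "A",
    outcome_area_pct = c(0, 0, 0, 0, 100)
  )
  z <- compute_zscores(rec)
  # mu = 20, population sigma = 40, so the hit scores exactly 2
  expect_equal(z$z[5], 2)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(pop_sd_test(z$z), 1, tolerance = 1e-9)

  zs <- compute_zscores(rec, sd_type = "sample")
  expect_equal(zs$z[5], (100 - 20) / sd(rec$outcome_area_pct))
})

test_that("degenerate transformations get z = 0 and a flag", {
  flat <- tibble::tibble(
    reaction_id = as.character(1:3), transformation_id = "T1",
    reaction_type = "BH", ligand = "A", outcome_area_pct = 7.3
  )
  z <- compute_zscores(flat)
  expect_true(all(z$degenerate))
  expect_true(all(z$z == 0))

  single <- flat[1, ]
  zs <- compute_zscores(single)
  expect_true(zs$degenerate)
  expect_equal(zs$z, 0)
})

test_that("top-n selection pools per transformation or globally", {
  zs <- tibble::tibble(
    transformation_id = c("T1", "T1", "T1", "T2", "T2"),
    reaction_id = as.character(1:5),
    z = c(3, 2, 1, 0, -1)
  )
  expect_equal(sort(select_top_n(zs, n_top = 2), decreasing = TRUE),
               c(3, 2, 0, -1))
  expect_equal(select_top_n(zs, n_top = 2, topn_scope = "global"), c(3, 2))
  # fewer available than n: take all (negatives eligible)
  one <- zs[zs$transformation_id == "T1", ]
  one$z <- c(2, 1, -0.5)
  expect_equal(sort(select_top_n(one, n_top = 5), decreasing = TRUE),
               c(2, 1, -0.5))
})

test_that("top-n ties at the boundary break on reaction_id, exactly n kept", {
  zs <- tibble::tibble(
    transformation_id = "T1",
    reaction_id = c("r3", "r1", "r2"),
    z = c(1, 1, 1)
  )
  rows <- hterank:::select_top_rows(zs, n_top = 2)
  expect_equal(rows$reaction_id, c("r1", "r2"))
  expect_equal(length(select_top_n(zs, n_top = 2)), 2)
})

test_that("ranking matches a hand-checked toy slice and hides thin support", {
  r <- rank_reagents(toy_records(), role = "ligand", n_top = 5,
                     min_transformations = 5)
  # both ligands occur in only 2 transformations -> hidden but retained
  expect_equal(nrow(r), 2)
  expect_false(any(r$displayed))

  r2 <- rank_reagents(toy_records(), role = "ligand", min_transformations = 2)
  expect_true(all(r2$displayed))
  oracle <- oracle_rank(toy_records(), min_transformations = 2)
  expect_equal(r2$reagent, oracle$reagent)
  expect_equal(r2$rank_score, oracle$rank_score, tolerance = 1e-12)
})

test_that("ranking equals the brute-force oracle on random micro-campaigns", {
  set.seed(2024)
  for (i in 1:60) {
    rec <- random_micro_campaign()
    for (scope in c("per_transformation", "global")) {
      for (sdt in c("population", "sample")) {
        got <- suppressMessages(rank_reagents(
          rec, role = "ligand", n_top = 3, min_transformations = 2,
          topn_scope = scope, sd_type = sdt
        ))
        want <- oracle_rank(rec, role = "ligand", n_top = 3,
                            min_transformations = 2, topn_scope = scope,
                            sd_type = sdt)
        if (is.null(want)) {
          expect_equal(nrow(got), 0)
        } else {
          expect_equal(got$reagent, want$reagent)
          expect_equal(got$rank_score, want$rank_score, tolerance = 1e-12)
          expect_equal(got$n_transformations, want$n_transformations)
          expect_equal(got$n_reactions, want$n_reactions)
          expect_equal(got$displayed, want$displayed)
        }
      }
    }
  }
})

test_that("rankings are invariant under per-transformation affine maps", {
  camp <- generate_campaign(small_spec(seed = 5))
  rec <- camp$dataset$records
  base_rank <- rank_reagents(rec, role = "ligand", min_transformations = 2)

  set.seed(77)
  shifts <- tibble::tibble(
    transformation_id = unique(rec$transformation_id),
    a = runif(dplyr::n_distinct(rec$transformation_id), 0.2, 3),
    b = runif(dplyr::n_distinct(rec$transformation_id), -5, 5)
  )
  rec2 <- dplyr::left_join(rec, shifts, by = "transformation_id")
  rec2$outcome_area_pct <- rec2$a * rec2$outcome_area_pct + rec2$b
  # affine map may cross the plate threshold; compare with the filter off so
  # the invariance of the statistic itself is what is tested
  r1 <- rank_reagents(rec, role = "ligand", min_transformations = 2,
                      apply_plate_filter = FALSE)
  r2 <- rank_reagents(rec2, role = "ligand", min_transformations = 2,
                      apply_plate_filter = FALSE)
  expect_equal(r1$reagent, r2$reagent)
  expect_equal(r1$rank_score, r2$rank_score, tolerance = 1e-9)
  expect_equal(base_rank$reagent[1], r1$reagent[1])
})

test_that("raising one outcome never lowers its own z-score", {
  set.seed(12)
  for (i in 1:20) {
    x <- runif(8, 0, 50)
    rec <- tibble::tibble(
      reaction_id = as.character(1:8), transformation_id = "T",
      reaction_type = "BH", ligand = "A", outcome_area_pct = x
    )
    j <- sample(8, 1)
    rec2 <- rec
    rec2$outcome_area_pct[j] <- rec2$outcome_area_pct[j] + runif(1, 0, 30)
    z1 <- compute_zscores(rec)$z[j]
    z2 <- compute_zscores(rec2)$z[j]
    expect_gte(z2, z1 - 1e-12)
  }
})

test_that("the median rank statistic resists a single crashing low value", {
  set.seed(3)
  for (i in 1:20) {
    v <- sort(rnorm(sample(3:9, 1)))
    crashed <- c(-1e6, v[-1])
    gap <- abs(median(v) - median(crashed))
    expect_lte(gap, abs(v[2] - v[1]) + 1e-12)
  }
})

test_that("pooling modes relabel records as expected", {
  rec <- toy_records()
  rec$catalyst <- c("SPhos Pd(allyl)OTf", "SPhos Pd(crotyl)Cl")[c(1, 2, 1, 2, 1, 2, 1, 2)]
  rec$base <- "Cs2CO3"
  rec$solvent <- "toluene"
  catalog <- tibble::tibble(
    catalyst = c("SPhos Pd(allyl)OTf", "SPhos Pd(crotyl)Cl"),
    ligand = c("SPhos", "SPhos")
  )
  expect_equal(pool_reagents(rec, role = "catalyst")$reagent, rec$catalyst)
  pooled <- pool_reagents(rec, role = "catalyst", pooling = "ligand_pooled",
                          catalog = catalog)
  expect_true(all(pooled$reagent == "SPhos"))
  combo <- pool_reagents(rec, pooling = "combination")
  expect_true(all(combo$reagent == "Cs2CO3∥toluene"))
  # unmapped catalysts keep their own name
  rec$catalyst[1] <- "OddCat"
  expect_message(
    kept <- pool_reagents(rec, role = "catalyst", pooling = "ligand_pooled",
                          catalog = catalog),
    "OddCat"
  )
  expect_equal(kept$reagent[1], "OddCat")
})

test_that("pooled ligand median lies between its precatalyst medians", {
  # two precatalysts of one ligand with different performance profiles
  set.seed(8)
  recs <- lapply(1:8, function(t) {
    n <- 12
    cat_names <- rep(c("Lig G3", "Lig allylOTf"), each = n / 2)
    boost <- ifelse(cat_names == "Lig allylOTf", 18, 6)
    tibble::tibble(
      reaction_id = sprintf("T%d_r%02d", t, 1:n),
      transformation_id = paste0("T", t), reaction_type = "BH",
      catalyst = cat_names, ligand = "Lig",
      outcome_area_pct = pmin(pmax(boost + rnorm(n, 0, 6), 0), 100)
    )
  })
  rec <- dplyr::bind_rows(recs)
  catalog <- tibble::tibble(catalyst = c("Lig G3", "Lig allylOTf"),
                            ligand = c("Lig", "Lig"))
  per_cat <- rank_reagents(rec, role = "catalyst", min_transformations = 1)
  pooled <- rank_reagents(rec, role = "catalyst", pooling = "ligand_pooled",
                          catalog = catalog, min_transformations = 1)
  m <- sort(per_cat$rank_score)
  expect_gte(pooled$rank_score, m[1])
  expect_lte(pooled$rank_score, m[2])
})

test_that("empty slices return an empty ranking naming the filter", {
  expect_message(
    r <- rank_reagents(toy_records(), reaction_type = "Suzuki"),
    "reaction_type"
  )
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "emptied_by"), "reaction_type")

  low <- toy_records()
  low$outcome_area_pct <- low$outcome_area_pct / 20  # everything below 10%
  expect_message(r2 <- rank_reagents(low), "plate_filter")
  expect_equal(nrow(r2), 0)
})

test_that("diagnostics report counts, skewness sign, and normality p-values", {
  sym <- tibble::tibble(
    reaction_id = as.character(1:400),
    transformation_id = rep(paste0("T", 1:4), each = 100),
    reaction_type = "SYM", ligand = "A",
    outcome_area_pct = pmin(pmax(rep(seq(-3, 3, length.out = 100), 4) * 5 + 50, 0), 100)
  )
  d <- dataset_diagnostics(sym)
  expect_equal(d$per_type$n_reactions, 400L)
  expect_equal(d$per_type$n_transformations, 4L)
  expect_lt(abs(d$per_type$skewness), 0.05)

  set.seed(6)
  skewed <- sym
  skewed$reaction_type <- "EXP"
  skewed$transformation_id <- rep(paste0("S", 1:4), each = 100)
  skewed$outcome_area_pct <- pmin(rexp(400, rate = 1 / 8), 100)
  d2 <- dataset_diagnostics(skewed)
  expect_gt(d2$per_type$skewness, 0.5)     # exponential: theoretical skewness 2
  expect_lt(d2$per_type$shapiro_p, 0.05)

  both <- dplyr::bind_rows(sym, skewed)
  dg <- dataset_diagnostics(both)$global
  expect_equal(dg$n_reaction_types, 2L)
  expect_equal(dg$mean_reactions_per_transformation, 100)
  expect_equal(dg$median_skewness,
               median(dataset_diagnostics(both)$per_type$skewness))

  tiny <- sym[1:2, ]
  expect_true(is.na(dataset_diagnostics(tiny)$per_type$skewness))
})
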