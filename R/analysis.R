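# Full cohort analysis: stratified descriptives with group tests, the
# MRI-vs-BIA correlation structure overall and by obesity stratum, and
# standardized age- and sex-adjusted associations.

MRI_OUTCOMES <- c("ammi_total", "ammi_fatfree")
BIA_PREDICTORS <- c("lean_body_mass_index", "appendicular_muscle_mass_index",
                    "smi_bia", "bmi", "waist", "hip")

#' Run the full concordance analysis
#'
#' Joins the subject table with the per-subject MRI measures and produces
#' three report tables shaped like a population-imaging cohort report:
#' stratified demographics/descriptives with Welch-t / chi-square tests
#' (sex-stratified MRI rows Bonferroni-adjusted for three tests), Pearson
#' correlations of the MRI indices with anthropometric/BIA measures overall
#' and by obesity stratum, and standardized linear-regression associations
#' both unadjusted and adjusted for age and sex.
#'
#' Degenerate strata (constant variables, too few cases) produce warnings
#' and NA rows rather than errors.
#'
#' @param cohort subject tibble (see [generate_cohort()] for columns).
#' @param measures per-subject measures from [quantify_cohort()] /
#'   [simulate_and_quantify()]. If `NULL`, the generator's stored targets are
#'   used as measures (cohort-only statistical runs without images).
#' @param bonferroni_m multiplier for the sex-stratified comparisons,
#'   default 3.
#' @return an object of class `muscle_report`: a list of tibbles
#'   `demographics`, `descriptives`, `correlations`, `associations` plus
#'   stratum counts.
#' @export
run_full_analysis <- function(cohort, measures = NULL, bonferroni_m = 3) {
  required <- c("subject_id", "age", "sex", "height", "bmi", "obese",
                "smi_bia", "lean_body_mass_index",
                "appendicular_muscle_mass_index", "waist", "hip")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    mm_abort(paste0("cohort is missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             class = "musclemap_schema_error")
  }
  if (is.null(measures)) {
    tcols <- c("target_ammi_total", "target_ammi_fatfree", "target_ratio",
               "target_pdff_muscle", "target_csa_total")
    if (!all(tcols %in% names(cohort))) {
      mm_abort("no measures given and cohort lacks generator targets",
               class = "musclemap_schema_error")
    }
    measures <- tibble(
      subject_id = cohort$subject_id,
      csa_total = cohort$target_csa_total,
      csa_fatfree = cohort$target_ratio * cohort$target_csa_total,
      ammi_total = cohort$target_ammi_total,
      ammi_fatfree = cohort$target_ammi_fatfree,
      ratio = 100 * cohort$target_ratio,
      pdff_muscle = cohort$target_pdff_muscle
    )
  }
  mcols <- c("subject_id", "csa_total", "csa_fatfree", "ammi_total",
             "ammi_fatfree", "ratio", "pdff_muscle")
  missing_cols <- setdiff(mcols, names(measures))
  if (length(missing_cols) > 0) {
    mm_abort(paste0("measures are missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             class = "musclemap_schema_error")
  }
  d <- dplyr::inner_join(as_tibble(cohort), as_tibble(measures[, mcols]),
                         by = "subject_id")
  if (nrow(d) == 0) mm_abort("cohort and measures share no subjects")

  strata <- list(all = rep(TRUE, nrow(d)), non_obese = !d$obese,
                 obese = d$obese)
  n_strata <- vapply(strata, sum, integer(1))
  if (n_strata[["non_obese"]] == 0 || n_strata[["obese"]] == 0) {
    mm_abort("both obesity strata must be non-empty",
             class = "musclemap_degenerate")
  }

  demo_vars <- intersect(c("age", "sex", "glucose_status", "hypertension"),
                         names(d))
  demographics <- purrr::map_dfr(demo_vars, function(v) {
    safe_compare(d, v)
  })

  desc_vars <- intersect(
    c("height", "weight", "bmi", "waist", "hip",
      "total_body_fat_mass_index", "lean_body_mass_index",
      "appendicular_muscle_mass_index", "smi_bia",
      "csa_total", "ammi_total", "csa_fatfree", "ammi_fatfree",
      "ratio", "pdff_muscle", "vat", "sat"),
    names(d)
  )
  descriptives <- purrr::map_dfr(desc_vars, function(v) {
    row <- dplyr::bind_cols(
      tibble(
        variable = v, sex = "all",
        mean_all = mean(d[[v]]), sd_all = sd(d[[v]]),
        mean_non_obese = mean(d[[v]][!d$obese]),
        sd_non_obese = sd(d[[v]][!d$obese]),
        mean_obese = mean(d[[v]][d$obese]),
        sd_obese = sd(d[[v]][d$obese])
      ),
      safe_compare(d, v)[, c("test", "statistic", "p_value", "p_adjusted")]
    )
    if (v %in% c("ammi_total", "ammi_fatfree", "ratio")) {
      sex_rows <- purrr::map_dfr(c("female", "male"), function(sx) {
        ds <- d[d$sex == sx, ]
        dplyr::bind_cols(
          tibble(
            variable = v, sex = sx,
            mean_all = mean(ds[[v]]), sd_all = sd(ds[[v]]),
            mean_non_obese = mean(ds[[v]][!ds$obese]),
            sd_non_obese = sd(ds[[v]][!ds$obese]),
            mean_obese = mean(ds[[v]][ds$obese]),
            sd_obese = sd(ds[[v]][ds$obese])
          ),
          safe_compare(ds, v, bonferroni_m = bonferroni_m)[
            , c("test", "statistic", "p_value", "p_adjusted")]
        )
      })
      row <- dplyr::bind_rows(row, sex_rows)
    }
    row
  })

  grid <- tidyr::expand_grid(
    outcome = MRI_OUTCOMES,
    predictor = intersect(BIA_PREDICTORS, names(d)),
    stratum = names(strata)
  )
  correlations <- purrr::pmap_dfr(grid, function(outcome, predictor, stratum) {
    ds <- d[strata[[stratum]], ]
    res <- tryCatch(
      pearson_r(ds[[outcome]], ds[[predictor]]),
      musclemap_degenerate = function(e) {
        warning("degenerate correlation ", outcome, " ~ ", predictor,
                " in stratum ", stratum, call. = FALSE)
        tibble(r = NA_real_, p_value = NA_real_, n = nrow(ds))
      }
    )
    dplyr::bind_cols(tibble(outcome = outcome, predictor = predictor,
                            stratum = stratum), res)
  })

  assoc_grid <- tidyr::expand_grid(
    outcome = MRI_OUTCOMES,
    predictor = intersect(BIA_PREDICTORS, names(d)),
    stratum = names(strata),
    adjusted = c(FALSE, TRUE)
  )
  associations <- purrr::pmap_dfr(
    assoc_grid,
    function(outcome, predictor, stratum, adjusted) {
      ds <- d[strata[[stratum]], ]
      covs <- if (adjusted) c("age", "sex") else character(0)
      res <- tryCatch(
        tidy(standardized_ols(ds, outcome, predictor, covariates = covs,
                              stratum = stratum)),
        error = function(e) {
          warning("degenerate association ", outcome, " ~ ", predictor,
                  " in stratum ", stratum, ": ", conditionMessage(e),
                  call. = FALSE)
          tibble(outcome = outcome, predictor = predictor,
                 estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, n = nrow(ds),
                 adjusted_for = paste(covs, collapse = "+"),
                 stratum = stratum)
        }
      )
      res
    }
  )

  structure(
    list(
      demographics = demographics,
      descriptives = descriptives,
      correlations = correlations,
      associations = associations,
      n = nrow(d),
      n_non_obese = n_strata[["non_obese"]],
      n_obese = n_strata[["obese"]]
    ),
    class = "muscle_report"
  )
}

safe_compare <- function(d, v, bonferroni_m = NULL) {
  tryCatch(
    compare_groups(d, v, bonferroni_m = bonferroni_m),
    musclemap_degenerate = function(e) {
      warning("degenerate comparison for ", v, ": ", conditionMessage(e),
              call. = FALSE)
      tibble(variable = v, test = NA_character_, group1 = NA_real_,
             group2 = NA_real_, statistic = NA_real_, p_value = NA_real_,
             bonferroni_m = NA_integer_, p_adjusted = NA_real_)
    }
  )
}

#' @export
print.muscle_report <- function(x, ...) {
  cat("<muscle_report> n =", x$n, "(", x$n_non_obese, "non-obese /",
      x$n_obese, "obese )\n")
  key <- x$correlations[x$correlations$stratum == "all" &
                          ((x$correlations$outcome == "ammi_total" &
                              x$correlations$predictor == "lean_body_mass_index") |
                             (x$correlations$outcome == "ammi_fatfree" &
                                x$correlations$predictor == "smi_bia")), ]
  if (nrow(key) > 0) {
    cat("  key correlations:\n")
    for (i in seq_len(nrow(key))) {
      cat(sprintf("    r(%s, %s) = %.2f\n", key$outcome[i], key$predictor[i],
                  key$r[i]))
    }
  }
  cat("  tables: demographics, descriptives, correlations, associations\n")
  invisible(x)
}

#' Write the report tables as CSV files
#'
#' @param report a `muscle_report`.
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_report_csvs <- function(report, dir) {
  stopifnot(inherits(report, "muscle_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    demographics = file.path(dir, "demographics.csv"),
    descriptives = file.path(dir, "descriptives.csv"),
    correlations = file.path(dir, "correlations.csv"),
    associations = file.path(dir, "associations.csv")
  )
  for (nm in names(paths)) readr::write_csv(report[[nm]], paths[[nm]])
  invisible(paths)
}
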