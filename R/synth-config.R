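# Configuration for the synthetic-cohort and synthetic-slice generator.
#
# Defaults encode the study conditions the generator emulates: a
# population-based cohort of 335 adults, 95 obese (BMI >= 30), with
# obesity-stratified (and, for the MRI indices, sex-stratified) means and SDs
# of anthropometry, BIA indices and MRI muscle measures, plus within-stratum
# correlation targets chosen so that the cohort-level MRI-vs-BIA correlation
# structure (stronger concordance in non-obese than obese subjects) emerges
# from the Gaussian copula.

# continuous variables drawn from the copula, in fixed order
COPULA_VARS <- c(
  "age", "height", "bmi", "waist", "hip",
  "total_body_fat_mass_index", "lean_body_mass_index",
  "appendicular_muscle_mass_index", "smi_bia", "vat", "sat",
  "ammi_total", "ammi_fatfree", "pdff_muscle"
)

#' Default stratum marginals and correlation targets
#'
#' `default_marginals()` returns the per-stratum marginal means and SDs the
#' generator is calibrated to: obesity-split for all variables, additionally
#' sex-split for the MRI indices. Height is in metres, areas in mm^2
#' (indices mm^2/m^2), VAT/SAT in cm^2, PDFF in percent.
#'
#' `default_correlations()` returns the within-stratum correlation targets
#' over the copula variables. The fat-free index is drawn jointly with the
#' total index (the ratio is derived), so the concordance-relevant pairs are
#' targeted directly; remaining pairs carry physiologically plausible
#' neutral values. With `calibrated = TRUE` (the default) the matrix is made
#' positive semi-definite by alternating projections that keep the targeted
#' pairs exactly fixed while the neutral entries adjust.
#'
#' @return a tibble of `(variable, obese, sex, mean, sd)` rows, or a named
#'   correlation matrix.
#' @export
default_marginals <- function() {
  tibble::tribble(
    ~variable,                        ~obese, ~sex,     ~mean,   ~sd,
    "age",                            FALSE,  "both",   55.8,    9.1,
    "age",                            TRUE,   "both",   57.7,    9.1,
    "height",                         FALSE,  "both",   1.724,   0.096,
    "height",                         TRUE,   "both",   1.693,   0.094,
    "bmi",                            FALSE,  "both",   25.5,    2.7,
    "bmi",                            TRUE,   "both",   33.7,    3.3,
    "waist",                          FALSE,  "both",   92.2,    10.9,
    "waist",                          TRUE,   "both",   111.2,   9.4,
    "hip",                            FALSE,  "both",   102.7,   5.6,
    "hip",                            TRUE,   "both",   115.6,   7.8,
    "total_body_fat_mass_index",      FALSE,  "both",   7.6,     1.9,
    "total_body_fat_mass_index",      TRUE,   "both",   12.8,    3.0,
    "lean_body_mass_index",           FALSE,  "both",   17.8,    2.1,
    "lean_body_mass_index",           TRUE,   "both",   20.9,    1.9,
    "appendicular_muscle_mass_index", FALSE,  "both",   7.4,     1.1,
    "appendicular_muscle_mass_index", TRUE,   "both",   8.8,     1.0,
    "smi_bia",                        FALSE,  "both",   8.9,     1.5,
    "smi_bia",                        TRUE,   "both",   10.0,    1.5,
    "vat",                            FALSE,  "both",   122.6,   76.4,
    "vat",                            TRUE,   "both",   208.0,   73.4,
    "sat",                            FALSE,  "both",   229.5,   74.2,
    "sat",                            TRUE,   "both",   397.7,   117.7,
    "pdff_muscle",                    FALSE,  "both",   10.8,    4.3,
    "pdff_muscle",                    TRUE,   "both",   13.3,    5.2,
    "ammi_total",                     FALSE,  "male",   3101.8,  481.5,
    "ammi_total",                     FALSE,  "female", 2495.3,  389.6,
    "ammi_total",                     TRUE,   "male",   3501.1,  532.9,
    "ammi_total",                     TRUE,   "female", 2939.0,  547.9,
    "ammi_fatfree",                   FALSE,  "male",   1909.0,  442.9,
    "ammi_fatfree",                   FALSE,  "female", 1417.3,  367.8,
    "ammi_fatfree",                   TRUE,   "male",   1983.0,  564.5,
    "ammi_fatfree",                   TRUE,   "female", 1454.4,  282.5,
  )
}

# Values were solved from pooled-correlation decompositions so that the
# cohort-level Pearson correlations land on the targeted values
# (e.g. AMMI_total ~ lean body mass index r = 0.70, AMMI_fatfree ~ SMI
# r = 0.58) with distinctly stronger within-stratum coupling in non-obese
# than obese subjects.

#' @rdname default_marginals
#' @param stratum obesity stratum of the correlation targets.
#' @param calibrated return the PSD-reconciled matrix (default) or the raw
#'   targets.
#' @export
default_correlations <- function(stratum = c("non_obese", "obese"),
                                 calibrated = TRUE) {
  stratum <- match.arg(stratum)
  if (calibrated && !is.null(.mm_corr_cache[[stratum]])) {
    return(.mm_corr_cache[[stratum]])
  }
  p <- length(COPULA_VARS)
  R <- diag(p)
  dimnames(R) <- list(COPULA_VARS, COPULA_VARS)
  set_r <- function(a, b, non_obese, obese = non_obese) {
    val <- if (stratum == "non_obese") non_obese else obese
    R[a, b] <<- val
    R[b, a] <<- val
  }
  set_r("ammi_total", "lean_body_mass_index",           0.90, 0.57)
  set_r("ammi_total", "appendicular_muscle_mass_index", 0.85, 0.65)
  set_r("ammi_total", "smi_bia",                        0.80, 0.66)
  set_r("ammi_fatfree", "lean_body_mass_index",           0.70, 0.53)
  set_r("ammi_fatfree", "appendicular_muscle_mass_index", 0.74, 0.55)
  set_r("ammi_fatfree", "smi_bia",                        0.77, 0.55)
  set_r("ammi_total", "ammi_fatfree", 0.73, 0.67)
  set_r("ammi_total", "bmi", 0.45)
  set_r("ammi_fatfree", "bmi", 0.18)
  set_r("ammi_total", "waist", 0.54)
  set_r("ammi_fatfree", "waist", 0.25)
  set_r("ammi_total", "hip", 0.12)
  set_r("ammi_total", "height", 0.15)
  set_r("ammi_fatfree", "height", 0.15)
  set_r("lean_body_mass_index", "appendicular_muscle_mass_index", 0.80)
  set_r("lean_body_mass_index", "smi_bia", 0.75)
  set_r("appendicular_muscle_mass_index", "smi_bia", 0.72)
  # BIA indices co-vary with anthropometry (BMI is roughly lean + fat mass
  # per height^2); required for a coherent joint distribution
  set_r("lean_body_mass_index", "bmi", 0.65)
  set_r("lean_body_mass_index", "waist", 0.55)
  set_r("lean_body_mass_index", "hip", 0.35)
  set_r("appendicular_muscle_mass_index", "bmi", 0.55)
  set_r("appendicular_muscle_mass_index", "waist", 0.45)
  set_r("appendicular_muscle_mass_index", "hip", 0.30)
  set_r("smi_bia", "bmi", 0.50)
  set_r("smi_bia", "waist", 0.45)
  set_r("smi_bia", "hip", 0.28)
  set_r("lean_body_mass_index", "vat", 0.30)
  set_r("lean_body_mass_index", "sat", 0.20)
  set_r("appendicular_muscle_mass_index", "vat", 0.25)
  set_r("appendicular_muscle_mass_index", "sat", 0.20)
  set_r("smi_bia", "vat", 0.25)
  set_r("smi_bia", "sat", 0.15)
  set_r("total_body_fat_mass_index", "smi_bia", 0.15)
  set_r("total_body_fat_mass_index", "appendicular_muscle_mass_index", 0.15)
  set_r("ammi_total", "vat", 0.30)
  set_r("ammi_total", "sat", 0.20)
  set_r("ammi_total", "total_body_fat_mass_index", 0.25)
  set_r("ammi_fatfree", "vat", 0.10)
  set_r("bmi", "waist", 0.80)
  set_r("bmi", "hip", 0.70)
  set_r("bmi", "total_body_fat_mass_index", 0.75)
  set_r("waist", "hip", 0.60)
  set_r("waist", "total_body_fat_mass_index", 0.65)
  set_r("hip", "total_body_fat_mass_index", 0.60)
  set_r("bmi", "vat", 0.50)
  set_r("bmi", "sat", 0.55)
  set_r("waist", "vat", 0.60)
  set_r("waist", "sat", 0.45)
  set_r("hip", "vat", 0.30)
  set_r("hip", "sat", 0.50)
  set_r("vat", "sat", 0.35)
  set_r("total_body_fat_mass_index", "vat", 0.50)
  set_r("total_body_fat_mass_index", "sat", 0.55)
  set_r("total_body_fat_mass_index", "lean_body_mass_index", 0.10)
  set_r("pdff_muscle", "ammi_fatfree", -0.35)
  set_r("pdff_muscle", "ammi_total", 0.10)
  set_r("pdff_muscle", "bmi", 0.25)
  set_r("pdff_muscle", "vat", 0.30)
  set_r("pdff_muscle", "total_body_fat_mass_index", 0.25)
  set_r("pdff_muscle", "age", 0.25)
  set_r("pdff_muscle", "waist", 0.20)
  set_r("pdff_muscle", "sat", 0.15)
  set_r("pdff_muscle", "hip", 0.10)
  set_r("age", "ammi_total", -0.10)
  set_r("age", "ammi_fatfree", -0.25)
  set_r("age", "smi_bia", -0.20)
  set_r("age", "lean_body_mass_index", -0.05)
  set_r("age", "appendicular_muscle_mass_index", -0.10)
  set_r("age", "height", -0.10)
  set_r("height", "lean_body_mass_index", 0.10)
  set_r("height", "waist", 0.10)
  if (calibrated) {
    R <- reconcile_correlations(R)
    .mm_corr_cache[[stratum]] <- R
  }
  R
}

# pairs whose values drive the calibrated cohort-level statistics; held
# exactly fixed while the matrix is made positive semi-definite
calibration_pairs <- function() {
  list(
    c("ammi_total", "lean_body_mass_index"),
    c("ammi_total", "appendicular_muscle_mass_index"),
    c("ammi_total", "smi_bia"),
    c("ammi_fatfree", "lean_body_mass_index"),
    c("ammi_fatfree", "appendicular_muscle_mass_index"),
    c("ammi_fatfree", "smi_bia"),
    c("ammi_total", "ammi_fatfree"),
    c("ammi_total", "bmi"), c("ammi_fatfree", "bmi"),
    c("ammi_total", "waist"), c("ammi_fatfree", "waist"),
    c("ammi_total", "hip"),
    c("ammi_total", "height"), c("ammi_fatfree", "height"),
    c("pdff_muscle", "ammi_fatfree")
  )
}

# Dykstra alternating projections between the PSD cone and the affine set
# {unit diagonal, calibration pairs fixed}: yields the nearest consistent
# correlation matrix that preserves the targeted entries exactly while the
# neutral filler entries adjust.
reconcile_correlations <- function(R, eps = 1e-6, max_iter = 3000,
                                   tol = 1e-10) {
  hp <- calibration_pairs()
  targets <- vapply(hp, function(p) R[p[1], p[2]], numeric(1))
  dn <- dimnames(R)
  X <- R
  dS <- matrix(0, nrow(R), ncol(R))
  for (i in seq_len(max_iter)) {
    Y <- X + dS
    e <- eigen(Y, symmetric = TRUE)
    Xp <- e$vectors %*% diag(pmax(e$values, eps), nrow(R)) %*% t(e$vectors)
    dimnames(Xp) <- dn
    dS <- Y - Xp
    prev <- X
    X <- Xp
    diag(X) <- 1
    for (k in seq_along(hp)) {
      p <- hp[[k]]
      X[p[1], p[2]] <- X[p[2], p[1]] <- targets[k]
    }
    if (max(abs(X - prev)) < tol) break
  }
  X
}

.mm_corr_cache <- new.env(parent = emptyenv())

# compartment layout on the unit square: anatomically ordered rows
# (rectus anterior, psoas central, quadratus lateral, autochthonous
# posterior); aspect = x-semi-axis over y-semi-axis; area fractions of total
# CSA sum to 1.
default_compartment_geometry <- function() {
  tibble::tribble(
    ~compartment,      ~cx,  ~cy,  ~aspect, ~area_fraction,
    "psoas_L",         0.40, 0.46, 0.90,    0.12,
    "psoas_R",         0.60, 0.46, 0.90,    0.12,
    "quadratus_L",     0.26, 0.60, 1.40,    0.08,
    "quadratus_R",     0.74, 0.60, 1.40,    0.08,
    "rectus_L",        0.37, 0.20, 3.50,    0.10,
    "rectus_R",        0.63, 0.20, 3.50,    0.10,
    "autochthonous_L", 0.40, 0.78, 0.95,    0.20,
    "autochthonous_R", 0.60, 0.78, 0.95,    0.20,
  )
}

#' Generator configuration
#'
#' Assembles and validates the configuration for [generate_cohort()] and
#' [generate_pdff_slice()]. Defaults encode the emulated study: n = 335
#' subjects, obese fraction 95/335, male fractions 136/240 (non-obese) and
#' 52/95 (obese), obesity/sex-stratified marginal means and SDs of
#' anthropometry, BIA and MRI measures, and within-stratum correlation
#' targets (see `default_correlations`). Correlation matrices are projected
#' to positive semi-definite by eigenvalue clipping at construction.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed; the whole cohort (and its slices) is a
#'   deterministic function of the configuration and this seed.
#' @param obese_fraction probability of the obese stratum, in (0, 1).
#' @param male_fraction named vector: probability of male sex within each
#'   stratum (`non_obese`, `obese`).
#' @param stratum_marginals tibble of (variable, obese, sex, mean, sd).
#' @param correlation_targets list of two correlation matrices
#'   (`non_obese`, `obese`) over the copula variables.
#' @param grid_size voxels per image side.
#' @param pixel_spacing in-plane voxel edge in mm.
#' @param septum_fat_fraction_range fat-fraction interval (percent) for
#'   fatty-septum voxels; must lie strictly above the 20% threshold.
#' @param compartment_geometry tibble of per-compartment shape parameters
#'   (centre as grid fraction, aspect ratio, area fraction).
#' @param background_intensity intensity (0-1000) filling voxels outside the
#'   muscle masks (subcutaneous/visceral fat); never read by quantification.
#' @param glucose_impaired_rate,hypertension_rate per-stratum prevalences of
#'   the categorical risk-factor covariates.
#' @return a validated `generator_config` object (a list).
#' @export
generator_config <- function(n_subjects = 335,
                             seed = 20220125,
                             obese_fraction = 95 / 335,
                             male_fraction = c(non_obese = 136 / 240,
                                               obese = 52 / 95),
                             stratum_marginals = default_marginals(),
                             correlation_targets = list(
                               non_obese = default_correlations("non_obese"),
                               obese = default_correlations("obese")
                             ),
                             grid_size = 256,
                             pixel_spacing = 1.5,
                             septum_fat_fraction_range = c(20.2, 33),
                             compartment_geometry = default_compartment_geometry(),
                             background_intensity = 850,
                             glucose_impaired_rate = c(non_obese = 0.288,
                                                       obese = 0.611),
                             hypertension_rate = c(non_obese = 0.267,
                                                   obese = 0.484)) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    mm_abort("`n_subjects` must be >= 2", class = "musclemap_config_error")
  }
  if (!(obese_fraction > 0 && obese_fraction < 1)) {
    mm_abort("`obese_fraction` must lie strictly in (0, 1)",
             class = "musclemap_config_error")
  }
  if (!all(c("non_obese", "obese") %in% names(male_fraction)) ||
      any(male_fraction <= 0 | male_fraction >= 1)) {
    mm_abort("`male_fraction` needs non_obese/obese entries in (0, 1)",
             class = "musclemap_config_error")
  }
  need <- c("variable", "obese", "sex", "mean", "sd")
  if (!all(need %in% names(stratum_marginals))) {
    mm_abort("`stratum_marginals` must have columns variable/obese/sex/mean/sd",
             class = "musclemap_config_error")
  }
  if (any(stratum_marginals$sd <= 0)) {
    mm_abort("every marginal sd must be > 0", class = "musclemap_config_error")
  }
  marg_height <- stratum_marginals$mean[stratum_marginals$variable == "height"]
  if (length(marg_height) > 0 && any(marg_height <= 0)) {
    mm_abort("infeasible marginals: height must be positive",
             class = "musclemap_config_error")
  }
  if (!is.list(correlation_targets) ||
      !all(c("non_obese", "obese") %in% names(correlation_targets))) {
    mm_abort("`correlation_targets` must be a list(non_obese=, obese=)",
             class = "musclemap_config_error")
  }
  correlation_targets <- lapply(correlation_targets, function(R) {
    if (!all(COPULA_VARS %in% rownames(R))) {
      mm_abort("correlation matrix must cover all copula variables",
               class = "musclemap_config_error")
    }
    R <- R[COPULA_VARS, COPULA_VARS]
    if (any(abs(diag(R) - 1) > 1e-12)) {
      mm_abort("correlation matrix must have unit diagonal",
               class = "musclemap_config_error")
    }
    R <- project_psd(R)
    ch <- tryCatch(chol(R + diag(1e-10, nrow(R))), error = function(e) NULL)
    if (is.null(ch)) {
      mm_abort("correlation matrix still singular after PSD projection",
               class = "musclemap_config_error")
    }
    R
  })
  if (length(septum_fat_fraction_range) != 2 ||
      septum_fat_fraction_range[1] <= 20 ||
      diff(septum_fat_fraction_range) <= 0) {
    mm_abort("`septum_fat_fraction_range` must be an increasing interval strictly above 20%",
             class = "musclemap_config_error")
  }
  if (grid_size < 16) {
    mm_abort("`grid_size` must be at least 16", class = "musclemap_config_error")
  }
  if (pixel_spacing <= 0) {
    mm_abort("`pixel_spacing` must be positive", class = "musclemap_config_error")
  }
  geom <- compartment_geometry
  if (!setequal(geom$compartment, COMPARTMENTS) ||
      abs(sum(geom$area_fraction) - 1) > 1e-8) {
    mm_abort("`compartment_geometry` must cover the 8 compartments with area fractions summing to 1",
             class = "musclemap_config_error")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      seed = as.integer(seed),
      obese_fraction = obese_fraction,
      male_fraction = male_fraction,
      stratum_marginals = as_tibble(stratum_marginals),
      correlation_targets = correlation_targets,
      grid_size = as.integer(grid_size),
      pixel_spacing = pixel_spacing,
      septum_fat_fraction_range = septum_fat_fraction_range,
      compartment_geometry = as_tibble(geom),
      background_intensity = background_intensity,
      glucose_impaired_rate = glucose_impaired_rate,
      hypertension_rate = hypertension_rate
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> n =", x$n_subjects,
      "| obese fraction", sprintf("%.3f", x$obese_fraction),
      "| seed", x$seed, "\n")
  cat("  grid", x$grid_size, "x", x$grid_size, "@", x$pixel_spacing,
      "mm; septum fat", paste(x$septum_fat_fraction_range, collapse = "-"),
      "%\n")
  invisible(x)
}

#' Read a generator configuration from YAML
#'
#' Scalar fields override the defaults of [generator_config()]; marginals
#' and correlation targets may be supplied as data frames / matrices encoded
#' in YAML, otherwise the calibrated defaults are used.
#'
#' @param path path to a YAML file.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) {
    mm_abort(paste0("config file not found: ", path),
             class = "musclemap_config_error")
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      mm_abort(paste0("malformed YAML in ", path, ": ", conditionMessage(e)),
               class = "musclemap_config_error")
    }
  )
  if (!is.list(raw)) {
    mm_abort("config YAML must be a mapping", class = "musclemap_config_error")
  }
  allowed <- c("n_subjects", "seed", "obese_fraction", "grid_size",
               "pixel_spacing", "septum_fat_fraction_range",
               "background_intensity")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    mm_abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")),
             class = "musclemap_config_error")
  }
  do.call(generator_config, raw)
}
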