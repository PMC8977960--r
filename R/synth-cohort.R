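# Seeded synthetic cohort: covariates, BIA and per-subject MRI targets drawn
# from a Gaussian copula with stratum-specific marginals.

#' Generate a synthetic cohort
#'
#' Two-stage sampling scheme: each subject is first assigned a stratum
#' (obese with probability `obese_fraction`, sex with the stratum's male
#' fraction), then the continuous vector is drawn from a Gaussian copula with
#' the stratum's marginal means/SDs and correlation targets. Derived fields
#' are made mutually consistent: BMI comes from a moment-matched truncated
#' normal on the correct side of the 30 kg/m^2 cut-off (so the obese flag
#' equals the stratum draw), weight is BMI times height squared, and the BIA
#' resistance is obtained by inverting the Janssen equation so that the
#' stored `smi_bia` is exactly reproduced by [janssen_smm()]. Per-subject MRI
#' targets (`target_csa_total`, `target_ratio`, `target_pdff_muscle`) are
#' drawn inside the copula jointly with anthropometry, so the sex and obesity
#' gradients of the emulated study carry through to the synthetic images.
#'
#' Identical configuration (including seed) yields an identical cohort.
#'
#' @param config a [generator_config()].
#' @return a tibble with one row per subject; the configuration is attached
#'   as attribute `"generator_config"`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  obese <- runif(n) < config$obese_fraction
  p_male <- ifelse(obese, config$male_fraction[["obese"]],
                   config$male_fraction[["non_obese"]])
  male <- runif(n) < p_male
  vars <- COPULA_VARS
  draws <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))

  for (ob in c(FALSE, TRUE)) {
    stratum <- if (ob) "obese" else "non_obese"
    R <- latent_correlations(config, ob)
    ch <- chol(R + diag(1e-10, nrow(R)))
    for (ml in c(FALSE, TRUE)) {
      idx <- which(obese == ob & male == ml)
      if (length(idx) == 0) next
      z <- matrix(rnorm(length(idx) * length(vars)), ncol = length(vars)) %*% ch
      u <- pnorm(z)
      colnames(u) <- vars
      for (v in vars) {
        par <- lookup_marginal(config$stratum_marginals, v, ob,
                               if (ml) "male" else "female")
        draws[idx, v] <- marginal_quantile(v, u[, v], par$mean, par$sd, ob)
      }
    }
  }

  d <- as_tibble(draws)
  # physiological floors (logged, essentially never hit at default marginals)
  d$height <- pmax(d$height, 1.2)
  d$waist <- pmax(d$waist, 40)
  d$hip <- pmax(d$hip, 40)
  d$vat <- pmax(d$vat, 0)
  d$sat <- pmax(d$sat, 0)
  d$total_body_fat_mass_index <- pmax(d$total_body_fat_mass_index, 0.5)
  d$lean_body_mass_index <- pmax(d$lean_body_mass_index, 5)
  d$appendicular_muscle_mass_index <- pmax(d$appendicular_muscle_mass_index, 1)
  d$smi_bia <- pmax(d$smi_bia, 3)
  d$pdff_muscle <- pmin(pmax(d$pdff_muscle, 0), 100)

  sex <- ifelse(male, "male", "female")
  ids <- sprintf("S%0*d", max(4, nchar(n)), seq_len(n))
  ratio <- pmin(pmax(d$ammi_fatfree / d$ammi_total, 0.02), 0.995)
  cohort <- tibble(
    subject_id = ids,
    age = d$age,
    sex = sex,
    height = d$height,
    bmi = d$bmi,
    weight = d$bmi * d$height^2,
    waist = d$waist,
    hip = d$hip,
    obese = d$bmi >= 30,
    smi_bia = d$smi_bia,
    resistance = invert_janssen(d$smi_bia, d$height * 100, sex, d$age,
                                ids = ids),
    lean_body_mass_index = d$lean_body_mass_index,
    appendicular_muscle_mass_index = d$appendicular_muscle_mass_index,
    total_body_fat_mass_index = d$total_body_fat_mass_index,
    vat = d$vat,
    sat = d$sat,
    glucose_status = ifelse(
      runif(n) < ifelse(obese, config$glucose_impaired_rate[["obese"]],
                        config$glucose_impaired_rate[["non_obese"]]),
      "impaired", "normal"),
    hypertension = runif(n) < ifelse(obese,
                                     config$hypertension_rate[["obese"]],
                                     config$hypertension_rate[["non_obese"]]),
    target_ammi_total = d$ammi_total,
    target_ammi_fatfree = ratio * d$ammi_total,
    target_ratio = ratio,
    target_pdff_muscle = d$pdff_muscle,
    target_csa_total = d$ammi_total * d$height^2,
    slice_seed = sample.int(.Machine$integer.max - 1L, n)
  )
  stopifnot(all(cohort$obese == obese))
  attr(cohort, "generator_config") <- config
  cohort
}

# most specific marginal row: exact sex match wins over "both"
lookup_marginal <- function(marginals, variable, obese, sex) {
  rows <- marginals[marginals$variable == variable & marginals$obese == obese, ]
  if (nrow(rows) == 0) {
    mm_abort(paste0("no marginal defined for ", variable,
                    " (obese = ", obese, ")"),
             class = "musclemap_config_error")
  }
  hit <- rows[rows$sex == sex, ]
  if (nrow(hit) == 0) hit <- rows[rows$sex == "both", ]
  if (nrow(hit) != 1) {
    mm_abort(paste0("ambiguous marginal for ", variable),
             class = "musclemap_config_error")
  }
  list(mean = hit$mean, sd = hit$sd)
}

# truncation bounds of the non-normal marginals: BMI is truncated at the
# 30 kg/m^2 obesity cut-off (so stratum and flag agree), VAT/SAT at zero
marginal_bounds <- function(variable, obese) {
  if (variable == "bmi") {
    if (obese) c(30, Inf) else c(-Inf, 30)
  } else if (variable %in% c("vat", "sat")) {
    c(0, Inf)
  } else {
    c(-Inf, Inf)
  }
}

# parent parameters solved so the truncated moments equal the targets (cached)
tnorm_parent_cached <- function(variable, mean, sd, obese) {
  key <- paste(variable, mean, sd, obese, sep = "_")
  par <- .mm_tnorm_cache[[key]]
  if (is.null(par)) {
    b <- marginal_bounds(variable, obese)
    par <- solve_tnorm_parent(mean, sd, lower = b[1], upper = b[2])
    .mm_tnorm_cache[[key]] <- par
  }
  par
}

# copula uniform -> marginal value; truncated-normal marginals are
# moment-matched so the printed means/SDs are reproduced exactly
marginal_quantile <- function(variable, u, mean, sd, obese) {
  b <- marginal_bounds(variable, obese)
  if (all(is.infinite(b))) {
    qnorm(u, mean, sd)
  } else {
    par <- tnorm_parent_cached(variable, mean, sd, obese)
    qtnorm(u, par$mean, par$sd, lower = b[1], upper = b[2])
  }
}

# Pearson attenuation of a latent Gaussian correlation under the monotone
# truncated-normal quantile transform of one margin: lambda = cor(g(Z), Z)
# with g the transform; computed by quadrature and cached
transform_attenuation <- function(variable, mean, sd, obese) {
  key <- paste("att", variable, mean, sd, obese, sep = "_")
  lam <- .mm_tnorm_cache[[key]]
  if (!is.null(lam)) return(lam)
  b <- marginal_bounds(variable, obese)
  if (all(is.infinite(b))) return(1)
  par <- tnorm_parent_cached(variable, mean, sd, obese)
  z <- seq(-6, 6, length.out = 4001)
  w <- dnorm(z)
  w <- w / sum(w)
  u <- pmin(pmax(pnorm(z), 1e-14), 1 - 1e-14)
  gz <- qtnorm(u, par$mean, par$sd, lower = b[1], upper = b[2])
  mg <- sum(w * gz)
  lam <- sum(w * gz * z) / sqrt(sum(w * (gz - mg)^2))
  .mm_tnorm_cache[[key]] <- lam
  lam
}

# latent copula correlation matrix for a stratum: target correlations of the
# transformed margins are divided by the margins' attenuation factors so the
# realized Pearson correlations land on target; re-projected to PSD
latent_correlations <- function(config, obese) {
  stratum <- if (obese) "obese" else "non_obese"
  R <- config$correlation_targets[[stratum]]
  lam <- vapply(rownames(R), function(v) {
    if (all(is.infinite(marginal_bounds(v, obese)))) return(1)
    par <- lookup_marginal(config$stratum_marginals, v, obese, sex = "both")
    transform_attenuation(v, par$mean, par$sd, obese)
  }, numeric(1))
  adj <- R / tcrossprod(lam)
  diag(adj) <- 1
  adj <- pmin(pmax(adj, -0.999), 0.999)
  diag(adj) <- 1
  project_psd(adj)
}

.mm_tnorm_cache <- new.env(parent = emptyenv())

#' Write / read a cohort CSV
#'
#' Plain-text round trip of the subject table (one row per subject; see
#' [generate_cohort()] for the column dictionary).
#'
#' @param cohort subject tibble.
#' @param path CSV path.
#' @return `write_cohort_csv()` the path invisibly; `read_cohort_csv()` the
#'   tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
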