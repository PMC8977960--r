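# Bioelectrical-impedance analysis (BIA) equations.
#
# Skeletal muscle mass from whole-body impedance follows the Janssen
# regression: SMM (kg) = height_cm^2 / resistance * 0.401
#                        + sex * 3.825 + age * (-0.071) + 5.102
# with height in centimetres, resistance in ohms, sex coded male = 1 /
# female = 0 and age in years. The height-squared-normalized index
# (SMI, kg/m^2) uses height in metres.

JANSSEN_COEF <- c(impedance = 0.401, sex = 3.825, age = -0.071, intercept = 5.102)

#' Janssen skeletal muscle mass from bioelectrical impedance
#'
#' Computes whole-body skeletal muscle mass (kg) from the 50 kHz BIA
#' resistance via the Janssen equation
#' \deqn{SMM = 0.401 \, h_{cm}^2 / R + 3.825 \, sex - 0.071 \, age + 5.102}
#' where \eqn{sex} is 1 for male and 0 for female.
#'
#' @param resistance ohmic resistance in \eqn{\Omega} (positive).
#' @param height_cm body height in centimetres (positive).
#' @param age age in years (non-negative).
#' @param sex `"male"`/`"female"`, or the numeric coding 1/0.
#' @return skeletal muscle mass in kg (vectorized).
#' @examples
#' janssen_smm(500, 170, 56, "male")
#' @export
janssen_smm <- function(resistance, height_cm, age, sex) {
  sex <- encode_sex(sex)
  if (any(!is.finite(resistance) | resistance <= 0)) {
    mm_abort("`resistance` must be positive and finite")
  }
  if (any(!is.finite(height_cm) | height_cm <= 0)) {
    mm_abort("`height_cm` must be positive")
  }
  if (any(age < 0)) mm_abort("`age` must be non-negative")
  height_cm^2 / resistance * JANSSEN_COEF[["impedance"]] +
    sex * JANSSEN_COEF[["sex"]] +
    age * JANSSEN_COEF[["age"]] +
    JANSSEN_COEF[["intercept"]]
}

#' Skeletal muscle index: muscle mass normalized to height squared
#'
#' @param smm skeletal muscle mass in kg.
#' @param height_m body height in metres (positive).
#' @return index in kg/m^2.
#' @examples
#' smi_bia(janssen_smm(500, 170, 56, "male"), 1.70)
#' @export
smi_bia <- function(smm, height_m) {
  if (any(!is.finite(height_m) | height_m <= 0)) {
    mm_abort("`height_m` must be positive")
  }
  smm / height_m^2
}

#' Invert the Janssen equation for resistance
#'
#' Given a target skeletal muscle index (kg/m^2), solves the Janssen equation
#' for the resistance that reproduces it exactly. Used by the synthetic-cohort
#' generator so that stored resistances and SMI values are mutually consistent.
#'
#' @param smi_target target skeletal muscle index in kg/m^2.
#' @param height_cm body height in centimetres.
#' @param sex `"male"`/`"female"` or 1/0.
#' @param age age in years.
#' @param ids optional record identifiers used in error messages.
#' @return resistance in \eqn{\Omega} (vectorized).
#' @examples
#' invert_janssen(9.733, 170, "male", 56)
#' @export
invert_janssen <- function(smi_target, height_cm, sex, age, ids = NULL) {
  sex <- encode_sex(sex)
  height_m <- height_cm / 100
  smm <- smi_target * height_m^2
  denom <- smm - sex * JANSSEN_COEF[["sex"]] - age * JANSSEN_COEF[["age"]] -
    JANSSEN_COEF[["intercept"]]
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    mm_abort(
      paste0("no positive resistance reproduces the requested muscle index ",
             "for record(s): ", paste(head(lab, 5), collapse = ", ")),
      class = "musclemap_infeasible"
    )
  }
  JANSSEN_COEF[["impedance"]] * height_cm^2 / denom
}

#' Add Janssen BIA columns to a subject table
#'
#' Data-frame-first convenience verb: computes `smm_bia` and `smi_bia` from
#' `resistance`, `height`, `age` and `sex` columns (height in metres).
#'
#' @param data a data frame with columns `resistance`, `height`, `age`, `sex`.
#' @return the input as a tibble with `smm_bia` and `smi_bia` appended.
#' @export
add_bia <- function(data) {
  need <- c("resistance", "height", "age", "sex")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    mm_abort(paste0("missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             class = "musclemap_schema_error")
  }
  data %>%
    as_tibble() %>%
    mutate(
      smm_bia = janssen_smm(.data$resistance, .data$height * 100, .data$age,
                            .data$sex),
      smi_bia = smi_bia(.data$smm_bia, .data$height)
    )
}

# sex coding used throughout: male = 1, female = 0
encode_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) mm_abort("numeric `sex` must be 0 or 1")
    return(sex)
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    mm_abort("`sex` must be \"male\" or \"female\" (or 1/0)")
  }
  as.numeric(sex == "male")
}
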