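#' Single-species allometric scaling of Vd,ss
#'
#' Scales an animal volume of distribution to human, optionally correcting
#' for the species difference in plasma protein binding:
#' `V_human = V_animal * (fup_human / fup_animal)` with the correction on,
#' or `V_human = V_animal` (direct correlation) with it off. The uncorrected
#' variant matters in practice because errors in animal fup predictions are
#' magnified by the ratio.
#'
#' @param V_animal animal Vd,ss in L/kg, > 0 (vectorized).
#' @param fup_animal,fup_human fractions unbound in plasma, in (0, 1];
#'   required only when `fup_correction = TRUE`.
#' @param fup_correction apply the fup-ratio correction (default TRUE).
#' @return Predicted human Vd,ss in L/kg.
#' @examples
#' single_species_scale(1.0, fup_animal = 0.1, fup_human = 0.2)  # 2.0
#' single_species_scale(1.0, fup_correction = FALSE)             # 1.0
#' @export
single_species_scale <- function(V_animal, fup_animal = NA_real_,
                                 fup_human = NA_real_,
                                 fup_correction = TRUE) {
  if (any(is.na(V_animal) | V_animal <= 0)) {
    stop("animal Vd,ss must be positive")
  }
  if (!fup_correction) return(V_animal)
  if (any(is.na(fup_animal)) || any(is.na(fup_human))) {
    stop("fup correction requested but animal and/or human fup is missing")
  }
  if (any(fup_animal <= 0 | fup_animal > 1) ||
      any(fup_human <= 0 | fup_human > 1)) {
    stop("fup values must lie in (0, 1]")
  }
  V_animal * (fup_human / fup_animal)
}

#' Two-species (rat + dog) log-linear scaling of Vd,ss
#'
#' Combines rat and dog volumes of distribution in log10 space:
#' `V_human = 10^(a0 + a_r * log10(V_rat) + a_d * log10(V_dog))`. The
#' default coefficients `a0 = 0, a_r = a_d = 0.5` give the unweighted
#' geometric mean; fitted coefficients from a two-species calibration can be
#' supplied instead.
#'
#' @param V_rat,V_dog animal Vd,ss in L/kg, > 0 (vectorized).
#' @param coeffs list with `a0`, `a_r`, `a_d`; `a_r + a_d` must be > 0.
#' @return Predicted human Vd,ss in L/kg.
#' @examples
#' two_species_scale(1, 4)  # geometric mean = 2
#' @export
two_species_scale <- function(V_rat, V_dog,
                              coeffs = list(a0 = 0, a_r = 0.5, a_d = 0.5)) {
  if (any(is.na(V_rat) | V_rat <= 0) || any(is.na(V_dog) | V_dog <= 0)) {
    stop("animal Vd,ss must be positive")
  }
  if (coeffs$a_r + coeffs$a_d <= 0) {
    stop("two-species coefficients must satisfy a_r + a_d > 0")
  }
  10^(coeffs$a0 + coeffs$a_r * log10(V_rat) + coeffs$a_d * log10(V_dog))
}

#' Allometric Vd,ss predictions for a compound table
#'
#' Applies single-species (rat or dog) or two-species scaling to every
#' compound that carries the required animal data; compounds missing an
#' input are skipped for that method.
#'
#' @param compounds data frame with `compound_id` and, as available,
#'   `V_rat, fup_rat, V_dog, fup_dog, fup` (human fup).
#' @param method one of `"allometry_rat"`, `"allometry_dog"`,
#'   `"allometry_two_species"`.
#' @param fup_correction apply the fup-ratio correction for single-species
#'   methods.
#' @param coeffs two-species coefficients (see [two_species_scale()]).
#' @return Data frame with `compound_id, method_label, vdss_L_per_kg`; one
#'   row per eligible compound.
#' @export
predict_vdss_allometry <- function(compounds,
                                   method = c("allometry_rat",
                                              "allometry_dog",
                                              "allometry_two_species"),
                                   fup_correction = TRUE,
                                   coeffs = list(a0 = 0, a_r = 0.5,
                                                 a_d = 0.5)) {
  method <- match.arg(method)
  col <- function(name) {
    if (name %in% names(compounds)) compounds[[name]] else
      rep(NA_real_, nrow(compounds))
  }
  v_rat <- col("V_rat"); v_dog <- col("V_dog")
  fup_rat <- col("fup_rat"); fup_dog <- col("fup_dog")
  fup_h <- col("fup")
  pred <- rep(NA_real_, nrow(compounds))
  if (method == "allometry_two_species") {
    ok <- !is.na(v_rat) & v_rat > 0 & !is.na(v_dog) & v_dog > 0
    pred[ok] <- two_species_scale(v_rat[ok], v_dog[ok], coeffs)
  } else {
    v <- if (method == "allometry_rat") v_rat else v_dog
    fup_a <- if (method == "allometry_rat") fup_rat else fup_dog
    ok <- !is.na(v) & v > 0
    if (fup_correction) {
      ok <- ok & !is.na(fup_a) & fup_a > 0 & !is.na(fup_h) & fup_h > 0
    }
    pred[ok] <- single_species_scale(v[ok], fup_a[ok], fup_h[ok],
                                     fup_correction)
  }
  data.frame(compound_id = compounds$compound_id[!is.na(pred)],
             method_label = method,
             vdss_L_per_kg = pred[!is.na(pred)],
             stringsAsFactors = FALSE)
}
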