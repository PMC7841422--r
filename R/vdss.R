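#' Erythrocyte-to-plasma concentration ratio
#'
#' Converts a blood-to-plasma concentration ratio into the
#' erythrocyte-to-plasma ratio via `E/P = (BPR + Hct - 1) / Hct`. When BPR
#' falls below the physical floor `1 - Hct` (the drug would have negative
#' cell content) the ratio is floored at 0 with a warning.
#'
#' @param BPR blood-to-plasma ratio, >= 0.
#' @param Hct hematocrit, in (0, 1).
#' @return Non-negative scalar E/P.
#' @examples
#' erythrocyte_plasma_ratio(1, 0.45)   # 1
#' erythrocyte_plasma_ratio(2, 0.45)   # 3.222...
#' @export
erythrocyte_plasma_ratio <- function(BPR, Hct) {
  if (any(Hct <= 0 | Hct >= 1)) stop("hematocrit must lie in (0, 1)")
  if (any(BPR < 0)) stop("BPR must be >= 0")
  ep <- (BPR + Hct - 1) / Hct
  if (any(ep < 0)) {
    warning("BPR below the physical floor 1 - Hct; E/P floored at 0")
    ep <- pmax(ep, 0)
  }
  ep
}

#' Assemble whole-body Vd,ss from a Kp vector
#'
#' `Vd,ss = V_P + V_E * (E/P) + sum_T Kp_T * V_T`, in L/kg: plasma volume,
#' erythrocyte content converted to plasma reference, and each tissue
#' weighted by its plasma-referenced partition coefficient.
#'
#' @param kp a `kp_vector` from [kp_all_tissues()], or a named numeric
#'   vector of per-tissue Kp values covering every tissue in `physiology`.
#' @param physiology a `body_physiology`.
#' @param EP_ratio erythrocyte-to-plasma ratio from
#'   [erythrocyte_plasma_ratio()].
#' @param compound_id,method_label labels carried into the result.
#' @return One-row data frame with columns `compound_id`, `method_label`,
#'   `vdss_L_per_kg`, `EP_ratio`.
#' @export
vdss_from_kp <- function(kp, physiology, EP_ratio,
                         compound_id = NA_character_,
                         method_label = "mechanistic") {
  if (inherits(kp, "kp_vector")) {
    if (is.na(compound_id)) compound_id <- kp$compound_id
    kp <- kp$kp
  }
  tiss <- physiology$tissues$tissue
  missing_t <- setdiff(tiss, names(kp))
  if (length(missing_t) > 0) {
    stop("Kp vector is missing tissue(s): ", paste(missing_t, collapse = ", "))
  }
  if (EP_ratio < 0) stop("E/P ratio must be >= 0")
  vdss <- physiology$V_P + physiology$V_E * EP_ratio +
    sum(kp[tiss] * physiology$tissues$V_T)
  data.frame(compound_id = compound_id, method_label = method_label,
             vdss_L_per_kg = vdss, EP_ratio = EP_ratio,
             stringsAsFactors = FALSE)
}

#' Mechanistic Vd,ss for a table of compounds
#'
#' Runs the full mechanistic chain (calibration, per-tissue Kp, erythrocyte
#' partitioning, whole-body assembly) for every row of a compound table.
#' Compounds without a measured BPR use BPR = 1, the recommended fallback.
#' Calibration floor and E/P floor warnings are collected rather than
#' emitted per compound; counts are attached as the `"floor_events"`
#' attribute.
#'
#' @param compounds data frame with columns `compound_id, logP, fup` and
#'   optionally `logD74, pKa_acidic, pKa_basic, BPR, ionization_class`.
#' @param physiology a `body_physiology`.
#' @param method_label label recorded in the output (default
#'   `"mechanistic"`).
#' @return Data frame with one row per compound (columns as in
#'   [vdss_from_kp()]), plus `Ka_AP` and `Ka_PR`.
#' @export
predict_vdss_mechanistic <- function(compounds, physiology,
                                     method_label = "mechanistic") {
  floor_events <- character(0)
  run_row <- function(i) {
    cmp <- as_compound(compounds[i, , drop = FALSE])
    kp <- withCallingHandlers(
      kp_all_tissues(cmp, physiology),
      warning = function(w) {
        floor_events <<- c(floor_events, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    bpr <- if (is.na(cmp$BPR)) 1 else cmp$BPR
    ep <- withCallingHandlers(
      erythrocyte_plasma_ratio(bpr, physiology$Hct),
      warning = function(w) {
        floor_events <<- c(floor_events, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    out <- vdss_from_kp(kp, physiology, ep, method_label = method_label)
    out$Ka_AP <- kp$Ka_AP
    out$Ka_PR <- kp$Ka_PR
    out
  }
  res <- do.call(rbind, lapply(seq_len(nrow(compounds)), run_row))
  attr(res, "floor_events") <- floor_events
  res
}

#' Per-tissue Kp table for a set of compounds
#'
#' Long-format export of the mechanistic partition coefficients: one row per
#' compound and tissue with the calibrated constants alongside.
#'
#' @inheritParams predict_vdss_mechanistic
#' @return Data frame with columns `compound_id, tissue, Kp, Ka_AP, Ka_PR`.
#' @export
kp_table <- function(compounds, physiology) {
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    kp <- suppressWarnings(
      kp_all_tissues(compounds[i, , drop = FALSE], physiology))
    data.frame(compound_id = kp$compound_id, tissue = names(kp$kp),
               Kp = unname(kp$kp), Ka_AP = kp$Ka_AP, Ka_PR = kp$Ka_PR,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
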