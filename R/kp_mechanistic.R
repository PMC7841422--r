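#' Calibrate the tissue-protein association constant from plasma binding
#'
#' The unbound fraction in plasma fixes the drug's affinity for plasma
#' protein. Writing plasma as water + neutral lipid + neutral phospholipid +
#' protein (protein ratio 1 by definition) gives
#' `1/fup = 1 + P*f_NL_P + (0.3*P + 0.7)*f_NP_P + Ka_PR`, which is solved
#' for `Ka_PR` and floored at zero. The same constant, scaled by each
#' tissue's protein ratio, models extracellular protein binding in tissue.
#'
#' @param fup fraction unbound in plasma, in (0, 1].
#' @param logP log P of the neutral species (P = 10^logP enters the plasma
#'   lipid terms).
#' @param physiology a `body_physiology` supplying the plasma neutral-lipid
#'   and phospholipid fractions.
#' @return Non-negative scalar `Ka_PR`. A negative solution (very lipophilic
#'   compound with high fup) is floored at 0 with a warning.
#' @examples
#' phys <- load_physiology()
#' calibrate_ka_pr(fup = 0.5, logP = -30, phys)  # ~1 (1/fup - 1, less the
#'                                               # small phospholipid term)
#' @export
calibrate_ka_pr <- function(fup, logP, physiology) {
  if (is.na(fup) || fup <= 0 || fup > 1) stop("fup must lie in (0, 1]")
  P <- 10^logP
  lipid <- P * physiology$plasma$f_NL_P + (0.3 * P + 0.7) *
    physiology$plasma$f_NP_P
  ka <- 1 / fup - 1 - lipid
  if (ka < 0) {
    warning("protein affinity calibration negative (", signif(ka, 3),
            "); floored at 0")
    ka <- 0
  }
  ka
}

#' Calibrate the acidic-phospholipid association constant from BPR
#'
#' For compounds carrying a cationic species, partitioning into erythrocytes
#' in excess of water and neutral-lipid uptake is attributed to binding to
#' intracellular acidic phospholipids. The blood-cell-to-plasma-water
#' partition is obtained from the measured blood-to-plasma ratio,
#' `Kpu_BC = (BPR - (1 - Hct)) / (Hct * fup)`, and the association constant
#' is solved from the blood-cell composition:
#' `Ka_AP = [Kpu_BC - ((1+X_BC+Z_BC)/(1+X_P+Z_P))*f_IW_BC -
#' (P*f_NL_BC + (0.3P+0.7)*f_NP_BC)/(1+X_P+Z_P)] * (1+X_P+Z_P) /
#' (AP_BC * X_BC)`, floored at zero.
#'
#' Compounds with no cationic species at blood-cell pH return 0. A missing
#' BPR falls back to 1 (the recommended default when unmeasured). A BPR at
#' or below the physical floor `1 - Hct` (drug fully excluded from cells)
#' returns 0 with a warning naming the compound.
#'
#' @param compound a `compound_properties` (or coercible row).
#' @param physiology a `body_physiology`.
#' @return Non-negative scalar `Ka_AP` (per mg/g acidic phospholipid).
#' @export
calibrate_ka_ap <- function(compound, physiology) {
  cmp <- as_compound(compound)
  bc <- physiology$blood_cell
  Hct <- physiology$Hct
  if (Hct <= 0 || Hct >= 1) stop("hematocrit must lie in (0, 1)")
  BPR <- if (is.na(cmp$BPR)) 1 else cmp$BPR
  if (BPR < 0) stop("BPR must be >= 0")
  if (is.na(cmp$pKa_basic)) return(0)  # no cationic species anywhere

  r_bc <- species_ratios(cmp$pKa_acidic, cmp$pKa_basic, bc$pH_BC)
  if (r_bc$X == 0) return(0)
  kpu_bc <- (BPR - (1 - Hct)) / (Hct * cmp$fup)
  if (kpu_bc <= 0) {
    warning("compound ", cmp$compound_id, ": BPR ", signif(BPR, 3),
            " at or below the physical floor 1 - Hct; Ka_AP set to 0")
    return(0)
  }
  r_p <- species_ratios(cmp$pKa_acidic, cmp$pKa_basic, physiology$pH_P)
  ion_p <- 1 + r_p$X + r_p$Z
  P <- 10^cmp$logP
  water <- (1 + r_bc$X + r_bc$Z) / ion_p * bc$f_IW_BC
  lipid <- (P * bc$f_NL_BC + (0.3 * P + 0.7) * bc$f_NP_BC) / ion_p
  ka <- (kpu_bc - water - lipid) * ion_p / (bc$AP_BC * r_bc$X)
  if (ka < 0) {
    warning("compound ", cmp$compound_id,
            ": acidic-phospholipid calibration negative (", signif(ka, 3),
            "); floored at 0")
    ka <- 0
  }
  ka
}

#' Tissue-to-plasma-water partition coefficient (single continuous equation)
#'
#' Evaluates the unified tissue-composition equation: Kpu is the sum of an
#' extracellular-water term, an intracellular-water term carrying cytosolic
#' ion partitioning (pH gradient), a neutral-lipid/phospholipid term, an
#' acidic-phospholipid term for the cationic species, and an extracellular
#' protein term. All five terms are present for every compound regardless of
#' its pKa — terms vanish naturally when their driver (ionization, AP
#' concentration, protein affinity) is zero, so Kpu is continuous in every
#' input and there is no equation switch at any pKa.
#'
#' `Kpu = f_EW + ((1+X_T+Z_T)/(1+X_P+Z_P))*f_IW +
#' (P*f_NL + (0.3P+0.7)*f_NP)/(1+X_P+Z_P) +
#' Ka_AP*AP*X_T/(1+X_P+Z_P) + Ka_PR*RA`
#'
#' where X/Z are Henderson-Hasselbalch ratios at the tissue intracellular pH
#' (subscript T) and plasma pH (subscript P), `P = 10^logP`, and `RA` is the
#' tissue:plasma lipoprotein ratio for bases and albumin ratio otherwise.
#' For adipose the neutral-lipid term uses `10^logD74` in place of P
#' (vegetable-oil-like partitioning into bulk fat tracks log D); if `logD74`
#' is not supplied it is derived with [logd_from_logp()].
#'
#' @param compound a `compound_properties` (or coercible row).
#' @param tissue one or more rows of `physiology$tissues` (data frame with
#'   columns `tissue, f_EW, f_IW, f_NL, f_NP, AP, RA_alb, RA_lip, pH`).
#' @param Ka_AP,Ka_PR calibrated association constants from
#'   [calibrate_ka_ap()] and [calibrate_ka_pr()].
#' @param physiology a `body_physiology` (supplies plasma pH).
#' @return Numeric vector of Kpu values, one per tissue row.
#' @export
kpu_tissue <- function(compound, tissue, Ka_AP, Ka_PR, physiology) {
  cmp <- as_compound(compound)
  r_p <- species_ratios(cmp$pKa_acidic, cmp$pKa_basic, physiology$pH_P)
  ion_p <- 1 + r_p$X + r_p$Z
  r_t <- species_ratios(cmp$pKa_acidic, cmp$pKa_basic, tissue$pH)
  P <- 10^cmp$logP
  # adipose neutral lipid partitions with logD at pH 7.4 rather than logP
  logD <- if (is.na(cmp$logD74)) {
    logd_from_logp(cmp$logP, cmp$pKa_acidic, cmp$pKa_basic, 7.4)
  } else {
    cmp$logD74
  }
  P_NL <- ifelse(tissue$tissue == "adipose", 10^logD, P)
  RA <- if (identical(cmp$ionization_class, "base")) {
    tissue$RA_lip
  } else {
    tissue$RA_alb
  }
  tissue$f_EW +
    (1 + r_t$X + r_t$Z) / ion_p * tissue$f_IW +
    (P_NL * tissue$f_NL + (0.3 * P + 0.7) * tissue$f_NP) / ion_p +
    Ka_AP * tissue$AP * r_t$X / ion_p +
    Ka_PR * RA
}

#' Plasma-referenced Kp for every tissue of a physiology
#'
#' Calibrates `Ka_PR` (from fup) and `Ka_AP` (from BPR), evaluates
#' [kpu_tissue()] for every tissue, and converts to plasma-referenced
#' partition coefficients `Kp = fup * Kpu`.
#'
#' @param compound a `compound_properties` (or coercible row).
#' @param physiology a `body_physiology`.
#' @return An object of class `kp_vector`: list with `kp` (named numeric,
#'   one entry per tissue), `Ka_AP`, `Ka_PR`, `compound_id`.
#' @examples
#' phys <- load_physiology()
#' cmp <- compound_properties("ex", logP = 2, fup = 0.5, BPR = 1.5,
#'                            pKa_basic = 9)
#' kp_all_tissues(cmp, phys)
#' @export
kp_all_tissues <- function(compound, physiology) {
  cmp <- as_compound(compound)
  ka_pr <- calibrate_ka_pr(cmp$fup, cmp$logP, physiology)
  ka_ap <- calibrate_ka_ap(cmp, physiology)
  kpu <- kpu_tissue(cmp, physiology$tissues, ka_ap, ka_pr, physiology)
  kp <- cmp$fup * kpu
  names(kp) <- physiology$tissues$tissue
  structure(list(kp = kp, Ka_AP = ka_ap, Ka_PR = ka_pr,
                 compound_id = cmp$compound_id),
            class = "kp_vector")
}

#' @export
print.kp_vector <- function(x, ...) {
  cat(sprintf("kp_vector for %s (Ka_AP = %.4g, Ka_PR = %.4g)\n",
              x$compound_id, x$Ka_AP, x$Ka_PR))
  print(round(x$kp, 4))
  invisible(x)
}
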