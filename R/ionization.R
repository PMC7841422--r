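#' Henderson-Hasselbalch species ratios
#'
#' Ratios of ionized to un-ionized drug at a given pH for a compound with at
#' most one acidic and one basic pKa: the cationic ratio
#' `X = 10^(pKa_basic - pH)` and the anionic ratio `Z = 10^(pH - pKa_acidic)`.
#' Absent pKa values (NA) contribute zero. The un-ionized fraction is
#' `1 / (1 + X + Z)`.
#'
#' @param pKa_acidic acidic pKa, or `NA` if the compound has no acidic group.
#' @param pKa_basic basic pKa, or `NA` if no basic group.
#' @param pH the pH at which to evaluate the ratios; must lie in [0, 14].
#' @return A list with numeric elements `X` (cationic) and `Z` (anionic),
#'   vectorized over the inputs.
#' @examples
#' species_ratios(NA, NA, 7.4)            # neutral: X = Z = 0
#' species_ratios(4.4, NA, 7.4)$Z         # 10^(7.4 - 4.4) = 1000
#' species_ratios(NA, 7.4, 7.4)$X         # 1 (half ionized)
#' @export
species_ratios <- function(pKa_acidic = NA_real_, pKa_basic = NA_real_,
                           pH = 7.4) {
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  n <- max(length(pKa_acidic), length(pKa_basic), length(pH))
  pa <- rep_len(pKa_acidic, n)
  pb <- rep_len(pKa_basic, n)
  ph <- rep_len(pH, n)
  X <- ifelse(is.na(pb), 0, 10^(pb - ph))
  Z <- ifelse(is.na(pa), 0, 10^(ph - pa))
  list(X = as.numeric(X), Z = as.numeric(Z))
}

#' Classify a compound's ionization state
#'
#' Assigns one of `acid`, `base`, `neutral`, `zwitterion` from the pKa
#' values. A compound counts as acidic when an acidic pKa below 7.4 is
#' present and as basic when a basic pKa above 6.0 is present; both give
#' `zwitterion`, neither gives `neutral`.
#'
#' @param pKa_acidic acidic pKa or `NA`.
#' @param pKa_basic basic pKa or `NA`.
#' @return Character vector of class labels.
#' @examples
#' classify_ionization(4.0, NA)   # "acid"
#' classify_ionization(NA, 9.0)   # "base"
#' classify_ionization(4.0, 9.0)  # "zwitterion"
#' @export
classify_ionization <- function(pKa_acidic = NA_real_, pKa_basic = NA_real_) {
  n <- max(length(pKa_acidic), length(pKa_basic))
  pKa_acidic <- rep_len(pKa_acidic, n)
  pKa_basic <- rep_len(pKa_basic, n)
  is_acid <- !is.na(pKa_acidic) & pKa_acidic < 7.4
  is_base <- !is.na(pKa_basic) & pKa_basic > 6.0
  out <- rep("neutral", n)
  out[is_acid & !is_base] <- "acid"
  out[!is_acid & is_base] <- "base"
  out[is_acid & is_base] <- "zwitterion"
  out
}

#' Derive log D from log P by ionization correction
#'
#' `logD(pH) = logP - log10(1 + X + Z)` with the Henderson-Hasselbalch
#' ratios X and Z evaluated at the given pH. For a neutral compound
#' `logD = logP`; ionization always lowers the distribution coefficient.
#'
#' @param logP octanol-water log partition coefficient of the neutral
#'   species.
#' @param pKa_acidic,pKa_basic pKa values or `NA`.
#' @param pH the pH of the aqueous phase (default 7.4).
#' @return Numeric log D at the given pH.
#' @examples
#' logd_from_logp(3, NA, 9.4)   # 3 - log10(101)
#' logd_from_logp(2, 7.4, NA)   # 2 - log10(2)
#' @export
logd_from_logp <- function(logP, pKa_acidic = NA_real_, pKa_basic = NA_real_,
                           pH = 7.4) {
  if (any(!is.finite(logP))) stop("logP must be finite")
  r <- species_ratios(pKa_acidic, pKa_basic, pH)
  logP - log10(1 + r$X + r$Z)
}
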