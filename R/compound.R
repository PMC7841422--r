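#' Construct a validated compound property record
#'
#' Bundles the physicochemical inputs the mechanistic Kp/Vd,ss machinery
#' needs for one compound. Missing optional values are `NA`. The ionization
#' class is derived from the pKa values via [classify_ionization()] unless
#' supplied.
#'
#' @param compound_id identifier (character).
#' @param logP octanol-water log P of the neutral species (finite; assay
#'   limits [-3, 10] are enforced at table validation/clipping, not here).
#' @param fup fraction unbound in plasma, in (0, 1]. Required: the protein
#'   affinity term cannot be calibrated without it.
#' @param BPR blood-to-plasma concentration ratio, >= 0; `NA` means
#'   unmeasured (downstream code falls back to BPR = 1).
#' @param pKa_acidic,pKa_basic optional pKa values in [-2, 16].
#' @param logD74 optional measured log D at pH 7.4; when absent it is
#'   derived from logP by [logd_from_logp()] where needed.
#' @param ionization_class optional override of the derived class.
#' @return A list of class `compound_properties`.
#' @examples
#' compound_properties("drugA", logP = 2, fup = 0.5, BPR = 1.5,
#'                     pKa_basic = 9)
#' @export
compound_properties <- function(compound_id, logP, fup, BPR = NA_real_,
                                pKa_acidic = NA_real_, pKa_basic = NA_real_,
                                logD74 = NA_real_,
                                ionization_class = NULL) {
  if (is.na(fup) || fup <= 0 || fup > 1) {
    stop("fup must lie in (0, 1] for compound ", compound_id)
  }
  if (!is.na(BPR) && BPR < 0) {
    stop("BPR must be >= 0 for compound ", compound_id)
  }
  if (is.na(logP) || !is.finite(logP)) {
    stop("logP must be finite for compound ", compound_id)
  }
  for (pk in c(pKa_acidic, pKa_basic)) {
    if (!is.na(pk) && (pk < -2 || pk > 16)) {
      stop("pKa values must lie in [-2, 16] for compound ", compound_id)
    }
  }
  if (is.null(ionization_class)) {
    ionization_class <- classify_ionization(pKa_acidic, pKa_basic)
  }
  structure(
    list(compound_id = as.character(compound_id), logP = logP,
         logD74 = logD74, pKa_acidic = pKa_acidic, pKa_basic = pKa_basic,
         fup = fup, BPR = BPR, ionization_class = ionization_class),
    class = "compound_properties"
  )
}

# Coerce a one-row data frame (or list) to compound_properties, filling
# absent optional columns with NA.
as_compound <- function(row) {
  if (inherits(row, "compound_properties")) return(row)
  g <- function(field) {
    v <- row[[field]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }
  cls <- row[["ionization_class"]]
  if (!is.null(cls) && (is.na(cls) || !nzchar(cls))) cls <- NULL
  compound_properties(
    compound_id = row[["compound_id"]],
    logP = g("logP"), fup = g("fup"), BPR = g("BPR"),
    pKa_acidic = g("pKa_acidic"), pKa_basic = g("pKa_basic"),
    logD74 = g("logD74"), ionization_class = cls
  )
}

#' @export
print.compound_properties <- function(x, ...) {
  cat(sprintf("compound %s [%s]: logP %.2f, fup %.4g, BPR %s\n",
              x$compound_id, x$ionization_class, x$logP, x$fup,
              ifelse(is.na(x$BPR), "NA", format(x$BPR))))
  invisible(x)
}
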