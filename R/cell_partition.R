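#' Cellular volume from well protein content
#'
#' Converts the protein mass measured in a culture well into a cell volume
#' assuming 6.5 ul of cell volume per mg protein.
#'
#' @param protein_mg protein per well in mg, > 0.
#' @return Cell volume in ul.
#' @examples
#' cell_volume(10)  # 65 ul
#' @export
cell_volume <- function(protein_mg) {
  if (any(is.na(protein_mg) | protein_mg <= 0)) {
    stop("protein mass must be positive")
  }
  6.5 * protein_mg
}

#' Intracellular partition coefficient from assay readouts
#'
#' Converts adipocyte/myocyte uptake readouts into intracellular-to-medium
#' partition coefficients. Per replicate: the amount in cells is the
#' cell-lysate peak-area ratio times the lysate volume (150 ul by default),
#' the intracellular concentration divides that by the cell volume
#' ([cell_volume()]), and Kp_cell is the ratio of intracellular to
#' (corrected) medium concentration. Replicates are computed individually
#' and then averaged per compound and cell type.
#'
#' Rows with zero medium signal are analytical failures: they are excluded
#' with a warning (mirroring the removal of compounds with analytical or
#' recovery issues) and listed in the `"excluded"` attribute of the result.
#'
#' @param readouts data frame with columns `compound_id`, `cell_type`
#'   (`"adipocyte"` or `"myocyte"`), `area_ratio_cells`,
#'   `area_ratio_medium`, `protein_mg`, and optionally `V_lysate` (ul,
#'   default 150) and `replicate`.
#' @return Data frame with one row per compound x cell type: `compound_id`,
#'   `cell_type`, `Kp_cell`, `n_replicates`.
#' @examples
#' r <- data.frame(compound_id = "a", cell_type = "adipocyte",
#'                 area_ratio_cells = 1.3, area_ratio_medium = 0.03,
#'                 protein_mg = 10)
#' intracellular_kp(r)$Kp_cell  # (1.3 * 150 / 65) / 0.03 = 100
#' @export
intracellular_kp <- function(readouts) {
  if (!"V_lysate" %in% names(readouts)) readouts$V_lysate <- 150
  if (any(readouts$area_ratio_cells < 0) || any(readouts$protein_mg <= 0)) {
    stop("area ratios must be >= 0 and protein mass positive")
  }
  bad <- readouts$area_ratio_medium <= 0
  excluded <- unique(readouts$compound_id[bad])
  if (length(excluded) > 0) {
    warning("zero medium signal (analytical failure); excluding replicate(s) ",
            "of compound(s): ", paste(excluded, collapse = ", "))
  }
  ok <- readouts[!bad, , drop = FALSE]
  if (nrow(ok) == 0) {
    out <- data.frame(compound_id = character(0), cell_type = character(0),
                      Kp_cell = numeric(0), n_replicates = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }
  amount_cells <- ok$area_ratio_cells * ok$V_lysate
  conc_cells <- amount_cells / cell_volume(ok$protein_mg)
  kp_rep <- conc_cells / ok$area_ratio_medium
  agg <- stats::aggregate(kp_rep,
                          by = list(compound_id = ok$compound_id,
                                    cell_type = ok$cell_type),
                          FUN = mean)
  n <- stats::aggregate(kp_rep,
                        by = list(compound_id = ok$compound_id,
                                  cell_type = ok$cell_type),
                        FUN = length)
  out <- data.frame(compound_id = agg$compound_id, cell_type = agg$cell_type,
                    Kp_cell = agg$x, n_replicates = as.integer(n$x),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Plasma-reference a cell partition coefficient
#'
#' Cell-partition assays run in (near) protein-free medium, so the measured
#' Kp_cell is referenced to unbound drug. Referencing to total plasma
#' multiplies by the fraction unbound: `Kp_tissue = Kp_cell * fup`
#' (`convention = "multiply"`, default). The inverse convention
#' (`"divide"`) is available for workflows that treat the medium as
#' plasma-like.
#'
#' @param Kp_cell intracellular partition coefficient, >= 0 (vectorized).
#' @param fup fraction unbound in plasma, in (0, 1].
#' @param convention `"multiply"` (default) or `"divide"`.
#' @return Plasma-referenced tissue Kp.
#' @examples
#' plasma_referenced_kp(100, 0.1)  # 10
#' @export
plasma_referenced_kp <- function(Kp_cell, fup,
                                 convention = c("multiply", "divide")) {
  convention <- match.arg(convention)
  if (any(is.na(fup) | fup <= 0 | fup > 1)) stop("fup must lie in (0, 1]")
  if (any(Kp_cell < 0)) stop("Kp_cell must be >= 0")
  if (convention == "multiply") Kp_cell * fup else Kp_cell / fup
}

#' Vd,ss from adipocyte/myocyte Kp via a tissue-level strategy
#'
#' Builds a full per-tissue Kp vector from measured fat and/or muscle
#' partition coefficients under one of five strategies, then assembles
#' Vd,ss with [vdss_from_kp()]:
#' \describe{
#'   \item{adipocyte_only}{fat = `Kp_fat`, all other tissues Kp = 1}
#'   \item{myocyte_only}{muscle = `Kp_muscle`, all other tissues Kp = 1}
#'   \item{combined}{fat and muscle measured, all other tissues Kp = 1}
#'   \item{average}{fat and muscle measured, other tissues get
#'     `(Kp_fat + Kp_muscle) / 2`}
#'   \item{separate}{fat and muscle measured, other tissues from the
#'     mechanistic `kp_vector`}
#' }
#' The erythrocyte term uses the compound's BPR (1 when unmeasured).
#'
#' @param strategy one of the five strategy names above.
#' @param Kp_fat,Kp_muscle plasma-referenced fat/muscle Kp (from
#'   [plasma_referenced_kp()]); each required only where the strategy uses
#'   it.
#' @param compound a `compound_properties` (or coercible row); supplies BPR
#'   and the id.
#' @param physiology a `body_physiology`.
#' @param mechanistic_kp a `kp_vector`, required for `"separate"`.
#' @return One-row data frame as from [vdss_from_kp()], with `method_label`
#'   set to the strategy name.
#' @export
strategy_vdss <- function(strategy = c("adipocyte_only", "myocyte_only",
                                       "combined", "average", "separate"),
                          Kp_fat = NA_real_, Kp_muscle = NA_real_,
                          compound, physiology, mechanistic_kp = NULL) {
  strategy <- match.arg(strategy)
  cmp <- as_compound(compound)
  needs_fat <- strategy != "myocyte_only"
  needs_muscle <- strategy != "adipocyte_only"
  if (needs_fat && is.na(Kp_fat)) {
    stop("strategy '", strategy, "' requires Kp_fat")
  }
  if (needs_muscle && is.na(Kp_muscle)) {
    stop("strategy '", strategy, "' requires Kp_muscle")
  }
  tiss <- physiology$tissues$tissue
  kp <- switch(strategy,
    adipocyte_only = ,
    myocyte_only = ,
    combined = stats::setNames(rep(1, length(tiss)), tiss),
    average = stats::setNames(rep((Kp_fat + Kp_muscle) / 2, length(tiss)),
                              tiss),
    separate = {
      if (is.null(mechanistic_kp)) {
        stop("strategy 'separate' requires a mechanistic kp_vector")
      }
      mechanistic_kp$kp
    }
  )
  if (needs_fat) kp[["adipose"]] <- Kp_fat
  if (needs_muscle) kp[["muscle"]] <- Kp_muscle
  bpr <- if (is.na(cmp$BPR)) 1 else cmp$BPR
  ep <- erythrocyte_plasma_ratio(bpr, physiology$Hct)
  vdss_from_kp(kp, physiology, ep, compound_id = cmp$compound_id,
               method_label = strategy)
}
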