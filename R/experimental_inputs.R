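#' ChromlogD at pH 7.4 from the chromatographic hydrophobicity index
#'
#' Linear transform of a CHI measurement into a chromatographic log D at
#' pH 7.4: `ChromlogD = 0.0857 * CHI - 2.00`.
#'
#' @param CHI chromatographic hydrophobicity index (vectorized).
#' @return ChromlogD at pH 7.4.
#' @examples
#' chromlogd_from_chi(c(0, 50, 100))  # -2.00, 2.285, 6.57
#' @export
chromlogd_from_chi <- function(CHI) {
  if (any(!is.finite(CHI))) stop("CHI must be finite")
  0.0857 * CHI - 2.00
}

# Assay limits applied to model-predicted inputs.
.assay_limits <- list(
  fup = c(0.001, 1),   # 0.1% - 100%
  BPR = c(0, 200),
  logP = c(-3, 10),
  logD74 = c(-3, 10)
)

#' Clip predicted input parameters to typical assay limits
#'
#' Model-predicted inputs can fall outside the range any assay could
#' report; before they enter the mechanistic equations they are clipped to
#' typical assay limits: fup to [0.001, 1] (0.1%-100%), BPR to [0, 200],
#' log P and log D to [-3, 10]. Only columns named in `predicted` are
#' clipped — measured values are never silently altered. Clipping is
#' idempotent. Every clip event is recorded in the `"clip_events"`
#' attribute (compound_id, field, original and clipped value).
#'
#' @param compounds data frame of compound properties.
#' @param predicted character vector of column names that hold predicted
#'   (rather than measured) values; defaults to all four limited fields.
#' @return The compound table with predicted fields clipped;
#'   `attr(, "clip_events")` holds the event log.
#' @export
clip_to_assay_limits <- function(compounds,
                                 predicted = c("fup", "BPR", "logP",
                                               "logD74")) {
  events <- data.frame(compound_id = character(0), field = character(0),
                       original = numeric(0), clipped = numeric(0),
                       stringsAsFactors = FALSE)
  for (field in intersect(predicted, names(.assay_limits))) {
    if (!field %in% names(compounds)) next
    lim <- .assay_limits[[field]]
    x <- compounds[[field]]
    clipped <- pmin(pmax(x, lim[1]), lim[2])
    moved <- which(!is.na(x) & x != clipped)
    if (length(moved) > 0) {
      events <- rbind(events, data.frame(
        compound_id = as.character(compounds$compound_id[moved]),
        field = field, original = x[moved], clipped = clipped[moved],
        stringsAsFactors = FALSE))
    }
    compounds[[field]] <- clipped
  }
  attr(compounds, "clip_events") <- events
  compounds
}

#' Read and validate a compound property table
#'
#' Reads a delimited compound table (comma default, tab accepted via `sep`),
#' matching headers case-insensitively against the documented schema:
#' `compound_id, logP, fup` required; `logD74, pKa_acidic, pKa_basic, BPR,
#' ionization_class, vdss_obs, CHI, Kp_cell_adipocyte, Kp_cell_myocyte,
#' V_rat, fup_rat, V_dog, fup_dog, SMILES` optional. Empty cells are missing
#' values. fup given in percent (any value > 1 in the column) is detected
#' and divided by 100 with a notice. Rows failing validation (duplicate id,
#' fup outside (0, 1], non-positive observed Vd,ss, logP outside [-3, 10])
#' are collected into a rejects table rather than aborting the batch.
#'
#' @param path file path.
#' @param sep field separator; `","` default, `"\t"` accepted.
#' @return Data frame of valid compounds; `attr(, "rejects")` is a data
#'   frame (`compound_id`, `reason`) of rejected rows.
#' @export
read_compound_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cannot read compound table: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  schema <- c("compound_id", "logP", "fup", "logD74", "pKa_acidic",
              "pKa_basic", "BPR", "ionization_class", "vdss_obs", "CHI",
              "Kp_cell_adipocyte", "Kp_cell_myocyte", "V_rat", "fup_rat",
              "V_dog", "fup_dog", "SMILES")
  idx <- match(tolower(names(tab)), tolower(schema))
  names(tab)[!is.na(idx)] <- schema[idx[!is.na(idx)]]
  required <- c("compound_id", "logP", "fup")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("compound table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  # percent-scale fup auto-detection
  if (any(tab$fup > 1, na.rm = TRUE)) {
    message("fup column contains values > 1; interpreting as percent and ",
            "dividing by 100")
    tab$fup <- tab$fup / 100
  }
  reject <- character(nrow(tab))
  dup <- duplicated(tab$compound_id)
  reject[dup] <- "duplicate compound_id"
  bad_fup <- is.na(tab$fup) | tab$fup <= 0 | tab$fup > 1
  reject[!nzchar(reject) & bad_fup] <- "fup missing or outside (0, 1]"
  bad_logp <- is.na(tab$logP) | tab$logP < -3 | tab$logP > 10
  reject[!nzchar(reject) & bad_logp] <- "logP missing or outside [-3, 10]"
  if ("vdss_obs" %in% names(tab)) {
    bad_obs <- !is.na(tab$vdss_obs) & tab$vdss_obs <= 0
    reject[!nzchar(reject) & bad_obs] <- "observed vdss must be positive"
  }
  if ("BPR" %in% names(tab)) {
    bad_bpr <- !is.na(tab$BPR) & tab$BPR < 0
    reject[!nzchar(reject) & bad_bpr] <- "BPR must be >= 0"
  }
  rejects <- data.frame(compound_id = as.character(tab$compound_id),
                        reason = reject,
                        stringsAsFactors = FALSE)[nzchar(reject), ]
  rownames(rejects) <- NULL
  out <- tab[!nzchar(reject), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) stop("compound table contains no valid rows")
  if (!"ionization_class" %in% names(out)) {
    pka_a <- if ("pKa_acidic" %in% names(out)) out$pKa_acidic else NA_real_
    pka_b <- if ("pKa_basic" %in% names(out)) out$pKa_basic else NA_real_
    out$ionization_class <- classify_ionization(pka_a, pka_b)
  }
  attr(out, "rejects") <- rejects
  out
}

#' Write predictions (and optional evaluation report) to disk
#'
#' Writes the prediction table as delimited text; when a report is supplied
#' it is written alongside as JSON and as a delimited table mirroring the
#' method-comparison layout (n, % within 2/3/10-fold, r2, AAFE).
#'
#' @param path output path for the prediction table (CSV).
#' @param predictions data frame with at least
#'   `compound_id, method_label, vdss_L_per_kg`.
#' @param report optional evaluation report from [evaluate_methods()];
#'   written to `<path stem>_report.json` and `<path stem>_report.csv`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(path, predictions, report = NULL) {
  utils::write.csv(predictions, path, row.names = FALSE, quote = FALSE)
  if (!is.null(report)) {
    stem <- sub("\\.[^.]+$", "", path)
    jsonlite::write_json(report, paste0(stem, "_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.csv(report, paste0(stem, "_report.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
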