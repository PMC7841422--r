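#' Run the full Vd,ss prediction pipeline
#'
#' Orchestrates an end-to-end run: read (or accept) a compound table, clip
#' predicted inputs to assay limits, generate Vd,ss predictions for every
#' selected method, evaluate against observed values when present, and
#' write a prediction table, evaluation report, rejects table and a
#' machine-readable run manifest.
#'
#' Config keys (a named list, or the path to a YAML file with the same
#' keys): `physiology` (packaged name or file, default `"human_70kg"`);
#' `methods` (character vector out of `mechanistic`, `allometry_rat`,
#' `allometry_dog`, `allometry_two_species`, `adipocyte_only`,
#' `myocyte_only`, `combined`, `average`, `separate`; default
#' `"mechanistic"`); `fup_correction` (single-species allometry, default
#' TRUE); `two_species` (list `a0, a_r, a_d`); `cell_kp_convention`
#' (`"multiply"` or `"divide"`, see [plasma_referenced_kp()]);
#' `predicted_fields` (columns treated as model predictions and clipped,
#' default none — inputs are assumed measured); `out` (output directory;
#' omit to skip writing); `seed` (recorded in the manifest).
#'
#' Compounds missing the inputs a method needs are skipped for that method
#' (not for the run), so per-method n varies; skip counts appear in the
#' manifest. The `separate` strategy requires `mechanistic` to be selected.
#'
#' @param input compound table: a data frame or the path of a delimited
#'   file for [read_compound_table()].
#' @param config named list or YAML file path, see above.
#' @return List with `predictions` (data frame), `report` (data frame or
#'   NULL when no observed values), `manifest` (list), `rejects`
#'   (data frame).
#' @examples
#' cmp <- sample_compounds(simulation_config(n_compounds = 10, seed = 7))
#' res <- run_pipeline(cmp, list(methods = "mechanistic"))
#' res$predictions
#' @export
run_pipeline <- function(input, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(physiology = "human_70kg", methods = "mechanistic",
                   fup_correction = TRUE,
                   two_species = list(a0 = 0, a_r = 0.5, a_d = 0.5),
                   cell_kp_convention = "multiply",
                   predicted_fields = character(0), out = NULL,
                   seed = NA_integer_)
  config <- utils::modifyList(defaults, config)
  methods <- config$methods
  if (length(methods) == 0) stop("config must select at least one method")
  known <- c("mechanistic", "allometry_rat", "allometry_dog",
             "allometry_two_species", "adipocyte_only", "myocyte_only",
             "combined", "average", "separate")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if ("separate" %in% methods && !"mechanistic" %in% methods) {
    stop("strategy 'separate' requires method 'mechanistic' to be selected")
  }

  phys <- load_physiology(config$physiology)
  if (is.character(input)) {
    compounds <- read_compound_table(input)
    rejects <- attr(compounds, "rejects")
  } else {
    compounds <- input
    rejects <- data.frame(compound_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  }
  compounds <- clip_to_assay_limits(compounds,
                                    predicted = config$predicted_fields)
  clip_events <- attr(compounds, "clip_events")

  strategies <- intersect(methods, c("adipocyte_only", "myocyte_only",
                                     "combined", "average", "separate"))
  skipped <- list()
  preds <- list()
  floor_events <- character(0)

  if ("mechanistic" %in% methods || length(strategies) > 0) {
    ok <- !is.na(compounds$fup) & !is.na(compounds$logP)
    skipped$mechanistic <- sum(!ok)
    mech <- predict_vdss_mechanistic(compounds[ok, , drop = FALSE], phys)
    floor_events <- c(floor_events, attr(mech, "floor_events"))
    if ("mechanistic" %in% methods) {
      preds$mechanistic <- mech[, c("compound_id", "method_label",
                                    "vdss_L_per_kg")]
    }
  }
  for (m in intersect(methods, c("allometry_rat", "allometry_dog",
                                 "allometry_two_species"))) {
    p <- predict_vdss_allometry(compounds, m,
                                fup_correction = config$fup_correction,
                                coeffs = config$two_species)
    skipped[[m]] <- nrow(compounds) - nrow(p)
    preds[[m]] <- p
  }
  if (length(strategies) > 0) {
    for (strat in strategies) {
      rows <- lapply(seq_len(nrow(compounds)), function(i) {
        row <- compounds[i, , drop = FALSE]
        kc_fat <- if ("Kp_cell_adipocyte" %in% names(row)) {
          row$Kp_cell_adipocyte
        } else {
          NA_real_
        }
        kc_mus <- if ("Kp_cell_myocyte" %in% names(row)) {
          row$Kp_cell_myocyte
        } else {
          NA_real_
        }
        kp_fat <- if (!is.na(kc_fat)) {
          plasma_referenced_kp(kc_fat, row$fup, config$cell_kp_convention)
        } else {
          NA_real_
        }
        kp_mus <- if (!is.na(kc_mus)) {
          plasma_referenced_kp(kc_mus, row$fup, config$cell_kp_convention)
        } else {
          NA_real_
        }
        need_fat <- strat != "myocyte_only"
        need_mus <- strat != "adipocyte_only"
        if ((need_fat && is.na(kp_fat)) || (need_mus && is.na(kp_mus))) {
          return(NULL)
        }
        mech_kp <- if (strat == "separate") {
          suppressWarnings(kp_all_tissues(row, phys))
        } else {
          NULL
        }
        suppressWarnings(
          strategy_vdss(strat, kp_fat, kp_mus, row, phys, mech_kp))
      })
      got <- do.call(rbind, rows)
      skipped[[strat]] <- nrow(compounds) - sum(!vapply(rows, is.null,
                                                        logical(1)))
      if (!is.null(got)) preds[[strat]] <- got[, c("compound_id",
                                                   "method_label",
                                                   "vdss_L_per_kg")]
    }
  }
  predictions <- do.call(rbind, unname(preds))
  if (is.null(predictions) || nrow(predictions) == 0) {
    stop("no method produced a prediction for any compound")
  }
  rownames(predictions) <- NULL

  report <- NULL
  if ("vdss_obs" %in% names(compounds) &&
      any(!is.na(compounds$vdss_obs))) {
    report <- evaluate_methods(predictions,
                               compounds[, c("compound_id", "vdss_obs")])
  }

  manifest <- list(
    package = "vdsspredict",
    version = as.character(utils::packageVersion("vdsspredict")),
    seed = config$seed,
    physiology = config$physiology,
    methods = methods,
    config = config[c("fup_correction", "two_species",
                      "cell_kp_convention", "predicted_fields")],
    n_compounds = nrow(compounds),
    n_rejected = nrow(rejects),
    n_clip_events = nrow(clip_events),
    n_floor_events = length(floor_events),
    skipped_per_method = skipped
  )

  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    write_predictions(file.path(config$out, "predictions.csv"),
                      predictions, report)
    utils::write.csv(rejects, file.path(config$out, "rejects.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(predictions = predictions, report = report, manifest = manifest,
       rejects = rejects)
}
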