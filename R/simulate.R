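#' Configuration for the synthetic compound generator
#'
#' Collects the distributional assumptions the generator uses to emulate a
#' drug-discovery compound set: a mix of ionization classes, a truncated
#' normal log P, uniform pKa values on class-typical ranges, a logit-normal
#' fup that decreases with lipophilicity, a blood-to-plasma ratio built from
#' a latent blood-cell partition (so BPR >= 1 - Hct by construction, with
#' basic compounds reaching larger values through acidic-phospholipid-like
#' uptake), and log-normal multiplicative observation noise on Vd,ss.
#'
#' @param n_compounds number of compounds to draw (default 254, a typical
#'   curated clinical-set size).
#' @param class_probabilities named probabilities over
#'   `acid, base, neutral, zwitterion`; must sum to 1. Default 0.25 / 0.45 /
#'   0.20 / 0.10, a base-heavy mix typical of small-molecule drug sets.
#' @param logP_mean,logP_sd,logP_range truncated-normal log P parameters
#'   (default mean 2.5, sd 1.5, truncated to [-3, 7.5]).
#' @param pKa_acidic_range,pKa_basic_range uniform pKa ranges (defaults
#'   [2, 7.4] and [5, 11]).
#' @param sigma sd of the log10 observation noise on Vd,ss (default 0.3).
#' @param include_animal also generate rat/dog Vd,ss and fup columns for
#'   allometry (default FALSE).
#' @param seed integer random seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 254,
                              class_probabilities = c(acid = 0.25,
                                                      base = 0.45,
                                                      neutral = 0.20,
                                                      zwitterion = 0.10),
                              logP_mean = 2.5, logP_sd = 1.5,
                              logP_range = c(-3, 7.5),
                              pKa_acidic_range = c(2, 7.4),
                              pKa_basic_range = c(5, 11),
                              sigma = 0.3, include_animal = FALSE,
                              seed = 1L) {
  classes <- c("acid", "base", "neutral", "zwitterion")
  if (!setequal(names(class_probabilities), classes) ||
      any(class_probabilities < 0) ||
      abs(sum(class_probabilities) - 1) > 1e-8) {
    stop("class_probabilities must be a probability vector over ",
         paste(classes, collapse = ", "))
  }
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(n_compounds = n_compounds,
                 class_probabilities = class_probabilities[classes],
                 logP_mean = logP_mean, logP_sd = logP_sd,
                 logP_range = logP_range,
                 pKa_acidic_range = pKa_acidic_range,
                 pKa_basic_range = pKa_basic_range,
                 sigma = sigma, include_animal = include_animal,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic compound table
#'
#' Draws `n_compounds` compounds from the distributions in a
#' [simulation_config()]. Reproducible from the config seed; the resulting
#' table satisfies the compound-property invariants (fup in (0, 1] after
#' clipping to the 0.1% assay floor, BPR >= 1 - Hct by construction).
#'
#' @param config a `simulation_config`.
#' @param physiology a `body_physiology` (supplies the hematocrit for the
#'   BPR model).
#' @return Data frame with columns `compound_id, ionization_class,
#'   pKa_acidic, pKa_basic, logP, logD74, fup, BPR` (plus
#'   `V_rat, fup_rat, V_dog, fup_dog` when `include_animal`).
#' @export
sample_compounds <- function(config, physiology = load_physiology()) {
  n <- config$n_compounds
  set.seed(config$seed)
  empty <- data.frame(compound_id = character(0),
                      ionization_class = character(0),
                      pKa_acidic = numeric(0), pKa_basic = numeric(0),
                      logP = numeric(0), logD74 = numeric(0),
                      fup = numeric(0), BPR = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  cls <- sample(names(config$class_probabilities), n, replace = TRUE,
                prob = config$class_probabilities)
  logP <- rtruncnorm1(n, config$logP_mean, config$logP_sd,
                      config$logP_range[1], config$logP_range[2])
  has_acid <- cls %in% c("acid", "zwitterion")
  has_base <- cls %in% c("base", "zwitterion")
  pKa_a <- ifelse(has_acid,
                  stats::runif(n, config$pKa_acidic_range[1],
                               config$pKa_acidic_range[2]), NA_real_)
  pKa_b <- ifelse(has_base,
                  stats::runif(n, config$pKa_basic_range[1],
                               config$pKa_basic_range[2]), NA_real_)
  # pKa_basic must exceed 6 for the label "base"/"zwitterion" to hold
  pKa_b[has_base] <- pmax(pKa_b[has_base], 6.0 + 1e-6)

  # fraction unbound: logit-normal, decreasing with lipophilicity
  eta <- -1.2 - 0.6 * (logP - 2.5) + stats::rnorm(n, 0, 1.2)
  fup <- pmin(pmax(stats::plogis(eta), 0.001), 1)

  # blood-to-plasma ratio through a latent blood-cell partition Kpu_BC:
  # BPR = (1 - Hct) + Hct * fup * Kpu_BC  (>= 1 - Hct by construction)
  Hct <- physiology$Hct
  kpu_bc <- ifelse(cls == "base",
                   10^(0.30 + 0.25 * logP + stats::rnorm(n, 0, 0.35)),
                   10^stats::rnorm(n, log10(0.7), 0.25))
  BPR <- pmin((1 - Hct) + Hct * fup * kpu_bc, 200)

  out <- data.frame(
    compound_id = sprintf("SYN%04d", seq_len(n)),
    ionization_class = cls, pKa_acidic = pKa_a, pKa_basic = pKa_b,
    logP = logP,
    logD74 = logd_from_logp(logP, pKa_a, pKa_b, 7.4),
    fup = fup, BPR = BPR, stringsAsFactors = FALSE)

  if (isTRUE(config$include_animal)) {
    true_v <- suppressWarnings(
      predict_vdss_mechanistic(out, physiology))$vdss_L_per_kg
    # species scatter around the human value; animal fup near human fup
    out$V_rat <- true_v * 10^stats::rnorm(n, 0, 0.25)
    out$V_dog <- true_v * 10^stats::rnorm(n, 0, 0.20)
    out$fup_rat <- pmin(pmax(stats::plogis(stats::qlogis(fup) +
                                             stats::rnorm(n, 0, 0.5)),
                             0.001), 1)
    out$fup_dog <- pmin(pmax(stats::plogis(stats::qlogis(fup) +
                                             stats::rnorm(n, 0, 0.5)),
                             0.001), 1)
  }
  out
}

#' Simulate observed Vd,ss values
#'
#' Ground truth is the mechanistic model itself: the observed value is the
#' mechanistic prediction times log-normal noise,
#' `obs_i = vdss_mech_i * 10^eps_i`, `eps_i ~ N(0, sigma)` independently.
#' This self-consistency design makes parameter recovery well defined —
#' recovery statistics measure pipeline correctness, not real-world
#' predictive accuracy.
#'
#' @param compounds compound table (as from [sample_compounds()]).
#' @param physiology a `body_physiology`.
#' @param sigma sd of the log10 noise (0 gives exact recovery).
#' @param seed integer seed for the noise draws.
#' @return Data frame `compound_id, vdss_obs`.
#' @export
simulate_observed_vdss <- function(compounds, physiology, sigma = 0.3,
                                   seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  pred <- suppressWarnings(predict_vdss_mechanistic(compounds, physiology))
  set.seed(seed)
  eps <- stats::rnorm(nrow(pred), 0, sigma)
  data.frame(compound_id = pred$compound_id,
             vdss_obs = pred$vdss_L_per_kg * 10^eps,
             stringsAsFactors = FALSE)
}

#' Simulate adipocyte/myocyte assay readouts for a target Kp
#'
#' Inverts the assay arithmetic: a medium peak-area ratio is fixed, the
#' cell-lysate ratio that would reproduce the target intracellular Kp is
#' back-computed (`AR_cells = Kp * AR_medium * cell_volume / V_lysate`), and
#' multiplicative noise with the given coefficient of variation is applied
#' to the cell signal per replicate. With `noise_cv = 0`,
#' [intracellular_kp()] recovers the target exactly.
#'
#' @param target_kp_cell intended intracellular Kp, >= 0.
#' @param protein_mg protein per well in mg (default 10).
#' @param noise_cv coefficient of variation of the replicate noise
#'   (default 0).
#' @param seed integer seed.
#' @param n_replicates wells per compound (default 3, the assay's
#'   triplicate).
#' @param compound_id,cell_type labels for the readout rows.
#' @param area_ratio_medium medium signal level (default 0.05).
#' @param V_lysate lysate volume in ul (default 150).
#' @return Data frame of `n_replicates` AssayReadout rows.
#' @export
simulate_assay_readouts <- function(target_kp_cell, protein_mg = 10,
                                    noise_cv = 0, seed = 1L,
                                    n_replicates = 3,
                                    compound_id = "SYN0001",
                                    cell_type = "adipocyte",
                                    area_ratio_medium = 0.05,
                                    V_lysate = 150) {
  if (target_kp_cell < 0) stop("target Kp_cell must be >= 0")
  set.seed(seed)
  ar_cells <- target_kp_cell * area_ratio_medium *
    cell_volume(protein_mg) / V_lysate
  noise <- 1 + stats::rnorm(n_replicates, 0, noise_cv)
  noise <- pmax(noise, 0)  # signals cannot go negative
  data.frame(compound_id = compound_id, cell_type = cell_type,
             area_ratio_cells = ar_cells * noise,
             area_ratio_medium = area_ratio_medium,
             protein_mg = protein_mg, V_lysate = V_lysate,
             replicate = seq_len(n_replicates), stringsAsFactors = FALSE)
}

#' Write a complete synthetic data set to a directory
#'
#' Generates a compound table with observed Vd,ss and matching noise-free
#' adipocyte/myocyte assay readouts (targets from the mechanistic
#' adipose/muscle Kp), and writes `compounds.csv` and `assay_readouts.csv`
#' under `dir`.
#'
#' @param dir output directory (created if needed).
#' @param config a [simulation_config()].
#' @param physiology a `body_physiology`.
#' @return Invisibly, a list with the `compounds` and `readouts` data
#'   frames.
#' @export
simulate_dataset <- function(dir, config = simulation_config(),
                             physiology = load_physiology()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- sample_compounds(config, physiology)
  obs <- simulate_observed_vdss(compounds, physiology, config$sigma,
                                seed = config$seed + 1L)
  compounds$vdss_obs <- obs$vdss_obs[match(compounds$compound_id,
                                           obs$compound_id)]
  readouts <- do.call(rbind, lapply(seq_len(nrow(compounds)), function(i) {
    kp <- suppressWarnings(
      kp_all_tissues(compounds[i, , drop = FALSE], physiology))
    fup <- compounds$fup[i]
    rbind(
      simulate_assay_readouts(kp$kp[["adipose"]] / fup,
                              seed = config$seed + 2L * i,
                              compound_id = compounds$compound_id[i],
                              cell_type = "adipocyte"),
      simulate_assay_readouts(kp$kp[["muscle"]] / fup,
                              seed = config$seed + 2L * i + 1L,
                              compound_id = compounds$compound_id[i],
                              cell_type = "myocyte")
    )
  }))
  utils::write.csv(compounds, file.path(dir, "compounds.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(readouts, file.path(dir, "assay_readouts.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(compounds = compounds, readouts = readouts))
}
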