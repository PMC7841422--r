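phys <- load_physiology()

test_that("cell volume and intracellular Kp follow the assay arithmetic", {
  expect_equal(cell_volume(10), 65)
  expect_equal(cell_volume(1), 6.5)
  expect_error(cell_volume(0), "positive")

  r <- data.frame(compound_id = "a", cell_type = "adipocyte",
                  area_ratio_cells = 1.3, area_ratio_medium = 0.03,
                  protein_mg = 10)
  expect_equal(intracellular_kp(r)$Kp_cell, 100)  # (1.3*150/65)/0.03
  # ratio invariance: scaling both signals leaves Kp unchanged
  r2 <- r; r2$area_ratio_cells <- 2.6; r2$area_ratio_medium <- 0.06
  expect_equal(intracellular_kp(r2)$Kp_cell, 100)
  r0 <- r; r0$area_ratio_cells <- 0
  expect_equal(intracellular_kp(r0)$Kp_cell, 0)
})

test_that("replicates average per compound; zero medium signal excludes", {
  r <- data.frame(compound_id = rep(c("a", "b"), each = 3),
                  cell_type = "myocyte",
                  area_ratio_cells = c(1.3, 1.3, 2.6, 1, 1, 1),
                  area_ratio_medium = c(0.03, 0.03, 0.03, 0, 0, 0),
                  protein_mg = 10, replicate = rep(1:3, 2))
  expect_warning(out <- intracellular_kp(r), "b")
  expect_equal(out$compound_id, "a")
  expect_equal(out$Kp_cell, mean(c(100, 100, 200)))
  expect_equal(out$n_replicates, 3L)
  expect_equal(attr(out, "excluded"), "b")
})

test_that("plasma referencing scales by fup under either convention", {
  expect_equal(plasma_referenced_kp(100, 0.1), 10)
  expect_equal(plasma_referenced_kp(100, 1), 100)
  expect_equal(plasma_referenced_kp(0, 0.5), 0)
  expect_equal(plasma_referenced_kp(100, 0.1, convention = "divide"), 1000)
  expect_error(plasma_referenced_kp(10, 0), "fup")
})

test_that("tissue-level strategies build the documented Kp vectors", {
  cmp <- compound_properties("s", logP = 2, fup = 0.5, BPR = 1, pKa_basic = 9)
  tiss <- phys$tissues$tissue
  baseline <- vdss_from_kp(setNames(rep(1, length(tiss)), tiss), phys, 1,
                           compound_id = "s")$vdss_L_per_kg

  # strategy collapse: combined with both Kp = 1 is the all-ones baseline
  v_comb <- strategy_vdss("combined", 1, 1, cmp, phys)
  expect_equal(v_comb$vdss_L_per_kg, baseline)
  expect_equal(v_comb$method_label, "combined")
  # adipocyte_only with Kp_fat = 1 equals myocyte_only with Kp_muscle = 1
  expect_equal(strategy_vdss("adipocyte_only", Kp_fat = 1, compound = cmp,
                             physiology = phys)$vdss_L_per_kg,
               strategy_vdss("myocyte_only", Kp_muscle = 1, compound = cmp,
                             physiology = phys)$vdss_L_per_kg)

  # adipocyte_only: direct sum over the volume table
  v_fat <- phys$tissues$V_T[tiss == "adipose"]
  expect_equal(strategy_vdss("adipocyte_only", Kp_fat = 10, compound = cmp,
                             physiology = phys)$vdss_L_per_kg,
               phys$V_P + phys$V_E + 10 * v_fat +
                 sum(phys$tissues$V_T[tiss != "adipose"]))

  # average fills non-fat/muscle tissues with the mean of the two
  v_avg <- strategy_vdss("average", 4, 2, cmp, phys)$vdss_L_per_kg
  other <- tiss[!tiss %in% c("adipose", "muscle")]
  expect_equal(v_avg, phys$V_P + phys$V_E +
                 4 * phys$tissues$V_T[tiss == "adipose"] +
                 2 * phys$tissues$V_T[tiss == "muscle"] +
                 3 * sum(phys$tissues$V_T[tiss %in% other]))

  # separate fed the mechanistic fat/muscle Kp reproduces full mechanistic
  kp <- kp_all_tissues(cmp, phys)
  v_sep <- strategy_vdss("separate", kp$kp[["adipose"]], kp$kp[["muscle"]],
                         cmp, phys, mechanistic_kp = kp)
  v_mech <- vdss_from_kp(kp, phys, erythrocyte_plasma_ratio(1, phys$Hct))
  expect_equal(v_sep$vdss_L_per_kg, v_mech$vdss_L_per_kg)

  expect_error(strategy_vdss("combined", Kp_fat = 1, compound = cmp,
                             physiology = phys), "Kp_muscle")
  expect_error(strategy_vdss("separate", 1, 1, cmp, phys), "mechanistic")
})

test_that("strategy output is monotone in every supplied Kp", {
  cmp <- compound_properties("m", logP = 1, fup = 0.4, BPR = 1.2)
  for (strat in c("adipocyte_only", "myocyte_only", "combined", "average")) {
    f <- function(kf, km) {
      strategy_vdss(strat, kf, km, cmp, phys)$vdss_L_per_kg
    }
    expect_gte(f(5, 2), f(2, 2))
    expect_gte(f(2, 5), f(2, 2))
  }
  # average dominates combined when the mean Kp exceeds the 1-baseline
  v_avg <- strategy_vdss("average", 4, 2, cmp, phys)$vdss_L_per_kg
  v_comb <- strategy_vdss("combined", 4, 2, cmp, phys)$vdss_L_per_kg
  expect_gte(v_avg, v_comb)
})
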