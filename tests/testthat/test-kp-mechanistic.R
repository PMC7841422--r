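phys <- load_physiology()

test_that("protein affinity calibration solves the plasma binding balance", {
  # unbound drug: no protein affinity (floored; plasma lipid term is tiny)
  expect_equal(suppressWarnings(calibrate_ka_pr(1, -10, phys)), 0)
  # P ~ 0: Ka_PR = 1/fup - 1 minus the aqueous phospholipid term 0.7*f_NP_P
  expect_equal(calibrate_ka_pr(0.5, -30, phys), 1 - 0.7 * 0.0013)
  # fup = 0.1, P = 1 with plasma lipid fractions 0.0023 / 0.0013
  expect_equal(calibrate_ka_pr(0.1, 0, phys),
               1 / 0.1 - 1 - (0.0023 + (0.3 + 0.7) * 0.0013))
  expect_error(calibrate_ka_pr(0, 2, phys), "fup")
  expect_error(calibrate_ka_pr(1.2, 2, phys), "fup")
})

test_that("acidic-phospholipid calibration handles the degenerate cases", {
  neutral <- compound_properties("n", logP = 2, fup = 0.5, BPR = 5)
  expect_equal(calibrate_ka_ap(neutral, phys), 0)
  acid <- compound_properties("a", logP = 2, fup = 0.5, BPR = 5,
                              pKa_acidic = 4)
  expect_equal(calibrate_ka_ap(acid, phys), 0)
  # BPR at the physical floor: zero with a warning naming the compound
  base_floor <- compound_properties("bfloor", logP = 2, fup = 0.5,
                                    BPR = 1 - phys$Hct, pKa_basic = 9)
  expect_warning(ka <- calibrate_ka_ap(base_floor, phys), "bfloor")
  expect_equal(ka, 0)
})

test_that("acidic-phospholipid calibration matches closed-form evaluation", {
  cmp <- compound_properties("b", logP = 2, fup = 0.5, BPR = 1.5,
                             pKa_basic = 9)
  # spreadsheet-style evaluation of the bracketed formula
  bc <- phys$blood_cell
  x_bc <- 10^(9 - bc$pH_BC)
  x_p <- 10^(9 - phys$pH_P)
  ion_p <- 1 + x_p
  kpu_bc <- (1.5 - (1 - phys$Hct)) / (phys$Hct * 0.5)
  P <- 100
  expected <- (kpu_bc - (1 + x_bc) / ion_p * bc$f_IW_BC -
                 (P * bc$f_NL_BC + (0.3 * P + 0.7) * bc$f_NP_BC) / ion_p) *
    ion_p / (bc$AP_BC * x_bc)
  expect_equal(calibrate_ka_ap(cmp, phys), expected)
  # missing BPR falls back to BPR = 1
  cmp_na <- compound_properties("b2", logP = 2, fup = 0.5, pKa_basic = 9)
  cmp_1 <- compound_properties("b2", logP = 2, fup = 0.5, BPR = 1,
                               pKa_basic = 9)
  expect_equal(calibrate_ka_ap(cmp_na, phys), calibrate_ka_ap(cmp_1, phys))
})

test_that("Kpu reduces to the water-plus-phospholipid-water limit", {
  # as P -> 0 the lipid term leaves only the aqueous phospholipid fraction
  # 0.7 * f_NP; all other non-water terms vanish for an unbound neutral
  cmp <- compound_properties("w", logP = -30, fup = 1)
  ka_pr <- suppressWarnings(calibrate_ka_pr(1, -30, phys))
  kpu <- kpu_tissue(cmp, phys$tissues, calibrate_ka_ap(cmp, phys), ka_pr,
                    phys)
  expect_equal(kpu,
               phys$tissues$f_EW + phys$tissues$f_IW +
                 0.7 * phys$tissues$f_NP,
               tolerance = 1e-12)
  # the residual above pure tissue water is small everywhere (< 0.02)
  expect_lt(max(kpu - (phys$tissues$f_EW + phys$tissues$f_IW)), 0.02)
})

test_that("single muscle Kpu matches a term-by-term hand evaluation", {
  cmp <- compound_properties("b", logP = 2, fup = 0.5, BPR = 1.5,
                             pKa_basic = 9)
  mus <- phys$tissues[phys$tissues$tissue == "muscle", ]
  ka_ap <- calibrate_ka_ap(cmp, phys)
  ka_pr <- calibrate_ka_pr(0.5, 2, phys)
  x_t <- 10^(9 - mus$pH)
  x_p <- 10^(9 - 7.4)
  ion_p <- 1 + x_p
  P <- 100
  expected <- mus$f_EW +
    (1 + x_t) / ion_p * mus$f_IW +
    (P * mus$f_NL + (0.3 * P + 0.7) * mus$f_NP) / ion_p +
    ka_ap * mus$AP * x_t / ion_p +
    ka_pr * mus$RA_lip   # base: lipoprotein ratio
  expect_equal(kpu_tissue(cmp, mus, ka_ap, ka_pr, phys), expected)
})

test_that("adipose neutral-lipid term runs on logD, not logP", {
  adi <- phys$tissues[phys$tissues$tissue == "adipose", ]
  cmp_lo <- compound_properties("d1", logP = 3, fup = 0.2, BPR = 2,
                                pKa_basic = 9, logD74 = 0.5)
  cmp_hi <- compound_properties("d2", logP = 3, fup = 0.2, BPR = 2,
                                pKa_basic = 9, logD74 = 2.5)
  ka_ap <- calibrate_ka_ap(cmp_lo, phys)
  ka_pr <- calibrate_ka_pr(0.2, 3, phys)
  k_lo <- kpu_tissue(cmp_lo, adi, ka_ap, ka_pr, phys)
  k_hi <- kpu_tissue(cmp_hi, adi, ka_ap, ka_pr, phys)
  expect_equal(k_hi - k_lo, (10^2.5 - 10^0.5) * adi$f_NL / (1 + 10^1.6))
  # supplied logD74 equal to the derived value reproduces the default path
  derived <- logd_from_logp(3, NA, 9, 7.4)
  cmp_na <- compound_properties("d3", logP = 3, fup = 0.2, BPR = 2,
                                pKa_basic = 9)
  cmp_eq <- compound_properties("d3", logP = 3, fup = 0.2, BPR = 2,
                                pKa_basic = 9, logD74 = derived)
  expect_equal(kpu_tissue(cmp_na, adi, ka_ap, ka_pr, phys),
               kpu_tissue(cmp_eq, adi, ka_ap, ka_pr, phys))
})

test_that("Kp vector covers every tissue, positive, with Kp = fup * Kpu", {
  cmp <- compound_properties("z", logP = 1.5, fup = 0.3, BPR = 1.2,
                             pKa_acidic = 4, pKa_basic = 8.5)
  kp <- kp_all_tissues(cmp, phys)
  expect_s3_class(kp, "kp_vector")
  expect_setequal(names(kp$kp), phys$tissues$tissue)
  expect_true(all(kp$kp > 0) && all(is.finite(kp$kp)))
  kpu <- kpu_tissue(cmp, phys$tissues, kp$Ka_AP, kp$Ka_PR, phys)
  expect_equal(unname(kp$kp), 0.3 * kpu)
})

test_that("Kpu is monotone in logP, BPR (bases) and 1/fup", {
  base_at <- function(logP = 2, fup = 0.4, BPR = 1.5) {
    cmp <- compound_properties("m", logP = logP, fup = fup, BPR = BPR,
                               pKa_basic = 9)
    kp_all_tissues(cmp, phys)
  }
  # monotone in logP at fixed calibrated constants (recalibrating Ka_AP
  # from a fixed BPR deliberately trades lipid against AP affinity)
  kpu_logp <- function(logP) {
    cmp <- compound_properties("m", logP = logP, fup = 0.4, BPR = 1.5,
                               pKa_basic = 9)
    kpu_tissue(cmp, phys$tissues, Ka_AP = 2, Ka_PR = 1.5, phys)
  }
  expect_true(all(kpu_logp(2) >= kpu_logp(1)))
  expect_true(all(kpu_logp(3) >= kpu_logp(2)))
  # doubling BPR strictly raises Kp in every AP-carrying tissue
  kb1 <- base_at(BPR = 1.5); kb2 <- base_at(BPR = 3)
  ap_pos <- phys$tissues$AP > 0
  expect_true(all(kb2$kp[ap_pos] > kb1$kp[ap_pos]))
  # lower fup means higher protein affinity, higher Kpu
  kf1 <- base_at(fup = 0.5); kf2 <- base_at(fup = 0.1)
  expect_gt(kf2$Ka_PR, kf1$Ka_PR)
})

test_that("Kpu is continuous across the basic pKa range (no switch at 7)", {
  kpu_at <- function(pka) {
    cmp <- compound_properties("c", logP = 2, fup = 0.5, BPR = 1.5,
                               pKa_basic = pka, ionization_class = "base")
    ka_ap <- suppressWarnings(calibrate_ka_ap(cmp, phys))
    ka_pr <- calibrate_ka_pr(0.5, 2, phys)
    kpu_tissue(cmp, phys$tissues[phys$tissues$tissue == "muscle", ],
               ka_ap, ka_pr, phys)
  }
  expect_lt(abs(kpu_at(7.001) - kpu_at(6.999)) / kpu_at(7), 1e-3)
})
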