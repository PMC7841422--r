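test_that("ChromlogD transform matches the calibration line", {
  expect_equal(chromlogd_from_chi(0), -2.00)
  expect_equal(chromlogd_from_chi(100), 6.57)
  expect_equal(chromlogd_from_chi(50), 2.285)
  expect_error(chromlogd_from_chi(NA), "finite")
})

test_that("predicted inputs are clipped to assay limits and logged", {
  cmp <- data.frame(compound_id = c("a", "b", "c"),
                    fup = c(0.0005, 0.5, 2e-4),
                    BPR = c(250, 1, 0.8),
                    logP = c(12, 2, -5),
                    logD74 = c(12, 1, -3.5))
  out <- clip_to_assay_limits(cmp)
  expect_equal(out$fup, c(0.001, 0.5, 0.001))
  expect_equal(out$BPR, c(200, 1, 0.8))
  expect_equal(out$logP, c(10, 2, -3))
  expect_equal(out$logD74, c(10, 1, -3))
  ev <- attr(out, "clip_events")
  expect_equal(nrow(ev), 7)
  expect_true(all(c("compound_id", "field", "original", "clipped") %in%
                    names(ev)))
  # idempotent
  out2 <- clip_to_assay_limits(out)
  expect_equal(out2$fup, out$fup)
  expect_equal(nrow(attr(out2, "clip_events")), 0)
  # measured fields are never touched
  out3 <- clip_to_assay_limits(cmp, predicted = "BPR")
  expect_equal(out3$fup, cmp$fup)
  expect_equal(out3$BPR, c(200, 1, 0.8))
})

test_that("compound tables read, validate and reject per row", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,logP,fup,BPR,pKa_basic,vdss_obs",
               "a,2,0.5,1.5,9,3.2",
               "b,1,0.9,,,0.7",
               "a,3,0.4,1,8,1.1",       # duplicate id
               "c,2,0,1,,2.0",          # fup out of range
               "d,15,0.2,1,,1.0"),      # logP out of range
             tmp)
  tab <- read_compound_table(tmp)
  expect_equal(tab$compound_id, c("a", "b"))
  expect_true(is.na(tab$BPR[2]))
  expect_equal(tab$ionization_class, c("base", "neutral"))
  rej <- attr(tab, "rejects")
  expect_equal(nrow(rej), 3)
  expect_true(any(grepl("duplicate", rej$reason)))

  # fup in percent is auto-detected
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,logP,fup", "a,2,50", "b,1,10"), tmp2)
  expect_message(tab2 <- read_compound_table(tmp2), "percent")
  expect_equal(tab2$fup, c(0.5, 0.1))

  # headers match case-insensitively; all rows invalid is an error
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Compound_ID,LOGP,FUP", "a,2,0.5"), tmp3)
  expect_equal(read_compound_table(tmp3)$compound_id, "a")
  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,logP,fup", "a,2,-1"), tmp4)
  expect_error(read_compound_table(tmp4), "no valid rows")
  expect_error(read_compound_table("no/such/file.csv"), "cannot read")
})

test_that("prediction tables round-trip through write/read", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  pred <- data.frame(compound_id = c("a", "b"),
                     method_label = "mechanistic",
                     vdss_L_per_kg = c(1.25, 0.5))
  report <- data.frame(method_label = "mechanistic", n = 2,
                       pct_within_2fold = 100, pct_within_3fold = 100,
                       pct_within_10fold = 100, r2 = 1, aafe = 1)
  write_predictions(tmp, pred, report)
  back <- utils::read.csv(tmp)
  expect_equal(back$vdss_L_per_kg, pred$vdss_L_per_kg)
  stem <- sub("\\.csv$", "", tmp)
  expect_true(file.exists(paste0(stem, "_report.json")))
  rep_back <- jsonlite::read_json(paste0(stem, "_report.json"),
                                  simplifyVector = TRUE)
  expect_equal(rep_back$aafe, 1)
})
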