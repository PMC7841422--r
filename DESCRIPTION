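Package: vdsspredict
Title: Mechanistic and Empirical Prediction of Human Volume of Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts the human volume of distribution at steady state
    (Vd,ss, L/kg) from physicochemical and in vitro inputs. Implements a
    single continuous tissue-composition equation for tissue-to-plasma
    partition coefficients (Kp) in the Rodgers-Rowland lineage, with
    acidic-phospholipid affinity calibrated from the blood-to-plasma ratio
    and protein affinity calibrated from the fraction unbound in plasma;
    assembles whole-body Vd,ss from per-tissue Kp values and erythrocyte
    partitioning; provides single- and two-species allometric scaling,
    adipocyte/myocyte cell-partition strategies, fold-error evaluation
    statistics (percent within 2/3/10-fold, log-scale r-squared, AAFE),
    and a synthetic-compound generator for end-to-end testing without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
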