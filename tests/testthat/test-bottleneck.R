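fct_from_folds <- function(folds, strain = "X", significant = TRUE) {
  tibble::tibble(strain = strain, metabolite_id = names(folds),
                 fold_change = unname(folds),
                 log2_fc = log2(unname(folds)),
                 significant = significant)
}

main_chain_folds <- function(...) {
  base <- c(PYR = 1, GAP = 1, DXP = 1, MEP = 1, "CDP-ME" = 1, "CDP-MEP" = 1,
            MEcDP = 1, HMBDP = 1, "IDP/DMADP" = 1, ISOPRENE = 1)
  override <- c(...)
  base[names(override)] <- override
  base
}

test_that("uniform fold changes give zero scores and no calls", {
  scores <- accumulation_scores(fct_from_folds(main_chain_folds()))
  expect_true(all(scores$score_bits == 0))
  expect_true(all(scores$classification == "none"))
})

test_that("differential accumulation is scored in bits and ranked", {
  folds <- main_chain_folds(DXP = 9.3, MEP = 5, "CDP-ME" = 9.1,
                            "CDP-MEP" = 6, MEcDP = 102, HMBDP = 5.5,
                            "IDP/DMADP" = 2.5)
  scores <- accumulation_scores(fct_from_folds(folds))
  ispg <- dplyr::filter(scores, reaction == "IspG")
  expect_equal(ispg$score_bits, log2(102 / 5.5), tolerance = 1e-12)
  expect_equal(ispg$score_bits, 4.21, tolerance = 1e-2)
  expect_identical(ispg$classification, "bottleneck")
  expect_identical(scores$reaction[1], "IspG")  # top-ranked
})

test_that("relieving a step flips its score sign", {
  # IspG co-overexpression: MEcDP stays low, HMBDP soars
  folds <- main_chain_folds(DXP = 6, MEP = 5, "CDP-ME" = 5, "CDP-MEP" = 3,
                            MEcDP = 2, HMBDP = 140, "IDP/DMADP" = 15)
  scores <- accumulation_scores(fct_from_folds(folds))
  expect_lt(scores$score_bits[scores$reaction == "IspG"], 0)
  expect_identical(scores$classification[scores$reaction == "IspG"], "mitigated")
  expect_gt(scores$score_bits[scores$reaction == "IspH"], 0)
})

test_that("the score is antisymmetric under substrate/product swap", {
  pw <- mep_pathway()
  folds <- main_chain_folds(MEcDP = 102, HMBDP = 5.5)
  swapped <- pw
  i <- match("IspG", swapped$reactions$id)
  swapped$reactions$main_substrate[i] <- "HMBDP"
  swapped$reactions$main_product[i] <- "MEcDP"
  st <- swapped$reactions$stoichiometry[[i]]
  st[c("MEcDP", "HMBDP")] <- -st[c("MEcDP", "HMBDP")]
  swapped$reactions$stoichiometry[[i]] <- st
  s1 <- accumulation_scores(fct_from_folds(folds), pw)
  s2 <- accumulation_scores(fct_from_folds(folds), swapped)
  expect_equal(s2$score_bits[s2$reaction == "IspG"],
               -s1$score_bits[s1$reaction == "IspG"], tolerance = 1e-12)
})

test_that("ranking is invariant to a common rescaling of all folds", {
  folds <- main_chain_folds(DXP = 9.3, MEcDP = 102, HMBDP = 5.5,
                            "IDP/DMADP" = 2.5)
  s1 <- accumulation_scores(fct_from_folds(folds))
  s2 <- accumulation_scores(fct_from_folds(folds * 3.7))
  expect_identical(s1$reaction, s2$reaction)
  expect_equal(s1$score_bits, s2$score_bits, tolerance = 1e-12)
})

test_that("a substrate fold that is not significant blocks the call", {
  folds <- main_chain_folds(MEcDP = 102, HMBDP = 5.5)
  fct <- fct_from_folds(folds, significant = FALSE)
  scores <- accumulation_scores(fct)
  expect_identical(scores$classification[scores$reaction == "IspG"], "none")
})

test_that("reports render, list the top bottleneck, and round-trip as JSON", {
  out <- withr::local_tempdir()
  # empty input is a valid report
  empty <- accumulation_scores(fct_from_folds(main_chain_folds())[0, ])
  paths <- render_report(empty, out = out, name = "empty")
  expect_true(all(file.exists(paths)))
  expect_silent(jsonlite::read_json(paths[["json"]]))
  # full DXS2-style scenario: IspG top-ranked
  cfg <- sim_config("DXS2", "single_timepoint", seed = 12, noise_cv = 0.1)
  res <- run_pipeline(cfg, out = out)
  expect_identical(
    res$scores$reaction[res$scores$classification == "bottleneck"][1], "IspG")
  js <- jsonlite::read_json(file.path(out, "bottleneck_report.json"),
                            simplifyVector = TRUE)
  expect_identical(js$top_bottleneck, "IspG")
  expect_equal(js$scores$score_bits, res$scores$score_bits, tolerance = 1e-9)
})

test_that("null pipeline run calls no bottlenecks and flags nothing", {
  cfg <- sim_config("GFP", "single_timepoint", seed = 5, noise_cv = 0.1)
  res <- run_pipeline(cfg)
  expect_false(any(res$fold_changes$significant, na.rm = TRUE))
  expect_false(any(res$scores$classification == "bottleneck"))
})

test_that("pipeline output is byte-identical across repeated runs", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- sim_config("DXS2", "single_timepoint", seed = 33, noise_cv = 0.2)
  run_pipeline(cfg, out = out1)
  run_pipeline(cfg, out = out2)
  j1 <- readLines(file.path(out1, "bottleneck_report.json"))
  j2 <- readLines(file.path(out2, "bottleneck_report.json"))
  expect_identical(j1, j2)
})
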