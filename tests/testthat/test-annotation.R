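# Accurate-mass annotation, cross-polarity confirmation, isomers,
# composition.

feat <- function(id, polarity, mz, rt) {
  data.frame(feature_id = id, polarity = polarity, mz = mz, rt = rt,
             stringsAsFactors = FALSE)
}

test_that("library matching gates candidates strictly below 5 ppm", {
  lib <- default_lipid_library()
  theo <- adduct_mz(lib$monoisotopic_mass[lib$name == "FFA 16:0"],
                    "[M-H]-")
  inside <- match_library(feat("N1", "negative", 255.2340, 300), lib)
  expect_true("FFA 16:0" %in% inside$name)
  hit <- inside[inside$name == "FFA 16:0", ]
  expect_equal(hit$ppm, ppm_error(255.2340, theo), tolerance = 1e-9)
  expect_equal(hit$ppm, 3.9, tolerance = 0.1)
  expect_false(any(inside$confirmed))

  outside <- match_library(feat("N2", "negative", 255.2360, 300), lib)
  expect_false("FFA 16:0" %in% outside$name)
})

test_that("multiple in-window lipids are all reported, ppm-sorted", {
  lib <- data.frame(
    name = c("X close", "X closer"), subclass = "FFA",
    formula = NA_character_,
    monoisotopic_mass = c(256.2402 + 256e-6, 256.2402),
    is_standard = FALSE, stringsAsFactors = FALSE)
  mz_obs <- adduct_mz(256.2402, "[M-H]-")
  cand <- match_library(feat("N1", "negative", mz_obs, 100), lib)
  expect_equal(cand$name, c("X closer", "X close"))
  expect_true(all(diff(cand$ppm) >= 0))
})

test_that("dual-polarity classes confirm on coelution within 30 s", {
  lib <- default_lipid_library()
  m <- lib$monoisotopic_mass[lib$name == "FFA 16:0"]
  fts <- rbind(
    feat("N1", "negative", adduct_mz(m, "[M-H]-"), 300),
    feat("P1", "positive", adduct_mz(m, "[M+NH4]+"), 310))
  ann <- cross_polarity_confirm(match_library(fts, lib))
  row_n <- ann[ann$feature_id == "N1" & ann$name == "FFA 16:0", ]
  row_p <- ann[ann$feature_id == "P1" & ann$name == "FFA 16:0", ]
  expect_true(row_n$confirmed)
  expect_true(row_p$confirmed)
  expect_equal(row_n$partner_feature_id, "P1")
  expect_equal(row_p$partner_feature_id, "N1")

  # same pair 45 s apart: not confirmed
  fts45 <- rbind(
    feat("N1", "negative", adduct_mz(m, "[M-H]-"), 300),
    feat("P1", "positive", adduct_mz(m, "[M+NH4]+"), 345))
  ann45 <- cross_polarity_confirm(match_library(fts45, lib))
  expect_false(any(ann45$confirmed[ann45$name == "FFA 16:0"]))
})

test_that("single-polarity classes confirm on their one required ion", {
  lib <- default_lipid_library()
  m_mgdg <- lib$monoisotopic_mass[lib$name == "MGDG 34:1"]
  m_lpg <- lib$monoisotopic_mass[lib$name == "LPG 34:1"]
  fts <- rbind(
    feat("P1", "positive", adduct_mz(m_mgdg, "[M+NH4]+"), 500),
    feat("N1", "negative", adduct_mz(m_lpg, "[M-H]-"), 700))
  ann <- cross_polarity_confirm(match_library(fts, lib))
  expect_true(ann$confirmed[ann$name == "MGDG 34:1"])
  expect_true(ann$confirmed[ann$name == "LPG 34:1"])
  expect_true(is.na(ann$partner_feature_id[ann$name == "MGDG 34:1"]))
})

test_that("isomers get RT-ordered letter suffixes, ties broken by m/z", {
  lib <- default_lipid_library()
  m <- lib$monoisotopic_mass[lib$name == "FFA 18:1"]
  mz_n <- adduct_mz(m, "[M-H]-")
  mz_p <- adduct_mz(m, "[M+NH4]+")
  fts <- rbind(
    feat("N1", "negative", mz_n, 500),
    feat("N2", "negative", mz_n, 300),
    feat("P1", "positive", mz_p, 500),
    feat("P2", "positive", mz_p, 300))
  ann <- label_isomers(cross_polarity_confirm(match_library(fts, lib)))
  ffa <- ann[ann$name == "FFA 18:1", ]
  expect_equal(ffa$isomer_label[ffa$feature_id == "N2"], "a")
  expect_equal(ffa$isomer_label[ffa$feature_id == "N1"], "b")
  expect_equal(ffa$isomer_label[ffa$feature_id == "P2"], "a")
  expect_equal(ffa$isomer_label[ffa$feature_id == "P1"], "b")

  # single confirmed feature keeps an empty suffix
  one <- label_isomers(cross_polarity_confirm(
    match_library(rbind(feat("N1", "negative", mz_n, 300),
                        feat("P1", "positive", mz_p, 305)), lib)))
  expect_equal(unique(one$isomer_label[one$name == "FFA 18:1"]), "")

  # identical RT: m/z breaks the tie
  mz_lpg <- adduct_mz(lib$monoisotopic_mass[lib$name == "LPG 30:0"],
                      "[M-H]-")
  fts3 <- rbind(feat("NA1", "negative", mz_lpg * (1 + 2e-6), 400),
                feat("NA2", "negative", mz_lpg * (1 - 2e-6), 400))
  ann3 <- label_isomers(cross_polarity_confirm(match_library(fts3, lib)))
  lpg <- ann3[ann3$name == "LPG 30:0", ]
  expect_equal(lpg$isomer_label[lpg$feature_id == "NA2"], "a")
  expect_equal(lpg$isomer_label[lpg$feature_id == "NA1"], "b")
})

test_that("composition counts lipids present in >= 80% of replicates", {
  # 2x FFA at 6/6, 1x PE at 5/6 kept; 1x PC at 3/6 excluded
  lib <- default_lipid_library()
  pick <- function(nm) lib$monoisotopic_mass[lib$name == nm]
  v <- matrix(1000, 8, 6)
  v[5, 6] <- NA          # PE negative feature 5/6
  v[6, 6] <- NA          # PE positive partner 5/6
  v[7, 4:6] <- NA        # PC 3/6
  v[8, 4:6] <- NA
  samples <- data.frame(sample_id = paste0("A_", 1:6), strain = "A",
                        replicate_index = 1:6, stringsAsFactors = FALSE)
  features <- rbind(
    feat("N1", "negative", adduct_mz(pick("FFA 16:0"), "[M-H]-"), 100),
    feat("P1", "positive", adduct_mz(pick("FFA 16:0"), "[M+NH4]+"), 101),
    feat("N2", "negative", adduct_mz(pick("FFA 18:0"), "[M-H]-"), 200),
    feat("P2", "positive", adduct_mz(pick("FFA 18:0"), "[M+NH4]+"), 201),
    feat("N3", "negative", adduct_mz(pick("PE 34:1"), "[M-H]-"), 300),
    feat("P3", "positive", adduct_mz(pick("PE 34:1"), "[M+H]+"), 301),
    feat("N4", "negative", adduct_mz(pick("PC 32:0"), "[M+FA-H]-"), 400),
    feat("P4", "positive", adduct_mz(pick("PC 32:0"), "[M+H]+"), 401))
  colnames(v) <- samples$sample_id
  rownames(v) <- features$feature_id
  fm <- structure(list(features = features, samples = samples,
                       values = v), class = "feature_matrix")
  ann <- label_isomers(cross_polarity_confirm(match_library(features, lib)))
  comp <- strain_composition(fm, ann, presence_threshold = 0.8)
  counts <- stats::setNames(comp$count, comp$subclass)
  expect_equal(unname(counts["FFA"]), 2)
  expect_equal(unname(counts["PE"]), 1)
  expect_equal(unname(counts["PC"]), 0)
  props <- stats::setNames(comp$proportion, comp$subclass)
  expect_equal(unname(props["FFA"]), 2 / 3)
  expect_equal(unname(props["PE"]), 1 / 3)
  expect_equal(sum(comp$proportion), 1)
})

test_that("an all-below-threshold matrix yields an empty summary with warning", {
  lib <- default_lipid_library()
  m <- lib$monoisotopic_mass[lib$name == "LPG 30:0"]
  features <- feat("N1", "negative", adduct_mz(m, "[M-H]-"), 100)
  v <- matrix(c(10, 10, NA, NA, NA, NA), 1, 6)
  samples <- data.frame(sample_id = paste0("A_", 1:6), strain = "A",
                        replicate_index = 1:6, stringsAsFactors = FALSE)
  colnames(v) <- samples$sample_id; rownames(v) <- "N1"
  fm <- structure(list(features = features, samples = samples,
                       values = v), class = "feature_matrix")
  ann <- cross_polarity_confirm(match_library(features, lib))
  expect_warning(comp <- strain_composition(fm, ann), "presence threshold")
  expect_true(all(comp$count == 0))
})

test_that("noiseless annotation recovers planted identities perfectly", {
  cfg <- noiseless_sim_config(n_lipids = 40, seed = 6)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  fm <- build_matrix(align_runs(obs[obs$polarity == "positive", ]),
                     align_runs(obs[obs$polarity == "negative", ]),
                     sample_sheet(cfg))
  ann <- annotate_features(fm, default_lipid_library(),
                           pipeline_config())
  # internal standards share sum compositions with library species
  # (e.g. PE 17:0/17:0 is PE 34:0); the QC-only standard entries are
  # not identities the generator can plant
  conf <- ann[ann$confirmed & !ann$is_standard, ]
  lipid <- match_truth(truth, fm$features, ppm_tol = 0.5, rt_tol = 1)
  truth_name <- truth$name[match(lipid, truth$lipid_id)]

  # precision: every confirmed annotation names the planted lipid
  planted <- truth_name[match(conf$feature_id, fm$features$feature_id)]
  expect_true(all(conf$name == planted))

  # recall: every expressed library lipid is confirmed under its name
  expressed_any <- Reduce(`|`, lapply(
    cfg$strains, function(s) truth[[paste0("expressed_", s)]]))
  expect_setequal(unique(conf$name),
                  unique(truth$name[expressed_any & truth$is_library]))

  # unknown features receive no annotation at all
  unknown_fids <- fm$features$feature_id[
    lipid %in% truth$lipid_id[!truth$is_library]]
  expect_false(any(ann$feature_id %in% unknown_fids))
})

test_that("confirmed annotations never violate adduct polarity rules", {
  cfg <- sim_config(n_lipids = 120, seed = 14)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  fm <- build_matrix(align_runs(obs[obs$polarity == "positive", ]),
                     align_runs(obs[obs$polarity == "negative", ]),
                     sample_sheet(cfg))
  ann <- annotate_features(fm)
  conf <- ann[ann$confirmed, ]
  expect_gt(nrow(conf), 0)
  expect_true(all(conf$adduct ==
                    rule_adduct_for_test(conf$subclass, conf$polarity)))
  # confirmation symmetry for dual-polarity classes
  dual <- conf[conf$subclass %in% c("FFA", "PE", "PG", "PC") &
                 !conf$is_standard, ]
  for (i in seq_len(nrow(dual))) {
    partner <- ann[ann$feature_id == dual$partner_feature_id[i] &
                     ann$name == dual$name[i], ]
    expect_true(any(partner$confirmed))
  }
})

test_that("internal-standard QC finds spiked standards within 5 ppm", {
  cfg <- sim_config(n_lipids = 30, seed = 19, spike_standards = TRUE)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  fm <- build_matrix(align_runs(obs[obs$polarity == "positive", ]),
                     align_runs(obs[obs$polarity == "negative", ]),
                     sample_sheet(cfg))
  qc <- qc_internal_standards(fm)
  expect_equal(nrow(qc), 6)
  expect_true(all(qc$detected))
  expect_true(all(qc$ppm < 5))
  expect_true(all(qc$n_samples >= 16))
})
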