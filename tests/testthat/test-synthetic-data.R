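# Ground-truth generator and observation simulator.

test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(n_lipids = 50, seed = 7)
  t1 <- generate_ground_truth(cfg)
  t2 <- generate_ground_truth(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  o1 <- simulate_observations(t1, cfg)
  o2 <- simulate_observations(t2, cfg)
  expect_identical(o1, o2)
})

test_that("a strain with zero MGDG/DGDG proportion expresses none", {
  cfg <- sim_config(n_lipids = 400, seed = 3)
  truth <- generate_ground_truth(cfg)
  glyco <- truth$subclass %in% c("MGDG", "DGDG")
  expect_gt(sum(glyco), 0)  # other strains do carry them
  expect_false(any(truth$expressed_OP50[glyco]))
  expect_true(any(truth[["expressed_HA-114"]][glyco]))
})

test_that("planted effects are recorded exactly", {
  cfg <- sim_config(n_lipids = 100, n_planted = 20,
                    planted_log2fc = log2(3), seed = 5,
                    unknown_feature_rate = 0)
  truth <- generate_ground_truth(cfg)
  planted <- truth$planted_log2fc != 0
  expect_equal(sum(planted), 20)
  expect_true(all(truth$planted_log2fc[planted] == log2(3)))
  # the planted strain's baseline is shifted by exactly the effect
  for (i in which(planted)) {
    s <- truth$planted_strain[i]
    others <- setdiff(attr(truth, "sim_config")$strains, s)
    expect_equal(truth[[paste0("base_", s)]][i] -
                   truth[[paste0("base_", others[1])]][i],
                 log2(3))
  }
})

test_that("invalid class proportions are rejected", {
  bad <- list("A" = c(FFA = 0.5, PE = 0.4),
              "B" = c(FFA = 0.5, PE = 0.5))
  expect_error(sim_config(strains = c("A", "B"),
                          class_proportions = bad), "sum to 1")
})

test_that("the noiseless limit emits exact theoretical adduct m/z", {
  cfg <- noiseless_sim_config(n_lipids = 30, seed = 2)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  ffa <- truth[truth$subclass == "FFA" & truth$expressed_OP50, ]
  expect_gt(nrow(ffa), 0)
  ns <- 6  # replicates per strain
  for (i in seq_len(nrow(ffa))) {
    for (ad in c("[M+NH4]+", "[M-H]-")) {
      mz_theo <- adduct_mz(ffa$monoisotopic_mass[i], ad)
      hits <- obs[abs(obs$mz - mz_theo) < 1e-9 &
                    obs$strain == "OP50", ]
      expect_equal(nrow(hits), ns)
      expect_true(all(hits$rt == ffa$rt_true[i]))
    }
  }
})

test_that("dropout probability one silences a strain completely", {
  cfg <- sim_config(strains = c("A", "B"), n_lipids = 20,
                    class_proportions = list(
                      A = c(FFA = 1), B = c(FFA = 1)),
                    dropout_prob = c(A = 0, B = 1),
                    unknown_feature_rate = 0, spike_standards = FALSE,
                    seed = 4)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  expect_false(any(obs$strain == "B"))
  expect_gt(sum(obs$strain == "A"), 0)
})

test_that("the generator never violates the adduct polarity rules", {
  cfg <- sim_config(n_lipids = 300, seed = 9, unknown_feature_rate = 0,
                    spike_standards = FALSE)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  # attribute each observation to its truth entity by exact-ish mass
  lipid <- match_truth(truth, data.frame(polarity = obs$polarity,
                                         mz = obs$mz, rt = obs$rt))
  sub <- truth$subclass[match(lipid, truth$lipid_id)]
  expect_false(any(sub %in% c("MGDG", "DGDG") &
                     obs$polarity == "negative", na.rm = TRUE))
  expect_false(any(sub == "LPG" & obs$polarity == "positive",
                   na.rm = TRUE))
})

test_that("simulated mass errors are bounded at 5 ppm", {
  cfg <- sim_config(n_lipids = 200, ppm_noise_sd = 5 / 3, seed = 12,
                    unknown_feature_rate = 0, spike_standards = FALSE)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  lipid <- match_truth(truth, data.frame(polarity = obs$polarity,
                                         mz = obs$mz, rt = obs$rt),
                       ppm_tol = 25, rt_tol = 60)
  idx <- match(lipid, truth$lipid_id)
  rules_ok <- !is.na(idx)
  mass <- truth$monoisotopic_mass[idx[rules_ok]]
  add <- rule_adduct_for_test(truth$subclass[idx[rules_ok]],
                              obs$polarity[rules_ok])
  theo <- adduct_mz(mass, add)
  expect_true(all(ppm_error(obs$mz[rules_ok], theo) <= 5 + 1e-9))
})

test_that("planted log2 fold changes are realized by the intensity model", {
  # Monte-Carlo check of the generator contract: 200 replicates,
  # planted log2FC = 1, noise_cv = 0.2
  cfg <- sim_config(strains = c("A", "B"), replicates = 200,
                    n_lipids = 10,
                    class_proportions = list(A = c(FFA = 1),
                                             B = c(FFA = 1)),
                    noise_cv = 0.2, ppm_noise_sd = 0, rt_jitter_sd = 0,
                    dropout_prob = 0, unknown_feature_rate = 0,
                    n_planted = 10, planted_log2fc = 1,
                    spike_standards = FALSE, seed = 21)
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  neg <- obs[obs$polarity == "negative", ]
  for (i in which(truth$planted_log2fc == 1)) {
    mz_theo <- adduct_mz(truth$monoisotopic_mass[i], "[M-H]-")
    sel <- neg[abs(neg$mz - mz_theo) < 1e-9, ]
    d <- mean(log2(sel$intensity[sel$strain == truth$planted_strain[i]])) -
      mean(log2(sel$intensity[sel$strain != truth$planted_strain[i]]))
    expect_equal(d, 1, tolerance = 0.1)
  }
})

test_that("expressed class proportions converge to the configured mix", {
  # chi-squared goodness of fit per strain, not rejected at alpha=0.01
  for (seed in 1:10) {
    cfg <- sim_config(n_lipids = 2000, seed = seed,
                      unknown_feature_rate = 0)
    truth <- generate_ground_truth(cfg)
    for (s in cfg$strains) {
      p_cfg <- cfg$class_proportions[[s]]
      p_cfg <- p_cfg[p_cfg > 0]
      expressed <- truth[truth[[paste0("expressed_", s)]], ]
      counts <- table(factor(expressed$subclass, levels = names(p_cfg)))
      test <- suppressWarnings(
        stats::chisq.test(counts, p = p_cfg / sum(p_cfg)))
      expect_gt(test$p.value, 0.01)
    }
  }
})

test_that("fixtures are written byte-identically for the same seed", {
  cfg <- sim_config(n_lipids = 25, seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  for (f in c("observations.csv", "truth.tsv", "simconfig.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # re-reading reproduces the observation multiset at printed precision
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  back <- read_feature_table(file.path(d1, "observations.csv"))
  expect_equal(nrow(back), nrow(obs))
  expect_equal(sort(back$mz), sort(obs$mz), tolerance = 1e-6)
  expect_equal(sort(back$intensity), sort(obs$intensity),
               tolerance = 1e-4)
  tr <- utils::read.table(file.path(d1, "truth.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE)
  expect_equal(nrow(tr), nrow(truth))
})
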