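# Score aggregation, disagreement flagging, set-2 mappings, final scores.

test_that("qualitative aggregation reproduces the worked example", {
  # obs1 = (2, 1), obs2 = (1, 2), one batch: per-parameter means (1.5, 1.5),
  # total 3, normalized 3 / (2 x 2) = 0.75
  ms <- aggregate_qualitative(worked_score_table(), "raman", "E_24")
  expect_equal(ms$per_parameter, c(p1 = 1.5, p2 = 1.5))
  expect_equal(ms$total, 3)
  expect_identical(ms$normalized_score, 0.75)
  expect_equal(ms$n_parameters_used, 2L)
})

test_that("aggregation hits the endpoints and handles missing parameters", {
  hi <- make_score_fixture("E_24", quality = 1, disagreement_sd = 0, seed = 1)
  expect_equal(aggregate_qualitative(hi, "raman", "E_24")$normalized_score, 1)
  lo <- make_score_fixture("E_24", quality = 0, disagreement_sd = 0, seed = 1)
  expect_equal(aggregate_qualitative(lo, "raman", "E_24")$normalized_score, 0)
  # a parameter scored in only one batch still averages over the batches
  # that evaluated it; n_parameters_used counts parameters, not cells
  part <- score_table(data.frame(
    modality = "HE", protocol = "F_6",
    batch = c(1L, 1L, 2L), observer = "obs1",
    parameter = c("a", "b", "a"), score = c(2L, 0L, 1L)))
  ms <- aggregate_qualitative(part, "HE", "F_6")
  expect_equal(ms$n_parameters_used, 2L)
  expect_equal(unname(ms$per_parameter["a"]), 1.5)
  expect_equal(ms$normalized_score, (1.5 + 0) / 4)
  expect_error(aggregate_qualitative(part, "raman", "F_6"), "no records")
})

test_that("aggregation is invariant to record order and observer labels", {
  tab <- make_score_fixture(c("E_24", "HF_8"), quality = 0.6,
                            disagreement_sd = 0.2, n_batches = 3, seed = 31)
  ref <- aggregate_qualitative(tab, "raman", "E_24")$normalized_score
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(aggregate_qualitative(shuffled, "raman", "E_24")$normalized_score,
               ref)
  relabel <- tab
  relabel$observer <- chartr("12", "21", relabel$observer)
  expect_equal(aggregate_qualitative(relabel, "raman", "E_24")$normalized_score,
               ref)
})

test_that("raising any single score never lowers the aggregate", {
  tab <- make_score_fixture("E_24", quality = 0.5, disagreement_sd = 0.3,
                            n_batches = 2, seed = 33)
  ref <- aggregate_qualitative(tab, "raman", "E_24")$normalized_score
  for (i in which(tab$score < 2L)) {
    bumped <- tab
    bumped$score[i] <- bumped$score[i] + 1L
    expect_gte(aggregate_qualitative(bumped, "raman", "E_24")$normalized_score,
               ref)
  }
})

test_that("disagreement flag fires strictly above a total difference of 1", {
  mk <- function(s1, s2) score_table(data.frame(
    modality = "HE", protocol = "E_24", batch = 1L,
    observer = rep(c("obs1", "obs2"), each = 3),
    parameter = rep(c("a", "b", "c"), 2),
    score = c(s1, s2)))
  # totals 5 vs 3: delta 2 -> flagged
  fl <- flag_disagreements(mk(c(2L, 2L, 1L), c(1L, 1L, 1L)), "HE")
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$max_difference, 2)
  # totals 5 vs 4: boundary, "more than 1" is strict -> not flagged
  expect_equal(nrow(flag_disagreements(mk(c(2L, 2L, 1L), c(2L, 1L, 1L)), "HE")),
               0L)
  # perfectly agreeing observers -> empty
  agree <- make_score_fixture(c("E_24", "HF_8"), quality = 1,
                              disagreement_sd = 0, seed = 2)
  expect_equal(nrow(flag_disagreements(agree, "raman")), 0L)
})

test_that("acquisition-derived set-2 scores honour the stated endpoints", {
  # protocol with cohort-minimum LP and DG in every channel -> 1.0,
  # cohort-maximum -> 0.0
  chans <- c("osteoclast", "preosteoblast", "actin", "nuclei")
  acq <- expand.grid(channel = chans, protocol = c("E_24", "T_12", "HF_8"),
                     stringsAsFactors = FALSE)
  acq$batch <- 1L
  acq$laser_power <- c(E_24 = 2, T_12 = 10, HF_8 = 20)[acq$protocol]
  acq$detector_gain <- c(E_24 = 500, T_12 = 750, HF_8 = 1000)[acq$protocol]
  s2 <- acquisition_to_set2_scores(acq)
  expect_equal(s2$set2_score[s2$protocol == "E_24"], 1)
  expect_equal(s2$set2_score[s2$protocol == "HF_8"], 0)
  expect_equal(s2$set2_score[s2$protocol == "T_12"], 0.5)
  # strictly ordered LP x DG -> monotone set-2 ordering
  expect_true(all(diff(s2$set2_score[match(c("HF_8", "T_12", "E_24"),
                                           s2$protocol)]) > 0))
  tie <- acq; tie$laser_power <- 5; tie$detector_gain <- 600
  # one warning each for the tied laser-power and detector-gain cohorts
  expect_warning(
    expect_warning(acquisition_to_set2_scores(tie[tie$channel == "actin", ]),
                   "identical"),
    "identical")
  s2t <- suppressWarnings(acquisition_to_set2_scores(tie))
  expect_true(all(s2t$set2_score == 0.5))
})

test_that("SNR-derived scores are rank-based tertiles", {
  expect_equal(snr_to_score(c(10, 20, 30)), c(0L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(snr_to_score(c(10, 20, 30) + 100), c(0L, 1L, 2L),
               ignore_attr = TRUE)
  expect_warning(all_one <- snr_to_score(rep(7, 5), tissue = "bone_marrow"),
                 "identical")
  expect_true(all(all_one == 1L))
  expect_error(snr_to_score(c(1, 2)), "at least 3")
})

test_that("modality totals and final scores follow their closed forms", {
  expect_equal(modality_total(1, 0), 0.5)
  expect_equal(modality_total(1, 1), 1)
  expect_equal(modality_total(0.75, 0.25), 0.5)
  expect_error(modality_total(1.2, 0), "\\[0, 1\\]")

  fs <- final_score(he = 1, fluorescence = 1, raman = 1)
  expect_equal(fs$mean_score, 1); expect_equal(fs$sd_across_modalities, 0)
  fs2 <- final_score(he = 1, fluorescence = 0)
  expect_equal(fs2$mean_score, 0.5)
  expect_equal(fs2$sd_across_modalities, 0.5)  # population SD of two values
  expect_equal(fs2$n_modalities, 2L)
  fs3 <- final_score(he = 0.9, fluorescence = 0.6, raman = 0.3)
  expect_equal(fs3$mean_score, 0.6)
  expect_equal(fs3$sd_across_modalities, sqrt(mean((c(0.9, 0.6, 0.3) - 0.6)^2)))
  expect_error(final_score(), "at least one")
})
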