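# Synthetic-data generator: band placement, determinism, mixture structure.

test_that("calcified spectra are dominated by the 959 phosphate band", {
  s <- make_bone_spectrum("calcified", "compact_bone", noise_sd = 0, seed = 1)
  clean <- attr(s, "clean")
  peak_w <- s$wavenumber[which.max(clean)]
  expect_lte(abs(peak_w - 959), 1)  # nearest channel on the 2 cm^-1 grid
  # all four phosphate bands present above baseline
  for (b in c(431, 583, 1072))
    expect_gt(max(clean[abs(s$wavenumber - b) <= 10]), 10)
})

test_that("decalcified spectra have no residue at 959 but keep collagen bands", {
  s <- make_bone_spectrum("decalcified", "compact_bone", noise_sd = 0)
  clean <- attr(s, "clean")
  expect_lt(max(clean[abs(s$wavenumber - 959) <= 10]), 1e-3)
  for (b in c(855, 876, 921, 1450))
    expect_gt(max(clean[abs(s$wavenumber - b) <= 10]), 10)
})

test_that("marrow spectra carry nucleic-acid and phenylalanine bands", {
  s <- make_bone_spectrum("decalcified", "bone_marrow", noise_sd = 0)
  clean <- attr(s, "clean")
  expect_gt(max(clean[abs(s$wavenumber - 780) <= 8]), 10)
  expect_gt(max(clean[abs(s$wavenumber - 1003) <= 8]), 10)
  cb <- make_bone_spectrum("decalcified", "compact_bone", noise_sd = 0)
  expect_lt(max(attr(cb, "clean")[abs(cb$wavenumber - 780) <= 8]), 1)
})

test_that("overridden band amplitude is recovered from noisy replicates", {
  # Monte-Carlo: mean height at 780 over replicates estimates the set
  # amplitude of 5 to within 3 standard errors
  n_rep <- 200
  heights <- vapply(seq_len(n_rep), function(i) {
    s <- make_bone_spectrum("decalcified", "bone_marrow",
                            band_overrides = list("780" = 5),
                            noise_sd = 1, seed = 1000 + i)
    ch <- which.min(abs(s$wavenumber - 780))
    s$intensity[ch] - attr(s, "baseline")[ch]
  }, numeric(1))
  sem <- stats::sd(heights) / sqrt(n_rep)
  expect_lt(abs(mean(heights) - 5), 3 * sem)
})

test_that("generators are deterministic under a fixed seed", {
  a <- make_bone_spectrum("calcified", "bone_marrow", noise_sd = 3, seed = 9)
  b <- make_bone_spectrum("calcified", "bone_marrow", noise_sd = 3, seed = 9)
  expect_identical(a$intensity, b$intensity)
  s1 <- make_scan(c(4, 4), k = 2, seed = 5, cosmic_ray_rate = 0.3)
  s2 <- make_scan(c(4, 4), k = 2, seed = 5, cosmic_ray_rate = 0.3)
  expect_identical(s1$pixels, s2$pixels)
  expect_identical(attr(s1, "truth")$spikes, attr(s2, "truth")$spikes)
  t1 <- make_score_fixture("E_24", quality = 0.5, seed = 3)
  t2 <- make_score_fixture("E_24", quality = 0.5, seed = 3)
  expect_identical(t1$score, t2$score)
})

test_that("scan mixtures are convex with pure pixels for every endmember", {
  scan <- make_scan(c(8, 8), k = 2, pure_fraction = 0.2, seed = 7)
  tru <- attr(scan, "truth")
  expect_true(all(tru$abundances >= 0 & tru$abundances <= 1))
  expect_equal(rowSums(tru$abundances), rep(1, 64))
  expect_true(all(lengths(tru$pure_pixels) >= 1))
  # k = 1: all pixels identical up to noise
  flat <- make_scan(c(4, 4), k = 1, noise_sd = 0, seed = 1)
  expect_equal(max(apply(flat$pixels, 2, stats::sd)), 0)
  expect_error(make_scan(c(4, 4), k = 2, pure_fraction = 0), "pure_fraction")
})

test_that("cosmic-ray spike counts follow the configured rate", {
  # rate 0.25 on 8x8 -> Binomial(64, 0.25); a 99% interval is [7, 26]
  scan <- make_scan(c(8, 8), cosmic_ray_rate = 0.25, seed = 3)
  n_spikes <- nrow(attr(scan, "truth")$spikes)
  expect_gte(n_spikes, qbinom(0.005, 64, 0.25))
  expect_lte(n_spikes, qbinom(0.995, 64, 0.25))
})

test_that("score fixtures hit the scale endpoints without noise", {
  hi <- make_score_fixture(c("E_24", "HF_8"), quality = 1.0,
                           disagreement_sd = 0, seed = 1)
  expect_true(all(hi$score == 2L))
  lo <- make_score_fixture(c("E_24", "HF_8"), quality = 0.0,
                           disagreement_sd = 0, seed = 1)
  expect_true(all(lo$score == 0L))
  expect_error(make_score_fixture(character(0), quality = 1), "at least one")
  expect_error(make_score_fixture("E_24", quality = 1, n_observers = 1),
               "two observers")
})

test_that("noisy score fixtures preserve the latent quality ranking", {
  # E_24 (0.9) should out-rank HF_8 (0.4) in nearly every seeded panel
  wins <- vapply(1:50, function(s) {
    tab <- make_score_fixture(c("E_24", "HF_8"),
                              quality = c(E_24 = 0.9, HF_8 = 0.4),
                              disagreement_sd = 0.1, seed = s)
    a <- aggregate_qualitative(tab, "raman", "E_24")$normalized_score
    b <- aggregate_qualitative(tab, "raman", "HF_8")$normalized_score
    a > b
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
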