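test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_per_class = c(5, 5)), "named")
  expect_error(cohort_spec(n_per_class = c(AD = 0, MCI = 1, NC = 1)),
               "positive")
  expect_error(small_cohort_spec(informative_rois = c(0, 1)), "1..n_rois")
  expect_error(small_cohort_spec(noise_sd = 0), "positive")
  # an implied within-block correlation >= 1 cannot be positive semidefinite
  expect_error(small_cohort_spec(connectivity_effect = 1.0),
               "non-positive-semidefinite")
})

test_that("simulated cohorts have the spec's shape and are bit-reproducible", {
  spec <- small_cohort_spec(seed = 3)
  coh <- simulate_cohort(spec)
  expect_equal(nrow(coh), 16)
  expect_equal(as.vector(table(coh$label)), c(8, 4, 4))
  expect_true(all(vapply(coh$series, function(m) {
    identical(dim(m), c(8L, 140L)) && !anyNA(m)
  }, logical(1))))
  expect_equal(rownames(coh$series[[1]]), sprintf("ROI_%03d", 1:8))

  coh2 <- simulate_cohort(small_cohort_spec(seed = 3))
  expect_identical(coh$series, coh2$series)
  coh3 <- simulate_cohort(small_cohort_spec(seed = 4))
  expect_false(identical(coh$series, coh3$series))
})

test_that("a null spec produces statistically exchangeable classes", {
  pvals <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_per_class = c(AD = 12, MCI = 1, NC = 12),
                        n_rois = 4, informative_rois = 1:2,
                        spectral_effect = 0, connectivity_effect = 0,
                        seed = 100 + s)
    coh <- simulate_cohort(spec)
    energy <- vapply(coh$series, function(m) sum(hwt_features(m[1, ])^2),
                     numeric(1))
    t.test(energy[coh$label == "AD"], energy[coh$label == "NC"])$p.value
  }, numeric(1))
  # at alpha = 0.05 expect ~1 rejection in 20; more than 4 signals structure
  expect_lte(sum(pvals < 0.05), 4)
})

test_that("the spectral effect separates informative-ROI wavelet energy between classes", {
  spec <- cohort_spec(n_per_class = c(AD = 50, MCI = 1, NC = 50), n_rois = 6,
                      informative_rois = 1:5, spectral_effect = 4,
                      connectivity_effect = 0, noise_sd = 1, seed = 77,
                      spectral_profile = c(AD = 1, MCI = 0, NC = 0))
  coh <- simulate_cohort(spec)
  # level-4 approximation energy of ROI 1 per subject
  a4_energy <- vapply(coh$series, function(m) {
    sum(hwt_features(m[1, ])[25:32]^2)
  }, numeric(1))
  m_ad <- mean(a4_energy[coh$label == "AD"])
  m_nc <- mean(a4_energy[coh$label == "NC"])
  spread <- sd(a4_energy[coh$label == "NC"])
  expect_gt(m_ad - m_nc, 3 * spread)
})

test_that("larger spectral effects widen the between-class energy gap monotonically", {
  gap <- vapply(c(0, 1.5, 3), function(eff) {
    spec <- cohort_spec(n_per_class = c(AD = 25, MCI = 1, NC = 25),
                        n_rois = 4, informative_rois = 1:2,
                        spectral_effect = eff, connectivity_effect = 0,
                        seed = 11,
                        spectral_profile = c(AD = 1, MCI = 0, NC = 0))
    coh <- simulate_cohort(spec)
    energy <- vapply(coh$series, function(m) sum(hwt_features(m[1, ])^2),
                     numeric(1))
    mean(energy[coh$label == "AD"]) - mean(energy[coh$label == "NC"])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("the connectivity effect raises within-block correlation by class", {
  spec <- cohort_spec(n_per_class = c(AD = 30, MCI = 1, NC = 30), n_rois = 8,
                      informative_rois = integer(0), spectral_effect = 0,
                      connectivity_effect = 0.6, connectivity_block = 1:4,
                      seed = 21,
                      connectivity_profile = c(AD = 1, MCI = 0, NC = 0))
  coh <- simulate_cohort(spec)
  block_cor <- vapply(coh$series, function(m) {
    w <- connectivity_matrix(m)$weights
    mean(w[1:4, 1:4][upper.tri(matrix(0, 4, 4))])
  }, numeric(1))
  m_ad <- mean(block_cor[coh$label == "AD"])
  m_nc <- mean(block_cor[coh$label == "NC"])
  # target correlation 0.6 vs 0 plus finite-sample |cor| bias
  expect_gt(m_ad, m_nc + 0.2)
  expect_gt(m_ad, 0.4)
})
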