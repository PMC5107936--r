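test_that("AUC of a constant profile is the rectangle area", {
  grid <- density_grid(0.05, 0.40, 0.01)
  expect_equal(covnet:::auc_trapezoid(grid, rep(3, length(grid))), 0.35 * 3)
  # degenerate single-point grid contributes 0 with a warning
  expect_warning(a <- covnet:::auc_trapezoid(0.19, 5), "fewer than two")
  expect_equal(a, 0)
})

test_that("stored AUC is recomputable from the stored profile", {
  cohort <- small_cohort(n_regions = 12, n_a = 20, n_b = 20, seed = 10)
  prof <- metric_profile(cohort, "A", "e_glob",
                         grid = density_grid(0.05, 0.40, 0.05))
  expect_equal(attr(prof, "auc"),
               pracma::trapz(prof$density, prof$value))
})

test_that("e_glob profiles are non-decreasing in density", {
  # nested edge sets plus edge-monotone efficiency
  for (s in 1:3) {
    cohort <- small_cohort(n_regions = 10, n_a = 15, n_b = 15, seed = s)
    prof <- metric_profile(cohort, "A", "e_glob",
                           grid = density_grid(0.05, 0.40, 0.05))
    expect_true(all(diff(prof$value) >= -1e-12))
  }
})

test_that("permutation p-values follow the add-one formula and its bounds", {
  cohort <- small_cohort(n_regions = 8, n_a = 10, n_b = 10, seed = 12)
  pt <- permutation_test_auc(cohort, "cp",
                             grid = density_grid(0.1, 0.4, 0.1),
                             n_perm = 100, seed = 5)
  expect_equal(
    pt$p_two_tailed,
    (1 + sum(abs(pt$null_diffs) >= abs(pt$observed_diff))) / (100 + 1)
  )
  expect_gt(pt$p_two_tailed, 0)
  expect_lte(pt$p_two_tailed, 1)
  expect_length(pt$null_diffs, 100)
  expect_equal(pt$observed_diff, pt$observed_a - pt$observed_b)
})

test_that("a constant scalar statistic yields p = 1", {
  cohort <- small_cohort(n_regions = 6, n_a = 8, n_b = 8, seed = 13)
  pt <- permutation_test_scalar(cohort, function(ch, g) 1.5,
                                n_perm = 100, seed = 1,
                                statistic_name = "const")
  expect_equal(pt$p_two_tailed, 1)
  expect_equal(pt$observed_diff, 0)
})

test_that("scalar permutation test reports non-finite statistics by index", {
  cohort <- small_cohort(n_regions = 6, n_a = 8, n_b = 8, seed = 14)
  bad <- local({
    calls <- 0
    function(ch, g) {
      calls <<- calls + 1
      if (calls > 4) NaN else 1
    }
  })
  expect_error(
    permutation_test_scalar(cohort, bad, n_perm = 100, seed = 1),
    "permutation 2"
  )
})

test_that("hub and attack statistic factories work end to end", {
  cohort <- small_cohort(n_regions = 12, n_a = 20, n_b = 20, seed = 15)
  stat <- hub_betweenness_statistic("region_01", density = 0.25)
  v <- stat(cohort, "A")
  expect_true(is.finite(v) && v >= 0)
  rstat <- attack_robustness_statistic("node", fraction = 0.2,
                                       density = 0.25)
  expect_true(rstat(cohort, "A") <= 1)
  pt <- permutation_test_scalar(cohort, stat, n_perm = 100, seed = 2,
                                statistic_name = "nb_region_01")
  expect_s3_class(pt, "covnet_permutation")
  expect_gt(pt$p_two_tailed, 0)
})

test_that("bonferroni adjustment multiplies, caps and preserves order", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.4, m = 5), 1)
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- bonferroni_adjust(p, m = 8)
  expect_equal(adj, pmin(1, p * 8))
  expect_equal(order(adj), order(p))
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
  expect_error(bonferroni_adjust(0), "lie in")
})

test_that("the test is symmetric in which group is listed first", {
  # presenting group B first flips the sign of the observed difference;
  # |observed| enters the p-value symmetrically, so p agrees up to
  # Monte-Carlo noise in the relabelling draws
  cohort <- small_cohort(n_regions = 8, n_a = 10, n_b = 10, seed = 16)
  reordered <- dplyr::bind_rows(
    dplyr::filter(cohort, group == "B"),
    dplyr::filter(cohort, group == "A")
  )
  grid <- density_grid(0.1, 0.4, 0.1)
  pt1 <- permutation_test_auc(cohort, "e_glob", grid = grid,
                              n_perm = 200, seed = 9)
  pt2 <- permutation_test_auc(reordered, "e_glob", grid = grid,
                              n_perm = 200, seed = 9)
  expect_equal(pt1$observed_diff, -pt2$observed_diff)
  expect_lt(abs(pt1$p_two_tailed - pt2$p_two_tailed), 0.15)
})

test_that("tidy and autoplot methods return the expected shapes", {
  cohort <- small_cohort(n_regions = 8, n_a = 10, n_b = 10, seed = 17)
  pts <- permutation_test_auc(cohort, c("cp", "e_glob"),
                              grid = density_grid(0.1, 0.4, 0.1),
                              n_perm = 100, seed = 3)
  td <- tidy(pts)
  expect_equal(nrow(td), 2)
  expect_true(all(c("statistic", "observed_diff", "p_two_tailed") %in%
                    names(td)))
  prof <- metric_profile(cohort, "A", "cp",
                         grid = density_grid(0.1, 0.4, 0.1))
  expect_s3_class(autoplot(prof), "ggplot")
  expect_s3_class(autoplot(pts[[1]]), "ggplot")
  curve <- targeted_attack_curve(
    threshold_at_density(correlation_matrix(cohort, "A"), 0.25), "node"
  )
  expect_s3_class(autoplot(curve), "ggplot")
})
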