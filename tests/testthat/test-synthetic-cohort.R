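test_that("build_covariance places entries by module, hub and background rule", {
  # 2 modules of 2, no hubs
  spec <- covariance_spec(4, partition = c(1, 1, 2, 2),
                          r_within = 0.6, r_between = 0.1)
  r <- build_covariance(spec)
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(r[1, 2], 0.6)
  expect_equal(r[3, 4], 0.6)
  expect_equal(r[1, 3], 0.1)
  expect_equal(r[2, 4], 0.1)
  expect_true(isSymmetric(r))

  # single module at r_within = 0 is the identity
  spec0 <- covariance_spec(5, partition = 1, r_within = 0, r_between = 0)
  expect_equal(build_covariance(spec0), diag(5), ignore_attr = TRUE)

  # hub region radiates r_hub to every region outside its module
  spec_h <- covariance_spec(6, partition = c(1, 1, 2, 2, 3, 3),
                            r_within = 0.6, r_between = 0.1,
                            hub_regions = 1, r_hub = 0.4)
  rh <- build_covariance(spec_h)
  expect_equal(unname(rh[1, 3:6]), rep(0.4, 4))
  expect_equal(rh[1, 2], 0.6)
  expect_equal(rh[3, 5], 0.1)
  # and the result is positive semi-definite by dense eigendecomposition
  expect_gte(min(eigen(rh, symmetric = TRUE)$values), -1e-10)
})

test_that("PSD repair is bounded and repaired matrices stay correlations", {
  # three hubs on tight modules make the target mildly indefinite; the
  # eigenvalue-clipping repair must restore PSD and the unit diagonal while
  # moving no entry by more than 0.05
  spec <- covariance_spec(15, partition = 3,
                          r_within = 0.66, r_between = 0.04,
                          hub_regions = c(7, 11, 15), r_hub = 0.28)
  target <- ifelse(outer(spec$partition, spec$partition, "=="), 0.66, 0.04)
  is_hub <- seq_len(15) %in% c(7, 11, 15)
  hub_pair <- outer(is_hub, is_hub, "|") &
    !outer(spec$partition, spec$partition, "==")
  target[hub_pair] <- 0.28
  diag(target) <- 1
  expect_lt(min(eigen(target, symmetric = TRUE)$values), -1e-6)

  r <- build_covariance(spec)
  expect_equal(diag(r), rep(1, 15), ignore_attr = TRUE)
  expect_gte(min(eigen(r, symmetric = TRUE)$values), -1e-10)
  expect_true(isSymmetric(r))
  expect_lt(max(abs(r - target)), 0.05)

  # a grossly indefinite target cannot be repaired within tolerance
  harsh <- covariance_spec(12, partition = 3,
                           r_within = 0.85, r_between = 0.02,
                           hub_regions = c(1, 5, 9), r_hub = 0.8)
  expect_error(build_covariance(harsh), "beyond tolerance")
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(covariance_spec(4, partition = c(1, 1, 2), r_within = 0.5,
                               r_between = 0.1), "partition")
  expect_error(covariance_spec(4, 2, r_within = 1.0, r_between = 0.1),
               "r_within")
  expect_error(covariance_spec(4, 2, r_within = 0.3, r_between = 0.4),
               "r_between")
  expect_error(covariance_spec(4, 2, r_within = 0.5, r_between = 0.1,
                               hub_regions = 9, r_hub = 0.3), "out of range")
  expect_error(covariance_spec(4, 2, r_within = 0.5, r_between = 0.1,
                               hub_regions = 1, r_hub = 0.05), "r_hub")
})

test_that("generate_cohort produces the requested cohort shape", {
  specs <- default_cohort_specs()
  cohort <- generate_cohort(specs$control, specs$patient, 43, 73, seed = 7,
                            group_names = c("HC", "CD"))
  expect_equal(nrow(cohort), 116)
  expect_equal(length(covnet:::region_columns(cohort)), 68)
  expect_equal(unname(table(cohort$group)[c("HC", "CD")]),
               c(43L, 73L), ignore_attr = TRUE)
  expect_false(anyNA(cohort))
})

test_that("generation is deterministic under a seed and leaves the RNG alone", {
  specs <- default_cohort_specs(n_regions = 8)
  a <- generate_cohort(specs$control, specs$patient, 5, 5, seed = 11)
  set.seed(999)
  before <- .Random.seed
  b <- generate_cohort(specs$control, specs$patient, 5, 5, seed = 11)
  expect_identical(a, b)
  expect_identical(before, .Random.seed)
})

test_that("sample moments converge to the spec at large n", {
  spec <- covariance_spec(10, partition = c(rep(1, 5), rep(2, 5)),
                          r_within = 0.5, r_between = 0.1,
                          mean_thickness = 2.5, sd_thickness = 0.25)
  cohort <- generate_cohort(spec, spec, 5000, 3, seed = 3)
  vals <- covnet:::group_values(cohort, "A")
  expect_lt(max(abs(cor(vals) - build_covariance(spec))), 0.05)
  expect_lt(max(abs(colMeans(vals) / 2.5 - 1)), 0.05)
  expect_lt(max(abs(apply(vals, 2, sd) / 0.25 - 1)), 0.05)
})

test_that("mismatched specs are rejected", {
  s8 <- covariance_spec(8, 2, r_within = 0.5, r_between = 0.1)
  s6 <- covariance_spec(6, 2, r_within = 0.5, r_between = 0.1)
  expect_error(generate_cohort(s8, s6, 10, 10, seed = 1), "identical regions")
  expect_error(generate_cohort(s8, s8, 2, 10, seed = 1), "at least 3")
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  cohort <- small_cohort(n_regions = 6, n_a = 5, n_b = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  header <- readLines(path, n = 1)
  expect_match(header, "^subject,group,")
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort), tolerance = 1e-12)
})
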