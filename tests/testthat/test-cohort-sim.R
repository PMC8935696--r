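test_that("default cohort has the study size and passes table invariants", {
  tab <- generate_cohort(cohort_config(seed = 1))
  expect_identical(nrow(tab), 62L)
  expect_false(anyDuplicated(tab$id) > 0)
  expect_true(all(tab$age_years >= 20 & tab$age_years <= 83))
  expect_true(all(tab$psd_cm3 >= 0))
  expect_true(all(tab$max_retrograde_mL_s < 0))
  # identical seed, identical table
  expect_identical(tab, generate_cohort(cohort_config(seed = 1)))
})

test_that("identity dependence yields near-independent draws", {
  R <- diag(8)
  dimnames(R) <- list(psdflow:::COHORT_VARS, psdflow:::COHORT_VARS)
  tab <- generate_cohort(cohort_config(n_subjects = 10000,
                                       dependence_matrix = R,
                                       sex_psd_offset_cm3 = 0, seed = 5))
  rk <- cor(apply(as.data.frame(tab)[psdflow:::COHORT_VARS], 2, rank))
  expect_lt(max(abs(rk[upper.tri(rk)])), 0.05)
})

test_that("rank-correlation targets are recovered after the copula adjustment", {
  tab <- generate_cohort(cohort_config(n_subjects = 10000,
                                       sex_psd_offset_cm3 = 0, seed = 4))
  R <- psdflow:::default_dependence_matrix()
  for (pair in list(c("psd_cm3", "age_years"), c("psd_cm3", "csf_cm3"),
                    c("age_years", "gm_cm3"),
                    c("psd_cm3", "max_retrograde_mL_s"))) {
    got <- cor(rank(tab[[pair[1]]]), rank(tab[[pair[2]]]))
    expect_lt(abs(got - R[pair[1], pair[2]]), 0.03)
  }
})

test_that("a non-positive-definite dependence matrix is rejected by eigenvalue", {
  R <- matrix(0.9, 8, 8); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.9
  dimnames(R) <- list(psdflow:::COHORT_VARS, psdflow:::COHORT_VARS)
  expect_error(generate_cohort(cohort_config(dependence_matrix = R)),
               "eigenvalue")
})

test_that("cohort CSV round-trips and missing columns are named", {
  tab <- generate_cohort(cohort_config(n_subjects = 10, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, f)
  back <- read_cohort(f)
  expect_equal(back$psd_cm3, tab$psd_cm3, tolerance = 1e-12)
  bad <- as.data.frame(tab); bad$psd_cm3 <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(read_cohort(f2), "psd_cm3")
})
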