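# independent enumeration oracle used by the rank tests
enum_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in enum_perms(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

test_that("exact linear data is fit exactly", {
  tab <- data.frame(age_years = c(21, 30, 45, 52, 60, 70, 81),
                    y = 2 * c(21, 30, 45, 52, 60, 70, 81) + 3)
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_linear_model(tab, model_spec("y", "age_years")))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "age_years"], 2, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "(Intercept)"], 3, tolerance = 1e-8)
  expect_lt(max(co$ci_high - co$ci_low), 1e-6)
})

test_that("OLS matches a normal-equations oracle to 1e-8", {
  withr::with_seed(10, {
    for (r in 1:5) {
      n <- 40
      tab <- data.frame(age_years = runif(n, 20, 83),
                        icv_cm3 = rnorm(n, 1371, 130),
                        sex = sample(c("female", "male"), n, replace = TRUE))
      tab$psd_cm3 <- 5 + 0.04 * tab$age_years + 0.001 * tab$icv_cm3 +
        0.8 * (tab$sex == "male") + rnorm(n, 0, 1)
      fit <- fit_linear_model(tab, model_spec("psd_cm3",
                                              c("age_years", "sex",
                                                "icv_cm3")))
      X <- cbind(1, tab$age_years, as.numeric(tab$sex == "male"),
                 tab$icv_cm3)
      beta <- solve(t(X) %*% X, t(X) %*% tab$psd_cm3)
      got <- fit$coefficients$estimate[
        match(c("(Intercept)", "age_years", "sex", "icv_cm3"),
              fit$coefficients$term)]
      expect_equal(got, as.numeric(beta), tolerance = 1e-8)
    }
  })
})

test_that("model contracts are enforced", {
  tab <- data.frame(y = rnorm(10), a = rnorm(10), b = rep(1, 10))
  expect_error(fit_linear_model(tab, model_spec("y", c("a", "b"))),
               "constant")
  tab2 <- data.frame(y = rnorm(10), a = rnorm(10))
  tab2$c <- 2 * tab2$a
  expect_error(fit_linear_model(tab2, model_spec("y", c("a", "c"))),
               "collinear")
  expect_error(model_spec("y", c("a", "y")), "also listed")
  expect_error(fit_linear_model(data.frame(y = rnorm(3), a = rnorm(3),
                                           b = rnorm(3), c = rnorm(3)),
                                model_spec("y", c("a", "b", "c"))),
               "exceed")
})

test_that("permuted responses give nominal type-I error for the age term", {
  withr::with_seed(11, {
    n <- 40
    age <- runif(n, 20, 83)
    y <- rnorm(n)
    hits <- vapply(1:1000, function(i) {
      tab <- data.frame(age_years = age, y = sample(y))
      fit <- fit_linear_model(tab, model_spec("y", "age_years"))
      fit$coefficients$p[fit$coefficients$term == "age_years"] < 0.05
    }, logical(1))
    # binomial 3.5-sigma band around 0.05
    expect_lt(abs(mean(hits) - 0.05), 3.5 * sqrt(0.05 * 0.95 / 1000))
  })
})

test_that("the calibrated PSD-age effect is detected in most n=62 cohorts", {
  hits <- vapply(1:200, function(s) {
    tab <- generate_cohort(cohort_config(seed = 5000 + s))
    fit <- fit_linear_model(tab, model_spec("psd_cm3",
                                            c("age_years", "sex",
                                              "icv_cm3")))
    co <- fit$coefficients
    co$estimate[co$term == "age_years"] > 0 &
      co$p[co$term == "age_years"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("spearman_rho handles monotone, reversed and degenerate inputs", {
  x <- c(2, 5, 9, 11, 20, 31, 44, 50, 61)
  expect_equal(spearman_rho(x, exp(x / 20))$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  s <- spearman_rho(c(1, 2, 3, 4), c(7, 7, 7, 7))
  expect_true(is.na(s$rho))
  expect_match(attr(s, "reason"), "rank variance")
  expect_equal(spearman_rho(1:10, 10:1)$rho, spearman_rho(10:1, 1:10)$rho)
})

test_that("small-n spearman p equals the exhaustive permutation oracle", {
  x <- c(3, 1, 4, 1, 5, 9)        # ties present
  y <- c(2, 7, 1, 8, 2, 8)
  got <- spearman_rho(x, y)
  expect_identical(got$method, "exact permutation")
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rhos <- vapply(enum_perms(6L), function(p) cor(rx, ry[p]), numeric(1))
  expect_equal(got$rho, rho_obs)
  expect_equal(got$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
})

test_that("kruskal_wallis matches its oracles", {
  # identical distributions: H = 0
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(g)$H, 0, tolerance = 1e-12)
  same <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # three non-overlapping groups of 5 separate significantly
  sep <- kruskal_wallis(list(1:5, 11:15, 21:25))
  expect_lt(sep$p, 0.05)
  # chi-square p sits inside the exact permutation band at small n
  gr <- list(c(1.2, 3.4, 2.2, 5.0), c(4.1, 6.3, 5.5, 7.2), c(8.8, 9.1, 7.9, 10))
  kt <- kruskal_wallis(gr)
  expect_false(is.na(kt$p_exact))
  expect_lt(abs(kt$p - kt$p_exact), 0.05)
  # H agrees with kruskal.test including tie correction
  vals <- c(1, 2, 2, 3, 5, 5, 6, 8)
  gi <- factor(c(1, 1, 1, 2, 2, 2, 3, 3))
  expect_equal(psdflow:::kw_statistic(vals, gi),
               unname(kruskal.test(vals, gi)$statistic), tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Benjamini-Hochberg q-values follow the hand step-up", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  # order invariance and q >= p
  p <- c(0.001, 0.2, 0.04, 0.9, 0.012)
  q <- fdr_bh(p)
  prm <- c(3, 1, 5, 2, 4)
  expect_equal(fdr_bh(p[prm]), q[prm])
  expect_true(all(q >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("age groups use the printed inclusive boundaries", {
  expect_identical(as.character(assign_age_group(c(20, 39, 40, 59, 60, 83))),
                   c("young", "young", "middle", "middle", "older", "older"))
  expect_error(assign_age_group(19), "outside")
  expect_error(assign_age_group(84), "outside")
})

test_that("cohort summaries use sample SDs and flag degenerate groups", {
  tab <- generate_cohort(cohort_config(n_subjects = 30, seed = 3))
  s1 <- suppressWarnings(summarize_cohort(tab))
  # duplicating every row leaves means identical; sample SD shrinks slightly
  tab2 <- rbind(as.data.frame(tab), as.data.frame(tab))
  tab2$id <- sprintf("sub-%03d", seq_len(nrow(tab2)))
  class(tab2) <- c("cohort_table", "data.frame")
  s2 <- suppressWarnings(summarize_cohort(tab2))
  m1 <- s1$summary[s1$summary$group == "total" &
                     s1$summary$variable == "psd_cm3", ]
  m2 <- s2$summary[s2$summary$group == "total" &
                     s2$summary$variable == "psd_cm3", ]
  expect_equal(m1$mean, m2$mean)
  expect_equal(m2$sd, sd(rep(tab$psd_cm3, 2)))
  # single-subject group: SD 0 with a degenerate flag
  one <- generate_cohort(cohort_config(n_subjects = 12, seed = 8))
  one$age_years <- c(25, rep(c(45, 70), length.out = 11))
  expect_warning(s3 <- summarize_cohort(one), "size 1")
  expect_identical(s3$degenerate_groups, "young")
})

test_that("large-cohort summary means match configured marginals within 2%", {
  tab <- generate_cohort(cohort_config(n_subjects = 10000, seed = 6))
  cfg <- cohort_config()
  s <- summarize_cohort(tab)
  tot <- s$summary[s$summary$group == "total", ]
  for (v in c("icv_cm3", "csf_cm3", "gm_cm3", "wm_cm3", "psd_cm3")) {
    expect_lt(abs(tot$mean[tot$variable == v] /
                    cfg$marginal_means[[v]] - 1), 0.02)
  }
})

test_that("the spearman panel carries within-panel q-values", {
  tab <- generate_cohort(cohort_config(seed = 9))
  pan <- spearman_panel(tab)
  expect_identical(nrow(pan), 28L)
  expect_true(all(pan$q >= pan$p - 1e-12))
  got <- pan[pan$var1 == "age_years" & pan$var2 == "psd_cm3", ]
  expect_gt(got$rho, 0.2)
})
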