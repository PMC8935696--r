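# Gaussian-copula synthetic cohort generator. The study cohort is available
# only as marginal summaries and pairwise Spearman coefficients, so subjects
# are drawn from a Gaussian copula whose latent Pearson correlations are
# adjusted so the *rank* correlations hit their targets
# (rho_P = 2 sin(pi * rho_S / 6) for the Gaussian copula).

COHORT_VARS <- c("age_years", "icv_cm3", "csf_cm3", "gm_cm3", "wm_cm3",
                 "psd_cm3", "max_anterograde_mL_s", "max_retrograde_mL_s")

default_dependence_matrix <- function() {
  v <- COHORT_VARS
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  set2 <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  # printed pairwise Spearman coefficients of the emulated study
  set2("age_years", "csf_cm3", 0.79)
  set2("age_years", "gm_cm3", -0.79)
  set2("age_years", "psd_cm3", 0.59)
  set2("age_years", "max_anterograde_mL_s", 0.36)
  set2("age_years", "max_retrograde_mL_s", -0.40)
  set2("csf_cm3", "psd_cm3", 0.60)
  set2("csf_cm3", "max_retrograde_mL_s", -0.45)
  set2("psd_cm3", "max_anterograde_mL_s", 0.36)
  set2("psd_cm3", "max_retrograde_mL_s", -0.50)
  # remaining cells: plausible weak structure keeping the matrix PD
  set2("age_years", "wm_cm3", -0.15)
  set2("icv_cm3", "csf_cm3", 0.25)
  set2("icv_cm3", "gm_cm3", 0.35)
  set2("icv_cm3", "wm_cm3", 0.35)
  set2("icv_cm3", "psd_cm3", 0.10)
  set2("csf_cm3", "gm_cm3", -0.50)
  set2("csf_cm3", "wm_cm3", -0.15)
  set2("csf_cm3", "max_anterograde_mL_s", 0.20)
  set2("gm_cm3", "wm_cm3", 0.30)
  set2("gm_cm3", "psd_cm3", -0.35)
  set2("gm_cm3", "max_anterograde_mL_s", -0.15)
  set2("gm_cm3", "max_retrograde_mL_s", 0.20)
  set2("wm_cm3", "psd_cm3", -0.10)
  set2("psd_cm3", "icv_cm3", 0.10)
  set2("max_anterograde_mL_s", "max_retrograde_mL_s", -0.55)
  R
}

#' Configuration of the synthetic cohort generator
#'
#' Marginal means/SDs default to the emulated study's whole-cohort summary:
#' ICV 1371 (130), CSF 280 (53), GM 675 (59), WM 415 (52), PSD 8.36 (2.17)
#' cm^3; maximum anterograde flow 0.10 (0.06) and maximum retrograde flow
#' -0.12 (0.06) mL/s (retrograde stored signed-negative). Age is uniform on
#' `age_range_years`; all other marginals are Gaussian, truncated at
#' physiologically sensible floors.
#'
#' @param n_subjects cohort size (default 62).
#' @param age_range_years numeric length-2 (default c(20, 83)).
#' @param marginal_means,marginal_sds named vectors over the non-age cohort
#'   variables.
#' @param dependence_matrix target Spearman rank-correlation matrix over
#'   `age_years, icv_cm3, csf_cm3, gm_cm3, wm_cm3, psd_cm3,
#'   max_anterograde_mL_s, max_retrograde_mL_s`.
#' @param sex_ratio_female fraction female (default 42/65).
#' @param sex_psd_offset_cm3 additive PSD offset for males, mean-centred so
#'   the marginal mean is preserved (cm^3).
#' @param systolic_fraction,cycle_duration_s waveform shape used to derive
#'   per-cycle flow volumes from the peak flows.
#' @param seed integer seed.
#' @return list of class `cohort_gen_config`.
#' @export
cohort_config <- function(n_subjects = 62L,
                          age_range_years = c(20, 83),
                          marginal_means = c(icv_cm3 = 1371, csf_cm3 = 280,
                                             gm_cm3 = 675, wm_cm3 = 415,
                                             psd_cm3 = 8.36,
                                             max_anterograde_mL_s = 0.10,
                                             max_retrograde_mL_s = -0.12),
                          marginal_sds = c(icv_cm3 = 130, csf_cm3 = 53,
                                           gm_cm3 = 59, wm_cm3 = 52,
                                           psd_cm3 = 2.17,
                                           max_anterograde_mL_s = 0.06,
                                           max_retrograde_mL_s = 0.06),
                          dependence_matrix = default_dependence_matrix(),
                          sex_ratio_female = 42 / 65,
                          sex_psd_offset_cm3 = 1.2,
                          systolic_fraction = 0.6,
                          cycle_duration_s = 1.0,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              age_range_years = as.numeric(age_range_years),
              marginal_means = marginal_means, marginal_sds = marginal_sds,
              dependence_matrix = dependence_matrix,
              sex_ratio_female = sex_ratio_female,
              sex_psd_offset_cm3 = sex_psd_offset_cm3,
              systolic_fraction = systolic_fraction,
              cycle_duration_s = cycle_duration_s,
              seed = as.integer(seed))
  if (cfg$n_subjects < 3L) stop("cohort_config: n_subjects must be >= 3")
  if (any(cfg$marginal_sds < 0)) stop("cohort_config: marginal SDs must be >= 0")
  R <- cfg$dependence_matrix
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("cohort_config: dependence_matrix must be symmetric with unit diagonal")
  class(cfg) <- "cohort_gen_config"
  cfg
}

#' Generate a synthetic cohort table
#'
#' Draws latent correlated Gaussians from the rank-adjusted copula, maps them
#' to the configured marginals, applies the sex offset to PSD volume, and
#' derives net flow, absolute flow and regurgitant fraction from the two peak
#' flows through the default biphasic waveform shape.
#'
#' @param config a [cohort_gen_config].
#' @return a `data.frame` of class `cohort_table`, one row per subject.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_gen_config"))
  R_s <- config$dependence_matrix[COHORT_VARS, COHORT_VARS]
  R_p <- 2 * sin(pi * R_s / 6)  # Pearson-to-Spearman adjustment
  diag(R_p) <- 1
  ev <- eigen(R_p, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("generate_cohort: dependence matrix is not positive definite after ",
         "copula adjustment (smallest eigenvalue ", signif(min(ev), 4), ")")
  withr::with_seed(config$seed, {
    n <- config$n_subjects
    L <- chol(R_p)
    z <- matrix(rnorm(n * ncol(R_p)), n) %*% L
    u <- pnorm(z)
    colnames(u) <- COHORT_VARS
    tab <- data.frame(id = sprintf("sub-%03d", seq_len(n)))
    tab$age_years <- config$age_range_years[1] +
      u[, "age_years"] * diff(config$age_range_years)
    tab$sex <- ifelse(rbinom(n, 1, config$sex_ratio_female) == 1,
                      "female", "male")
    for (v in setdiff(COHORT_VARS, "age_years")) {
      x <- qnorm(u[, v], config$marginal_means[[v]], config$marginal_sds[[v]])
      tab[[v]] <- x
    }
    # physiological floors (volumes positive, flows directional)
    for (v in c("icv_cm3", "csf_cm3", "gm_cm3", "wm_cm3", "psd_cm3"))
      tab[[v]] <- pmax(tab[[v]], 0.05 * config$marginal_means[[v]])
    tab$max_anterograde_mL_s <- pmax(tab$max_anterograde_mL_s, 0.005)
    tab$max_retrograde_mL_s <- pmin(tab$max_retrograde_mL_s, -0.005)
    male <- tab$sex == "male"
    tab$psd_cm3 <- tab$psd_cm3 +
      config$sex_psd_offset_cm3 * (male - mean(male))
    tab$psd_cm3 <- pmax(tab$psd_cm3, 0.05 * config$marginal_means[["psd_cm3"]])
    # per-cycle flow volumes from the biphasic waveform shape:
    # integral of a half-sine lobe = (2/pi) * peak * lobe duration
    fs <- config$systolic_fraction; Tt <- config$cycle_duration_s
    vol_a <- (2 / pi) * tab$max_anterograde_mL_s * fs * Tt
    vol_r <- (2 / pi) * abs(tab$max_retrograde_mL_s) * (1 - fs) * Tt
    tab$net_flow_mL <- vol_a - vol_r
    tab$absolute_flow_mL <- vol_a + vol_r
    tab$regurgitant_fraction <- vol_r / vol_a
    class(tab) <- c("cohort_table", "data.frame")
    validate_cohort_table(tab, config$age_range_years)
    tab
  })
}

validate_cohort_table <- function(tab, age_range = c(20, 83)) {
  req <- c("id", "age_years", "sex", "icv_cm3", "csf_cm3", "gm_cm3",
           "wm_cm3", "psd_cm3", "max_anterograde_mL_s",
           "max_retrograde_mL_s")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("cohort table: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("cohort table: duplicated subject ids")
  if (any(tab$age_years < age_range[1] - 1e-9 |
          tab$age_years > age_range[2] + 1e-9))
    stop("cohort table: ages outside [", age_range[1], ", ", age_range[2], "]")
  vols <- c("icv_cm3", "csf_cm3", "gm_cm3", "wm_cm3", "psd_cm3")
  if (any(unlist(tab[vols]) < 0)) stop("cohort table: negative volumes")
  invisible(tab)
}

#' Read / write cohort tables as CSV
#' @param tab a `cohort_table`.
#' @param path CSV file path.
#' @return `read_cohort()` returns a validated `cohort_table`.
#' @export
write_cohort <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  validate_cohort_table(tab)
  tab
}
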