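# Cohort statistics: the three multivariate linear-model specifications,
# Spearman rank correlation (with an exact permutation option at small n),
# Kruskal-Wallis age-group tests (idem), Benjamini-Hochberg FDR, Wald
# intervals, and Table-1-style cohort summaries.

#' Model specifications of the cohort analysis
#'
#' The three hypotheses tested on each dependent variable: M1 regresses on
#' demographics and intracranial volume; M2 on demographics and the three
#' tissue volumes; M3 (for PSD volume) on the CSF flow metrics plus
#' demographics.
#'
#' @param dependent dependent-variable column name.
#' @param independents character vector of covariate column names.
#' @param name model label.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(dependent, independents, name = "model") {
  if (dependent %in% independents)
    stop("model_spec: dependent variable also listed among independents")
  structure(list(dependent = dependent, independents = independents,
                 name = name), class = "model_spec")
}

#' @rdname model_spec
#' @export
default_model_specs <- function(dependent = "psd_cm3") {
  list(
    M1_demographics_icv = model_spec(dependent,
      c("age_years", "sex", "icv_cm3"), "M1_demographics_icv"),
    M2_tissue_volumes = model_spec(dependent,
      c("age_years", "sex", "csf_cm3", "gm_cm3", "wm_cm3"),
      "M2_tissue_volumes"),
    M3_psd_flow = model_spec(dependent,
      c("max_anterograde_mL_s", "max_retrograde_mL_s", "age_years", "sex"),
      "M3_psd_flow"))
}

#' Fit a linear cohort model with Wald intervals and FDR-adjusted p-values
#'
#' Ordinary least squares with intercept; sex is coded 0/1 (female = 0).
#' 95% confidence intervals use the Wald method, estimate +/- z * SE with
#' z = 1.96 by default (`use_t = TRUE` switches to the t quantile), and
#' two-sided Wald p-values to match. q-values are Benjamini-Hochberg
#' adjusted within the model's non-intercept term family.
#'
#' @param table a `cohort_table` (or data.frame with the model columns).
#' @param spec a [model_spec].
#' @param conf_level confidence level (default 0.95).
#' @param use_t use the t rather than normal quantile.
#' @return list of class `fit_result`: `coefficients` (data.frame with term,
#'   estimate, se, ci_low, ci_high, p, q), `n`, `spec`, `lm_fit`.
#' @export
fit_linear_model <- function(table, spec, conf_level = 0.95, use_t = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$dependent, spec$independents)
  miss <- setdiff(vars, names(table))
  if (length(miss))
    stop("fit_linear_model: column(s) not in table: ",
         paste(miss, collapse = ", "))
  df <- as.data.frame(table)[vars]
  if ("sex" %in% names(df))
    df$sex <- as.numeric(df$sex == "male")          # female = 0
  const <- vapply(df[spec$independents], function(x) var(as.numeric(x)) == 0,
                  logical(1))
  if (any(const))
    stop("fit_linear_model: constant-valued covariate(s): ",
         paste(names(const)[const], collapse = ", "))
  n <- nrow(df)
  if (n <= length(spec$independents) + 1L)
    stop("fit_linear_model: n must exceed the number of terms + 1")
  form <- stats::reformulate(spec$independents, response = spec$dependent)
  fit <- lm(form, data = df)
  if (fit$rank < length(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("fit_linear_model: rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  zq <- if (use_t) stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
        else qnorm(1 - (1 - conf_level) / 2)
  z <- est / se
  p <- if (use_t) 2 * pt(-abs(z), df = fit$df.residual) else 2 * pnorm(-abs(z))
  co <- data.frame(term = names(est), estimate = unname(est),
                   se = unname(se),
                   ci_low = unname(est - zq * se),
                   ci_high = unname(est + zq * se),
                   p = unname(p), q = NA_real_, row.names = NULL)
  fam <- co$term != "(Intercept)"
  co$q[fam] <- fdr_bh(co$p[fam])
  structure(list(coefficients = co, n = n, spec = spec, lm_fit = fit),
            class = "fit_result")
}

# All distinct permutations of a small vector (n! rows).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). The p-value
#' uses the t approximation; for n <= `exact_n` it is computed exactly by
#' enumerating all n! rank permutations (two-sided, counting |rho| >=
#' |rho_obs|).
#'
#' @param x,y numeric vectors.
#' @param exact_n exhaustive-enumeration cutoff (default 8).
#' @return list: `rho`, `p`, `method`. `rho` is NA (with a reason attribute)
#'   when either variable has zero rank variance.
#' @export
spearman_rho <- function(x, y, exact_n = 8L) {
  if (length(x) != length(y)) stop("spearman_rho: length mismatch")
  n <- length(x)
  if (n < 3L) stop("spearman_rho: need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("spearman_rho: non-finite values")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    out <- list(rho = NA_real_, p = NA_real_, method = "undefined")
    attr(out, "reason") <- "zero rank variance"
    return(out)
  }
  rho <- cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    ryv <- ry
    rhos <- apply(perms, 1, function(pm) cor(rx, ryv[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    p <- ct$p.value
    method <- "t approximation"
  }
  list(rho = rho, p = p, method = method)
}

kw_statistic <- function(values, groups) {
  # tie-corrected Kruskal-Wallis H (used by the exact permutation option)
  r <- rank(values)
  n <- length(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(g) length(g) * mean(g)^2)) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  H
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction and the chi-square approximation for p
#' (via `kruskal.test`). For total n <= `exact_n`, an exact permutation
#' p-value is computed by enumerating all distinct assignments of the pooled
#' values to the group sizes.
#'
#' @param groups list of numeric vectors (one per group).
#' @param exact_n exhaustive-enumeration cutoff on total n (default 12).
#' @return list: `H`, `p` (chi-square), `p_exact` (NA above the cutoff),
#'   `df`.
#' @export
kruskal_wallis <- function(groups, exact_n = 12L) {
  if (length(groups) < 2L) stop("kruskal_wallis: need >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("kruskal_wallis: empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, p_exact = if (length(values) <= exact_n) 1
                else NA_real_, df = length(groups) - 1L))
  kt <- kruskal.test(values, g)
  H <- unname(kt$statistic); p <- kt$p.value
  p_exact <- NA_real_
  n <- length(values)
  if (n <= exact_n) {
    sizes <- lengths(groups)
    Hobs <- kw_statistic(values, g)
    # enumerate distinct multiset partitions of indices into the group sizes
    assigns <- list(list(remaining = seq_len(n), groups = list()))
    for (s in sizes) {
      nxt <- list()
      for (a in assigns) {
        cmb <- combn(a$remaining, s, simplify = FALSE)
        for (cc in cmb)
          nxt[[length(nxt) + 1L]] <-
            list(remaining = setdiff(a$remaining, cc),
                 groups = c(a$groups, list(cc)))
      }
      assigns <- nxt
    }
    Hs <- vapply(assigns, function(a) {
      gi <- integer(n)
      for (j in seq_along(a$groups)) gi[a$groups[[j]]] <- j
      kw_statistic(values, factor(gi))
    }, numeric(1))
    p_exact <- mean(Hs >= Hobs - 1e-12)
  }
  list(H = H, p = p, p_exact = p_exact, df = length(groups) - 1L)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; invariant to input
#' ordering.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values, same order as input.
#' @export
fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("fdr_bh: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Assign the study age group
#'
#' Young 20-39, middle 40-59, older 60-83 years, boundaries inclusive.
#' @param age_years numeric vector.
#' @return factor with levels young/middle/older.
#' @export
assign_age_group <- function(age_years) {
  if (any(age_years < 20 | age_years > 83))
    stop("assign_age_group: age outside [20, 83]")
  cut(age_years, breaks = c(20, 40, 60, 83.001), right = FALSE,
      include.lowest = TRUE, labels = c("young", "middle", "older"))
}

#' Table-1-style cohort summary
#'
#' Per age group and for the whole cohort: n, sex split, and mean (sample
#' SD) of each variable, with a Kruskal-Wallis p-value across age groups per
#' variable. Groups of size 1 are reported with SD 0 and flagged.
#'
#' @param table a `cohort_table`.
#' @param variables columns to summarise.
#' @return list of class `cohort_summary`: `summary` (data.frame, one row
#'   per variable x group), `kruskal_p` (named vector), `counts`,
#'   `degenerate_groups`.
#' @export
summarize_cohort <- function(table,
                             variables = c("age_years", "icv_cm3", "csf_cm3",
                                           "gm_cm3", "wm_cm3",
                                           "max_anterograde_mL_s",
                                           "max_retrograde_mL_s", "psd_cm3")) {
  df <- as.data.frame(table)
  if (nrow(df) == 0L) stop("summarize_cohort: empty table")
  grp <- assign_age_group(df$age_years)
  lv <- levels(grp)
  counts <- c(setNames(tabulate(grp, nbins = length(lv)), lv),
              total = nrow(df))
  sexes <- vapply(c(lv, "total"), function(g) {
    sel <- if (g == "total") rep(TRUE, nrow(df)) else grp == g
    sprintf("%d/%d", sum(df$sex[sel] == "female"), sum(df$sex[sel] == "male"))
  }, character(1))
  degenerate <- names(counts)[counts == 1L]
  if (length(degenerate))
    warning("summarize_cohort: group(s) of size 1 (SD reported as 0): ",
            paste(degenerate, collapse = ", "))
  rows <- list()
  kw_p <- setNames(rep(NA_real_, length(variables)), variables)
  for (v in variables) {
    for (g in c(lv, "total")) {
      sel <- if (g == "total") rep(TRUE, nrow(df)) else grp == g
      x <- df[[v]][sel]
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, group = g, n = length(x),
                   mean = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1L) sd(x) else if (length(x) == 1L) 0
                        else NA_real_)
    }
    by_grp <- split(df[[v]], grp)
    by_grp <- by_grp[lengths(by_grp) > 0L]
    if (length(by_grp) >= 2L && v != "age_years")
      kw_p[v] <- kruskal_wallis(by_grp)$p
  }
  structure(list(summary = do.call(rbind, rows), kruskal_p = kw_p,
                 counts = counts, sex_split = sexes,
                 degenerate_groups = degenerate),
            class = "cohort_summary")
}

#' Spearman correlation panel with FDR correction
#'
#' All pairwise Spearman correlations among the given columns, with
#' Benjamini-Hochberg q-values adjusted within the panel.
#'
#' @param table a `cohort_table`.
#' @param variables columns to correlate.
#' @return data.frame: var1, var2, rho, p, q.
#' @export
spearman_panel <- function(table,
                           variables = c("age_years", "icv_cm3", "csf_cm3",
                                         "gm_cm3", "wm_cm3", "psd_cm3",
                                         "max_anterograde_mL_s",
                                         "max_retrograde_mL_s")) {
  df <- as.data.frame(table)
  prs <- combn(variables, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    s <- spearman_rho(df[[a]], df[[b]])
    data.frame(var1 = a, var2 = b, rho = s$rho, p = s$p)
  }))
  out$q <- fdr_bh(out$p)
  out
}
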