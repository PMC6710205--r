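#' Welch two-sample t-test from summaries or raw vectors
#'
#' Unequal-variance t-test with Welch–Satterthwaite degrees of freedom and
#' a two-sided p-value. Group tables in the clinical literature usually
#' print only means, SDs and ns, so the summary form is first-class: it
#' reproduces a published p-value from the printed summaries alone. Raw
#' vectors are reduced to their summaries first (dropping `NA`s), so both
#' routes agree exactly.
#'
#' @param m1,m2 Group means, or (when `n1` is `NULL` and both are vectors
#'   of length > 1) the raw observation vectors.
#' @param s1,s2 Group SDs.
#' @param n1,n2 Group sizes (`>= 2`).
#' @return A one-row tibble with `statistic`, `df`, `p`, `estimate` (mean
#'   difference), `n1`, `n2`.
#' @examples
#' welch_t(1.1546, 0.6461, 16, 0.5449, 0.6031, 36)$p
#' @export
welch_t <- function(m1, s1 = NULL, n1 = NULL, m2 = NULL, s2 = NULL,
                    n2 = NULL) {
  if (is.null(n1) && length(m1) > 1L && length(s1) > 1L) {
    x <- m1[!is.na(m1)]; y <- s1[!is.na(s1)]
    m1 <- mean(x); s1 <- sd(x); n1 <- length(x)
    m2 <- mean(y); s2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) dvr_abort("Need n >= 2 per group.", "dvr_bad_n")
  if (s1 < 0 || s2 < 0) dvr_abort("SDs must be >= 0.", "dvr_bad_sd")
  if (s1 == 0 && s2 == 0) {
    dvr_abort("degenerate variance: both group SDs are zero.",
              "dvr_degenerate_variance")
  }
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se2 <- v1 + v2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(statistic = stat, df = df, p = 2 * pt(-abs(stat), df),
         estimate = m1 - m2, n1 = n1, n2 = n2)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1, two-sided),
#' as used for categorical demographics in clinical group tables.
#'
#' @param a,b First row counts (e.g. users / non-users among controls).
#' @param c,d Second row counts (patients).
#' @return A one-row tibble with `statistic`, `df`, `p`, and the four
#'   counts.
#' @examples
#' chi2_2x2(9, 7, 14, 22)$p
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    dvr_abort("Counts must be nonnegative integers.", "dvr_bad_counts")
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    dvr_abort("All table margins must be positive.", "dvr_zero_margin")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = 1,
         p = unname(ct$p.value), a = a, b = b, c = c, d = d)
}

# internal: coerce gender-like columns to 0/1 numerics
binary_numeric <- function(v) {
  if (is.numeric(v)) return(v)
  f <- factor(v)
  if (nlevels(f) > 2L) {
    dvr_abort("Binary covariate has more than two levels.", "dvr_bad_covariate")
  }
  as.numeric(f) - 1
}

#' Covariate adjustment by fixed-effects regression
#'
#' Separates the effects of nuisance covariates (by default age, gender
#' and education) from a marker or score: the variable is regressed on the
#' covariates by ordinary least squares over all subjects pooled, and each
#' subject's adjusted value is their residual plus the fitted value at the
#' control-group covariate means. Anchoring at the control means leaves
#' the control-group mean of the adjusted variable exactly equal to its
#' unadjusted mean, so before/after group tables remain directly
#' comparable.
#'
#' @param data A subject table (see [generate_cohort()] /
#'   [read_subject_table()]) with a `group` column.
#' @param variable Name of the column to adjust (string).
#' @param covariates Character vector of covariate columns.
#' @param control Group label whose covariate means anchor the adjustment.
#' @return Numeric vector of adjusted values aligned with `data` rows
#'   (`NA` where the variable or a covariate is missing);
#'   `attr(, "coefficients")` holds the OLS coefficients.
#' @export
covariate_adjust <- function(data, variable,
                             covariates = c("age", "gender", "education"),
                             control = "CS") {
  missing_cols <- setdiff(c(variable, covariates, "group"), names(data))
  if (length(missing_cols) > 0L) {
    dvr_abort(paste0("Missing column(s): ",
                     paste(missing_cols, collapse = ", ")), "dvr_bad_table")
  }
  d <- data[, c("group", variable, covariates)]
  for (cv in covariates) d[[cv]] <- binary_numeric(d[[cv]])
  cc <- complete.cases(d[, c(variable, covariates)])
  if (sum(cc) < length(covariates) + 2L) {
    dvr_abort("Too few complete cases for covariate adjustment.",
              "dvr_too_few_cases")
  }
  X <- as.matrix(d[cc, covariates, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    dvr_abort("Covariates are collinear.", "dvr_collinear")
  }
  f <- stats::reformulate(covariates, response = variable)
  fit <- lm(f, data = d, na.action = stats::na.exclude)
  cs_rows <- cc & d$group == control
  if (!any(cs_rows)) {
    dvr_abort(paste0("No complete cases in control group '", control, "'."),
              "dvr_bad_table")
  }
  cs_means <- colMeans(d[cs_rows, covariates, drop = FALSE])
  anchor <- unname(coef(fit)[1L] +
                     sum(coef(fit)[-1L] * cs_means[covariates]))
  out <- residuals(fit) + anchor
  attr(out, "coefficients") <- coef(fit)
  out
}

#' Pearson correlation with pairwise-complete deletion
#'
#' Pearson r with the two-sided p-value from the t transform on `n - 2`
#' degrees of freedom; incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble with `estimate` (r), `statistic`, `df`, `p`,
#'   `n` (complete pairs used).
#' @export
pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) {
    dvr_abort("Need at least 4 complete pairs.", "dvr_too_few_cases")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    dvr_abort("Zero variance in x or y.", "dvr_degenerate_variance")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

#' Simple linear regression of y on x
#'
#' Ordinary least squares line with `r^2` (the squared Pearson
#' correlation) and the two-sided p-value for a nonzero slope.
#'
#' @param x,y Numeric vectors of equal length (incomplete pairs dropped).
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`, `p`,
#'   `n`.
#' @export
simple_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) dvr_abort("Need n >= 3.", "dvr_too_few_cases")
  if (sd(x) == 0) dvr_abort("Constant x.", "dvr_degenerate_variance")
  fit <- lm(y ~ x)
  # a perfect fit is legitimate here (exact synthetic lines); silence the
  # summary.lm advisory rather than surface it to every caller
  sm <- suppressWarnings(summary(fit))
  tibble(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r_squared = sm$r.squared,
         p = unname(sm$coefficients[2L, 4L]), n = length(x))
}

#' Group comparison table before and after covariate adjustment
#'
#' For each marker/score: group means and SDs, the Welch p-value, and the
#' same after fixed-effects covariate adjustment ([covariate_adjust()]),
#' with significance flags at p < 0.05 and p < 0.01 — the layout of a
#' clinical marker-comparison table.
#'
#' @param data A subject table with a `group` column.
#' @param variables Columns to compare; defaults to every numeric column
#'   other than id and the covariates.
#' @param covariates Covariates for the adjusted columns.
#' @param control,case The two group labels (control group first).
#' @return A tibble of class `dvr_group_table`, one row per variable, with
#'   columns `variable`, `mean_cs`, `sd_cs`, `mean_mp`, `sd_mp`,
#'   `p_before`, `mean_cs_adj`, `sd_cs_adj`, `mean_mp_adj`, `sd_mp_adj`,
#'   `p_after`, `sig_before`, `sig_after` (`""`, `"*"` p<0.05, `"**"`
#'   p<0.01). Variables entirely missing in one group are dropped with a
#'   warning.
#' @export
group_table <- function(data, variables = NULL,
                        covariates = c("age", "gender", "education"),
                        control = "CS", case = "MP") {
  if (!all(c(control, case) %in% data$group)) {
    dvr_abort("Both groups must be present.", "dvr_bad_table")
  }
  if (min(table(factor(data$group, levels = c(control, case)))) < 2L) {
    dvr_abort("Need at least 2 subjects per group.", "dvr_bad_n")
  }
  if (is.null(variables)) {
    skip <- c("id", "group", covariates)
    variables <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         skip)
  }
  is_cs <- data$group == control
  is_mp <- data$group == case
  flag <- function(p) dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*",
                                       TRUE ~ "")
  rows <- purrr::map(variables, function(v) {
    x_cs <- data[[v]][is_cs]; x_mp <- data[[v]][is_mp]
    if (all(is.na(x_cs)) || all(is.na(x_mp))) {
      warn(paste0("group_table: '", v,
                  "' entirely missing in one group; excluded."),
           class = "dvr_variable_excluded")
      return(NULL)
    }
    before <- welch_t(x_cs, x_mp)
    adj <- covariate_adjust(data, v, covariates = covariates,
                            control = control)
    after <- welch_t(adj[is_cs], adj[is_mp])
    tibble(
      variable = v,
      mean_cs = mean(x_cs, na.rm = TRUE), sd_cs = sd(x_cs, na.rm = TRUE),
      mean_mp = mean(x_mp, na.rm = TRUE), sd_mp = sd(x_mp, na.rm = TRUE),
      p_before = before$p,
      mean_cs_adj = mean(adj[is_cs], na.rm = TRUE),
      sd_cs_adj = sd(adj[is_cs], na.rm = TRUE),
      mean_mp_adj = mean(adj[is_mp], na.rm = TRUE),
      sd_mp_adj = sd(adj[is_mp], na.rm = TRUE),
      p_after = after$p,
      n_cs = sum(!is.na(x_cs)), n_mp = sum(!is.na(x_mp)))
  })
  out <- dplyr::bind_rows(rows)
  out$sig_before <- flag(out$p_before)
  out$sig_after <- flag(out$p_after)
  structure(out, class = c("dvr_group_table", class(out)))
}

#' Pairwise Pearson correlation matrix
#'
#' Symmetric matrix of Pearson correlations with per-cell two-sided
#' p-values and pairwise-complete sample sizes. Cells whose test fails
#' (zero variance, too few pairs) are set to `NA` without aborting the
#' rest of the matrix.
#'
#' @param data A subject table.
#' @param variables Columns to correlate; defaults to every numeric
#'   column other than id/group/covariates.
#' @return An object of class `dvr_corr_matrix`: list of matrices `r`,
#'   `p`, `n`. `tidy()` returns the lower triangle as a long tibble.
#' @export
correlation_matrix <- function(data, variables = NULL) {
  if (is.null(variables)) {
    skip <- c("id", "group", "age", "gender", "education")
    variables <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         skip)
  }
  if (nrow(data) < 4L) {
    dvr_abort("Need at least 4 subjects.", "dvr_too_few_cases")
  }
  k <- length(variables)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  diag(nm) <- vapply(variables, function(v) sum(!is.na(data[[v]])), numeric(1))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cell <- tryCatch(pearson(data[[variables[i]]], data[[variables[j]]]),
                       error = function(e) NULL)
      if (!is.null(cell)) {
        r[i, j] <- r[j, i] <- cell$estimate
        p[i, j] <- p[j, i] <- cell$p
        nm[i, j] <- nm[j, i] <- cell$n
      }
    }
  }
  structure(list(r = r, p = p, n = nm, variables = variables),
            class = "dvr_corr_matrix")
}

#' @export
print.dvr_corr_matrix <- function(x, digits = 3, ...) {
  cat("<dvr_corr_matrix> Pearson r (pairwise-complete):\n")
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname correlation_matrix
#' @param x A `dvr_corr_matrix`.
#' @param ... Unused.
#' @method tidy dvr_corr_matrix
#' @export
tidy.dvr_corr_matrix <- function(x, ...) {
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble(var1 = x$variables[idx[, 2L]], var2 = x$variables[idx[, 1L]],
         r = x$r[idx], p = x$p[idx], n = x$n[idx])
}
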