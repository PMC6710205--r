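#' Discrete Laguerre basis
#'
#' Constructs the first `L` discrete-time Laguerre functions with decay
#' parameter `alpha`, truncated to a memory of `M` samples. These form an
#' orthonormal family of exponentially decaying sequences and are the
#' conventional compact basis for expanding slow physiological
#' impulse-response kernels: the zeroth function is
#' \eqn{b_0(m) = \sqrt{1-\alpha^2}\,\alpha^m} and higher orders follow the
#' standard recursion
#' \eqn{b_j(m) = \alpha b_j(m-1) + b_{j-1}(m-1) - \alpha b_{j-1}(m)}.
#'
#' @param alpha Decay parameter in `[0, 1)`. Larger values give slower decay
#'   and therefore longer effective memory.
#' @param L Number of basis functions (model order), `>= 1`.
#' @param M Memory length in samples, `>= L`. Orthonormality over the
#'   truncated support holds up to a truncation error of order `alpha^M`.
#' @return An object of class `laguerre_basis`: a list with `alpha`, `L`,
#'   `M` and `values`, an `L x M` matrix whose row `j` holds
#'   \eqn{b_{j-1}(m)} for lags `m = 0, ..., M-1`.
#' @examples
#' b <- laguerre_basis(0.5, L = 3, M = 60)
#' # rows are orthonormal:
#' round(tcrossprod(b$values), 6)
#' @export
laguerre_basis <- function(alpha, L, M) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1) {
    dvr_abort("`alpha` must be a single number in [0, 1).", "dvr_bad_alpha")
  }
  if (L < 1) dvr_abort("`L` must be >= 1.", "dvr_bad_order")
  if (M < L) dvr_abort("`M` must be >= L.", "dvr_bad_memory")
  L <- as.integer(L); M <- as.integer(M)

  B <- matrix(0, nrow = L, ncol = M)
  m <- 0:(M - 1L)
  B[1L, ] <- sqrt(1 - alpha^2) * alpha^m
  if (L > 1L) {
    for (j in 2:L) {
      prev <- B[j - 1L, ]
      row <- numeric(M)
      row[1L] <- -alpha * prev[1L]
      for (k in 2:M) {
        row[k] <- alpha * row[k - 1L] + prev[k - 1L] - alpha * prev[k]
      }
      B[j, ] <- row
    }
  }
  structure(list(alpha = alpha, L = L, M = M, values = B),
            class = "laguerre_basis")
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat(sprintf("<laguerre_basis> alpha = %.3g, L = %d, M = %d samples\n",
              x$alpha, x$L, x$M))
  invisible(x)
}

#' Convolve an input series with a Laguerre basis
#'
#' Builds the regressor table of a Laguerre-expansion model: column `j` at
#' time `n` is \eqn{\sum_{m=0}^{M-1} b_j(m) x(n-m)}. The first `M - 1` rows
#' cannot be formed without samples preceding the record and are returned as
#' `NA` (burn-in); model fitting excludes them.
#'
#' @param x Numeric input series, longer than the basis memory `M`.
#' @param basis A [laguerre_basis()].
#' @return A numeric matrix with `length(x)` rows and `basis$L` columns;
#'   rows `1:(M-1)` are `NA` (burn-in).
#' @export
convolve_basis <- function(x, basis) {
  stopifnot(inherits(basis, "laguerre_basis"))
  x <- as.numeric(x)
  if (length(x) <= basis$M) {
    dvr_abort("Input series must be longer than the basis memory `M`.",
              "dvr_series_too_short")
  }
  out <- vapply(seq_len(basis$L), function(j) {
    as.numeric(stats::filter(x, basis$values[j, ], method = "convolution",
                             sides = 1))
  }, numeric(length(x)))
  colnames(out) <- paste0("b", seq_len(basis$L) - 1L)
  out
}

#' Fit the two-input (ABP, ETCO2) -> CBFV dynamic model
#'
#' Estimates a first-order (linear) two-input Volterra model of beat-to-beat
#' CBFV from concurrent ABP and ETCO2 deviations, with each input's
#' impulse-response kernel expanded on its own Laguerre basis. The
#' coefficients and intercept are obtained by least squares on the stacked
#' regressors (Laguerre convolutions of the two inputs), excluding the
#' burn-in rows; an optional ridge penalty `lambda I` (intercept
#' unpenalized) handles ill-conditioned designs.
#'
#' @param u A [uniform_series()] (demeaned beat-to-beat ABP/ETCO2/CBFV on a
#'   uniform grid), or any data frame with numeric columns `abp`, `etco2`,
#'   `cbfv`.
#' @param basis_p,basis_c [laguerre_basis()] objects for the ABP and ETCO2
#'   branches.
#' @param ridge Non-negative ridge penalty. `0` requests plain least
#'   squares; a rank-deficient design then raises an error advising a
#'   positive ridge.
#' @return An object of class `two_input_model` with the coefficient
#'   vectors, intercept, bases, `dt` and training NMSE (residual power over
#'   output power); `attr(, "fit_report")` carries a one-row [tibble()] of
#'   fit diagnostics.
#' @seealso [kernel_of()], [predict.two_input_model()], [select_structure()]
#' @export
fit_two_input_model <- function(u, basis_p, basis_c, ridge = 0) {
  stopifnot(inherits(basis_p, "laguerre_basis"),
            inherits(basis_c, "laguerre_basis"))
  if (!all(c("abp", "etco2", "cbfv") %in% names(u))) {
    dvr_abort("`u` must have columns abp, etco2, cbfv.", "dvr_bad_series")
  }
  if (ridge < 0) dvr_abort("`ridge` must be >= 0.", "dvr_bad_ridge")
  dt <- attr(u, "dt") %||% 1

  Vp <- convolve_basis(u$abp, basis_p)
  Vc <- convolve_basis(u$etco2, basis_c)
  burn <- max(basis_p$M, basis_c$M) - 1L
  idx <- (burn + 1L):nrow(Vp)
  n_par <- 1L + basis_p$L + basis_c$L
  if (length(idx) < 2L * n_par) {
    dvr_abort("Series too short after burn-in for the requested model order.",
              "dvr_series_too_short")
  }
  X <- cbind(intercept = 1, Vp[idx, , drop = FALSE], Vc[idx, , drop = FALSE])
  y <- u$cbfv[idx]

  beta <- solve_ls(X, y, ridge)
  yhat <- drop(X %*% beta)
  nmse <- sum((y - yhat)^2) / sum((y - mean(y))^2)

  XtX <- crossprod(X)
  cond <- tryCatch(kappa(XtX, exact = FALSE), error = function(e) Inf)

  model <- structure(
    list(basis_p = basis_p, basis_c = basis_c,
         a_p = unname(beta[2:(1 + basis_p$L)]),
         a_c = unname(beta[(2 + basis_p$L):n_par]),
         intercept = unname(beta[1L]),
         dt = dt, fit_nmse = nmse,
         baselines = attr(u, "baselines")),
    class = "two_input_model")
  attr(model, "fit_report") <- tibble(
    nmse_train = nmse, nmse_validation = NA_real_, condition = cond,
    alpha_p = basis_p$alpha, L_p = basis_p$L,
    alpha_c = basis_c$alpha, L_c = basis_c$L,
    ridge = ridge, n_fit = length(y))
  model
}

# internal: least squares with optional ridge (intercept in column 1 is
# never penalized); errors on rank deficiency when ridge = 0
solve_ls <- function(X, y, ridge) {
  if (ridge == 0) {
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      dvr_abort(paste("Regressor matrix is rank-deficient; the two input",
                      "channels may be collinear. Retry with ridge > 0."),
                "dvr_rank_deficient")
    }
    return(qr.coef(qr_x, y))
  }
  D <- diag(ncol(X)); D[1L, 1L] <- 0
  drop(solve(crossprod(X) + ridge * D, crossprod(X, y)))
}

#' @export
print.two_input_model <- function(x, ...) {
  cat(sprintf(paste0("<two_input_model> dt = %g s\n",
                     "  ABP branch:   alpha = %.3g, L = %d\n",
                     "  ETCO2 branch: alpha = %.3g, L = %d\n",
                     "  training NMSE = %.4g\n"),
              x$dt, x$basis_p$alpha, x$basis_p$L,
              x$basis_c$alpha, x$basis_c$L, x$fit_nmse))
  invisible(x)
}

#' First-order kernel of a fitted (or true) model branch
#'
#' Reconstructs the impulse-response kernel
#' \eqn{k(m) = \sum_j a_j b_j(m)} of the requested input branch from its
#' Laguerre coefficients.
#'
#' @param model A `two_input_model` (from [fit_two_input_model()]) or
#'   `true_model` (from [true_model()]).
#' @param branch `"abp"` or `"etco2"`.
#' @return A tibble with columns `lag_s` and `kernel`.
#' @export
kernel_of <- function(model, branch = c("abp", "etco2")) {
  branch <- tryCatch(match.arg(branch),
                     error = function(e) dvr_abort(
                       "`branch` must be \"abp\" or \"etco2\".", "dvr_bad_branch"))
  basis <- if (branch == "abp") model$basis_p else model$basis_c
  a <- if (branch == "abp") model$a_p else model$a_c
  k <- drop(crossprod(basis$values, a))
  tibble(lag_s = (seq_len(basis$M) - 1) * model$dt, kernel = k)
}

#' Predict CBFV deviations from a fitted two-input model
#'
#' @param object A `two_input_model`.
#' @param abp,etco2 Input deviation series (equal length, longer than the
#'   model memory). Defaults to `newdata`'s columns when a series is given.
#' @param newdata Optionally a [uniform_series()] or data frame with `abp`
#'   and `etco2` (and, if present, `cbfv` for NMSE).
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `prediction` and, when observed
#'   CBFV is available, `observed`; `attr(, "nmse")` holds the NMSE over
#'   the post-burn-in window.
#' @export
predict.two_input_model <- function(object, newdata = NULL, abp = NULL,
                                    etco2 = NULL, ...) {
  if (!is.null(newdata)) {
    abp <- newdata$abp; etco2 <- newdata$etco2
    observed <- newdata$cbfv
  } else observed <- NULL
  if (is.null(abp) || is.null(etco2)) {
    dvr_abort("Provide `newdata` or both `abp` and `etco2`.", "dvr_bad_input")
  }
  if (length(abp) != length(etco2)) {
    dvr_abort("`abp` and `etco2` must have the same length.",
              "dvr_length_mismatch")
  }
  M <- max(object$basis_p$M, object$basis_c$M)
  if (length(abp) <= M) {
    dvr_abort("Inputs must be longer than the model memory.",
              "dvr_series_too_short")
  }
  kp <- kernel_of(object, "abp")$kernel
  kc <- kernel_of(object, "etco2")$kernel
  pred <- object$intercept +
    as.numeric(stats::filter(abp, kp, method = "convolution", sides = 1)) +
    as.numeric(stats::filter(etco2, kc, method = "convolution", sides = 1))
  out <- tibble(time_s = (seq_along(abp) - 1) * object$dt, prediction = pred)
  burn <- max(object$basis_p$M, object$basis_c$M) - 1L
  if (!is.null(observed)) {
    out$observed <- observed
    idx <- (burn + 1L):nrow(out)
    resid <- observed[idx] - pred[idx]
    attr(out, "nmse") <- sum(resid^2) /
      sum((observed[idx] - mean(observed[idx]))^2)
  }
  attr(out, "burn_in") <- burn
  out
}

#' Grid search over Laguerre model structure
#'
#' Exhaustive search over `(alpha, L)` per input branch, minimizing the
#' prediction NMSE on a held-out temporal validation segment (the last 30%
#' of the record; the model is fit on the first 70%). Ties are broken
#' toward the smaller total order `L_p + L_c`, then the smaller
#' `alpha_p + alpha_c`.
#'
#' @inheritParams fit_two_input_model
#' @param alpha_grid,L_grid Candidate decay parameters and orders, applied
#'   to both branches (the full cross product over the two branches is
#'   searched).
#' @param M Kernel memory in samples for every candidate.
#' @param train_frac Fraction of the record (in time order) used for
#'   fitting; the remainder is the validation segment.
#' @return The winning `two_input_model` refit on the full record;
#'   `attr(, "selection")` is a tibble of all candidates with their
#'   validation NMSE, ordered as searched.
#' @export
select_structure <- function(u, alpha_grid = seq(0.2, 0.8, by = 0.1),
                             L_grid = 1:4, M = 50L, ridge = 0,
                             train_frac = 0.7) {
  if (length(alpha_grid) == 0L || length(L_grid) == 0L) {
    dvr_abort("`alpha_grid` and `L_grid` must be nonempty.", "dvr_bad_grid")
  }
  n <- nrow(u)
  n_train <- floor(train_frac * n)
  if (n_train <= M + 2L || (n - n_train) <= M) {
    dvr_abort("Series too short for a temporal train/validation split.",
              "dvr_series_too_short")
  }
  cand <- expand.grid(L_p = sort(L_grid), L_c = sort(L_grid),
                      alpha_p = sort(alpha_grid), alpha_c = sort(alpha_grid),
                      KEEP.OUT.ATTRS = FALSE)
  # tie-break order: smaller total L first, then smaller total alpha
  cand <- cand[order(cand$L_p + cand$L_c, cand$alpha_p + cand$alpha_c), ]

  u_train <- u[seq_len(n_train), , drop = FALSE]
  attr(u_train, "dt") <- attr(u, "dt")
  val_idx <- (n_train + 1L):n

  scores <- purrr::pmap_dbl(cand, function(L_p, L_c, alpha_p, alpha_c) {
    fit <- tryCatch(
      fit_two_input_model(u_train,
                          laguerre_basis(alpha_p, L_p, M),
                          laguerre_basis(alpha_c, L_c, M), ridge = ridge),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- predict(fit, newdata = u)
    resid <- u$cbfv[val_idx] - pred$prediction[val_idx]
    sum(resid^2) / sum((u$cbfv[val_idx] - mean(u$cbfv[val_idx]))^2)
  })
  if (all(is.na(scores))) {
    dvr_abort("Every candidate structure failed to fit (rank-deficient?).",
              "dvr_rank_deficient")
  }
  best <- which.min(scores)  # first minimum in tie-break order
  win <- cand[best, ]
  model <- fit_two_input_model(
    u, laguerre_basis(win$alpha_p, win$L_p, M),
    laguerre_basis(win$alpha_c, win$L_c, M), ridge = ridge)
  rep <- attr(model, "fit_report")
  rep$nmse_validation <- scores[best]
  attr(model, "fit_report") <- rep
  attr(model, "selection") <- as_tibble(cbind(cand, nmse_validation = scores))
  model
}

#' @rdname fit_two_input_model
#' @param x A `two_input_model`.
#' @param ... Unused.
#' @method tidy two_input_model
#' @export
tidy.two_input_model <- function(x, ...) {
  tibble(
    branch = c(rep("abp", x$basis_p$L), rep("etco2", x$basis_c$L)),
    order = c(seq_len(x$basis_p$L) - 1L, seq_len(x$basis_c$L) - 1L),
    estimate = c(x$a_p, x$a_c))
}

#' @rdname fit_two_input_model
#' @method glance two_input_model
#' @export
glance.two_input_model <- function(x, ...) {
  attr(x, "fit_report")
}
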