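#' Fit a biomass-diversity functional form
#'
#' Four candidate shapes for the relationship between a diversity measure
#' (x) and AGC density (y), each motivated by ecological theory:
#' linear `y = a x + b`, saturating `y = a x / (b + x)` (Michaelis-Menten
#' type), quadratic `y = a x^2 + b x + c`, and the unimodal Ricker curve
#' `y = a x exp(-b x)`. Linear and quadratic are solved in closed form
#' (ordinary least squares); the two nonlinear forms use
#' Levenberg-Marquardt least squares from data-driven starting values with
#' seeded jittered restarts.
#'
#' @param x,y Finite numeric vectors (diversity as x, AGC as y).
#' @param form One of `"linear"`, `"saturating"`, `"quadratic"`, `"ricker"`.
#' @param n_restarts Jittered restarts for the nonlinear forms.
#' @param seed Optional RNG seed for the restart jitter.
#' @return A `model_fit`: `form`, named `parameters`, `rss`, `n`,
#'   `k_params`, `aicc` (`-Inf` for a numerically exact fit), `r_squared`,
#'   `converged`. Nonlinear non-convergence returns `converged = FALSE`
#'   with `NA` parameters rather than failing silently.
#' @export
fit_form <- function(x, y, form = c("linear", "saturating", "quadratic", "ricker"),
                     n_restarts = 10, seed = NULL) {
  form <- match.arg(form)
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("`x` and `y` must be finite")
  n <- length(x)
  k_params <- switch(form, linear = 2L, saturating = 2L, quadratic = 3L, ricker = 2L)
  if (n < k_params + 2L) stopf("need at least %d observations for form '%s'", k_params + 2L, form)
  tss <- sum((y - mean(y))^2)
  pars <- NULL; rss <- NA_real_; converged <- TRUE
  if (form == "linear") {
    fit <- stats::lm(y ~ x)
    pars <- c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
    rss <- sum(stats::resid(fit)^2)
  } else if (form == "quadratic") {
    fit <- stats::lm(y ~ I(x^2) + x)
    cf <- stats::coef(fit)
    pars <- c(a = unname(cf[2]), b = unname(cf[3]), c = unname(cf[1]))
    rss <- sum(stats::resid(fit)^2)
  } else {
    starts <- if (form == "saturating") {
      c(a = max(y), b = max(stats::median(x), 1e-6))
    } else {
      x_at_max <- max(x[which.max(y)], 1e-6)
      c(a = max(y) * exp(1) / x_at_max, b = 1 / x_at_max)
    }
    pred <- if (form == "saturating") {
      function(p) p[1] * x / (p[2] + x)
    } else {
      function(p) p[1] * x * exp(-p[2] * x)
    }
    lower <- if (form == "saturating") c(-Inf, 1e-8) else c(-Inf, -Inf)
    best <- with_seed(seed, {
      acc <- NULL
      for (r in seq_len(max(1L, n_restarts))) {
        st <- if (r == 1) starts else starts * exp(stats::rnorm(2, 0, 1))
        st <- pmax(st, lower)
        fit <- tryCatch(
          minpack.lm::nls.lm(par = st, lower = lower,
                             fn = function(p) y - pred(p),
                             control = minpack.lm::nls.lm.control(maxiter = 1000)),
          error = function(e) NULL)
        if (!is.null(fit) && fit$info %in% 1:4 && is.finite(fit$deviance)) {
          if (is.null(acc) || fit$deviance < acc$rss) {
            acc <- list(par = fit$par, rss = fit$deviance)
          }
        }
      }
      acc
    })
    if (is.null(best)) {
      pars <- stats::setNames(rep(NA_real_, 2), c("a", "b"))
      rss <- NA_real_; converged <- FALSE
    } else {
      pars <- stats::setNames(as.numeric(best$par), c("a", "b"))
      rss <- best$rss
    }
  }
  exact <- is.finite(rss) && rss < 1e-12 * max(tss, 1)
  if (exact) rss <- 0                     # numerically exact fit
  aicc_val <- if (!is.finite(rss)) NA_real_ else if (exact) -Inf else aicc(rss, n, k_params)
  structure(
    list(form = form, parameters = pars, rss = rss, n = n,
         k_params = k_params, aicc = aicc_val,
         r_squared = if (tss > 0 && is.finite(rss)) 1 - rss / tss else NA_real_,
         converged = converged),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Fit '%s': %s | rss = %.4g, AICc = %.4g, r2 = %.3f%s\n",
              x$form,
              paste(names(x$parameters), signif(x$parameters, 4),
                    sep = "=", collapse = ", "),
              x$rss, x$aicc, x$r_squared,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n - k - 1)` with
#' `k = k_params + 1`, counting the error variance as an estimated
#' parameter. As `n` grows the correction term vanishes and AICc tends to
#' AIC.
#'
#' @param rss Residual sum of squares, `> 0`.
#' @param n Number of observations.
#' @param k_params Number of mean-function parameters (excluding the error
#'   variance).
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k_params) {
  if (!is_scalar_num(rss) || rss <= 0) stopf("`rss` must be positive")
  k <- k_params + 1
  if (n - k - 1 <= 0) stopf("AICc undefined: need n > k_params + 2")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the best model fit by AICc
#'
#' Minimum AICc wins; ties break toward lower RSS, then fewer parameters.
#'
#' @param fits List of `model_fit` objects (possibly including failed fits).
#' @return The selected `model_fit`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  ok <- Filter(function(f) f$converged && is.finite(f$rss), fits)
  if (!length(ok)) stopf("no valid fits to select from")
  key <- vapply(ok, function(f) c(f$aicc, f$rss, f$k_params), c(0, 0, 0))
  ok[[order(key[1, ], key[2, ], key[3, ])[1]]]
}

#' Ordinary least-squares summary
#'
#' Simple linear regression with a two-sided t-test on the slope.
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must vary.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_summary <- function(x, y) {
  if (length(x) < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0) stopf("`x` has zero variance")
  if (stats::sd(y) == 0) {                # constant response: flat line
    return(list(slope = 0, intercept = mean(y), r_squared = 0, p_value = 1,
                n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = unname(co["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged).
#'
#' @param x,y Numeric vectors, `n >= 3`, neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stopf("need equal-length vectors, n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("rank correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}
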