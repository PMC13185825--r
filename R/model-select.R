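## Nine-candidate-model curve fitting with RSS-based information criteria.
##
## Goodness of fit uses, for every model class:
##   R^2  = 1 - SS_res / SS_tot
##   AIC  = n * ln(SS_res / n) + 2k
##   BIC  = n * ln(SS_res / n) + k * ln(n)
## (the Gaussian-likelihood RSS approximations), so linear and nonlinear
## fits are directly comparable. The model with the smallest AIC wins.

#' Candidate model registry
#'
#' Nine models: seven linear-in-parameters (fit by OLS) and two nonlinear
#' (fit by Levenberg-Marquardt least squares). Functional forms:
#' Linear `y = a + b x`; Inverse `y = a + b/x`; Logarithmic
#' `y = a + b ln x`; Quadratic `y = a + b x + c x^2`; InverseAndLinear
#' `y = a + b/x + c x`; ConstantAndLogarithmic `y = a + b ln x`;
#' InverseAndConstant `y = a + b/x`; Exponential `y = a e^(b x)`; Power
#' `y = a x^b`. ConstantAndLogarithmic and InverseAndConstant coincide with
#' Logarithmic and Inverse respectively (every linear form carries an
#' intercept); they are retained as named aliases so the full candidate set
#' can be swept.
#'
#' @return named list of model specifications; each has `k` (parameter
#'   count), `linear`, `positive_x`, `pnames`, `design` (transform of x into
#'   design columns, linear models), `predict`, and `grad` (parameter
#'   Jacobian).
#' @export
model_specs <- function() {
  lin <- function(k, pnames, design, predict, grad, positive_x = FALSE)
    list(k = k, linear = TRUE, positive_x = positive_x, pnames = pnames,
         design = design, predict = predict, grad = grad)
  list(
    Linear = lin(2, c("a", "b"),
      function(x) cbind(x = x),
      function(p, x) p[1] + p[2] * x,
      function(p, x) cbind(1, x)),
    Inverse = lin(2, c("a", "b"),
      function(x) cbind(inv_x = 1 / x),
      function(p, x) p[1] + p[2] / x,
      function(p, x) cbind(1, 1 / x), positive_x = TRUE),
    Logarithmic = lin(2, c("a", "b"),
      function(x) cbind(log_x = log(x)),
      function(p, x) p[1] + p[2] * log(x),
      function(p, x) cbind(1, log(x)), positive_x = TRUE),
    Quadratic = lin(3, c("a", "b", "c"),
      function(x) cbind(x = x, x2 = x^2),
      function(p, x) p[1] + p[2] * x + p[3] * x^2,
      function(p, x) cbind(1, x, x^2)),
    InverseAndLinear = lin(3, c("a", "b", "c"),
      function(x) cbind(inv_x = 1 / x, x = x),
      function(p, x) p[1] + p[2] / x + p[3] * x,
      function(p, x) cbind(1, 1 / x, x), positive_x = TRUE),
    ConstantAndLogarithmic = lin(2, c("a", "b"),
      function(x) cbind(log_x = log(x)),
      function(p, x) p[1] + p[2] * log(x),
      function(p, x) cbind(1, log(x)), positive_x = TRUE),
    InverseAndConstant = lin(2, c("a", "b"),
      function(x) cbind(inv_x = 1 / x),
      function(p, x) p[1] + p[2] / x,
      function(p, x) cbind(1, 1 / x), positive_x = TRUE),
    Exponential = list(k = 2, linear = FALSE, positive_x = FALSE,
      pnames = c("a", "b"),
      formula = y ~ a * exp(b * x),
      predict = function(p, x) p[1] * exp(p[2] * x),
      grad = function(p, x) cbind(exp(p[2] * x), p[1] * x * exp(p[2] * x)),
      init = function(x, y) {
        pos <- y > 0
        if (sum(pos) < 2) return(NULL)
        cf <- coef(stats::lm(log(y[pos]) ~ x[pos]))
        c(a = exp(unname(cf[1])), b = unname(cf[2]))
      }),
    Power = list(k = 2, linear = FALSE, positive_x = TRUE,
      pnames = c("a", "b"),
      formula = y ~ a * x^b,
      predict = function(p, x) p[1] * x^p[2],
      grad = function(p, x) cbind(x^p[2], p[1] * x^p[2] * log(x)),
      init = function(x, y) {
        pos <- y > 0
        if (sum(pos) < 2) return(NULL)
        cf <- coef(stats::lm(log(y[pos]) ~ log(x[pos])))
        c(a = exp(unname(cf[1])), b = unname(cf[2]))
      })
  )
}

#' Transform x into a model's design columns
#'
#' @param x numeric predictor.
#' @param model model name (linear-in-parameters models only).
#' @return matrix of design columns (without the intercept).
#' @export
transform_data <- function(x, model) {
  spec <- model_specs()[[model]]
  if (is.null(spec)) stop("unknown model: ", model)
  if (spec$positive_x && any(x <= 0))
    stop(model, " requires x > 0; offending indices: ",
         paste(utils::head(which(x <= 0), 10), collapse = ", "))
  if (!spec$linear) stop(model, " is nonlinear; no design transform")
  spec$design(x)
}

#' RSS-based goodness of fit
#'
#' Evaluates `R^2`, AIC and BIC from `(n, k, SS_res, SS_tot)`. `SS_res` is
#' floored at `.Machine$double.eps * SS_tot` so that exact fits yield a
#' finite criterion and still always rank first.
#'
#' @param n sample size; `k` parameter count; `ss_res`, `ss_tot` sums of
#'   squares.
#' @return list `n`, `k`, `ss_res`, `ss_tot`, `r_squared`, `aic`, `bic`.
#' @export
goodness_of_fit <- function(n, k, ss_res, ss_tot) {
  floor_ <- .Machine$double.eps * max(ss_tot, .Machine$double.xmin)
  ss_eff <- max(ss_res, floor_)
  list(n = n, k = k, ss_res = ss_res, ss_tot = ss_tot,
       r_squared = 1 - ss_res / ss_tot,
       aic = n * log(ss_eff / n) + 2 * k,
       bic = n * log(ss_eff / n) + k * log(n))
}

#' Fit one candidate model
#'
#' Linear-in-parameters models are solved by OLS (QR); the nonlinear pair by
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) started from log-linearised
#' initial guesses (regressing `ln y` on `x` or `ln x` over the positive-y
#' points). A non-converging nonlinear fit is returned with
#' `converged = FALSE` and is excluded from selection.
#'
#' @param x,y numeric data, `length(x) > k`.
#' @param model model name from [model_specs()].
#' @return object of class `model_fit`: `model`, `coefficients`, `vcov`,
#'   `n`, `k`, `ss_res`, `ss_tot`, `r_squared`, `aic`, `bic`, `converged`,
#'   `x_range`, and the data.
#' @export
fit_model <- function(x, y, model) {
  spec <- model_specs()[[model]]
  if (is.null(spec)) stop("unknown model: ", model)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite data")
  if (spec$positive_x && any(x <= 0))
    stop(model, " requires x > 0; offending indices: ",
         paste(utils::head(which(x <= 0), 10), collapse = ", "))
  n <- length(x)
  if (n <= spec$k) stop("need n > k observations")
  ss_tot <- sum((y - mean(y))^2)

  if (spec$linear) {
    fit <- stats::lm(y ~ spec$design(x))
    cf <- stats::setNames(coef(fit), spec$pnames)
    ## vcov -> summary.lm warns on numerically perfect fits; harmless here
    V <- unname(suppressWarnings(vcov(fit)))
    ss_res <- sum(residuals(fit)^2)
    converged <- TRUE
  } else {
    start <- spec$init(x, y)
    fit <- if (is.null(start)) NULL else tryCatch(
      minpack.lm::nlsLM(spec$formula, data = data.frame(x = x, y = y),
                        start = as.list(start),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(model = model, coefficients = NULL, vcov = NULL,
                            n = n, k = spec$k, ss_res = NA_real_,
                            ss_tot = ss_tot, r_squared = NA_real_,
                            aic = NA_real_, bic = NA_real_,
                            converged = FALSE, x_range = range(x),
                            data = list(x = x, y = y)),
                       class = "model_fit"))
    }
    cf <- stats::setNames(coef(fit), spec$pnames)
    V <- tryCatch(unname(vcov(fit)), error = function(e) NULL)
    ss_res <- sum(residuals(fit)^2)
    converged <- TRUE
  }
  gof <- goodness_of_fit(n, spec$k, ss_res, ss_tot)
  structure(c(list(model = model, coefficients = cf, vcov = V,
                   converged = converged, x_range = range(x),
                   data = list(x = x, y = y)),
              gof),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<model_fit> %s: did not converge\n", x$model))
    return(invisible(x))
  }
  cat(sprintf("<model_fit> %s: %s | R^2 = %.4f, AIC = %.2f, BIC = %.2f\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$r_squared, x$aic, x$bic))
  invisible(x)
}

#' Fit all candidate models
#'
#' @param x,y numeric data.
#' @param models model names (default: all nine).
#' @return named list of `model_fit` objects (non-fittable models, e.g.
#'   positive-x models on data containing non-positive x, are skipped with a
#'   message).
#' @export
fit_all_models <- function(x, y, models = names(model_specs())) {
  fits <- lapply(models, function(m)
    tryCatch(fit_model(x, y, m), error = function(e) {
      message("skipping ", m, ": ", conditionMessage(e))
      NULL
    }))
  names(fits) <- models
  fits[!vapply(fits, is.null, logical(1))]
}

#' Select the best model by AIC
#'
#' Ranks converged fits by AIC (ascending); ties break by BIC, then by fewer
#' parameters, then by model name for determinism.
#'
#' @param fits list of `model_fit` objects (e.g. from [fit_all_models()]).
#' @return list `best` (the winning `model_fit`) and `table` (data.frame of
#'   all converged fits: `model`, `k`, `r_squared`, `aic`, `bic`, ranked).
#' @export
select_best <- function(fits) {
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (!length(fits)) stop("no converged fits to select from")
  names(fits) <- vapply(fits, `[[`, character(1), "model")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, k = f$k, r_squared = f$r_squared,
               aic = f$aic, bic = f$bic, stringsAsFactors = FALSE)))
  o <- order(tab$aic, tab$bic, tab$k, tab$model)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  list(best = fits[[tab$model[1]]], table = tab)
}

#' Confidence band of a fitted model
#'
#' Pointwise band `yhat(x) +- t_{1-(1-level)/2, n-k} * se(x)` with
#' `se(x) = sqrt(J(x)' Cov J(x))`, `J` the parameter gradient of the model
#' at x (for linear models this reduces to the classical OLS mean-response
#' interval). The band is restricted to the observed x range: extrapolation
#' is an error.
#'
#' @param fit a converged `model_fit`.
#' @param x_grid evaluation points (default: 100 points spanning the
#'   observed range).
#' @param level confidence level (default 0.95).
#' @return data.frame `x`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(fit, x_grid = NULL, level = 0.95) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (is.null(fit$vcov)) stop("no parameter covariance available")
  if (is.null(x_grid))
    x_grid <- seq(fit$x_range[1], fit$x_range[2], length.out = 100)
  eps <- sqrt(.Machine$double.eps) * max(1, diff(fit$x_range))
  if (any(x_grid < fit$x_range[1] - eps | x_grid > fit$x_range[2] + eps))
    stop("x_grid outside the observed x range: no extrapolation")
  spec <- model_specs()[[fit$model]]
  p <- unname(fit$coefficients)
  yhat <- spec$predict(p, x_grid)
  J <- spec$grad(p, x_grid)
  se <- sqrt(pmax(rowSums((J %*% fit$vcov) * J), 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - fit$k)
  data.frame(x = x_grid, fit = yhat, lwr = yhat - tq * se, upr = yhat + tq * se)
}
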