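## Four-parameter logistic dose-response fitting.

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose/IC50)^hill)`,
#' the standard 4PL with the relative (inflection-point) IC50. Starting
#' values come from the response range and the dose at half-maximal
#' response; optimization uses Levenberg-Marquardt least squares.
#' A flat response (range below `flat_tol`) is unidentifiable and raises
#' an error rather than returning a silent value.
#'
#' Asymptotes may be constrained: for viability already normalized to
#' the untreated control the standard analysis fixes `top = 1` and
#' `bottom = 0` (the "normalized response, variable slope" model),
#' which leaves only `hill` and the IC50 free and stabilizes the
#' estimate considerably on sparse dose grids.
#'
#' @param dose Numeric doses (>= 0), at least 4 distinct values.
#' @param response Responses, typically viability as a fraction of the
#'   untreated control.
#' @param fix_bottom,fix_top Fix an asymptote at the given value
#'   (`NULL`, the default, leaves it free).
#' @param flat_tol Minimal response range considered identifiable.
#' @return A `dose_response_fit` object with elements `coefficients`
#'   (`bottom`, `top`, `hill`, `ic50`, including any fixed values),
#'   `fitted`, `residuals`, `dose`, `response`.
#' @export
fit_dose_response <- function(dose, response, fix_bottom = NULL,
                              fix_top = NULL, flat_tol = 1e-8) {
  if (length(dose) != length(response))
    stop("dose and response must have equal length", call. = FALSE)
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (length(unique(dose)) < 4)
    stop("need at least 4 distinct doses", call. = FALSE)
  if (any(!is.finite(response)))
    stop("responses must be finite", call. = FALSE)
  if (diff(range(response)) < flat_tol)
    stop("flat response: dose-response curve is unidentifiable",
         call. = FALSE)

  ## starting values: range for the asymptotes, half-response crossing
  ## for the IC50, slope sign for the hill coefficient
  mu <- tapply(response, dose, mean)
  d <- as.numeric(names(mu))
  o <- order(d); d <- d[o]; mu <- as.numeric(mu)[o]
  top0 <- max(mu); bot0 <- min(mu)
  half <- (top0 + bot0) / 2
  pos <- d[d > 0]
  below <- which(mu <= half & d > 0)
  ic0 <- if (length(below)) d[below[1]] else exp(mean(log(pos)))
  decreasing <- mu[length(mu)] < mu[1]
  hill0 <- if (decreasing) 1 else -1

  df <- data.frame(dose = dose, response = response)
  start <- list(bottom = bot0, top = top0, hill = hill0, ic50 = ic0)
  bounds <- list(bottom = c(-Inf, Inf), top = c(-Inf, Inf),
                 hill = c(-20, 20), ic50 = c(1e-12, Inf))
  fixed <- c(bottom = fix_bottom, top = fix_top)
  free <- setdiff(names(start), names(fixed))
  form <- response ~ bottom + (top - bottom) / (1 + (dose / ic50)^hill)
  if (length(fixed))
    form <- as.formula(do.call(substitute, list(form, as.list(fixed))))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = df, start = start[free],
      lower = vapply(bounds[free], `[`, numeric(1), 1),
      upper = vapply(bounds[free], `[`, numeric(1), 2),
      control = nls.control(maxiter = 200)),
    error = function(e)
      stop("dose-response fit failed to converge: ",
           conditionMessage(e), call. = FALSE))
  cf <- c(coef(fit), unlist(fixed))
  est <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
           hill = unname(cf["hill"]), ic50 = unname(cf["ic50"]))
  if (!is.finite(est["ic50"]) || est["ic50"] <= 0)
    stop("dose-response fit failed: non-positive IC50", call. = FALSE)
  structure(list(coefficients = est,
                 fitted = predict(fit),
                 residuals = residuals(fit),
                 dose = dose, response = response),
            class = "dose_response_fit")
}

#' Extract the IC50 from a dose-response fit
#'
#' @param fit A `dose_response_fit`.
#' @param log2 Return `log2(IC50)` instead of the linear value.
#' @return The relative IC50 (dose units), or its log2.
#' @export
ic50 <- function(fit, log2 = FALSE) {
  stopifnot(inherits(fit, "dose_response_fit"))
  v <- unname(fit$coefficients["ic50"])
  if (log2) base::log2(v) else v
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
residuals.dose_response_fit <- function(object, ...) object$residuals

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$dose else
    (if (is.data.frame(newdata)) newdata$dose else newdata)
  cf <- object$coefficients
  cf["bottom"] + (cf["top"] - cf["bottom"]) /
    (1 + (d / cf["ic50"])^cf["hill"])
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  bottom %.4g  top %.4g  hill %.4g\n",
              cf["bottom"], cf["top"], cf["hill"]))
  cat(sprintf("  IC50 %.4g (log2 %.3f), RSS %.4g on %d points\n",
              cf["ic50"], log2(cf["ic50"]), sum(x$residuals^2),
              length(x$dose)))
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  pos <- x$dose > 0
  dmin <- min(x$dose[pos]); dmax <- max(x$dose)
  grid <- exp(seq(log(dmin / 4), log(dmax * 2), length.out = 200))
  plot(x$dose[pos], x$response[pos], log = "x",
       xlab = "dose", ylab = "response", ...)
  lines(grid, predict(x, grid))
  abline(v = x$coefficients["ic50"], lty = 2)
  invisible(x)
}
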