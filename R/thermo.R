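# Two-state thermal unfolding: the six-parameter sigmoid-with-baselines
# model for tryptophan-fluorescence melting curves, its nonlinear
# least-squares fit, and closed-form stability differences (delta-delta-G)
# for thermal and chemical unfolding.

#' Two-state thermal unfolding model
#'
#' Predicted fluorescence at temperature T for a folded/unfolded two-state
#' equilibrium with linear baselines:
#' \deqn{F(T) = \frac{(y_n + m_n T) + (y_d + m_d T)\,e^{K}}{1 + e^{K}},
#'   \quad K = \frac{\Delta H_m}{R T_m} - \frac{\Delta H_m}{R T}}
#' At `T = Tm` the exponent vanishes and F is the average of the two
#' baselines (half the molecules unfolded).
#'
#' @param T Temperatures, K.
#' @param Tm Melting temperature, K.
#' @param dHm van't Hoff enthalpy at Tm, kcal/mol (> 0 for a cooperative
#'   transition).
#' @param yn,mn Pre-transition (folded) baseline intercept and slope.
#' @param yd,md Post-transition (unfolded) baseline intercept and slope.
#' @param R Gas constant, kcal/(mol K).
#' @return Predicted signal, same length as `T`.
#' @export
two_state_model <- function(T, Tm, dHm, yn, mn, yd, md,
                            R = GAS_CONSTANT_KCAL) {
  expo <- exp(dHm / (R * Tm) - dHm / (R * T))
  ((yn + mn * T) + (yd + md * T) * expo) / (1 + expo)
}

#' Fit the two-state unfolding model to a melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) estimation of the six
#' model parameters from a signal-vs-temperature curve. Default starting
#' values: baselines from linear fits of the first and last 20% of points,
#' `Tm` at the temperature of steepest signal change, `dHm = 100` kcal/mol.
#'
#' @param curve Data frame with columns `T` (K, strictly increasing) and
#'   `F` (signal), or two numeric vectors via `T`/`F` columns of a tibble
#'   from [make_unfolding_curve()]. At least 8 points spanning both
#'   baselines and the transition.
#' @param R Gas constant, kcal/(mol K).
#' @param init Optional named list of starting values overriding the
#'   defaults (`Tm`, `dHm`, `yn`, `mn`, `yd`, `md`).
#' @return Object of class `two_state_fit`: list with `par` (named
#'   estimates), `fit` (the underlying `nls` object), `curve`, `R`,
#'   `sigma` (residual standard error). Methods: [tidy()], [glance()],
#'   `predict()`, [autoplot()].
#' @export
fit_thermal_unfolding <- function(curve, R = GAS_CONSTANT_KCAL, init = NULL) {
  stopifnot(is.data.frame(curve), all(c("T", "F") %in% names(curve)))
  Tv <- as.numeric(curve$T)
  Fv <- as.numeric(curve$F)
  if (length(Tv) < 8L) abort("unfolding curve needs at least 8 points")
  if (any(diff(Tv) <= 0)) abort("temperatures must be strictly increasing")

  n <- length(Tv)
  edge <- max(2L, floor(0.2 * n))
  pre <- stats::lm(Fv[1:edge] ~ Tv[1:edge])
  post <- stats::lm(Fv[(n - edge + 1):n] ~ Tv[(n - edge + 1):n])

  # steepest change in a lightly smoothed signal locates the transition
  sm <- stats::filter(Fv, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- Fv[is.na(sm)]
  slope <- diff(sm) / diff(Tv)
  k <- which.max(abs(slope))
  baseline_sep <- abs((coef(post)[1] + coef(post)[2] * Tv[k]) -
                        (coef(pre)[1] + coef(pre)[2] * Tv[k]))
  if (baseline_sep < 4 * sd(stats::residuals(pre)) +
      1e-8 * (diff(range(Fv)) + 1)) {
    abort("no transition detected within the sampled temperature range")
  }

  start <- list(Tm = (Tv[k] + Tv[k + 1]) / 2, dHm = 100,
                yn = unname(coef(pre)[1]), mn = unname(coef(pre)[2]),
                yd = unname(coef(post)[1]), md = unname(coef(post)[2]))
  if (!is.null(init)) start[names(init)] <- init

  dat <- data.frame(T = Tv, F = Fv)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      F ~ two_state_model(T, Tm, dHm, yn, mn, yd, md, R = R),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(sprintf("two-state fit failed to converge: %s",
                                      conditionMessage(e)))
  )
  par <- coef(fit)
  if (par[["Tm"]] < min(Tv) || par[["Tm"]] > max(Tv)) {
    abort(sprintf("fitted Tm = %.1f K lies outside the sampled range [%.1f, %.1f] K: no transition in the data",
                  par[["Tm"]], min(Tv), max(Tv)))
  }
  structure(
    list(par = par, fit = fit, curve = tibble::as_tibble(dat), R = R,
         sigma = stats::sigma(fit)),
    class = "two_state_fit"
  )
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("<two_state_fit> Tm = %.2f K, dHm = %.1f kcal/mol (sigma = %.3g)\n",
              x$par[["Tm"]], x$par[["dHm"]], x$sigma))
  invisible(x)
}

#' @export
predict.two_state_fit <- function(object, newdata = NULL, ...) {
  Tv <- if (is.null(newdata)) object$curve$T else newdata$T
  p <- as.list(object$par)
  two_state_model(Tv, p$Tm, p$dHm, p$yn, p$mn, p$yd, p$md, R = object$R)
}

#' Tidy a two-state unfolding fit
#'
#' `tidy()` returns one row per model parameter with standard errors;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `two_state_fit`.
#' @param ... Unused.
#' @method tidy two_state_fit
#' @export
tidy.two_state_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname tidy.two_state_fit
#' @method glance two_state_fit
#' @export
glance.two_state_fit <- function(x, ...) {
  tibble::tibble(
    Tm = x$par[["Tm"]], dHm = x$par[["dHm"]], sigma = x$sigma,
    n = nrow(x$curve), converged = x$fit$convInfo$isConv
  )
}

#' Stability difference from melting temperatures (thermal unfolding)
#'
#' `ddG = dHm_wt / Tm_wt * (Tm_mut - Tm_wt)` in kcal/mol. Negative values
#' mark destabilizing mutations (lower melting temperature than wild type).
#'
#' @param fit_wt Wild-type `two_state_fit`, or a named list/vector with
#'   `Tm` and `dHm`.
#' @param Tm_mut Mutant melting temperature, K.
#' @return Stability difference, kcal/mol.
#' @export
#' @examples
#' ddg_thermal(list(Tm = 330, dHm = 100), Tm_mut = 325) # -1.5152
ddg_thermal <- function(fit_wt, Tm_mut) {
  p <- if (inherits(fit_wt, "two_state_fit")) as.list(fit_wt$par) else as.list(fit_wt)
  if (!is.numeric(p$Tm) || p$Tm <= 0) abort("wild-type Tm must be positive (kelvin)")
  p$dHm / p$Tm * (Tm_mut - p$Tm)
}

#' Stability difference from denaturation midpoints (chemical unfolding)
#'
#' `ddG = m_wt * (Cm_mut - Cm_wt)` in kcal/mol, with the wild-type
#' transition slope `m_wt` (kcal/(mol M)) and the denaturant concentrations
#' at which half the protein is unfolded.
#'
#' @param m_wt Wild-type transition slope, kcal/(mol M), > 0.
#' @param Cm_wt,Cm_mut Denaturant midpoint concentrations, M.
#' @return Stability difference, kcal/mol.
#' @export
#' @examples
#' ddg_chemical(2.0, 1.5, 2.0) # +1.0
ddg_chemical <- function(m_wt, Cm_wt, Cm_mut) {
  if (!is.numeric(m_wt) || m_wt <= 0) abort("wild-type transition slope must be positive")
  m_wt * (Cm_mut - Cm_wt)
}
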