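# Two-state equilibrium unfolding: linear-extrapolation model with folded
# and unfolded baselines, curve simulation and nonlinear fitting.
#
# signal(x) = [(a_f + b_f x) + (a_u + b_u x) K(x)] / [1 + K(x)],
# K(x) = exp(-(dG - m x) / RT),
# where dG is the folding free energy at zero denaturant (kcal/mol, positive
# = stable), m the denaturant dependence (kcal/mol/M), and Cm = dG/m the
# transition midpoint (M).

GAS_CONSTANT_KCAL <- 1.9872041e-3  # kcal / (mol K)

two_state_signal <- function(x, dG, m, a_f, b_f, a_u, b_u, RT) {
  K <- exp(-(dG - m * x) / RT)
  ((a_f + b_f * x) + (a_u + b_u * x) * K) / (1 + K)
}

#' Simulate a chemical-denaturation curve
#'
#' Two-state transition with pre- and post-transition baselines plus i.i.d.
#' Gaussian noise; deterministic for a given seed.
#'
#' @param dG folding free energy at zero denaturant (kcal/mol).
#' @param m_value m-value (kcal/mol/M), positive for a cooperative unfolder.
#' @param baselines list or vector with `a_f`, `b_f`, `a_u`, `b_u` (folded /
#'   unfolded baseline intercepts and slopes).
#' @param x denaturant concentration grid (M).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param temperature fit temperature (K); default 298.15 (RT = 0.592
#'   kcal/mol).
#' @return Tibble of class `denaturation_curve` with columns `denaturant`,
#'   `signal`; the temperature is kept as an attribute.
#' @export
simulate_curve <- function(dG, m_value, baselines = list(a_f = 1, b_f = 0,
                                                         a_u = 0, b_u = 0),
                           x = seq(0, 7.5, length.out = 30), noise_sd = 0,
                           seed = 1, temperature = 298.15) {
  stopifnot(m_value > 0, length(x) > 0)
  b <- as.list(baselines)
  RT <- GAS_CONSTANT_KCAL * temperature
  y <- two_state_signal(x, dG, m_value, b$a_f, b$b_f, b$a_u, b$b_u, RT)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(x), sd = noise_sd)
  }
  out <- tibble::tibble(denaturant = x, signal = y)
  attr(out, "temperature") <- temperature
  class(out) <- c("denaturation_curve", class(out))
  out
}

#' Fit the two-state unfolding model
#'
#' Nonlinear least squares over (dG, m, a_f, b_f, a_u, b_u) with the
#' linear-extrapolation two-state model. Initial values: baselines from
#' linear fits to the three first / last points, midpoint at the denaturant
#' concentration of half signal range, m from the apparent transition width.
#' Cm is reported as dG/m with its delta-method standard error.
#'
#' @param curve data frame with columns `denaturant`, `signal` (>= 8 points
#'   spanning both baselines and the transition).
#' @param temperature K; defaults to the curve's attribute or 298.15.
#' @return Object of class `two_state_fit`: list with `dG`, `m_value`, `Cm`,
#'   baseline coefficients, `RT`, a tibble of `estimates` with standard
#'   errors, the fitted curve, and `converged`.
#' @export
fit_two_state <- function(curve, temperature = NULL) {
  x <- curve$denaturant
  y <- curve$signal
  if (length(x) < 8) stop("need at least 8 points to fit")
  if (is.null(temperature))
    temperature <- attr(curve, "temperature") %||% 298.15
  RT <- GAS_CONSTANT_KCAL * temperature
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n <- length(x)
  lo <- seq_len(3); hi <- n - 2:0
  f_lo <- stats::lm(y[lo] ~ x[lo])
  f_hi <- stats::lm(y[hi] ~ x[hi])
  a_f0 <- unname(stats::coef(f_lo)[1]); b_f0 <- unname(stats::coef(f_lo)[2])
  a_u0 <- unname(stats::coef(f_hi)[1]); b_u0 <- unname(stats::coef(f_hi)[2])
  yr <- (y - (a_f0 + b_f0 * x)) / ((a_u0 + b_u0 * x) - (a_f0 + b_f0 * x))
  cm0 <- x[which.min(abs(yr - 0.5))]
  trans <- range(x[yr > 0.1 & yr < 0.9], na.rm = TRUE)
  width <- max(diff(trans), diff(range(x)) / 10)
  m0 <- 4 * RT / width
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ((a_f + b_f * x) + (a_u + b_u * x) * exp(-(dG - m * x) / RT)) /
        (1 + exp(-(dG - m * x) / RT)),
      data = dat,
      start = list(dG = m0 * cm0, m = m0, a_f = a_f0, b_f = b_f0,
                   a_u = a_u0, b_u = b_u0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("two-state fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (cf[["dG"]] / cf[["m"]] > max(x) || cf[["dG"]] / cf[["m"]] < min(x))
    warning("transition midpoint outside the sampled denaturant range")
  Cm <- cf[["dG"]] / cf[["m"]]
  # delta-method SE for Cm = dG/m
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  Cm_se <- if (!is.null(vc)) {
    g <- c(1 / cf[["m"]], -cf[["dG"]] / cf[["m"]]^2)
    sqrt(drop(t(g) %*% vc[c("dG", "m"), c("dG", "m")] %*% g))
  } else NA_real_
  est <- tibble::tibble(
    term = c(names(cf), "Cm"),
    estimate = c(unname(cf), Cm),
    std_error = c(unname(se), Cm_se))
  structure(list(dG = cf[["dG"]], m_value = cf[["m"]], Cm = Cm,
                 a_f = cf[["a_f"]], b_f = cf[["b_f"]],
                 a_u = cf[["a_u"]], b_u = cf[["b_u"]],
                 RT = RT, temperature = temperature,
                 estimates = est,
                 data = tibble::tibble(denaturant = x, signal = y,
                                       fitted = stats::fitted(fit)),
                 sigma = summary(fit)$sigma,
                 converged = TRUE),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state unfolding fit: dG = %.2f kcal/mol, m = %.2f kcal/mol/M, Cm = %.2f M\n",
    x$dG, x$m_value, x$Cm))
  invisible(x)
}

#' Thermal melt summary
#'
#' Summarises a thermal denaturation trace: fractional signal change from
#' start to the highest temperature, reversibility (post-cooling signal
#' against initial), and an apparent midpoint only when a sigmoidal
#' transition is detected (logistic fit with midpoint inside the scanned
#' range and amplitude covering most of the signal change); otherwise the
#' trace is reported as having no complete transition.
#'
#' @param data data frame with columns `temperature` (monotone, degrees C or
#'   K) and `signal`.
#' @param cooled_signal optional signal after cooling back to the start
#'   temperature.
#' @param change_threshold minimum fractional signal change for a
#'   transition.
#' @return One-row tibble: `fractional_change`, `transition` (logical),
#'   `midpoint` (NA when no transition), `reversible` (NA when
#'   `cooled_signal` missing).
#' @export
thermal_melt_summary <- function(data, cooled_signal = NULL,
                                 change_threshold = 0.2) {
  tt <- data$temperature; y <- data$signal
  if (is.unsorted(tt) && is.unsorted(rev(tt)))
    stop("temperature grid must be monotone")
  span <- max(abs(y)) + 1e-12
  frac <- abs(y[length(y)] - y[1]) / span
  midpoint <- NA_real_
  transition <- FALSE
  if (frac >= change_threshold) {
    fit <- tryCatch(
      suppressWarnings(stats::nls(y ~ lo + (hi - lo) / (1 + exp((tm - tt) / k)),
                 start = list(lo = y[1], hi = y[length(y)],
                              tm = stats::median(tt), k = diff(range(tt)) / 10),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      amp_ok <- abs(cf[["hi"]] - cf[["lo"]]) >= 0.5 * abs(y[length(y)] - y[1])
      in_range <- cf[["tm"]] > min(tt) && cf[["tm"]] < max(tt)
      if (amp_ok && in_range) {
        transition <- TRUE
        midpoint <- cf[["tm"]]
      }
    }
  }
  reversible <- if (is.null(cooled_signal)) NA else
    abs(cooled_signal - y[1]) <= 0.1 * span
  tibble::tibble(fractional_change = frac, transition = transition,
                 midpoint = midpoint, reversible = reversible,
                 note = ifelse(transition, "transition detected",
                               "no complete transition"))
}
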