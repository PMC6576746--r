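#' Percent control from competition-binding signals
#'
#' The kinome competition-binding readout:
#' \deqn{\%control = \frac{test - positive}{negative - positive} \times 100}
#' where the positive control (a known high-affinity ligand) defines complete
#' displacement and the negative control (vehicle) defines no displacement.
#' Lower values mean stronger binding of the test compound.
#'
#' @param test_signal,positive_control_signal,negative_control_signal Raw
#'   assay signals (any common unit; the ratio is unit-free).
#' @return Percent control (vectorized).
#' @examples
#' percent_control(50, 0, 100)  # 50
#' @export
percent_control <- function(test_signal, positive_control_signal,
                            negative_control_signal) {
  if (any(negative_control_signal == positive_control_signal))
    stop("negative and positive control signals coincide; %control undefined")
  (test_signal - positive_control_signal) /
    (negative_control_signal - positive_control_signal) * 100
}

#' Single-site Hill binding response
#'
#' Competition-binding dose-response with Hill slope 1:
#' \deqn{response = background + \frac{signal - background}{1 + dose/K_d}}
#' The response falls from `signal` at zero dose to `background` at
#' saturating dose, with midpoint at `dose = kd`.
#'
#' @param dose Compound concentration (uM), >= 0.
#' @param background Lower asymptote (full displacement).
#' @param signal Upper asymptote (no compound).
#' @param kd Binding constant (uM), > 0.
#' @return Response values.
#' @export
hill_response <- function(dose, background, signal, kd) {
  stopifnot(all(dose >= 0), kd > 0)
  background + (signal - background) / (1 + dose / kd)
}

#' Fit the Hill binding model to a dose-response curve
#'
#' Nonlinear least squares via the Levenberg-Marquardt algorithm
#' ([minpack.lm::nlsLM()]). Requires at least 4 points.
#'
#' @param curve Data.frame with columns `dose` (uM, > 0) and `response`.
#' @param init Optional named list/vector of starting values
#'   (`background`, `signal`, `kd`); defaults are data-driven (background =
#'   min response, signal = response nearest zero dose, kd = geometric mean
#'   dose).
#' @param lower Optional named lower bounds; by default only `kd > 0` is
#'   enforced.
#' @return Object of class `hill_fit` with `coefficients` (background,
#'   signal, kd), `rss`, `fitted`, and the underlying `nls` object in `$fit`.
#' @examples
#' d <- simulate_dose_response("hill",
#'        params = list(background = 0, signal = 100, kd = 1), noise_sd = 0)
#' coef(fit_hill(d))
#' @export
fit_hill <- function(curve, init = NULL, lower = NULL) {
  curve <- validate_curve(curve, min_points = 4L)
  y <- curve$response; d <- curve$dose
  start <- list(background = min(y),
                signal = y[which.min(d)],
                kd = exp(mean(log(d))))
  if (!is.null(init)) start[names(init)] <- init
  lo <- c(background = -Inf, signal = -Inf, kd = 1e-9)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ background + (signal - background) / (1 + dose / kd),
                      data = curve, start = start,
                      lower = lo[c("background", "signal", "kd")],
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit failed: ", conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(coefficients = co,
                 rss = sum(stats::residuals(fit)^2),
                 fitted = stats::fitted(fit),
                 curve = curve, fit = fit),
            class = "hill_fit")
}

#' Four-parameter sigmoidal dose-response
#'
#' The single-site viability model
#' \deqn{y = A + \frac{B - A}{1 + (C/x)^D}}
#' with lower limit A, upper limit B, midpoint concentration C (the EC50) and
#' Hill slope D. For D > 0 the curve rises from A (x -> 0) to B (x -> Inf);
#' negative D reverses the direction.
#'
#' @param x Concentration, > 0.
#' @param A,B Lower and upper response limits.
#' @param C Midpoint concentration (EC50), > 0.
#' @param D Hill slope.
#' @return Response values.
#' @export
sigmoid_response <- function(x, A, B, C, D) {
  if (any(x <= 0)) stop("concentration must be > 0")
  stopifnot(C > 0)
  A + (B - A) / (1 + (C / x)^D)
}

#' Fit the four-parameter sigmoid to a viability curve
#'
#' Levenberg-Marquardt nonlinear least squares on the model of
#' [sigmoid_response()]. Requires >= 5 points; constant responses are
#' rejected as degenerate (the midpoint is unidentifiable).
#'
#' @param curve Data.frame with columns `dose` (uM, > 0) and `response`
#'   (relative cell count).
#' @param init Optional named starting values (`A`, `B`, `C`, `D`).
#' @return Object of class `sigmoid_fit` with `coefficients` (A, B, C, D),
#'   `rss`, `fitted`, `curve`, and the `nls` object in `$fit`. `C` is the
#'   EC50.
#' @examples
#' d <- simulate_dose_response("sigmoid",
#'        params = list(A = 0.1, B = 1, C = 2, D = 1.5), noise_sd = 0)
#' coef(fit_sigmoid(d))
#' @export
fit_sigmoid <- function(curve, init = NULL) {
  curve <- validate_curve(curve, min_points = 5L)
  y <- curve$response; d <- curve$dose
  if (stats::sd(y) == 0)
    stop("constant responses: sigmoid fit is degenerate")
  slope_dir <- sign(stats::cor(log(d), y))
  if (slope_dir == 0) slope_dir <- 1
  start <- list(A = min(y), B = max(y), C = exp(mean(log(d))), D = slope_dir)
  if (!is.null(init)) start[names(init)] <- init
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ A + (B - A) / (1 + (C / dose)^D),
                      data = curve, start = start,
                      lower = c(A = -Inf, B = -Inf, C = 1e-12, D = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sigmoid fit failed: ", conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(coefficients = co,
                 rss = sum(stats::residuals(fit)^2),
                 fitted = stats::fitted(fit),
                 curve = curve, fit = fit),
            class = "sigmoid_fit")
}

validate_curve <- function(curve, min_points) {
  stopifnot(is.data.frame(curve))
  if (!all(c("dose", "response") %in% names(curve)))
    stop("curve needs columns 'dose' and 'response'")
  if (anyNA(curve$dose) || anyNA(curve$response))
    stop("curve contains missing values")
  if (any(curve$dose <= 0)) stop("doses must be positive (uM)")
  if (nrow(curve) < min_points)
    stop("at least ", min_points, " dose points are required")
  curve[order(curve$dose), c("dose", "response"), drop = FALSE]
}

#' @export
print.hill_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Hill binding fit: Kd = %.4g uM (signal %.4g -> background %.4g), RSS = %.4g\n",
              co[["kd"]], co[["signal"]], co[["background"]], x$rss))
  invisible(x)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Sigmoid fit: EC50 (C) = %.4g uM, A = %.4g, B = %.4g, slope D = %.4g, RSS = %.4g\n",
              co[["C"]], co[["A"]], co[["B"]], co[["D"]], x$rss))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$curve$dose else newdata$dose
  co <- object$coefficients
  hill_response(d, co[["background"]], co[["signal"]], co[["kd"]])
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$curve$dose else newdata$dose
  co <- object$coefficients
  sigmoid_response(d, co[["A"]], co[["B"]], co[["C"]], co[["D"]])
}

# invert y = A + (B-A)/(1+(C/x)^D) for x at a response level; NA when the
# level is not strictly between the asymptotes
invert_sigmoid <- function(level, A, B, C, D) {
  lo <- min(A, B); hi <- max(A, B)
  if (!(level > lo && level < hi)) return(NA_real_)
  t <- (B - A) / (level - A) - 1  # = (C/x)^D, > 0 inside the range
  C / t^(1 / D)
}

#' Midpoint concentrations from a fitted sigmoid
#'
#' Extracts the three summary concentrations of the viability curve:
#' * EC50 — the fitted midpoint, parameter C;
#' * IC50 — the concentration where the curve crosses half the upper limit,
#'   `y = B/2` (interpreted reading of "50% of the maximum possible
#'   response"; when A = 0 this coincides with the EC50);
#' * GI50 — the concentration halving observed growth: the level midway
#'   between the curve maximum B and the relative cell count at compound
#'   addition (`time_zero_count`), i.e. `y = (B + time_zero_count)/2`.
#'
#' Levels are solved analytically on the fitted closed form; a level outside
#' the open interval between the fitted asymptotes is reported as `NA`
#' (not reached), with the corresponding flag set.
#'
#' @param fit A `sigmoid_fit`.
#' @param time_zero_count Relative cell count at compound addition; required
#'   for GI50 (`NA` otherwise).
#' @return List with `ec50`, `ic50`, `gi50` (uM or `NA`) and a logical
#'   `flags` vector (`ic50_not_reached`, `gi50_not_reached`,
#'   `gi50_degenerate` when the GI50 level sits on the curve maximum).
#' @export
derive_response_parameters <- function(fit, time_zero_count = NULL) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  co <- fit$coefficients
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]; D <- co[["D"]]
  ic50 <- invert_sigmoid(0.5 * B, A, B, C, D)
  gi50 <- NA_real_
  gi50_degenerate <- FALSE
  if (!is.null(time_zero_count)) {
    lvl <- (B + time_zero_count) / 2
    if (lvl == B) {
      gi50_degenerate <- TRUE  # no growth since time zero: level at curve max
    } else {
      gi50 <- invert_sigmoid(lvl, A, B, C, D)
    }
  }
  list(ec50 = C, ic50 = ic50, gi50 = gi50,
       flags = c(ic50_not_reached = is.na(ic50),
                 gi50_not_reached = is.null(time_zero_count) ||
                   (is.na(gi50) && !gi50_degenerate),
                 gi50_degenerate = gi50_degenerate))
}

#' Activity area of a dose-response series
#'
#' Discrete estimate of the integrated area above the response curve: the sum
#' over tested concentrations of the inhibition fraction `1 - y`, with each
#' term clipped to \[0, 1\]. For the standard 10-concentration half-log
#' series the value ranges from 0 (no inhibition anywhere) to 10 (complete
#' inhibition everywhere).
#'
#' @param responses Relative cell counts at the tested concentrations
#'   (typically 10).
#' @return Activity area in \[0, length(responses)\].
#' @examples
#' activity_area(rep(0.5, 10))  # 5
#' @export
activity_area <- function(responses) {
  stopifnot(is.numeric(responses), length(responses) >= 1,
            all(is.finite(responses)))
  sum(pmin(1, pmax(0, 1 - responses)))
}
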