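# Diagnostic reconstruction of chest displacement from I/Q: imbalance
# compensation followed by extended differentiate-and-cross-multiply (DACM)
# phase demodulation. Not on the detection path (the detector is
# calibration-free); used to inspect recordings and to verify the simulator.

#' Compensate I/Q amplitude, offset and phase imbalance
#'
#' Given calibration parameters (from simulator ground truth or
#' [fit_iq_calibration()]), returns channels with zero offsets, unit equal
#' amplitudes and orthogonal phases:
#' `I' = (I - DC_I)/A_I`; `Q' = ((Q - DC_Q)/A_Q - sin(dphi) I') / cos(dphi)`.
#'
#' @param i_ch,q_ch `radar_ts` baseband channels of equal rate and length.
#' @param calib list (or named vector) with `A_I`, `A_Q`, `DC_I`, `DC_Q`,
#'   `dphi`.
#' @return list with balanced `radar_ts` elements `i` and `q`.
#' @export
compensate_imbalance <- function(i_ch, q_ch, calib) {
  stopifnot(inherits(i_ch, "radar_ts"), inherits(q_ch, "radar_ts"),
            i_ch$rate == q_ch$rate,
            length(i_ch$values) == length(q_ch$values))
  calib <- as.list(calib)
  for (k in c("A_I", "A_Q", "DC_I", "DC_Q", "dphi"))
    if (is.null(calib[[k]])) stop("calibration missing parameter ", k)
  if (abs(cos(calib$dphi)) < 1e-6)
    stop("degenerate phase imbalance: |cos(dphi)| ~ 0")
  ib <- (i_ch$values - calib$DC_I) / calib$A_I
  qb <- ((q_ch$values - calib$DC_Q) / calib$A_Q - sin(calib$dphi) * ib) /
    cos(calib$dphi)
  list(i = time_series(ib, i_ch$rate, i_ch$t0),
       q = time_series(qb, q_ch$rate, q_ch$t0))
}

#' Extended DACM phase demodulation
#'
#' Computes the relative chest displacement from balanced I/Q channels as
#' `x_n = (lambda / 4 pi) * sum_{k<=n} (I_k dQ_k - Q_k dI_k) / (I_k^2 + Q_k^2)`
#' with first-difference increments and `x_0 = 0`. Integrating the phase
#' derivative avoids arctangent wrapping, so displacements crossing several
#' multiples of `lambda/4` are recovered without discontinuities. The result
#' is defined up to an additive constant.
#'
#' @param i_ch,q_ch balanced `radar_ts` channels (apply
#'   [compensate_imbalance()] first).
#' @param wavelength carrier wavelength, m.
#' @return list of class `displacement_trace`: `x` (a [time_series()], metres,
#'   relative) and `lambda_used`.
#' @export
dacm_demodulate <- function(i_ch, q_ch, wavelength) {
  stopifnot(inherits(i_ch, "radar_ts"), inherits(q_ch, "radar_ts"),
            i_ch$rate == q_ch$rate,
            length(i_ch$values) == length(q_ch$values),
            wavelength > 0)
  iv <- i_ch$values; qv <- q_ch$values
  pwr <- iv^2 + qv^2
  if (length(pwr) && any(pwr < 1e-12))
    stop("phase undefined: I^2 + Q^2 below 1e-12 at some sample")
  if (!length(iv))
    return(structure(list(x = time_series(numeric(0), i_ch$rate, i_ch$t0),
                          lambda_used = wavelength),
                     class = "displacement_trace"))
  di <- c(0, diff(iv)); dq <- c(0, diff(qv))
  dphase <- (iv * dq - qv * di) / pwr
  x <- (wavelength / (4 * pi)) * cumsum(dphase)
  x <- x - x[1]
  structure(list(x = time_series(x, i_ch$rate, i_ch$t0),
                 lambda_used = wavelength),
            class = "displacement_trace")
}

#' Estimate I/Q calibration by least-squares ellipse fit
#'
#' The noise-free imbalanced channels trace the ellipse
#' `(u/A_I)^2 + ((v/A_Q - sin(dphi) u/A_I)/cos(dphi))^2 = 1` about the centre
#' `(DC_I, DC_Q)`. A linear least-squares conic fit
#' `a x^2 + b xy + c y^2 + d x + e y = 1` on a calibration segment yields the
#' centre and, from the centred quadratic form, `A_I`, `A_Q` and `dphi`.
#' Requires the segment to sweep an appreciable arc of the ellipse.
#'
#' @param i_ch,q_ch `radar_ts` channels of a calibration segment.
#' @return list with `A_I`, `A_Q`, `DC_I`, `DC_Q`, `dphi`.
#' @export
fit_iq_calibration <- function(i_ch, q_ch) {
  x <- i_ch$values; y <- q_ch$values
  stopifnot(length(x) == length(y), length(x) >= 10)
  M <- cbind(x^2, x * y, y^2, x, y)
  coef <- stats::lm.fit(M, rep(1, length(x)))$coefficients
  a <- coef[1]; b <- coef[2]; cc <- coef[3]; d <- coef[4]; e <- coef[5]
  det2 <- 4 * a * cc - b^2
  if (!is.finite(det2) || det2 <= 0)
    stop("conic fit did not produce an ellipse; widen the calibration segment")
  # centre solves 2a cx + b cy = -d ; b cx + 2c cy = -e
  cx <- (b * e - 2 * cc * d) / det2
  cy <- (b * d - 2 * a * e) / det2
  # centred form: a u^2 + b uv + c v^2 = f0
  f0 <- 1 - (d * cx + e * cy) - (a * cx^2 + b * cx * cy + cc * cy^2)
  if (!is.finite(f0) || f0 <= 0)
    stop("conic fit inconsistent with an I/Q ellipse")
  ap <- a / f0; bp <- b / f0; cp <- cc / f0
  s <- -bp / (2 * sqrt(ap * cp))
  if (abs(s) >= 1) stop("conic fit inconsistent with an I/Q ellipse")
  dphi <- asin(s)
  A_I <- 1 / (sqrt(ap) * cos(dphi))
  A_Q <- 1 / (sqrt(cp) * cos(dphi))
  list(A_I = unname(A_I), A_Q = unname(A_Q), DC_I = unname(cx),
       DC_Q = unname(cy), dphi = unname(dphi))
}
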