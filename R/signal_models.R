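#' Protocol b-values
#'
#' The seven diffusion weightings of the acquisition protocol, s/mm^2.
#' @export
protocol_bvalues <- function() c(0, 50, 100, 150, 200, 500, 800)

#' Forward diffusion signal models
#'
#' Noise-free signal decay as a function of b-value for the three models used
#' throughout the package:
#' \describe{
#'   \item{biexponential (IVIM)}{`S(b) = S0 [(1-f) exp(-b D) + f exp(-b (D + D*))]`
#'     — a slow tissue-water pool with diffusivity D and a fast vascular pool
#'     with volume fraction f whose pseudo-diffusion adds D* on top of D.}
#'   \item{mono-exponential}{`S(b) = S0 exp(-b ADC)`.}
#'   \item{stretched exponential}{`S(b) = S0 exp(-(b DDC)^Alpha)` — a
#'     continuous distribution of diffusivities with distribution coefficient
#'     DDC and heterogeneity index Alpha; Alpha = 1 recovers the
#'     mono-exponential model.}
#' }
#' All diffusivities are in mm^2/s and b-values in s/mm^2; `f` is a fraction
#' in `[0, 1]`.
#'
#' @param f Perfusion (vascular volume) fraction in `[0, 1]`.
#' @param D True (tissue) diffusion coefficient, mm^2/s.
#' @param Dstar Pseudo-diffusion coefficient of the vascular pool, mm^2/s;
#'   the fast pool decays at rate `D + Dstar`.
#' @param S0 Signal at b = 0.
#' @param bvalues Numeric vector of b-values, s/mm^2.
#' @return Numeric signal vector, one value per b-value.
#' @export
biexp_signal <- function(f, D, Dstar, S0, bvalues) {
  check_param(f, 0, 1, "f")
  check_param(D, 0, Inf, "D", strict_lower = TRUE)
  check_param(Dstar, 0, Inf, "Dstar")
  check_param(S0, 0, Inf, "S0", strict_lower = TRUE)
  S0 * ((1 - f) * exp(-bvalues * D) + f * exp(-bvalues * (D + Dstar)))
}

#' @rdname biexp_signal
#' @param ADC Apparent diffusion coefficient, mm^2/s.
#' @export
mono_signal <- function(ADC, S0, bvalues) {
  check_param(ADC, 0, Inf, "ADC")
  check_param(S0, 0, Inf, "S0", strict_lower = TRUE)
  S0 * exp(-bvalues * ADC)
}

#' @rdname biexp_signal
#' @param DDC Diffusion distribution coefficient, mm^2/s.
#' @param Alpha Heterogeneity index in `(0, 1]`.
#' @export
stretched_signal <- function(DDC, Alpha, S0, bvalues) {
  check_param(DDC, 0, Inf, "DDC", strict_lower = TRUE)
  check_param(Alpha, 0, 1, "Alpha", strict_lower = TRUE)
  check_param(S0, 0, Inf, "S0", strict_lower = TRUE)
  S0 * exp(-(bvalues * DDC)^Alpha)
}

check_param <- function(x, lo, hi, name, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if ((strict_lower && x <= lo) || (!strict_lower && x < lo) || x > hi)
    stop(sprintf("'%s' = %g outside [%g, %g]", name, x, lo, hi), call. = FALSE)
  invisible(TRUE)
}

#' Virtual MR elastography configuration
#'
#' The virtual stiffness is a linear calibration of the log signal ratio
#' between a low and a high diffusion weighting:
#' `mu_diff = alpha_scale * ln(S_low / S_high) + beta_shift`.
#' Defaults follow the liver-calibrated constants alpha = -9.8 kPa and
#' beta = 14 kPa with b_low = 200 and b_high = 800 s/mm^2. With alpha < 0,
#' stronger attenuation between the two weightings (a softer, faster-diffusing
#' tissue) maps to lower stiffness.
#'
#' @param alpha_scale Scaling factor alpha, kPa.
#' @param beta_shift Shift factor beta, kPa.
#' @param b_low,b_high The two key b-values, s/mm^2; `b_high > b_low > 0`.
#' @return An object of class `vmre_config`.
#' @export
vmre_config <- function(alpha_scale = -9.8, beta_shift = 14,
                        b_low = 200, b_high = 800) {
  if (!(b_high > b_low && b_low > 0))
    stop("require b_high > b_low > 0", call. = FALSE)
  structure(list(alpha_scale = alpha_scale, beta_shift = beta_shift,
                 b_low = b_low, b_high = b_high),
            class = "vmre_config")
}

#' @export
print.vmre_config <- function(x, ...) {
  cat(sprintf("vMRE calibration: mu_diff = %g * ln(S[b=%g]/S[b=%g]) + %g kPa\n",
              x$alpha_scale, x$b_low, x$b_high, x$beta_shift))
  invisible(x)
}

#' Compute virtual MR elastography stiffness from a signal curve
#'
#' Evaluates `mu_diff = alpha * ln(S_low/S_high) + beta` for one voxel's
#' signal decay. If several volumes share the required b-value, their signals
#' are averaged. A nonpositive signal at either key b-value yields `NaN`
#' rather than an error, so failed voxels do not abort volume-level maps.
#'
#' @param signal Numeric signal vector.
#' @param bvalues b-values matching `signal`.
#' @param config A [vmre_config()].
#' @return Stiffness `mu_diff` in kPa (scalar).
#' @export
compute_vmre <- function(signal, bvalues, config = vmre_config()) {
  stopifnot(inherits(config, "vmre_config"))
  if (length(signal) != length(bvalues))
    stop("signal and bvalues differ in length", call. = FALSE)
  i_low <- which(bvalues == config$b_low)
  i_high <- which(bvalues == config$b_high)
  if (!length(i_low) || !length(i_high))
    stop(sprintf("required b-values %g and %g not both present",
                 config$b_low, config$b_high), call. = FALSE)
  s_low <- mean(signal[i_low])
  s_high <- mean(signal[i_high])
  if (!is.finite(s_low) || !is.finite(s_high) || s_low <= 0 || s_high <= 0)
    return(NaN)
  config$alpha_scale * log(s_low / s_high) + config$beta_shift
}
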