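# Physiological parameter bounds bracketing placental tissue values (mm^2/s).
ivim_bounds <- list(
  f = c(0, 1),
  D = c(1e-5, 5e-3),
  Dstar = c(5e-3, 0.5),
  DDC = c(1e-5, 1e-2),
  Alpha = c(0.01, 1)
)

new_dwi_fit <- function(subclass, params, S0, rss, converged, bvalues, signal,
                        extra = list()) {
  structure(
    c(list(coefficients = params, S0 = S0, rss = rss, converged = converged,
           bvalues = bvalues, signal = signal), extra),
    class = c(subclass, "dwi_fit"))
}

#' @export
coef.dwi_fit <- function(object, ...) object$coefficients

#' @export
print.dwi_fit <- function(x, ...) {
  cat(class(x)[1], if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  print(signif(c(x$coefficients, S0 = x$S0), 6))
  cat(sprintf("residual sum of squares: %.4g over %d b-values\n",
              x$rss, length(x$bvalues)))
  invisible(x)
}

#' @export
residuals.dwi_fit <- function(object, ...) {
  object$signal - predict(object, object$bvalues)
}

#' @export
predict.mono_fit <- function(object, bvalues = object$bvalues, ...) {
  p <- object$coefficients
  mono_signal(p[["ADC"]], object$S0, bvalues)
}

#' @export
predict.ivim_fit <- function(object, bvalues = object$bvalues, ...) {
  p <- object$coefficients
  if (is.na(p[["Dstar"]]))
    return(mono_signal(p[["D"]], object$S0 * (1 - p[["f"]]), bvalues))
  biexp_signal(p[["f"]], p[["D"]], p[["Dstar"]], object$S0, bvalues)
}

#' @export
predict.stretched_fit <- function(object, bvalues = object$bvalues, ...) {
  p <- object$coefficients
  stretched_signal(p[["DDC"]], p[["Alpha"]], object$S0, bvalues)
}

rss_of <- function(pred, signal) sum((signal - pred)^2)

check_fit_input <- function(signal, bvalues, min_b = 2L) {
  if (length(signal) != length(bvalues))
    stop("signal and bvalues differ in length", call. = FALSE)
  if (length(unique(bvalues)) < min_b)
    stop(sprintf("need at least %d distinct b-values", min_b), call. = FALSE)
  invisible(TRUE)
}

unfit <- function(what, bvalues, signal) {
  params <- switch(what,
    mono = c(ADC = NaN),
    ivim = c(f = NaN, D = NaN, Dstar = NaN),
    stretched = c(DDC = NaN, Alpha = NaN))
  new_dwi_fit(paste0(what, "_fit"), params, NaN, NaN, FALSE, bvalues, signal)
}

#' Fit the mono-exponential (ADC) model
#'
#' Log-linear least squares of `log S(b)` on `b` over all b-values, the
#' standard apparent-diffusion-coefficient estimate. Voxels containing a
#' nonpositive signal cannot be log-transformed and come back as an unfit
#' result (all-NaN, `converged = FALSE`) rather than an error, so volume
#' fitting can proceed past bad voxels.
#'
#' @param signal Numeric signal vector.
#' @param bvalues b-values, s/mm^2 (at least 2 distinct).
#' @return Object of class `c("mono_fit", "dwi_fit")` with coefficient `ADC`
#'   (mm^2/s), `S0`, residual sum of squares and a convergence flag.
#' @export
fit_adc <- function(signal, bvalues) {
  check_fit_input(signal, bvalues, 2L)
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(unfit("mono", bvalues, signal))
  fit <- stats::lm.fit(cbind(1, -bvalues), log(signal))
  adc <- fit$coefficients[2]
  s0 <- exp(fit$coefficients[1])
  pred <- mono_signal(max(adc, 0), s0, bvalues)
  new_dwi_fit("mono_fit", c(ADC = unname(adc)), unname(s0),
              rss_of(pred, signal),
              converged = fit$rank == 2L && is.finite(adc),
              bvalues, signal)
}

#' Fit the biexponential IVIM model, segmented algorithm
#'
#' Three-step segmented fit, the reproducible workhorse for perfusion
#' fraction estimation:
#' \enumerate{
#'   \item log-linear fit on `b >= b_threshold`, where the fast vascular pool
#'     has fully decayed, gives D and the tissue-compartment intercept;
#'   \item `f = 1 - intercept / S0` with S0 the mean signal at the minimum b;
#'   \item D* by 1-D bounded minimization of the residual sum of squares over
#'     the full curve with f and D held fixed.
#' }
#' If step 2 yields `f <= 0` the voxel is declared perfusion-free (f = 0,
#' D* = NaN); f > 1 is clipped and flagged. Parameters are clipped to
#' physiological bounds.
#'
#' @inheritParams fit_adc
#' @param b_threshold Split between perfusion-sensitive and diffusion-only
#'   weightings, s/mm^2. Default 200 (the low/high split of the protocol).
#' @return Object of class `c("ivim_fit", "dwi_fit")` with coefficients `f`
#'   (fraction), `D`, `Dstar` (mm^2/s), plus `S0`, `rss`, `method`,
#'   `converged`.
#' @export
fit_ivim_segmented <- function(signal, bvalues, b_threshold = 200) {
  check_fit_input(signal, bvalues, 4L)
  hi <- bvalues >= b_threshold
  lo <- !hi
  if (sum(hi) < 2L || sum(lo) < 2L)
    stop(sprintf("need >= 2 b-values on each side of b_threshold = %g",
                 b_threshold), call. = FALSE)
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(unfit("ivim", bvalues, signal))
  s0_obs <- mean(signal[bvalues == min(bvalues)])

  hfit <- stats::lm.fit(cbind(1, -bvalues[hi]), log(signal[hi]))
  D <- unname(hfit$coefficients[2])
  intercept <- exp(unname(hfit$coefficients[1]))
  ok <- is.finite(D)
  D <- min(max(D, ivim_bounds$D[1]), ivim_bounds$D[2])

  f <- 1 - intercept / s0_obs
  clipped <- FALSE
  if (f > 1) { f <- 1; clipped <- TRUE }
  if (f <= 0) {
    # noise can push the tissue intercept above S0: perfusion-free voxel
    fit <- new_dwi_fit("ivim_fit", c(f = 0, D = D, Dstar = NaN), s0_obs,
                       rss_of(mono_signal(D, s0_obs * (1 - 0), bvalues), signal),
                       converged = ok, bvalues, signal,
                       extra = list(method = "segmented"))
    return(fit)
  }

  rss_ds <- function(ds)
    rss_of(biexp_signal(f, D, ds, s0_obs, bvalues), signal)
  opt <- stats::optimize(rss_ds, interval = ivim_bounds$Dstar, tol = 1e-12)
  dstar <- opt$minimum
  # flat objective over the whole D* range: fast pool carries no information
  r_lo <- rss_ds(ivim_bounds$Dstar[1]); r_hi <- rss_ds(ivim_bounds$Dstar[2])
  spread <- max(r_lo, r_hi, opt$objective) - min(r_lo, r_hi, opt$objective)
  degenerate <- spread <= 1e-10 * max(r_lo, r_hi, 1e-30)
  if (degenerate) dstar <- NaN

  new_dwi_fit("ivim_fit", c(f = f, D = D, Dstar = dstar), s0_obs,
              if (is.na(dstar)) NaN else opt$objective,
              converged = ok && !clipped && !degenerate, bvalues, signal,
              extra = list(method = "segmented"))
}

#' Fit the biexponential IVIM model, full nonlinear least squares
#'
#' Bounded Levenberg-Marquardt least squares over all four parameters
#' `(S0, f, D, Dstar)`, initialized from the segmented fit unless an explicit
#' init is given. Deterministic for identical input and init: no multi-start,
#' no randomness. Falls back to `optim(L-BFGS-B)` on the residual sum of
#' squares if the LM step fails; if both fail, the initial parameters are
#' returned with `converged = FALSE`.
#'
#' @inheritParams fit_ivim_segmented
#' @param init Optional `ivim_fit` (or named list with `f`, `D`, `Dstar`,
#'   `S0`) used as the starting point.
#' @return Object of class `c("ivim_fit", "dwi_fit")`, `method = "full"`.
#' @export
fit_ivim_full <- function(signal, bvalues, init = NULL, b_threshold = 200) {
  check_fit_input(signal, bvalues, 4L)
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(unfit("ivim", bvalues, signal))
  if (is.null(init)) init <- fit_ivim_segmented(signal, bvalues, b_threshold)
  p0 <- if (inherits(init, "ivim_fit"))
    c(coef(init)[c("f", "D", "Dstar")], S0 = init$S0)
  else c(f = init$f, D = init$D, Dstar = init$Dstar, S0 = init$S0)
  if (is.na(p0[["Dstar"]])) p0[["Dstar"]] <- 0.05      # bound midpoint on log scale
  if (is.na(p0[["f"]])) p0[["f"]] <- 0.1
  lower <- c(ivim_bounds$f[1], ivim_bounds$D[1], ivim_bounds$Dstar[1], 1e-12)
  upper <- c(ivim_bounds$f[2], ivim_bounds$D[2], ivim_bounds$Dstar[2], Inf)
  p0 <- pmin(pmax(p0, lower), upper)
  df <- data.frame(b = bvalues, s = signal)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      s ~ S0 * ((1 - f) * exp(-b * D) + f * exp(-b * (D + Dstar))),
      data = df, start = as.list(p0), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
    cf <- stats::coef(m)
    list(par = cf[c("f", "D", "Dstar", "S0")], ok = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) rss_of(biexp_signal(p[1], p[2], p[3], p[4], bvalues),
                              signal)
    o <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B",
                               lower = lower, upper = pmin(upper, 1e12)),
                  error = function(e) NULL)
    fit <- if (is.null(o)) list(par = p0, ok = FALSE)
           else list(par = o$par, ok = o$convergence == 0)
  }
  par <- fit$par
  pred <- biexp_signal(par[[1]], par[[2]], par[[3]], par[[4]], bvalues)
  new_dwi_fit("ivim_fit",
              c(f = par[[1]], D = par[[2]], Dstar = par[[3]]), par[[4]],
              rss_of(pred, signal), converged = fit$ok, bvalues, signal,
              extra = list(method = "full"))
}

#' Fit the stretched-exponential model
#'
#' Bounded nonlinear least squares over `(S0, DDC, Alpha)` with
#' `Alpha` constrained to `(0, 1]`. Initialization: DDC from the
#' mono-exponential ADC fit, Alpha = 0.8. The model is implemented as
#' `S0 exp(-(b DDC)^Alpha)`, the standard stretched-exponential form in which
#' Alpha is identifiable (the variant that raises the whole exponential to
#' Alpha collapses to a mono-exponential with rate `Alpha * DDC`).
#'
#' @inheritParams fit_adc
#' @return Object of class `c("stretched_fit", "dwi_fit")` with coefficients
#'   `DDC` (mm^2/s) and `Alpha`.
#' @export
fit_stretched <- function(signal, bvalues) {
  check_fit_input(signal, bvalues, 3L)
  if (any(!is.finite(signal)) || any(signal <= 0))
    return(unfit("stretched", bvalues, signal))
  adc <- fit_adc(signal, bvalues)
  ddc0 <- if (isTRUE(adc$converged)) coef(adc)[["ADC"]] else 1e-3
  ddc0 <- min(max(ddc0, ivim_bounds$DDC[1]), ivim_bounds$DDC[2])
  s0_obs <- mean(signal[bvalues == min(bvalues)])
  lower <- c(ivim_bounds$DDC[1], ivim_bounds$Alpha[1], 1e-12)
  upper <- c(ivim_bounds$DDC[2], ivim_bounds$Alpha[2], Inf)
  df <- data.frame(b = bvalues, s = signal)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      s ~ S0 * exp(-(b * DDC)^Alpha),
      data = df, start = list(DDC = ddc0, Alpha = 0.8, S0 = s0_obs),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
    cf <- stats::coef(m)
    list(par = cf, ok = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) rss_of(stretched_signal(p[1], p[2], p[3], bvalues),
                              signal)
    o <- tryCatch(stats::optim(c(DDC = ddc0, Alpha = 0.8, S0 = s0_obs), obj,
                               method = "L-BFGS-B", lower = lower,
                               upper = pmin(upper, 1e12)),
                  error = function(e) NULL)
    fit <- if (is.null(o)) list(par = c(DDC = ddc0, Alpha = 0.8, S0 = s0_obs),
                                ok = FALSE)
           else list(par = o$par, ok = o$convergence == 0)
  }
  par <- fit$par
  pred <- stretched_signal(par[["DDC"]], par[["Alpha"]], par[["S0"]], bvalues)
  new_dwi_fit("stretched_fit",
              c(DDC = unname(par[["DDC"]]), Alpha = unname(par[["Alpha"]])),
              unname(par[["S0"]]), rss_of(pred, signal),
              converged = fit$ok, bvalues, signal)
}

#' Fit a model voxelwise over a masked volume
#'
#' Every masked voxel is fitted independently with the requested model;
#' voxels outside the mask, and voxels whose fit fails, are `NaN` in the
#' output maps. Deterministic for fixed input.
#'
#' @param series A [dwi_series()].
#' @param mask A [roi_mask()] on the same grid.
#' @param model One of `"adc"`, `"ivim_segmented"`, `"ivim_full"`,
#'   `"stretched"`, `"vmre"`.
#' @param config A [vmre_config()] (used by `model = "vmre"`).
#' @param b_threshold Passed to the segmented IVIM fitter.
#' @return Named list of [parameter_map()]s (e.g. `f`, `D`, `Dstar`, `S0` for
#'   IVIM; `mu_diff` for vMRE).
#' @export
fit_volume <- function(series, mask,
                       model = c("adc", "ivim_segmented", "ivim_full",
                                 "stretched", "vmre"),
                       config = vmre_config(), b_threshold = 200) {
  model <- match.arg(model)
  stopifnot(inherits(series, "dwi_series"), inherits(mask, "roi_mask"))
  if (!identical(as.integer(dim(mask$mask)), as.integer(spatial_dim(series))))
    stop("mask grid does not match series grid", call. = FALSE)
  dims <- spatial_dim(series)
  flat <- matrix(series$signal, prod(dims), n_volumes(series))
  idx <- which(as.vector(mask$mask))
  if (!length(idx)) stop("empty mask", call. = FALSE)

  param_names <- switch(model,
    adc = c("ADC", "S0"),
    ivim_segmented = , ivim_full = c("f", "D", "Dstar", "S0"),
    stretched = c("DDC", "Alpha", "S0"),
    vmre = "mu_diff")
  out <- lapply(param_names, function(p) array(NaN, dims))
  names(out) <- param_names

  for (i in idx) {
    sig <- flat[i, ]
    vals <- switch(model,
      adc = { ft <- fit_adc(sig, series$bvalues)
              c(coef(ft), S0 = ft$S0) },
      ivim_segmented = { ft <- fit_ivim_segmented(sig, series$bvalues, b_threshold)
                         c(coef(ft), S0 = ft$S0) },
      ivim_full = { ft <- fit_ivim_full(sig, series$bvalues, b_threshold = b_threshold)
                    c(coef(ft), S0 = ft$S0) },
      stretched = { ft <- fit_stretched(sig, series$bvalues)
                    c(coef(ft), S0 = ft$S0) },
      vmre = c(mu_diff = tryCatch(compute_vmre(sig, series$bvalues, config),
                                  error = function(e) stop(e))))
    for (p in param_names) out[[p]][i] <- vals[[p]]
  }
  maps <- lapply(param_names, function(p)
    parameter_map(out[[p]], p, affine = series$affine))
  names(maps) <- param_names
  maps
}

#' Convert fitted parameters to reporting scales
#'
#' Internally diffusivities are mm^2/s and f is a fraction; reports use
#' 10^-3 mm^2/s and percent. `mu_diff` (kPa) and `Alpha` are unchanged.
#'
#' @param values Named numeric vector or list of parameter values on internal
#'   scales.
#' @return Named numeric vector on reporting scales.
#' @export
report_scale <- function(values) {
  v <- unlist(values)
  for (nm in names(v)) {
    if (nm %in% c("D", "Dstar", "DDC", "ADC")) v[[nm]] <- v[[nm]] * 1e3
    if (nm == "f") v[[nm]] <- v[[nm]] * 100
  }
  v
}
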