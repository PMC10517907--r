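# Published group summaries used to calibrate the cohort generator.
# Parameters on reporting scales: mu_diff kPa; D, Dstar, DDC, ADC in
# 10^-3 mm^2/s; f percent; Alpha unitless.
default_parameter_stats <- list(
  adverse = list(
    mean = c(mu_diff = 5.47, D = 1.55, Dstar = 161.13, f = 23.56,
             DDC = 2.40, Alpha = 0.70, ADC = 2.34),
    sd   = c(mu_diff = 0.68, D = 0.23, Dstar = 48.07, f = 3.94,
             DDC = 0.49, Alpha = 0.04, ADC = 0.44)),
  non_adverse = list(
    mean = c(mu_diff = 4.89, D = 1.62, Dstar = 138.80, f = 28.44,
             DDC = 2.94, Alpha = 0.69, ADC = 2.75),
    sd   = c(mu_diff = 0.59, D = 0.13, Dstar = 46.58, f = 5.98,
             DDC = 0.63, Alpha = 0.05, ADC = 0.45))
)

# Clinical covariate distributions by group (normal mean/sd, or proportion).
default_covariate_stats <- list(
  adverse = list(
    maternal_age = c(29.90, 4.01), ga_mri = c(33.42, 2.76),
    ga_delivery = c(36.31, 2.19), birth_weight = c(1797.50, 516.43),
    p_vaginal = 4 / 20, p_preterm = 11 / 20, p_male = 6 / 20),
  non_adverse = list(
    maternal_age = c(30.85, 3.86), ga_mri = c(34.25, 2.80),
    ga_delivery = c(38.38, 1.43), birth_weight = c(2593.75, 327.81),
    p_vaginal = 19 / 40, p_preterm = 6 / 40, p_male = 16 / 40)
)

# Physical bounds for rejection sampling, on reporting scales.
parameter_truncation <- list(
  mu_diff = c(0, Inf), D = c(0, Inf), Dstar = c(0, Inf), f = c(0, 100),
  DDC = c(0, Inf), Alpha = c(0, 1), ADC = c(0, Inf)
)

#' Specification of one outcome group for cohort simulation
#'
#' Defaults reproduce the published group summaries: n = 20 adverse vs
#' n = 40 non-adverse subjects; quantitative parameters drawn from a
#' multivariate normal with the published means/SDs (independent by default,
#' correlation configurable); clinical covariates from the published
#' distributions. Draws are truncated to physical bounds (f in (0,100),
#' Alpha in (0,1], positive quantities positive) by rejection sampling, which
#' preserves the distribution shape near a bound.
#'
#' @param name `"adverse"` or `"non_adverse"`.
#' @param n Number of subjects.
#' @param parameter_means,parameter_sds Named vectors over `mu_diff`, `D`,
#'   `Dstar`, `f`, `DDC`, `Alpha`, `ADC` (reporting scales).
#' @param correlation Between-parameter correlation matrix (default
#'   identity).
#' @param covariates List of clinical covariate generators (normal mean/sd
#'   pairs and category proportions).
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(name = c("adverse", "non_adverse"),
                       n = if (match.arg(name) == "adverse") 20L else 40L,
                       parameter_means = default_parameter_stats[[match.arg(name)]]$mean,
                       parameter_sds = default_parameter_stats[[match.arg(name)]]$sd,
                       correlation = diag(length(parameter_means)),
                       covariates = default_covariate_stats[[match.arg(name)]]) {
  name <- match.arg(name)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (any(parameter_sds <= 0)) stop("parameter SDs must be positive", call. = FALSE)
  if (!identical(names(parameter_means), names(parameter_sds)))
    stop("means and sds must share names", call. = FALSE)
  correlation <- as.matrix(correlation)
  if (!isSymmetric(unname(correlation)) ||
      any(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("correlation matrix must be symmetric positive-semidefinite",
         call. = FALSE)
  structure(list(name = name, n = as.integer(n),
                 parameter_means = parameter_means,
                 parameter_sds = parameter_sds,
                 correlation = correlation, covariates = covariates),
            class = "group_spec")
}

draw_group_parameters <- function(spec) {
  p <- length(spec$parameter_means)
  Sigma <- diag(spec$parameter_sds) %*% spec$correlation %*%
    diag(spec$parameter_sds)
  nm <- names(spec$parameter_means)
  out <- matrix(NA_real_, spec$n, p, dimnames = list(NULL, nm))
  need <- spec$n; filled <- 0L; tried <- 0L; accepted <- 0L
  while (need > 0L) {
    draw <- MASS::mvrnorm(max(need * 2L, 10L), spec$parameter_means, Sigma)
    if (is.null(dim(draw))) draw <- matrix(draw, 1, dimnames = list(NULL, nm))
    ok <- rep(TRUE, nrow(draw))
    for (j in nm) {
      b <- parameter_truncation[[j]]
      if (!is.null(b)) ok <- ok & draw[, j] > b[1] & draw[, j] <= b[2]
    }
    tried <- tried + nrow(draw); accepted <- accepted + sum(ok)
    if (tried >= 1000L && accepted / tried < 0.01)
      stop("infeasible truncation: acceptance below 1%", call. = FALSE)
    take <- min(sum(ok), need)
    if (take > 0L) {
      out[filled + seq_len(take), ] <- draw[ok, , drop = FALSE][seq_len(take), ]
      filled <- filled + take; need <- need - take
    }
  }
  out
}

draw_group_covariates <- function(spec) {
  cv <- spec$covariates
  rnorm2 <- function(ms) stats::rnorm(spec$n, ms[1], ms[2])
  data.frame(
    maternal_age = rnorm2(cv$maternal_age),
    ga_mri = rnorm2(cv$ga_mri),
    ga_delivery = rnorm2(cv$ga_delivery),
    delivery_route = ifelse(stats::runif(spec$n) < cv$p_vaginal,
                            "vaginal", "cesarean"),
    preterm = ifelse(stats::runif(spec$n) < cv$p_preterm, "yes", "no"),
    neonatal_sex = ifelse(stats::runif(spec$n) < cv$p_male, "male", "female"),
    birth_weight = rnorm2(cv$birth_weight),
    stringsAsFactors = FALSE)
}

#' Simulate a per-subject cohort calibrated to the published groups
#'
#' Draws per-subject quantitative parameters and clinical covariates for both
#' outcome groups. Bit-reproducible for a fixed seed.
#'
#' @param adverse,non_adverse [group_spec()]s for the two groups.
#' @param seed Integer seed.
#' @return A `cohort_table`.
#' @export
simulate_cohort <- function(adverse = group_spec("adverse"),
                            non_adverse = group_spec("non_adverse"),
                            seed = 1L) {
  set.seed(seed)
  pieces <- lapply(list(adverse, non_adverse), function(spec) {
    stopifnot(inherits(spec, "group_spec"))
    params <- draw_group_parameters(spec)
    cov <- draw_group_covariates(spec)
    cbind(data.frame(group = spec$name, stringsAsFactors = FALSE),
          cov, as.data.frame(params))
  })
  df <- do.call(rbind, pieces)
  df <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(df))), df)
  as_cohort_table(df)
}

#' Specification of a signal-level DWI phantom
#'
#' The phantom grid is split into equal slabs along x, one per region; each
#' region decays according to its forward model (biexponential, stretched, or
#' mono-exponential) with its own true parameters (internal units: mm^2/s,
#' fraction). Noise models: `none`; `gaussian` (additive N(0, sigma*S0));
#' `rician` (magnitude of the complex signal with independent N(0, sigma*S0)
#' real/imaginary perturbations, producing the MRI noise floor
#' sigma*sqrt(pi/2) where the true signal vanishes).
#'
#' @param shape Integer length-3 grid dimensions.
#' @param regions List of regions; each a list with `model` (`"biexp"`,
#'   `"stretched"`, `"mono"`) and `params` (named list incl. `S0`).
#' @param bvalues b-values, s/mm^2.
#' @param noise_model `"none"`, `"gaussian"`, `"rician"`.
#' @param noise_sigma Noise SD as a fraction of S0.
#' @param seed Integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(8L, 8L, 2L),
                         regions = list(
                           list(model = "biexp",
                                params = list(f = 0.2356, D = 1.55e-3,
                                              Dstar = 161.13e-3, S0 = 100))),
                         bvalues = protocol_bvalues(),
                         noise_model = c("none", "gaussian", "rician"),
                         noise_sigma = 0.02, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(regions) >= 1L, shape[1] >= length(regions))
  for (r in regions) {
    if (!r$model %in% c("biexp", "stretched", "mono"))
      stop("unknown region model: ", r$model, call. = FALSE)
    # evaluate once at b = 0 to validate parameters before generation
    do.call(forward_model_fun(r$model), c(r$params, list(bvalues = 0)))
  }
  structure(list(shape = shape, regions = regions, bvalues = bvalues,
                 noise_model = noise_model, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

forward_model_fun <- function(model) {
  switch(model, biexp = biexp_signal, stretched = stretched_signal,
         mono = mono_signal)
}

region_truth_params <- function(region) {
  p <- region$params
  switch(region$model,
    biexp = c(f = p$f, D = p$D, Dstar = p$Dstar, S0 = p$S0),
    stretched = c(DDC = p$DDC, Alpha = p$Alpha, S0 = p$S0),
    mono = c(ADC = p$ADC, S0 = p$S0))
}

#' Simulate a DWI phantom with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `series` ([dwi_series()]), `truth` (named list of
#'   [parameter_map()]s), `mask` ([roi_mask()] covering all regions), and
#'   `region_masks` (one [roi_mask()] per region).
#' @export
simulate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$shape
  nb <- length(spec$bvalues)
  nregion <- length(spec$regions)
  slab <- split(seq_len(dims[1]),
                ceiling(seq_len(dims[1]) * nregion / dims[1]))

  signal <- array(0, c(dims, nb))
  truth_names <- unique(unlist(lapply(spec$regions, function(r)
    names(region_truth_params(r)))))
  truth <- lapply(truth_names, function(p) array(NaN, dims))
  names(truth) <- truth_names
  region_masks <- vector("list", nregion)

  for (k in seq_len(nregion)) {
    region <- spec$regions[[k]]
    curve <- do.call(forward_model_fun(region$model),
                     c(region$params, list(bvalues = spec$bvalues)))
    m <- array(FALSE, dims); m[slab[[k]], , ] <- TRUE
    region_masks[[k]] <- roi_mask(m, label = sprintf("region%d", k))
    for (v in seq_len(nb)) signal[, , , v][m] <- curve[v]
    tp <- region_truth_params(region)
    for (p in names(tp)) truth[[p]][m] <- tp[[p]]
  }

  s0ref <- max(vapply(spec$regions, function(r) r$params$S0, 1.0))
  if (spec$noise_model == "gaussian" && spec$noise_sigma > 0) {
    signal <- signal + stats::rnorm(length(signal), 0,
                                    spec$noise_sigma * s0ref)
    signal[signal < 0] <- 0
  } else if (spec$noise_model == "rician" && spec$noise_sigma > 0) {
    n1 <- stats::rnorm(length(signal), 0, spec$noise_sigma * s0ref)
    n2 <- stats::rnorm(length(signal), 0, spec$noise_sigma * s0ref)
    signal <- sqrt((signal + n1)^2 + n2^2)
  }

  all_mask <- array(FALSE, dims)
  for (rm in region_masks) all_mask <- all_mask | rm$mask
  list(series = dwi_series(signal, spec$bvalues),
       truth = lapply(truth_names, function(p)
         parameter_map(truth[[p]], p))  |> stats::setNames(truth_names),
       mask = roi_mask(all_mask, label = "phantom"),
       region_masks = region_masks)
}

#' Simulate repeated reader measurements
#'
#' Rater k observes `truth + bias[k] + N(0, reader_sd^2)` per subject —
#' the additive two-way model underlying the ICC machinery.
#'
#' @param truth Numeric vector of per-subject true summaries.
#' @param reader_sd Within-reader noise SD (>= 0).
#' @param bias Per-rater systematic offsets (recycled to `n_raters`).
#' @param n_raters Number of raters/reads.
#' @param seed Integer seed.
#' @return Numeric matrix, subjects x raters.
#' @export
simulate_reader_pair <- function(truth, reader_sd, bias = 0, n_raters = 2L,
                                 seed = 1L) {
  if (reader_sd < 0) stop("reader_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  bias <- rep_len(bias, n_raters)
  n <- length(truth)
  ratings <- sapply(seq_len(n_raters), function(k)
    truth + bias[k] + stats::rnorm(n, 0, reader_sd))
  dimnames(ratings) <- list(names(truth),
                            paste0("rater", seq_len(n_raters)))
  ratings
}
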