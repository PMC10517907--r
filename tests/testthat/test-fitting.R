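test_that("ADC fit recovers mono-exponential parameters from noise-free data", {
  b <- protocol_b
  s <- mono_signal(2.75e-3, 120, b)
  fit <- fit_adc(s, b)
  expect_true(fit$converged)
  expect_lt(rel_err(coef(fit)[["ADC"]], 2.75e-3), 1e-6)
  expect_lt(rel_err(fit$S0, 120), 1e-6)

  flat <- fit_adc(rep(5, 7), b)          # ADC = 0 boundary
  expect_equal(coef(flat)[["ADC"]], 0, tolerance = 1e-12)

  expect_error(fit_adc(c(1, 0.5), c(100, 100)), "distinct")
  bad <- fit_adc(c(1, 0, 0.5, 0.2, 0.1, 0.05, 0.01), b)  # nonpositive voxel
  expect_false(bad$converged)
  expect_true(is.nan(coef(bad)[["ADC"]]))
})

test_that("apparent diffusivity of a perfused voxel lies between D and D + D*", {
  b <- protocol_b
  for (f in c(0.1, 0.2356, 0.4)) {
    s <- biexp_signal(f, 1.55e-3, 161.13e-3, 1, b)
    adc <- coef(fit_adc(s, b))[["ADC"]]
    expect_gt(adc, 1.55e-3)
    expect_lt(adc, 1.55e-3 + 161.13e-3)
  }
})

test_that("segmented IVIM fit recovers the generating parameters exactly", {
  b <- protocol_b
  for (tr in list(adverse_truth, non_adverse_truth)) {
    s <- biexp_signal(tr$f, tr$D, tr$Dstar, 1, b)
    fit <- fit_ivim_segmented(s, b)
    expect_true(fit$converged)
    expect_lt(rel_err(coef(fit)[["f"]], tr$f), 1e-3)
    expect_lt(rel_err(coef(fit)[["D"]], tr$D), 1e-3)
    expect_lt(rel_err(coef(fit)[["Dstar"]], tr$Dstar), 1e-2)
  }
})

test_that("perfusion-free voxels are declared f = 0 with unidentifiable D*", {
  b <- protocol_b
  s <- mono_signal(1.5e-3, 1, b)
  fit <- fit_ivim_segmented(s, b)
  expect_equal(coef(fit)[["f"]], 0, tolerance = 1e-6)
  expect_equal(coef(fit)[["D"]], 1.5e-3, tolerance = 1e-8)
  expect_true(is.nan(coef(fit)[["Dstar"]]))
})

test_that("full IVIM fit agrees with the segmented fit on noise-free data", {
  b <- protocol_b
  s <- biexp_signal(0.2844, 1.62e-3, 138.80e-3, 1, b)
  seg <- fit_ivim_segmented(s, b)
  full <- fit_ivim_full(s, b)
  expect_true(full$converged)
  expect_lt(rel_err(coef(full)[["D"]], 1.62e-3), 1e-3)
  expect_lt(rel_err(coef(full)[["f"]], coef(seg)[["f"]]), 1e-3)
  expect_lt(rel_err(coef(full)[["Dstar"]], coef(seg)[["Dstar"]]), 1e-2)

  # initializing at the truth is a fixed point
  init <- list(f = 0.2844, D = 1.62e-3, Dstar = 138.80e-3, S0 = 1)
  at_truth <- fit_ivim_full(s, b, init = init)
  expect_lt(rel_err(coef(at_truth)[["f"]], 0.2844), 1e-6)
  expect_lt(rel_err(coef(at_truth)[["Dstar"]], 138.80e-3), 1e-6)
})

test_that("full IVIM fit has small median f bias at 0.5% Gaussian noise", {
  b <- protocol_b
  truth_f <- adverse_truth$f
  clean <- biexp_signal(truth_f, adverse_truth$D, adverse_truth$Dstar, 1, b)
  set.seed(20)
  fs <- replicate(1000, {
    s <- pmax(clean + rnorm(length(b), 0, 0.005), 1e-6)
    coef(fit_ivim_full(s, b))[["f"]]
  })
  expect_lt(abs(stats::median(fs) - truth_f) * 100, 2)  # percentage points
})

test_that("stretched fit recovers DDC and Alpha, and degrades gracefully", {
  b <- protocol_b
  s <- stretched_signal(2.94e-3, 0.69, 1, b)
  fit <- fit_stretched(s, b)
  expect_true(fit$converged)
  expect_lt(rel_err(coef(fit)[["DDC"]], 2.94e-3), 1e-3)
  expect_lt(rel_err(coef(fit)[["Alpha"]], 0.69), 1e-3)

  # mono-exponential input drives Alpha to its upper boundary
  mono <- fit_stretched(mono_signal(2e-3, 1, b), b)
  expect_gt(coef(mono)[["Alpha"]], 0.999)
  expect_lt(rel_err(coef(mono)[["DDC"]], 2e-3), 1e-3)

  # multi-compartment decay is sub-mono-exponential
  bi <- fit_stretched(biexp_signal(0.25, 1.5e-3, 0.15, 1, b), b)
  expect_lt(coef(bi)[["Alpha"]], 1)
})

test_that("all fitters are invariant to signal scale and volume order", {
  b <- protocol_b
  set.seed(11)
  for (i in 1:5) {
    f <- runif(1, 0.1, 0.4); D <- runif(1, 1e-3, 2.5e-3)
    Ds <- runif(1, 0.05, 0.25)
    s <- pmax(biexp_signal(f, D, Ds, 1, b) + rnorm(length(b), 0, 0.005), 1e-6)
    scl <- runif(1, 0.5, 200)
    perm <- sample(length(b))

    # exact scale invariance is checked on well-conditioned noise-free decay;
    # with noise the optimizer's absolute stopping rules add slack
    clean <- biexp_signal(f, D, Ds, 1, b)
    base_clean <- coef(fit_ivim_full(clean, b))
    expect_equal(coef(fit_ivim_full(clean * scl, b)), base_clean,
                 tolerance = 1e-5)
    base_ivim <- coef(fit_ivim_full(s, b))
    expect_equal(coef(fit_ivim_full(s * scl, b)), base_ivim, tolerance = 5e-3)
    expect_equal(coef(fit_ivim_full(s[perm], b[perm])), base_ivim,
                 tolerance = 1e-5)

    base_adc <- coef(fit_adc(s, b))[["ADC"]]
    expect_equal(coef(fit_adc(s * scl, b))[["ADC"]], base_adc,
                 tolerance = 1e-9)
    expect_equal(coef(fit_adc(s[perm], b[perm]))[["ADC"]], base_adc,
                 tolerance = 1e-9)

    base_st <- coef(fit_stretched(s, b))
    expect_equal(coef(fit_stretched(s * scl, b)), base_st, tolerance = 1e-5)
    expect_equal(coef(fit_stretched(s[perm], b[perm])), base_st,
                 tolerance = 1e-5)

    expect_equal(compute_vmre(s * scl, b), compute_vmre(s, b),
                 tolerance = 1e-10)
    expect_equal(compute_vmre(s[perm], b[perm]), compute_vmre(s, b),
                 tolerance = 1e-10)
  }
})

test_that("fit methods predict and leave near-zero residuals on clean data", {
  b <- protocol_b
  s <- biexp_signal(0.25, 1.5e-3, 0.15, 10, b)
  fit <- fit_ivim_full(s, b)
  expect_equal(predict(fit), s, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("volume fitting equals the per-voxel scalar fit and isolates failures", {
  ph <- simulate_phantom(phantom_spec(shape = c(4L, 2L, 1L),
                                      noise_model = "none"))
  maps <- fit_volume(ph$series, ph$mask, model = "ivim_segmented")
  scalar <- fit_ivim_segmented(ph$series$signal[1, 1, 1, ],
                               ph$series$bvalues)
  fvox <- maps$f$values[ph$mask$mask]
  expect_true(all(abs(fvox - coef(scalar)[["f"]]) < 1e-9))

  # full-model volume fit matches voxel-by-voxel full fits
  maps_full <- fit_volume(ph$series, ph$mask, model = "ivim_full")
  v <- which(ph$mask$mask, arr.ind = TRUE)[2, ]
  single <- fit_ivim_full(ph$series$signal[v[1], v[2], v[3], ],
                          ph$series$bvalues)
  expect_equal(maps_full$f$values[v[1], v[2], v[3]], coef(single)[["f"]],
               tolerance = 1e-12)

  # a zero signal at b_high poisons only its own voxel in the mu_diff map
  sig <- ph$series$signal
  sig[1, 1, 1, 7] <- 0
  broken <- dwi_series(sig, ph$series$bvalues)
  mu <- fit_volume(broken, ph$mask, model = "vmre")$mu_diff$values
  expect_true(is.nan(mu[1, 1, 1]))
  expect_false(anyNA(mu[ph$mask$mask][-1]))

  expect_error(fit_volume(ph$series,
                          structure(list(mask = array(TRUE, c(2, 2, 2)),
                                         label = "bad"),
                                    class = "roi_mask"),
                          model = "adc"),
               "does not match")
})

test_that("reporting scales convert diffusivities and perfusion fraction", {
  v <- report_scale(c(f = 0.2356, D = 1.55e-3, Dstar = 161.13e-3,
                      Alpha = 0.7, mu_diff = 5.47))
  expect_equal(unname(v[c("f", "D", "Dstar")]), c(23.56, 1.55, 161.13),
               tolerance = 1e-9)
  expect_equal(unname(v[["Alpha"]]), 0.7)
  expect_equal(unname(v[["mu_diff"]]), 5.47)
})
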