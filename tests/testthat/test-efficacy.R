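rad_t <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1)

test_that("efficacy identities: no treatment 0, elimination 100", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  expect_equal(treatment_efficacy(p, rad_t, treatment_schedule(),
                                  treatment_schedule()), 0)
  # huge activation drives C below the extinction threshold -> exactly 100
  sch <- treatment_schedule(treatment_event(8, dose = 8, A = 200))
  expect_equal(treatment_efficacy(p, rad_t, sch, eval_day = 40), 100)
  # extinct control is an error
  p0 <- model_params(c1 = 0.01, cmax = 100)
  expect_error(
    treatment_efficacy(p0, rad_t, treatment_schedule(), treatment_schedule(),
                       init = c(C = 1e-7, E = 0, M = 0, Mstar = 0)),
    "extinct")
})

test_that("efficacy increases with activation at fixed dose", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  effs <- vapply(c(2, 5, 10, 20), function(A)
    treatment_efficacy(p, rad_t,
                       treatment_schedule(treatment_event(12, dose = 8,
                                                          A = A))), 1)
  expect_true(all(diff(effs) > 0))
  expect_true(all(effs > 0 & effs < 100))
})

test_that("efficacy grid is consistent with single evaluations and monotone in A", {
  p <- set_params(tt$params, c(phi_mstar = 0))
  grid <- efficacy_grid(A_range = c(0, 5, 15), phi_range = c(0, 4.43e-8),
                        dose_range = c(0, 8), params = p, rad = rad_t,
                        treatment_day = 12, eval_day = 22)
  # zero-treatment cell is exactly 0
  z <- grid$efficacy[grid$A == 0 & grid$phi == 0 & grid$dose_Gy == 0]
  expect_equal(z, 0)
  # one cell recomputed directly
  cell <- grid[grid$A == 15 & grid$phi == 0 & grid$dose_Gy == 8, ]
  direct <- treatment_efficacy(
    p, rad_t, treatment_schedule(treatment_event(12, dose = 8, A = 15)),
    params_control = p, eval_day = 22, use_Mstar = TRUE)
  expect_equal(cell$efficacy, direct, tolerance = 1e-10)
  # cell-wise nondecreasing in A at fixed (phi, dose)
  for (ph in unique(grid$phi)) for (d in unique(grid$dose_Gy)) {
    sl <- grid[grid$phi == ph & grid$dose_Gy == d, ]
    # dose-0 cells carry integrator-breakpoint jitter of ~1e-6 on the
    # percentage scale
    expect_true(all(diff(sl$efficacy[order(sl$A)]) >= -1e-5))
  }
})

test_that("radio-resistance never increases efficacy on the grid", {
  p <- set_params(tt$params, c(phi_mstar = 0))
  res <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1,
                          resistance_scale = 0.5)
  g1 <- efficacy_grid(c(0, 10), c(0, 4.43e-8), c(4, 8), params = p,
                      rad = rad_t)
  g2 <- efficacy_grid(c(0, 10), c(0, 4.43e-8), c(4, 8), params = p,
                      rad = res)
  expect_true(all(g2$efficacy <= g1$efficacy + 1e-8))
})

test_that("dose needed for 50% efficacy does not increase with phagocytosis", {
  p <- set_params(tt$params, c(phi_mstar = 0))
  doses <- seq(0, 15, by = 2.5)
  d50 <- vapply(c(0, 2e-8, 4.43e-8), function(ph) {
    effs <- vapply(doses, function(d) {
      sch <- if (d > 0)
        treatment_schedule(treatment_event(12, dose = d, A = 10))
      else treatment_schedule()
      treatment_efficacy(set_params(p, c(phi_mstar = ph)), rad_t, sch,
                         params_control = p, use_Mstar = TRUE)
    }, 1)
    i <- which(effs >= 50)
    if (length(i)) doses[min(i)] else Inf
  }, 1)
  expect_true(all(diff(d50) <= 0))
})

test_that("abscopal tumor with zero activation grows like an untreated one", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  sch <- treatment_schedule(treatment_event(12, dose = 8, A = 0))
  absc <- abscopal_predict(p, rad_t, sch, engrafted_volume(1e5), 0:20)
  ctrl <- simulate_tumor(p, rad_t, init = engrafted_volume(1e5),
                         t_grid = 0:20)
  expect_equal(absc$C, ctrl$C, tolerance = 1e-6)
})

test_that("abscopal regression: small tumors are eliminated, large persist longer", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  sch <- treatment_schedule(treatment_event(10, dose = 8, A = 30))  # I > 1
  small <- abscopal_predict(p, rad_t, sch,
                            init_small <- engrafted_volume(1e5), 0:40)
  large <- abscopal_predict(p, rad_t, sch,
                            c(C = 300, E = 0, M = 0, Mstar = 0), 0:40)
  post_s <- small$C[small$day > 10 & small$day < 40]
  expect_true(all(diff(post_s) <= 0))
  expect_equal(small$C[small$day == 40], 0)  # clamped at extinction
  # larger initial burden stays above the smaller one at every shared day
  expect_true(all(large$C[large$day >= 10] >= small$C[small$day >= 10]))
  # a schedule without RT has nothing to share
  expect_error(abscopal_predict(p, rad_t, treatment_schedule(
    treatment_event(5, kind = "injection", bolus = 1))), "RT")
})

test_that("abscopal burden bounds the primary from above (1 - I >= S - I)", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  for (A in c(0, 5, 20)) {
    sch <- treatment_schedule(treatment_event(10, dose = 8, A = A))
    prim <- simulate_tumor(p, rad_t, sch, engrafted_volume(5e5), 0:22)
    absc <- abscopal_predict(p, rad_t, sch, engrafted_volume(5e5), 0:22)
    expect_true(all(absc$C >= prim$C - 1e-8))
  }
})

test_that("level-set extraction returns polylines on the swept grid", {
  p <- set_params(tt$params, c(phi_mstar = 0))
  grid <- efficacy_grid(A_range = seq(0, 30, length.out = 5),
                        phi_range = 4.43e-8,
                        dose_range = seq(0, 15, length.out = 5),
                        params = p, rad = rad_t)
  ls <- efficacy_levels(grid, levels = c(25, 50, 75))
  expect_true(nrow(ls) > 0)
  expect_true(all(ls$level %in% c(25, 50, 75)))
  expect_true(all(ls$dose_Gy >= 0 & ls$dose_Gy <= 15))
})
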