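test_that("cost is zero on noise-free data and quadratic in residuals", {
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "none")
  c0 <- tumor_cost(NULL, ds, tt$params, tt$rad, rtol = 1e-8, atol = 1e-10)
  expect_lt(c0 / sum(ds$arms$wt$summary$mean^2), 1e-10)

  # single observation: cost = squared residual
  arm1 <- dataset_arm("one", engrafted_volume(5e5), treatment_schedule(),
                      data.frame(mouse_id = "m", day = 10, volume_mm3 = 500))
  ds1 <- growth_dataset(list(arm1))
  pred <- simulate_tumor(tt$params, tt$rad, init = engrafted_volume(5e5),
                         t_grid = c(0, 10), obs_mode = "C")$observed_volume[2]
  expect_equal(tumor_cost(NULL, ds1, tt$params, tt$rad,
                          rtol = 1e-8, atol = 1e-10),
               (500 - pred)^2, tolerance = 1e-8)

  # doubling every residual quadruples the cost
  mk <- function(k) {
    days <- seq(6, 20, 2)
    base <- simulate_tumor(tt$params, tt$rad, init = engrafted_volume(5e5),
                           t_grid = c(0, days), obs_mode = "C")
    v <- base$observed_volume[match(days, base$day)] + k * 10
    a <- dataset_arm("a", engrafted_volume(5e5), treatment_schedule(),
                     data.frame(mouse_id = "m", day = days, volume_mm3 = v))
    growth_dataset(list(a))
  }
  expect_equal(tumor_cost(NULL, mk(2), tt$params, tt$rad,
                          rtol = 1e-8, atol = 1e-10),
               4 * tumor_cost(NULL, mk(1), tt$params, tt$rad,
                              rtol = 1e-8, atol = 1e-10),
               tolerance = 1e-8)
})

test_that("empty free set returns the frozen parameters and their cost", {
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "poisson", seed = 3)
  f <- fit_stage(ds, character(0), tt$params, tt$rad)
  expect_length(f$estimates, 0)
  expect_equal(f$params$c1, tt$params$c1)
  expect_equal(f$cost, tumor_cost(NULL, ds, tt$params, tt$rad))
})

test_that("noise-free growth data recover c1 and cmax to within 0.1%", {
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "none")
  f <- fit_stage(ds, c("c1", "cmax"),
                 set_params(tt$params, c(c1 = 0.3, cmax = 1000)),
                 tt$rad, n_starts = 4, seed = 9)
  expect_lt(abs(f$estimates[["c1"]] - 0.7) / 0.7, 1e-3)
  expect_lt(abs(f$estimates[["cmax"]] - 2500) / 2500, 1e-3)
  # cost recorded equals cost recomputed at the estimates
  expect_equal(f$cost,
               tumor_cost(f$estimates, ds,
                          set_params(tt$params, c(c1 = 0.3, cmax = 1000)),
                          tt$rad),
               tolerance = 1e-10)
})

test_that("multistart fitting is deterministic given the seed", {
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "poisson", seed = 21)
  f1 <- fit_stage(ds, c("c1", "cmax"), tt$params, tt$rad, n_starts = 3,
                  seed = 5)
  f2 <- fit_stage(ds, c("c1", "cmax"), tt$params, tt$rad, n_starts = 3,
                  seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$cost, f2$cost)
})

test_that("four-step calibration freezes earlier stages exactly", {
  suite <- four_condition_suite(seed = 31, noise = "none")
  fit <- run_four_step(suite,
                       params = set_params(tt$params,
                                           c(c1 = 0.4, cmax = 1200,
                                             phi_mstar = 1e-9)),
                       rad = radiation_params(alpha = 0.03, beta = 2e-4,
                                              lam = 1, tau = 1),
                       n_starts = 3, seed = 8)
  s <- fit$stages
  # stage 2-4 carry stage-1 values bit-for-bit
  expect_identical(s$treated$params$c1, s$wt$params$c1)
  expect_identical(s$treated$params$cmax, s$wt$params$cmax)
  expect_identical(s$wt_rt$params$c1, s$wt$params$c1)
  expect_identical(s$treated_rt$params$phi_mstar,
                   s$treated$params$phi_mstar)
  expect_identical(fit$rad$alpha, s$wt_rt$rad$alpha)
  # assembled set reproduces the recorded stage-4 cost
  expect_equal(tumor_cost(NULL, suite$treated_rt, fit$params, fit$rad,
                          fit$A_values),
               s$treated_rt$cost, tolerance = 1e-10)
  # missing condition errors by name
  expect_error(run_four_step(suite[c("wt", "treated")], params = tt$params),
               "wt_rt")
})

test_that("activation fitted on data generated without ICD is near zero", {
  spec <- kort_arm_spec(A = 0, label = "A_wtlike")
  ds <- generate_cohort(list(spec), tt$params, tt$rad, noise = "none",
                        use_Mstar = TRUE)
  f <- fit_stage(ds, "A_wtlike", tt$params, tt$rad,
                 A_values = c(A_wtlike = 1), n_starts = 4, seed = 2)
  S8 <- survival_fraction(8, tt$rad)
  expect_lt(icd_value(f$estimates[["A_wtlike"]], S8), 1e-4)
})

test_that("profile likelihood is flat for a parameter with no pathway", {
  # wild-type dataset, M* disabled: phi_mstar cannot affect the likelihood
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "poisson", seed = 13)
  grid <- 4.43e-8 * 10^seq(-1, 1, length.out = 5)
  pl <- profile_likelihood("phi_mstar", grid, ds, free = character(0),
                           params = tt$params, rad = tt$rad)
  expect_identical(attr(pl, "classification"), "flat")
  expect_lt(max(pl$rise), 1e-8)
})

test_that("profile likelihood is curved for the growth rate on rich data", {
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "poisson", seed = 17)
  pl <- profile_likelihood("c1", seq(0.5, 0.95, length.out = 7), ds,
                           free = "cmax", params = tt$params, rad = tt$rad,
                           n_starts = 2, seed = 4)
  expect_identical(attr(pl, "classification"), "curved")
  # profile minimum is interior and close to the truth
  expect_equal(pl$value[which.min(pl$cost)], 0.725, tolerance = 0.11)
  # rises on both sides of the minimum
  i <- which.min(pl$cost)
  expect_gt(max(pl$rise[seq_len(i - 1)]), attr(pl, "threshold"))
  expect_gt(max(pl$rise[seq(i + 1, nrow(pl))]), attr(pl, "threshold"))
})
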