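p_ce <- model_params(c1 = 0.5, cmax = 1000, phi_e = 0.01,
                     gamma_e = 1, eta_e = 0.001, delta_e = 0.1)

test_that("CE right-hand side matches hand arithmetic", {
  d <- ce_rhs(c(C = 100, E = 2), p_ce)
  expect_equal(unname(d["C"]), 43.0)   # 0.5*100*0.9 - 0.01*100*2
  expect_equal(unname(d["E"]), 0.6)    # 1 - 0.001*100*2 - 0.1*2
  # extinct tumor stays extinct; logistic equilibrium
  expect_equal(unname(ce_rhs(c(C = 0, E = 5), p_ce)["C"]), 0)
  expect_equal(unname(ce_rhs(c(C = 1000, E = 0), p_ce)["C"]), 0)
  expect_error(ce_rhs(c(C = NaN, E = 1), p_ce), "finite")
  expect_error(ce_rhs(c(C = 1, E = 1), p_ce, rt_factor = Inf), "finite")
})

test_that("CEM reduces to CE and adds phagocytosis terms", {
  pm <- set_params(p_ce, c(phi_mstar = 4.43e-8, gamma_mstar = 2,
                           eta_mstar = 1e-3, delta_mstar = 0.2))
  st <- c(C = 100, E = 2, M = 0, Mstar = 0)
  expect_equal(cem_rhs(st, pm)[c("C", "E")], ce_rhs(st, pm))
  # phagocytosis term enters dC/dt linearly
  st2 <- c(C = 100, E = 2, M = 0, Mstar = 5)
  expect_equal(unname(cem_rhs(st2, pm)["C"] - cem_rhs(st, pm)["C"]),
               -4.43e-8 * 100 * 5, tolerance = 1e-9)
  # no tumor: macrophage dynamics lose the exhaustion term
  d0 <- cem_rhs(c(C = 0, E = 0, M = 0, Mstar = 10), pm)
  expect_equal(unname(d0["Mstar"]), 2 - 0.2 * 10)
})

test_that("observed volume sums enabled compartments", {
  expect_equal(observed_volume(c(C = 100, E = 0)), 100)
  expect_equal(observed_volume(c(C = 0, E = 0, M = 0, Mstar = 0)), 0)
  expect_equal(observed_volume(c(C = 100, E = 20, Mstar = 5)), 125)
  expect_equal(observed_volume(c(C = 100, E = 20, Mstar = 5), mode = "C"), 100)
})

test_that("integration matches the closed-form logistic solution", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  tr <- simulate_tumor(p, init = engrafted_volume(5e5), t_grid = 0:22)
  ref <- logistic_solution(tr$day, 0.5, 0.6, 1500)
  expect_lt(max(abs(tr$C - ref) / ref), 1e-6)
  # engraftment conversion: 5e5 cells at 1e6 cells/mm^3
  expect_equal(tr$C[1], 0.5)
})

test_that("zero-dose RT event leaves the trajectory unchanged", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  rad <- radiation_params()
  base <- simulate_tumor(p, rad, init = engrafted_volume(5e5), t_grid = 0:20)
  ev <- treatment_schedule(treatment_event(10, dose = 0, A = 5))
  with_ev <- simulate_tumor(p, rad, ev, engrafted_volume(5e5), t_grid = 0:20)
  expect_equal(with_ev$C, base$C, tolerance = 1e-6)
  applied <- attr(with_ev, "events_applied")[[1]]
  expect_equal(applied$S, 1)
  expect_equal(applied$I, 0)
  expect_equal(applied$F, 1)
})

test_that("an event with I > 1 drives sustained regression", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  rad <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1)
  sch <- treatment_schedule(treatment_event(12, dose = 8, A = 40))
  tr <- simulate_tumor(p, rad, sch, engrafted_volume(5e5), t_grid = 0:22)
  post <- tr$C[tr$day >= 12]
  expect_true(all(diff(post) < 0))
  expect_lt(attr(tr, "events_applied")[[1]]$F, 0)
})

test_that("all-zero initial state stays identically zero", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  sch <- treatment_schedule(treatment_event(10, dose = 8, A = 5))
  tr <- simulate_tumor(p, radiation_params(), sch,
                       init = c(C = 0, E = 0, M = 0, Mstar = 0),
                       t_grid = 0:20, use_E = FALSE)
  expect_true(all(as.matrix(tr[, c("C", "E", "M", "Mstar")]) == 0))
})

test_that("compartments stay nonnegative across random parameter draws", {
  set.seed(42)
  rad <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1)
  for (i in 1:15) {
    p <- model_params(c1 = runif(1, 0.2, 1), cmax = runif(1, 500, 3000),
                      phi_e = runif(1, 0, 0.05), gamma_e = runif(1, 0, 3),
                      eta_e = runif(1, 0, 0.01), delta_e = runif(1, 0.01, 0.5),
                      phi_mstar = runif(1, 0, 1e-7),
                      gamma_mstar = runif(1, 0, 2e6),
                      eta_mstar = runif(1, 0, 0.02),
                      delta_mstar = runif(1, 0.05, 0.5))
    sch <- treatment_schedule(
      treatment_event(sample(6:14, 1), dose = sample(c(4, 8, 15), 1),
                      A = runif(1, 0, 35)))
    tr <- simulate_tumor(p, rad, sch, engrafted_volume(5e5), t_grid = 0:20,
                         use_Mstar = TRUE)
    expect_true(all(as.matrix(tr[, c("C", "E", "M", "Mstar")]) >= 0))
  }
})

test_that("halving solver tolerances barely changes the solution", {
  p <- model_params(c1 = 0.7, cmax = 2500, phi_e = 0.01, gamma_e = 1,
                    eta_e = 1e-3, delta_e = 0.1)
  rad <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1)
  sch <- treatment_schedule(treatment_event(12, dose = 8, A = 15))
  a <- simulate_tumor(p, rad, sch, engrafted_volume(5e5), t_grid = 0:22,
                      rtol = 1e-8, atol = 1e-10)
  b <- simulate_tumor(p, rad, sch, engrafted_volume(5e5), t_grid = 0:22,
                      rtol = 5e-9, atol = 5e-11)
  rel <- abs(a$observed_volume[-1] - b$observed_volume[-1]) /
    pmax(b$observed_volume[-1], 1e-9)
  expect_lt(max(rel), 1e-4)
})

test_that("jump mode removes the non-surviving fraction at the event", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  rad <- radiation_params(alpha = 0.1, beta = 1e-3, lam = 1, tau = 1)
  sch <- treatment_schedule(treatment_event(10, dose = 8, A = 0))
  tr <- simulate_tumor(p, rad, sch, engrafted_volume(5e5),
                       t_grid = c(0, 9.999, 10, 20), rt_mode = "jump")
  S <- survival_fraction(8, rad)
  pre <- tr$C[tr$day == 9.999]
  at <- tr$C[tr$day == 10]
  # C drops by about the survival fraction across the event
  expect_equal(at / pre, S, tolerance = 0.01)
  # A = 0 so post-event factor is 1: growth resumes
  expect_gt(tr$C[tr$day == 20], at)
})

test_that("abscopal factor 1 - I flips the sign of a growing derivative", {
  p <- model_params(c1 = 0.6, cmax = 1500)
  rad <- radiation_params(alpha = 0.01, beta = 1e-4, lam = 1, tau = 1)
  ev <- treatment_event(10, dose = 8, A = 20, target = "abscopal")
  tr <- simulate_tumor(p, rad, treatment_schedule(ev),
                       engrafted_volume(5e5), t_grid = 0:20)
  expect_true(all(diff(tr$C[tr$day >= 10]) < 0))
})

test_that("simulation rejects invalid inputs", {
  p <- model_params()
  expect_error(simulate_tumor(p, t_grid = c(0, 2, 1)), "increasing")
  expect_error(simulate_tumor(p, init = c(C = -1, E = 0, M = 0, Mstar = 0)),
               "nonnegative")
  expect_error(treatment_event(5, bolus = -1), "nonnegative")
})

test_that("macrophage injection raises M* by the bolus", {
  p <- model_params(c1 = 0.6, cmax = 1500, gamma_mstar = 0,
                    delta_mstar = 0.2)
  sch <- treatment_schedule(treatment_event(5, kind = "injection", bolus = 10))
  tr <- simulate_tumor(p, radiation_params(), sch, engrafted_volume(5e5),
                       t_grid = 0:10, use_Mstar = TRUE)
  expect_equal(tr$Mstar[tr$day == 5], 10, tolerance = 1e-6)
  expect_lt(tr$Mstar[tr$day == 10], 10)  # cleared at delta_mstar
  expect_equal(tr$Mstar[tr$day == 4], 0)
})
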