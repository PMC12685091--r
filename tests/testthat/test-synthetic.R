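test_that("noise-free cohorts equal model predictions exactly", {
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "none")
  arm <- ds$arms$wt
  pred <- simulate_tumor(tt$params, tt$rad, init = engrafted_volume(5e5),
                         t_grid = c(0, arm$summary$day),
                         obs_mode = "C")
  expect_equal(arm$summary$mean,
               pred$observed_volume[match(arm$summary$day, pred$day)])
})

test_that("cohort generation is deterministic in the seed", {
  d1 <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad, seed = 4)
  d2 <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad, seed = 4)
  d3 <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad, seed = 5)
  expect_identical(d1$arms$wt$observations, d2$arms$wt$observations)
  expect_false(identical(d1$arms$wt$observations, d3$arms$wt$observations))
  # different seeds share the underlying means
  expect_equal(mean(d1$arms$wt$summary$mean), mean(d3$arms$wt$summary$mean),
               tolerance = 0.1)
})

test_that("across-mouse means track the Poisson center", {
  # predicted volume at day 12 is a few hundred mm^3; with 50 mice the
  # mean should sit within 3 standard errors of the prediction
  for (seed in 1:5) {
    ds <- generate_cohort(list(list(arm_id = "a", cells = 5e5,
                                    days = 12, n_mice = 50)),
                          tt$params, tt$rad, seed = seed)
    pred <- simulate_tumor(tt$params, tt$rad, init = engrafted_volume(5e5),
                           t_grid = c(0, 12), obs_mode = "C")$observed_volume[2]
    m <- ds$arms$a$summary$mean
    expect_lt(abs(m - pred), 3 * sqrt(pred / 50))
  }
})

test_that("generated volumes are Poisson-dispersed (variance ~ mean)", {
  ds <- generate_cohort(list(list(arm_id = "a", cells = 5e5, days = c(10, 14),
                                  n_mice = 200)),
                        tt$params, tt$rad, seed = 6)
  obs <- ds$arms$a$observations
  for (d in c(10, 14)) {
    v <- obs$volume_mm3[obs$day == d]
    expect_gt(var(v) / mean(v), 0.75)
    expect_lt(var(v) / mean(v), 1.35)
  }
})

test_that("four-condition suite has the expected structure", {
  suite <- four_condition_suite(seed = 2, noise = "none")
  expect_setequal(names(suite),
                  c("wt", "treated", "wt_rt", "treated_rt", "truth"))
  expect_length(suite$wt_rt$arms, 9)      # 3 doses x 3 treatment days
  expect_length(suite$treated_rt$arms, 9)
  expect_false(suite$wt$use_Mstar)
  expect_true(suite$treated$use_Mstar)
})

test_that("RT arms depart from control only after their treatment day", {
  suite <- four_condition_suite(seed = 2, noise = "none")
  wt <- suite$wt$arms$wt_5e5$summary
  rt <- suite$wt_rt$arms$wtrt_d12_8Gy$summary
  pre <- wt$day <= 12   # derivative scaling leaves the RT-day value itself
  expect_equal(rt$mean[pre], wt$mean[pre], tolerance = 1e-6)
  expect_true(all(rt$mean[!pre] < wt$mean[!pre]))
  # WT + RT keeps growing (F = S > 0) while high-ICD treated arms regress
  expect_true(all(diff(rt$mean[!pre]) > 0))
  ko <- suite$treated_rt$arms$kort_d8_8Gy$summary   # I > 1 for this arm
  post <- ko$day >= 8
  expect_true(all(diff(ko$mean[post]) < 0))
})

test_that("write-read round trip reproduces the fit bit-for-bit", {
  ds <- generate_cohort(list(wt_arm_spec()), tt$params, tt$rad,
                        noise = "poisson", seed = 12)
  path <- tempfile(fileext = ".csv")
  write_growth_csv(ds, path, note = "seed 12")
  back <- read_growth_csv(path,
                          inits = list(wt = engrafted_volume(5e5)))
  expect_equal(back$arms$wt$summary, ds$arms$wt$summary)
  f1 <- fit_stage(ds, "c1", tt$params, tt$rad, n_starts = 2, seed = 3)
  f2 <- fit_stage(back, "c1", tt$params, tt$rad, n_starts = 2, seed = 3)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$cost, f2$cost)
})
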