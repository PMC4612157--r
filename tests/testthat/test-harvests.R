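ref_list <- function() list(LT = small_reference_sim())

test_that("zero-noise harvests equal the k-scaled simulation exactly", {
  ref <- ref_list()
  days <- c(20L, 28L, 36L, 44L)
  iv <- data.frame(from = c(21, 29, 37), to = c(28, 36, 44))
  kt <- data.frame(regime = "LT", salinity = 0, from = iv$from, to = iv$to,
                   k = c(1, 1, 1))
  gt <- ground_truth(k_table = kt, noise_cv = 0)
  h <- generate_harvests(gt, list(treatment("LT", 0)), ref,
                         harvest_days = days, n_reps = 2, seed = 1)
  w_ref <- small_reference_sim()$w_sh[match(days, small_reference_sim()$dafla)]
  expect_equal(h$shoot_mass, rep(w_ref, each = 2), tolerance = 1e-12)
  # k = 0.5 everywhere halves every inter-harvest increment
  kt2 <- kt; kt2$k <- 0.5
  # schedule must cover the full horizon for exact halving
  kt2 <- rbind(data.frame(regime = "LT", salinity = 0, from = 1, to = 20,
                          k = 0.5), kt2)
  gt2 <- ground_truth(k_table = kt2, noise_cv = 0)
  h2 <- generate_harvests(gt2, list(treatment("LT", 0)), ref,
                          harvest_days = days, n_reps = 1, seed = 1)
  w0 <- attr(small_reference_sim(), "initial_mass") * 0.87
  expect_equal(diff(c(w0, h2$shoot_mass)), diff(c(w0, w_ref)) / 2,
               tolerance = 1e-10)
})

test_that("zero-noise harvests lie exactly on the allometric line", {
  ref <- ref_list()
  kt <- data.frame(regime = "LT", salinity = 0, from = 21, to = 44, k = 0.9)
  gt <- ground_truth(k_table = kt,
                     allometry = list(LT = list(p = 0.62, q = 6.15)),
                     noise_cv = 0)
  h <- generate_harvests(gt, list(treatment("LT", 0)), ref,
                         harvest_days = c(28L, 36L, 44L), n_reps = 3,
                         seed = 2)
  expect_equal(log(h$leaf_area), 0.62 * log(h$shoot_mass) + 6.15,
               tolerance = 1e-10)
})

test_that("higher ground-truth salinity stress lowers every harvest mass", {
  ref <- list(LT = small_reference_sim())
  iv <- data.frame(from = 21, to = 44)
  mk <- function(x, k) data.frame(regime = "LT", salinity = x,
                                  from = iv$from, to = iv$to, k = k)
  gt <- ground_truth(k_table = rbind(mk(0, 1), mk(40, 0.8), mk(80, 0.55)),
                     noise_cv = 0)
  trs <- list(treatment("LT", 0), treatment("LT", 40), treatment("LT", 80))
  h <- generate_harvests(gt, trs, ref, harvest_days = c(28L, 36L, 44L),
                         n_reps = 1, seed = 3)
  w <- matrix(h$shoot_mass[order(h$salinity, h$dafla)], nrow = 3)
  expect_true(all(w[, 1] > w[, 2]))
  expect_true(all(w[, 2] > w[, 3]))
})

test_that("generation is seed-reproducible and validates harvest days", {
  ref <- ref_list()
  gt <- ground_truth(k_table = data.frame(regime = "LT", salinity = 0,
                                          from = 21, to = 44, k = 1))
  a <- generate_harvests(gt, list(treatment("LT", 0)), ref,
                         harvest_days = c(28L, 36L), seed = 7)
  b <- generate_harvests(gt, list(treatment("LT", 0)), ref,
                         harvest_days = c(28L, 36L), seed = 7)
  expect_identical(a, b)
  expect_error(generate_harvests(gt, list(treatment("LT", 0)), ref,
                                 harvest_days = c(28L, 99L)),
               "outside the simulated horizon")
})

test_that("noisy harvests recover the ground-truth allometry within CI", {
  ref <- ref_list()
  kt <- data.frame(regime = "LT", salinity = 0, from = 21, to = 44, k = 1)
  gt <- ground_truth(k_table = kt,
                     allometry = list(LT = list(p = 0.62, q = 6.15)),
                     noise_cv = 0.05)
  h <- generate_harvests(gt, list(treatment("LT", 0)), ref,
                         harvest_days = c(20L, 28L, 32L, 36L, 40L, 44L),
                         n_reps = 4, seed = 3)
  fit <- fit_allometry(h)$LT.nonstress
  expect_lt(abs(fit$p - 0.62), 1.96 * fit$p_se)
  expect_lt(abs(fit$q - 6.15), 1.96 * fit$q_se)
})

test_that("harvest CSV round-trips", {
  ref <- ref_list()
  gt <- ground_truth(k_table = data.frame(regime = "LT", salinity = 0,
                                          from = 21, to = 44, k = 1))
  h <- generate_harvests(gt, list(treatment("LT", 0)), ref,
                         harvest_days = c(28L, 36L), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_harvest_csv(h, path)
  back <- read_harvest_csv(path)
  expect_equal(back$shoot_mass, h$shoot_mass, tolerance = 1e-10)
  expect_equal(back$leaf_area, h$leaf_area, tolerance = 1e-10)
})
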