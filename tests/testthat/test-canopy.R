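run_canopy <- function(n_days, salinity = 0, params = small_params(),
                       regime = "LT", seed = 1, n_plants = 4,
                       salinity_start = 21) {
  cl <- small_climate(regime, max(n_days, 45))
  tr <- treatment(regime, salinity, salinity_start)
  can <- init_canopy(params, seed = seed, n_plants = n_plants)
  for (d in seq_len(n_days)) can <- step_day(can, cl[d, ], tr, params)
  can
}

test_that("canopy initialises on the grid with seeded azimuths", {
  p <- growth_params()
  can <- init_canopy(p, seed = 0, n_plants = 16)
  expect_equal(nrow(can$positions), 16)
  expect_setequal(unique(can$positions[, 1]), 0:3)
  expect_setequal(unique(can$positions[, 2]), 0:3)
  expect_equal(leaf_number(can), 1)
  can2 <- init_canopy(p, seed = 5, n_plants = 16)
  can3 <- init_canopy(p, seed = 5, n_plants = 16)
  expect_identical(can2, can3)
})

test_that("zero jitter gives exact phyllotaxis increments", {
  can <- run_canopy(40, params = small_params())
  az <- can$azimuth
  inc <- (diff(az) %% 360)
  expect_true(all(abs(inc - 144) < 1e-9))
})

test_that("jittered azimuth increments centre on the phyllotaxis angle", {
  p <- growth_params(phyllotaxis_jitter_deg = 10)
  can <- run_canopy(45, params = p, n_plants = 16)
  inc <- (diff(can$azimuth) %% 360)
  n <- length(inc)
  # circular mean within jitter/sqrt(n) of 144 (jitter sd = 10/sqrt(3))
  expect_lt(abs(mean(inc) - 144), 4 * 10 / sqrt(3) / sqrt(n))
  expect_true(all(inc >= 134 - 1e-9 & inc <= 154 + 1e-9))
})

test_that("step_day enforces the climate sequence", {
  p <- small_params()
  can <- init_canopy(p, 1, 4)
  cl <- small_climate()
  expect_error(step_day(can, cl[3, ], treatment("LT", 0), p), "climate gap")
})

test_that("salinity acts only after application and reduces leaf area", {
  before0 <- run_canopy(20, salinity = 0)
  before80 <- run_canopy(20, salinity = 80)
  expect_identical(before0, before80)
  a0 <- run_canopy(45, salinity = 0)
  a40 <- run_canopy(45, salinity = 40)
  a80 <- run_canopy(45, salinity = 80)
  p <- small_params()
  expect_gt(total_leaf_area(a0, p), total_leaf_area(a40, p))
  expect_gt(total_leaf_area(a40, p), total_leaf_area(a80, p))
  # internode lengths are unaffected by salinity
  expect_equal(a0$int_len, a80$int_len)
  expect_equal(plant_height(a0), plant_height(a80))
})

test_that("growth is monotone and saturates at potential sizes", {
  p <- small_params()
  cl <- small_climate()
  tr <- treatment("LT", 0)
  can <- init_canopy(p, 1, 4)
  prev_len <- can$leaf_len
  prev_area <- 0
  for (d in 1:45) {
    can <- step_day(can, cl[d, ], tr, p)
    len <- can$leaf_len[seq_along(prev_len)]
    expect_true(all(len >= prev_len - 1e-12))
    area <- total_leaf_area(can, p)
    expect_gte(area, prev_area - 1e-12)
    prev_len <- can$leaf_len
    prev_area <- area
  }
  expect_true(all(can$leaf_len <= p$l_max + 1e-12))
  expect_true(all(can$int_len <= p$i_max + 1e-12))
  expect_equal(plant_height(can), sum(can$int_len))
})

test_that("final leaf number under LT control falls in the target band", {
  cl <- full_climate("LT")
  p <- growth_params()
  tr <- treatment("LT", 0)
  can <- init_canopy(p, 1, 4)
  for (d in 1:80) can <- step_day(can, cl[d, ], tr, p)
  expect_gte(leaf_number(can), 25)
  expect_lte(leaf_number(can), 35)
})

test_that("mesh geometry is consistent with area bookkeeping", {
  p <- small_params()
  can <- run_canopy(45)
  mesh <- to_mesh(can, p)
  # every leaflet contributes exactly 2 triangles
  expect_equal(unname(table(mesh$surface_id[mesh$material == "leaf"])),
               rep(2L, nrow(mesh$surfaces)), ignore_attr = TRUE)
  areas <- mesh_triangle_areas(mesh)
  expect_true(all(areas > 0))
  leaf_area_mesh <- sum(areas[mesh$material == "leaf"])
  n_plants <- nrow(can$positions)
  expect_equal(leaf_area_mesh * 1e4 / n_plants, total_leaf_area(can, p),
               tolerance = 1e-9)
  # per-surface bookkeeping matches triangle geometry too
  tri_by_surf <- tapply(areas[mesh$material == "leaf"],
                        mesh$surface_id[mesh$material == "leaf"], sum)
  expect_equal(as.numeric(tri_by_surf[as.character(mesh$surfaces$surface_id)]),
               mesh$surfaces$area_m2, tolerance = 1e-9)
})

test_that("single-leaf blade area equals the sum of rhombus areas", {
  p <- growth_params()
  lt <- saltcanopy:::leaf_triangles(30, 0, c(0, 0, 0), p)
  expect_equal(sum(lt$area_cm2), p$blade_area_coef * 30^2, tolerance = 1e-12)
  expect_equal(nrow(lt$tri), 14)
})

test_that("empty canopy produces an empty mesh with zero area", {
  p <- growth_params()
  can <- init_canopy(p, 1, 4)
  can$leaf_len <- 0
  mesh <- to_mesh(can, p, include_ground = FALSE)
  expect_equal(nrow(mesh$tri), 0)
  expect_equal(total_leaf_area(can, p), 0)
})

test_that("OBJ export writes the expected counts", {
  p <- small_params()
  can <- run_canopy(30)
  mesh <- to_mesh(can, p)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(mesh, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), 3 * nrow(mesh$tri))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$tri))
})
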