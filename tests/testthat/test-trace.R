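test_that("single horizontal leaflet absorbs the side-specific fraction", {
  mesh <- flat_leaf_mesh(1, 1)
  map <- trace_scene(mesh, vertical_beam(), n_rays = 5000, seed = 1)
  intercepted <- map$incident - map$escaped_primary
  expect_equal(intercepted, map$incident, tolerance = 1e-12)
  # adaxial: 1 - 0.073 - 0.024
  expect_equal(map$per_surface$frac, 0.903, tolerance = 1e-12)
  # flipped leaf exposes the abaxial side: 1 - 0.127 - 0.025
  flipped <- mesh
  flipped$tri <- flipped$tri[, c(1:3, 7:9, 4:6)]
  map2 <- trace_scene(flipped, vertical_beam(), n_rays = 5000, seed = 1)
  expect_equal(map2$per_surface$frac, 0.848, tolerance = 1e-12)
})

test_that("empty canopy transmits fully and the ground absorbs 20%", {
  mesh <- flat_leaf_mesh(1, 1, ground = c(0, 2, 0, 2))
  mesh$tri <- mesh$tri[3:4, , drop = FALSE]  # keep only the ground
  mesh$surface_id <- mesh$surface_id[3:4]
  mesh$material <- mesh$material[3:4]
  mesh$surfaces <- mesh$surfaces[0, ]
  sky <- build_sky(52.38, 9.62, 120)
  attr(sky, "flux") <- 1
  map <- trace_scene(mesh, sky, n_rays = 2000, seed = 2)
  expect_equal(canopy_transmittance(map), 1.0, tolerance = 1e-12)
  expect_equal(map$ground_absorbed / map$incident, 0.2, tolerance = 1e-12)
  expect_equal(map$escaped / map$incident, 0.8, tolerance = 1e-12)
})

test_that("energy accounting closes exactly", {
  scene <- random_leaf_scene(60, seed = 3)
  map <- trace_scene(scene, vertical_beam(), n_rays = 2e4, seed = 4)
  expect_lt(energy_residual(map), 1e-9)
  sky <- build_sky(52.38, 9.62, 140, diffuse_fraction = 0.7)
  map2 <- trace_scene(scene, sky, n_rays = 2e4, seed = 5)
  expect_lt(energy_residual(map2), 1e-9)
})

test_that("tracing is deterministic for a fixed seed", {
  scene <- random_leaf_scene(30, seed = 6)
  sky <- build_sky(52.38, 9.62, 120)
  a <- trace_scene(scene, sky, n_rays = 5000, seed = 9)
  b <- trace_scene(scene, sky, n_rays = 5000, seed = 9)
  expect_identical(a$per_surface$frac, b$per_surface$frac)
  expect_identical(a$transmittance, b$transmittance)
  c <- trace_scene(scene, sky, n_rays = 5000, seed = 10)
  expect_false(identical(a$transmittance, c$transmittance))
})

test_that("two parallel layers match the truncated multiple-reflection
           series", {
  # 1D flux bookkeeping oracle, independent of the tracer: propagate
  # packets between the two layers for the same number of scattering
  # events as the tracer allows.
  ad_r <- 0.073; ad_t <- 0.024; ab_r <- 0.127; ab_t <- 0.025
  oracle <- function(max_depth) {
    abs1 <- 0; abs2 <- 0; esc <- 0
    # packets: list of (location, direction, weight); start above layer 1
    pk <- list(c(1, -1, 1)) # at layer 1, moving down, weight 1
    for (depth in 0:max_depth) {
      nxt <- list()
      for (p in pk) {
        layer <- p[1]; dir <- p[2]; w <- p[3]
        if (layer == 1 && dir == -1) {        # hits layer 1 adaxial
          abs1 <- abs1 + w * (1 - ad_r - ad_t)
          if (depth < max_depth) {
            nxt <- c(nxt, list(c(0, 1, w * ad_r)),   # reflected up, escapes
                     list(c(2, -1, w * ad_t)))       # transmitted to layer 2
          }
        } else if (layer == 2 && dir == -1) { # hits layer 2 adaxial
          abs2 <- abs2 + w * (1 - ad_r - ad_t)
          if (depth < max_depth) {
            nxt <- c(nxt, list(c(1, 1, w * ad_r)),   # up to layer 1 abaxial
                     list(c(0, -1, w * ad_t)))       # down, escapes
          }
        } else if (layer == 1 && dir == 1) {  # hits layer 1 abaxial
          abs1 <- abs1 + w * (1 - ab_r - ab_t)
          if (depth < max_depth) {
            nxt <- c(nxt, list(c(2, -1, w * ab_r)),  # back down to layer 2
                     list(c(0, 1, w * ab_t)))        # through, escapes
          }
        } else {
          esc <- esc + w
        }
      }
      pk <- Filter(function(p) p[3] > 1e-16, nxt)
      if (!length(pk)) break
    }
    c(abs1 = abs1, abs2 = abs2)
  }
  expected <- oracle(10)

  make_scene <- function() {
    top <- flat_leaf_mesh(24, 1.0)
    bot <- flat_leaf_mesh(24, 0.5)
    tri <- rbind(top$tri, bot$tri)
    structure(list(tri = tri, surface_id = c(1L, 1L, 2L, 2L),
                   material = rep("leaf", 4),
                   surfaces = data.frame(surface_id = 1:2, plant = 1L,
                                         rank = 1:2, leaflet = 1L,
                                         area_m2 = 24^2),
                   ground = c(xmin = -0.5, xmax = 0.5, ymin = -0.5,
                              ymax = 0.5)),  # launch window only
              class = "canopy_mesh")
  }
  scene <- make_scene()
  runs <- sapply(1:4, function(s) {
    m <- trace_scene(scene, vertical_beam(), n_rays = 8000, seed = 100 + s)
    m$per_surface$frac
  })
  means <- rowMeans(runs)
  se <- apply(runs, 1, sd) / sqrt(ncol(runs))
  for (i in 1:2) {
    expect_lt(abs(means[i] - expected[i]), 3 * se[i] + 2e-3)
  }
})

test_that("transmittance follows Beer-Lambert across leaf area index", {
  plot_area <- 16
  lai_grid <- c(0.5, 1, 1.5, 2, 2.5, 3)
  trans <- sapply(lai_grid, function(lai) {
    n <- round(lai * plot_area / 0.25)
    scene <- random_leaf_scene(n, seed = 20 + round(10 * lai))
    trace_scene(scene, vertical_beam(), n_rays = 2e4,
                seed = 30 + round(10 * lai))$transmittance
  })
  expect_true(all(diff(trans) < 0))  # monotone decreasing in LAI
  fit <- lm(log(trans) ~ lai_grid)
  expect_gt(summary(fit)$r.squared, 0.98)
})

test_that("estimates at doubled ray counts agree within Monte Carlo error", {
  scene <- random_leaf_scene(80, seed = 40)
  sky <- build_sky(52.38, 9.62, 130)
  t1 <- trace_scene(scene, sky, n_rays = 1e4, seed = 1)$transmittance
  t2 <- trace_scene(scene, sky, n_rays = 2e4, seed = 2)$transmittance
  se <- sqrt(t1 * (1 - t1) / 1e4 + t2 * (1 - t2) / 2e4)
  expect_lt(abs(t1 - t2), 4 * se)
})

test_that("trace input validation", {
  mesh <- flat_leaf_mesh(1, 1)
  expect_error(trace_scene(mesh, vertical_beam(), n_rays = 0), "n_rays")
  map <- trace_scene(mesh, vertical_beam(), n_rays = 100, seed = 1)
  expect_error(canopy_transmittance(map), "no ground")
})
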