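# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small canopy scenario for unit tests: 4 plants, 45 days, few rays
small_params <- function(...) growth_params(phyllotaxis_jitter_deg = 0, ...)

small_climate <- function(regime = "LT", n_days = 45, seed = 11) {
  cached(paste0("climate.", regime, ".", n_days, ".", seed),
         function() generate_climate(n_days, regime, seed = seed))
}

small_reference_sim <- function() {
  cached("small_ref_sim", function()
    simulate_canopy(small_params(), small_climate(), treatment("LT", 0),
                    n_rays = 800, seed = 3, n_plants = 4))
}

# 80-day LT reference simulation shared by recovery/closure tests
lt_reference_sim <- function() {
  cached("lt_ref_sim", function()
    simulate_canopy(growth_params(), full_climate("LT"), treatment("LT", 0),
                    n_rays = 2000, seed = 7))
}

full_climate <- function(regime) {
  cached(paste0("full_climate.", regime),
         function() generate_climate(80, regime, seed = 42))
}

# single horizontal square leaf (two triangles, one surface) of side s at
# height z, centred on (cx, cy); ground optional
flat_leaf_mesh <- function(s = 1, z = 1, cx = 0, cy = 0, ground = NULL) {
  h <- s / 2
  v <- rbind(c(cx - h, cy - h, z), c(cx + h, cy - h, z),
             c(cx + h, cy + h, z), c(cx - h, cy + h, z))
  tri <- rbind(as.vector(t(v[c(1, 2, 3), ])), as.vector(t(v[c(1, 3, 4), ])))
  surface_id <- c(1L, 1L)
  material <- c("leaf", "leaf")
  surfaces <- data.frame(surface_id = 1L, plant = 1L, rank = 1L,
                         leaflet = 1L, area_m2 = s^2)
  if (!is.null(ground)) {
    g <- ground
    tri <- rbind(tri,
                 c(g[1], g[3], 0, g[2], g[3], 0, g[2], g[4], 0),
                 c(g[1], g[3], 0, g[2], g[4], 0, g[1], g[4], 0))
    surface_id <- c(surface_id, 2L, 2L)
    material <- c(material, "ground", "ground")
  }
  structure(list(tri = tri, surface_id = surface_id, material = material,
                 surfaces = surfaces,
                 ground = if (!is.null(ground))
                   c(xmin = ground[1], xmax = ground[2],
                     ymin = ground[3], ymax = ground[4]) else NULL),
            class = "canopy_mesh")
}

# scene of n randomly placed horizontal unit leaves over a ground plot
random_leaf_scene <- function(n, plot = 4, zmax = 2, seed = 1,
                              leaf_side = 0.5) {
  set.seed(seed)
  meshes <- lapply(seq_len(n), function(i) {
    cx <- runif(1, 0, plot)
    cy <- runif(1, 0, plot)
    z <- runif(1, 0.2, zmax)
    flat_leaf_mesh(leaf_side, z, cx, cy)
  })
  tri <- do.call(rbind, lapply(meshes, `[[`, "tri"))
  tri <- rbind(tri,
               c(0, 0, 0, plot, 0, 0, plot, plot, 0),
               c(0, 0, 0, plot, plot, 0, 0, plot, 0))
  surface_id <- c(rep(seq_len(n), each = 2), n + 1L, n + 1L)
  material <- c(rep("leaf", 2 * n), "ground", "ground")
  surfaces <- data.frame(surface_id = seq_len(n), plant = 1L,
                         rank = seq_len(n), leaflet = 1L,
                         area_m2 = leaf_side^2)
  structure(list(tri = tri, surface_id = as.integer(surface_id),
                 material = material, surfaces = surfaces,
                 ground = c(xmin = 0, xmax = plot, ymin = 0, ymax = plot)),
            class = "canopy_mesh")
}

vertical_beam <- function(flux = 1) sky_dome(matrix(c(0, 0, -1), 1), 1, flux)
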