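#' Initialise a virtual canopy
#'
#' Creates a grid of single-phytomer plants (default 16 on a 4 x 4 grid at
#' 1 m spacing) above a reflective ground rectangle. Successive leaves on a
#' plant are rotated by the phyllotaxis angle plus a seeded uniform jitter;
#' the jitter is the only stochastic architectural factor, so plants share
#' one deterministic growth state and differ only in leaf azimuths.
#'
#' @param params A [growth_params()] object.
#' @param seed Integer seed for the phyllotaxis jitter.
#' @param n_plants Number of plants (a perfect square).
#' @param spacing Row and plant distance, m.
#' @return An object of class `canopy`.
#' @export
init_canopy <- function(params, seed = 1, n_plants = 16, spacing = 1) {
  side <- sqrt(n_plants)
  if (side != round(side)) stop("n_plants must be a perfect square")
  side <- as.integer(side)
  pos <- as.matrix(expand.grid(x = (seq_len(side) - 1) * spacing,
                               y = (seq_len(side) - 1) * spacing))
  margin <- spacing / 2
  ground <- c(xmin = min(pos[, 1]) - margin, xmax = max(pos[, 1]) + margin,
              ymin = min(pos[, 2]) - margin, ymax = max(pos[, 2]) + margin)
  canopy <- list(
    positions = pos,
    ground = ground,
    dafla = 0L,
    cum_tt = 0,
    n_phytomers = 1L,
    leaf_app_tt = 0,              # thermal time at appearance, per rank
    leaf_len = 0,                 # cm, per rank (shared across plants)
    int_len = 0,                  # cm, per rank
    azimuth = NULL,               # rank x plant matrix, degrees
    jitter_seed = as.integer(seed),
    rng = init_jitter_rng(seed)
  )
  canopy <- add_azimuth_row(canopy, first = TRUE)
  class(canopy) <- "canopy"
  canopy
}

# Dedicated RNG stream for phyllotaxis jitter so canopy growth does not
# perturb (or get perturbed by) the global RNG state.
init_jitter_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  state
}

with_jitter_rng <- function(canopy, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", canopy$rng, globalenv())
  value <- force(expr)
  canopy$rng <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(canopy = canopy, value = value)
}

add_azimuth_row <- function(canopy, first = FALSE, params = NULL) {
  n_plants <- nrow(canopy$positions)
  jit <- params$phyllotaxis_jitter_deg %||% 10
  phy <- params$phyllotaxis_deg %||% 144
  if (first) {
    res <- with_jitter_rng(canopy, stats::runif(n_plants, 0, 360))
    canopy <- res$canopy
    canopy$azimuth <- matrix(res$value, nrow = 1)
  } else {
    res <- with_jitter_rng(canopy, stats::runif(n_plants, -jit, jit))
    canopy <- res$canopy
    prev <- canopy$azimuth[nrow(canopy$azimuth), ]
    canopy$azimuth <- rbind(canopy$azimuth, (prev + phy + res$value) %% 360)
  }
  canopy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance the canopy by one day
#'
#' Accumulates thermal time, initiates new phytomers when the cumulative
#' thermal time crosses the next phyllochron, and elongates every extant
#' leaf and internode according to [organ_elongation()]. Salinity acts only
#' from `treatment$salinity_start` onwards, and only on leaves.
#'
#' @param canopy A `canopy` object.
#' @param climate A single-row climate record for `canopy$dafla + 1`.
#' @param treatment A [treatment()] object.
#' @param params A [growth_params()] object.
#' @return The updated `canopy`.
#' @export
step_day <- function(canopy, climate, treatment, params) {
  if (nrow(as.data.frame(climate)) != 1)
    stop("step_day expects a single climate day")
  if (climate$dafla != canopy$dafla + 1)
    stop("climate gap: expected dafla ", canopy$dafla + 1,
         ", got ", climate$dafla)
  x <- if (climate$dafla >= treatment$salinity_start) treatment$salinity_x else 0

  dtt <- daily_thermal_time(climate, params)
  canopy$cum_tt <- canopy$cum_tt + dtt

  # leaf/phytomer initiation on the thermal-time phyllochron
  while (canopy$cum_tt >= canopy$n_phytomers * params$phyllochron_dd) {
    canopy$n_phytomers <- canopy$n_phytomers + 1L
    canopy$leaf_app_tt <- c(canopy$leaf_app_tt,
                            (canopy$n_phytomers - 1L) * params$phyllochron_dd)
    canopy$leaf_len <- c(canopy$leaf_len, 0)
    canopy$int_len <- c(canopy$int_len, 0)
    canopy <- add_azimuth_row(canopy, params = params)
  }

  age <- pmax(canopy$cum_tt - canopy$leaf_app_tt, 0)
  dl <- organ_elongation("leaf", age, climate, x, params)
  di <- organ_elongation("internode", age, climate, 0, params)
  canopy$leaf_len <- pmin(canopy$leaf_len + dl, params$l_max)
  canopy$int_len <- pmin(canopy$int_len + di, params$i_max)
  canopy$dafla <- as.integer(climate$dafla)
  canopy
}

# Relative leaflet layout of the compound leaf: rachis stations (fraction
# of leaf length) and raw length fractions for 3 pairs + terminal leaflet.
leaflet_layout <- function() {
  list(stations = c(0.35, 0.35, 0.55, 0.55, 0.75, 0.75, 1.00),
       side = c(1, -1, 1, -1, 1, -1, 0),
       frac = c(0.30, 0.30, 0.33, 0.33, 0.35, 0.35, 0.40))
}

# Leaflet dimensions (long diagonal d1, short diagonal d2, cm) for a leaf
# of length L, scaled so the 7 rhombus areas sum exactly to the blade area
# s * L^2.
leaflet_dims <- function(length_cm, params) {
  lay <- leaflet_layout()
  s <- params$blade_area_coef
  asp <- params$leaflet_aspect
  scale <- sqrt(2 * s / (asp * sum(lay$frac^2)))
  d1 <- scale * lay$frac * length_cm
  list(d1 = d1, d2 = asp * d1, stations = lay$stations, side = lay$side)
}

#' Total leaf area of the canopy
#'
#' Blade area of a leaf of length L is `blade_area_coef * L^2`; leaflet
#' rhombus areas sum to it exactly by construction.
#'
#' @param canopy A `canopy` object.
#' @param params A [growth_params()] object.
#' @param per_plant If `TRUE`, return the per-plant vector (cm^2).
#' @return Average total leaf area per plant, cm^2 (or a vector).
#' @export
total_leaf_area <- function(canopy, params, per_plant = FALSE) {
  a <- sum(params$blade_area_coef * canopy$leaf_len^2)
  if (per_plant) rep(a, nrow(canopy$positions)) else a
}

#' Plant height and leaf number
#'
#' Height is the sum of all internode lengths of a plant (cm); leaf number
#' is the number of initiated phytomers.
#'
#' @param canopy A `canopy` object.
#' @return A scalar (identical across plants).
#' @export
plant_height <- function(canopy) sum(canopy$int_len)

#' @rdname plant_height
#' @export
leaf_number <- function(canopy) length(canopy$leaf_len)

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

# Build the 7 leaflet rhombi (each 2 triangles) of one leaf in the
# canonical frame (azimuth 0, base at the origin).
# Returns a list(tri = 14 x 9 matrix in metres, area_cm2 = per-leaflet).
leaf_triangles <- function(length_cm, azimuth_deg = 0,
                           base_point_m = c(0, 0, 0), params) {
  if (length_cm <= 0) return(NULL)
  ld <- leaflet_dims(length_cm, params)
  n_st <- 8
  u <- seq(0, 1, length.out = n_st + 1)
  # rachis polyline: progressive droop from theta_base to theta_base+curv
  theta <- -(params$theta_base_deg + params$curvature_deg * u[-1]) * pi / 180
  seg <- length_cm / 100 / n_st
  dxyz <- cbind(cos(theta), 0, sin(theta)) * seg
  pts <- rbind(c(0, 0, 0), apply(dxyz, 2, cumsum))
  R <- rot_z(azimuth_deg)
  pts <- t(R %*% t(pts))
  pts <- sweep(pts, 2, base_point_m, "+")
  arc <- seq(0, 1, length.out = n_st + 1)

  tris <- matrix(0, nrow = 14, ncol = 9)
  areas <- numeric(7)
  for (i in seq_len(7)) {
    st <- ld$stations[i]
    j <- min(max(1, ceiling(st * n_st)), n_st)
    f <- st * n_st - (j - 1)
    p0 <- pts[j, ] + f * (pts[j + 1, ] - pts[j, ])
    tang <- pts[j + 1, ] - pts[j, ]
    tang <- tang / sqrt(sum(tang^2))
    up <- c(0, 0, 1)
    sidev <- c(tang[2], -tang[1], 0)
    nv <- sqrt(sum(sidev^2))
    if (nv < 1e-12) sidev <- c(1, 0, 0) else sidev <- sidev / nv
    d1 <- ld$d1[i] / 100
    d2 <- ld$d2[i] / 100
    if (ld$side[i] == 0) {
      a1 <- tang
    } else {
      # lateral leaflets leave the rachis at ~55 deg in the leaf plane
      ang <- 55 * pi / 180
      a1 <- cos(ang) * tang + sin(ang) * ld$side[i] * sidev
      a1 <- a1 / sqrt(sum(a1^2))
    }
    a2 <- vcross(a1, vcross(up, a1))
    n2 <- sqrt(sum(a2^2))
    if (n2 < 1e-9) a2 <- sidev else a2 <- a2 / n2
    # rhombus with diagonals d1 (along a1) and d2 (along a2), attached at p0
    tip <- p0 + a1 * d1
    mid <- p0 + a1 * (d1 / 2)
    q1 <- mid + a2 * (d2 / 2)
    q2 <- mid - a2 * (d2 / 2)
    t1 <- orient_up(rbind(p0, q1, tip))
    t2 <- orient_up(rbind(p0, tip, q2))
    tris[2 * i - 1, ] <- as.vector(t(t1))
    tris[2 * i, ] <- as.vector(t(t2))
    areas[i] <- d1 * d2 / 2 * 1e4
  }
  list(tri = tris, area_cm2 = areas)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orient a triangle so its normal points upward (+z); the +normal side is
# the adaxial (upper) leaf surface.
orient_up <- function(v) {
  n <- vcross(v[2, ] - v[1, ], v[3, ] - v[1, ])
  if (n[3] < 0) v[c(1, 3, 2), ] else v
}

#' Triangulate the canopy into a scene mesh
#'
#' Every leaflet contributes two triangles (one rhombus); the ground is two
#' triangles. Surface ids group the two triangles of each leaflet; the
#' mapping table records plant, rank and leaflet per surface.
#'
#' @param canopy A `canopy` object.
#' @param params A [growth_params()] object.
#' @param include_ground Include the ground rectangle (default `TRUE`).
#' @return An object of class `canopy_mesh`: list with `tri` (n x 9 matrix,
#'   metres), `surface_id`, `material` (`"leaf"`/`"ground"`), `surfaces`
#'   (data frame: surface_id, plant, rank, leaflet, area_m2).
#' @export
to_mesh <- function(canopy, params, include_ground = TRUE) {
  heights <- cumsum(canopy$int_len) / 100
  n_plants <- nrow(canopy$positions)
  live <- which(canopy$leaf_len > 0)
  # canonical (azimuth-0, origin-based) geometry once per rank, then
  # rotate/translate per plant — lengths are shared across plants
  canon <- lapply(live, function(rk)
    leaf_triangles(canopy$leaf_len[rk], 0, c(0, 0, 0), params))
  n_leaf <- length(live)
  if (n_leaf > 0) {
    ctri <- do.call(rbind, lapply(canon, `[[`, "tri"))   # (14 n_leaf) x 9
    areas <- unlist(lapply(canon, `[[`, "area_cm2")) / 1e4
    zoff <- rep(heights[live], each = 14)
    blocks <- vector("list", n_plants)
    xi <- c(1, 4, 7); yi <- c(2, 5, 8); zi <- c(3, 6, 9)
    for (pl in seq_len(n_plants)) {
      az <- canopy$azimuth[live, pl] * pi / 180
      ca <- rep(cos(az), each = 14)
      sa <- rep(sin(az), each = 14)
      m <- ctri
      m[, xi] <- ca * ctri[, xi] - sa * ctri[, yi] + canopy$positions[pl, 1]
      m[, yi] <- sa * ctri[, xi] + ca * ctri[, yi] + canopy$positions[pl, 2]
      m[, zi] <- ctri[, zi] + zoff
      blocks[[pl]] <- m
    }
    tri <- do.call(rbind, blocks)
    n_surf_per_plant <- 7L * n_leaf
    surface_id <- rep(seq_len(n_surf_per_plant * n_plants), each = 2)
    surfaces <- data.frame(
      surface_id = seq_len(n_surf_per_plant * n_plants),
      plant = rep(seq_len(n_plants), each = n_surf_per_plant),
      rank = rep(rep(live, each = 7), n_plants),
      leaflet = rep(rep(seq_len(7), n_leaf), n_plants),
      area_m2 = rep(areas, n_plants))
  } else {
    tri <- matrix(0, 0, 9)
    surface_id <- integer(0)
    surfaces <- data.frame(surface_id = integer(0), plant = integer(0),
                           rank = integer(0), leaflet = integer(0),
                           area_m2 = numeric(0))
  }
  material <- rep("leaf", nrow(tri))
  if (include_ground) {
    g <- canopy$ground
    g1 <- c(g["xmin"], g["ymin"], 0, g["xmax"], g["ymin"], 0, g["xmax"], g["ymax"], 0)
    g2 <- c(g["xmin"], g["ymin"], 0, g["xmax"], g["ymax"], 0, g["xmin"], g["ymax"], 0)
    tri <- rbind(tri, g1, g2)
    gid <- if (nrow(surfaces)) max(surfaces$surface_id) + 1L else 1L
    surface_id <- c(surface_id, gid, gid)
    material <- c(material, "ground", "ground")
  }
  rownames(tri) <- NULL
  structure(list(tri = tri, surface_id = as.integer(surface_id),
                 material = material, surfaces = surfaces,
                 ground = canopy$ground, n_plants = n_plants),
            class = "canopy_mesh")
}

#' Triangle areas of a mesh, m^2
#' @param mesh A `canopy_mesh`.
#' @return Numeric vector of per-triangle areas.
#' @export
mesh_triangle_areas <- function(mesh) {
  tri <- mesh$tri
  if (nrow(tri) == 0) return(numeric(0))
  e1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  e2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Export a mesh as Wavefront OBJ
#'
#' Leaf triangles are written under material group `adaxial` (front face)
#' with the ground under `ground`.
#'
#' @param mesh A `canopy_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tri <- mesh$tri
  writeLines("# saltcanopy scene mesh", con)
  for (i in seq_len(nrow(tri))) {
    v <- matrix(tri[i, ], 3, 3, byrow = TRUE)
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  }
  writeLines("g adaxial", con)
  leaf <- which(mesh$material == "leaf")
  if (length(leaf))
    writeLines(sprintf("f %d %d %d", 3 * (leaf - 1) + 1, 3 * (leaf - 1) + 2,
                       3 * (leaf - 1) + 3), con)
  writeLines("g ground", con)
  grd <- which(mesh$material == "ground")
  if (length(grd))
    writeLines(sprintf("f %d %d %d", 3 * (grd - 1) + 1, 3 * (grd - 1) + 2,
                       3 * (grd - 1) + 3), con)
  invisible(path)
}

#' Canopy summary row
#'
#' @param canopy A `canopy` object.
#' @param params A [growth_params()] object.
#' @return One-row data frame: dafla, leaf_number, height_cm, leaf_area_cm2.
#' @export
canopy_summary <- function(canopy, params) {
  data.frame(dafla = canopy$dafla,
             leaf_number = leaf_number(canopy),
             height_cm = plant_height(canopy),
             leaf_area_cm2 = total_leaf_area(canopy, params))
}
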