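#' Configuration for the synthetic liver phantom
#'
#' Defines the study conditions the generator emulates: an annotation
#' protocol reaching to the second branch ramification, a 2 mm minimum
#' vessel diameter (`min_radius = 1` mm), and a labeled blood pool of about
#' 9% of the liver volume. Grids default to 128^3 voxels at 1 mm isotropic
#' spacing; the liver is a smoothly deformed ellipsoid whose shape responds
#' qualitatively to the liver condition (cirrhosis shrinks and roughens it).
#'
#' @param grid_shape Voxel counts per axis.
#' @param spacing mm per voxel along each axis.
#' @param liver_axes Ellipsoid semi-axes in mm.
#' @param lesion_count Number of lesions (placed on the resect side).
#' @param lesion_radius_range Lesion radius range in mm.
#' @param trunk_radii Named trunk radii (mm) for the eight annotated vessels.
#' @param ivc_radius IVC tube radius (mm).
#' @param taper Radius multiplier per branching generation, in (0, 1].
#' @param branch_angle_range Branch take-off angle range, degrees.
#' @param generations Branching depth; 2 = trunk + primary branches +
#'   secondary-origin stubs.
#' @param min_radius Minimum tube radius in mm (2 mm diameter floor).
#' @param blood_fraction_target Fraction of the liver volume occupied by
#'   labeled vessels; must lie in (0, 0.2).
#' @param resect_fractions Named fractions of liver volume removed by each
#'   resection type.
#' @param condition_mix,resection_mix Sampling proportions for cohort
#'   generation (defaults follow a 27/3/2 condition and 10/21/1 resection
#'   split over 32 candidates).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(128, 128, 128),
                           spacing = c(1, 1, 1),
                           liver_axes = c(58, 45, 38),
                           lesion_count = 1,
                           lesion_radius_range = c(12, 25),
                           trunk_radii = c(RHV = 4, MHV = 4, LHV = 4,
                                           SRHV = 2.5, IRHV = 2.5,
                                           MPV = 5.5, RPV = 4, LPV = 4),
                           ivc_radius = 5,
                           taper = 0.6,
                           branch_angle_range = c(30, 60),
                           generations = 2,
                           min_radius = 1.0,
                           blood_fraction_target = 0.09,
                           resect_fractions = c(left = 0.35, right = 0.60,
                                                extended_right = 0.72),
                           condition_mix = c(healthy = 27, fatty = 3,
                                             cirrhosis = 2) / 32,
                           resection_mix = c(left = 10, right = 21,
                                             extended_right = 1) / 32) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
              liver_axes = liver_axes, lesion_count = lesion_count,
              lesion_radius_range = lesion_radius_range,
              trunk_radii = trunk_radii, ivc_radius = ivc_radius,
              taper = taper, branch_angle_range = branch_angle_range,
              generations = generations, min_radius = min_radius,
              blood_fraction_target = blood_fraction_target,
              resect_fractions = resect_fractions,
              condition_mix = condition_mix, resection_mix = resection_mix)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 16))
    stop("grid_shape must be three counts >= 16", call. = FALSE)
  if (any(cfg$spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (cfg$min_radius < 1.0)
    stop("min_radius below 1 mm violates the 2 mm minimum vessel diameter",
         call. = FALSE)
  if (cfg$blood_fraction_target <= 0 || cfg$blood_fraction_target >= 0.2)
    stop("blood_fraction_target must lie in (0, 0.2)", call. = FALSE)
  if (cfg$taper <= 0 || cfg$taper > 1)
    stop("taper must lie in (0, 1]", call. = FALSE)
  if (cfg$generations != 2)
    stop("generations must be 2 (annotation to the second ramification)",
         call. = FALSE)
  bad <- cfg$trunk_radii < cfg$min_radius
  if (any(bad))
    stop("infeasible geometry: trunk radius of ",
         paste(names(cfg$trunk_radii)[bad], collapse = ", "),
         " is smaller than min_radius = ", cfg$min_radius, " mm",
         call. = FALSE)
  invisible(cfg)
}

# Smooth random field on an arbitrary grid: low-resolution Gaussian control
# lattice, trilinearly upsampled. Uses the current RNG stream.
smooth_field <- function(d, n_ctrl = 5) {
  n_ctrl <- max(2L, as.integer(n_ctrl))
  ctrl <- array(stats::rnorm(n_ctrl^3), c(n_ctrl, n_ctrl, n_ctrl))
  axis_u <- function(n) {
    u <- seq(0, 1, length.out = n) * (n_ctrl - 1)
    i0 <- pmin(floor(u), n_ctrl - 2)
    list(i = as.integer(i0) + 1L, w = u - i0)
  }
  gx <- axis_u(d[1]); gy <- axis_u(d[2]); gz <- axis_u(d[3])
  I <- array(gx$i, d); WX <- array(gx$w, d)
  J <- array(rep(gy$i, each = d[1]), d); WY <- array(rep(gy$w, each = d[1]), d)
  K <- array(rep(gz$i, each = d[1] * d[2]), d)
  WZ <- array(rep(gz$w, each = d[1] * d[2]), d)
  at <- function(di, dj, dk) ctrl[cbind(c(I + di), c(J + dj), c(K + dk))]
  v <- at(0L, 0L, 0L) * (1 - WX) * (1 - WY) * (1 - WZ) +
       at(1L, 0L, 0L) * WX * (1 - WY) * (1 - WZ) +
       at(0L, 1L, 0L) * (1 - WX) * WY * (1 - WZ) +
       at(0L, 0L, 1L) * (1 - WX) * (1 - WY) * WZ +
       at(1L, 1L, 0L) * WX * WY * (1 - WZ) +
       at(1L, 0L, 1L) * WX * (1 - WY) * WZ +
       at(0L, 1L, 1L) * (1 - WX) * WY * WZ +
       at(1L, 1L, 1L) * WX * WY * WZ
  array(v, d)
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# A direction at angle `theta` (radians) from unit tangent `t`, with random
# azimuth drawn from the current RNG stream.
rotated_direction <- function(t, theta) {
  t <- normalize3(t)
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize3(pracma_cross(t, ref))
  v <- pracma_cross(t, u)
  phi <- runif(1, 0, 2 * pi)
  normalize3(cos(theta) * t + sin(theta) * (cos(phi) * u + sin(phi) * v))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Nearest-voxel lookup of array `arr` at physical point(s) `p` (rows, mm).
grid_lookup <- function(arr, p, spacing) {
  p <- matrix(p, ncol = 3)
  d <- dim(arr)
  idx <- sweep(round(sweep(p, 2, spacing, "/")), 2, c(1, 1, 1), "+")
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), d[a])
  arr[cbind(idx[, 1], idx[, 2], idx[, 3])]
}

# March a slightly curving polyline from `start` along `direction`, stepping
# `step` mm, stopping at `max_len` mm or when `allowed(point)` turns FALSE.
polyline_march <- function(start, direction, step, max_len, allowed,
                           curvature = 0) {
  dir <- normalize3(direction)
  pts <- matrix(start, ncol = 3)
  travelled <- 0
  while (travelled + step <= max_len + 1e-9) {
    if (curvature > 0) dir <- normalize3(dir + curvature * rnorm(3) * 0.4)
    nxt <- pts[nrow(pts), ] + dir * step
    if (!allowed(nxt)) break
    pts <- rbind(pts, nxt)
    travelled <- travelled + step
  }
  pts
}

# Convert a polyline + radius into a capsule segment matrix (n-1 x 7).
polyline_segs <- function(pts, radius) {
  n <- nrow(pts)
  if (n < 2) return(matrix(numeric(0), ncol = 7))
  cbind(pts[-n, , drop = FALSE], pts[-1, , drop = FALSE], radius)
}

#' Parameters for a single synthetic vessel tree
#'
#' @param radius Trunk radius, mm.
#' @param length Maximum trunk length, mm.
#' @param n_branches Number of primary branches (0 for a trunk-only vessel).
#' @param taper Radius multiplier per generation.
#' @param min_radius Radius floor, mm.
#' @param branch_angle_range Take-off angle range, degrees.
#' @param generations Branching depth (2 adds secondary-origin stubs).
#' @param step March step, mm.
#' @param curvature Direction jitter per step (0 = straight tube).
#' @return A list of tree-growing parameters.
#' @export
vessel_params <- function(radius = 4, length = 60, n_branches = 2,
                          taper = 0.6, min_radius = 1.0,
                          branch_angle_range = c(30, 60), generations = 2,
                          step = 2, curvature = 0.12) {
  list(radius = radius, length = length, n_branches = n_branches,
       taper = taper, min_radius = min_radius,
       branch_angle_range = branch_angle_range, generations = generations,
       step = step, curvature = curvature)
}

# Grow one vessel tree (no rasterization). `allowed(p, margin)` must return
# TRUE when a centerline point at physical position p with clearance
# `margin` mm is admissible. Uses the current RNG stream.
build_tree <- function(vessel, root, direction, params, allowed,
                       prefix_pts = NULL) {
  r0 <- params$radius
  margin_trunk <- max(1, 0.6 * r0)
  ok_trunk <- function(p) allowed(p, margin_trunk)
  if (!ok_trunk(root))
    stop("vessel root lies outside the allowed region (", vessel, ")",
         call. = FALSE)
  inner <- polyline_march(root, direction, params$step, params$length,
                          ok_trunk, params$curvature)
  pts <- if (is.null(prefix_pts)) inner else rbind(prefix_pts, inner)
  if (nrow(pts) < 2)
    stop("trunk of ", vessel, " could not be grown from its root",
         call. = FALSE)
  trunk <- centerline(pts)
  trunk_segs <- polyline_segs(pts, r0)

  branches <- list()
  branch_segs <- list()
  branch_radii <- numeric(0)
  nb <- params$n_branches
  if (nb > 0) {
    r1 <- max(params$min_radius, params$taper * r0)
    r2 <- max(params$min_radius, params$taper * r1)
    fracs <- seq(0.45, 0.85, length.out = nb)
    inner_cl <- centerline(inner)
    for (b in seq_len(nb)) {
      anchor <- centerline_point(inner_cl, fracs[b] * centerline_length(inner_cl))
      tangent <- centerline_tangent(inner_cl, fracs[b] * centerline_length(inner_cl))
      ok_branch <- function(p) allowed(p, max(1, 0.6 * r1))
      bpts <- NULL
      for (try in 1:8) {
        theta <- runif(1, params$branch_angle_range[1],
                       params$branch_angle_range[2]) * pi / 180
        dirb <- rotated_direction(tangent, theta)
        cand <- polyline_march(anchor, dirb, params$step,
                               0.6 * params$length, ok_branch,
                               params$curvature)
        if (nrow(cand) >= 3) { bpts <- cand; break }
      }
      if (is.null(bpts)) next
      cl <- centerline(bpts)
      segs <- polyline_segs(bpts, r1)
      if (params$generations >= 2 && nrow(bpts) >= 4) {
        scl <- centerline(bpts)
        sanchor <- centerline_point(scl, 0.6 * centerline_length(scl))
        stangent <- centerline_tangent(scl, 0.6 * centerline_length(scl))
        ok_sec <- function(p) allowed(p, max(1, 0.6 * r2))
        for (try in 1:4) {
          theta <- runif(1, params$branch_angle_range[1],
                         params$branch_angle_range[2]) * pi / 180
          dirs <- rotated_direction(stangent, theta)
          spts <- polyline_march(sanchor, dirs, params$step,
                                 0.3 * params$length, ok_sec,
                                 params$curvature)
          if (nrow(spts) >= 3) {
            segs <- rbind(segs, polyline_segs(spts, r2))
            break
          }
        }
      }
      branches <- c(branches, list(cl))
      branch_segs <- c(branch_segs, list(segs))
      branch_radii <- c(branch_radii, r1)
    }
  }
  structure(list(vessel = vessel, trunk = trunk, branches = branches,
                 trunk_segs = trunk_segs, branch_segs = branch_segs,
                 radius = r0, branch_radii = branch_radii),
            class = "vessel_tree")
}

tree_all_segs <- function(tree) {
  do.call(rbind, c(list(tree$trunk_segs), tree$branch_segs))
}

# Rescale every capsule radius of a tree by `scale`, flooring at `floor_r`.
scale_tree_radii <- function(tree, scale, floor_r) {
  fix <- function(m) { m[, 7] <- pmax(floor_r, m[, 7] * scale); m }
  tree$trunk_segs <- fix(tree$trunk_segs)
  tree$branch_segs <- lapply(tree$branch_segs, fix)
  tree$radius <- max(floor_r, tree$radius * scale)
  tree$branch_radii <- pmax(floor_r, tree$branch_radii * scale)
  tree
}

#' Grow and rasterize a single synthetic vessel tree
#'
#' Grows a tapering tube tree inside (or, for `allow_outside`, through the
#' border of) a region mask and rasterizes it as capsules around the
#' centerline polylines. Radii taper monotonically by `taper` per generation
#' and never drop below `min_radius`.
#'
#' @param region_mask Logical 3D array the tree must stay inside.
#' @param spacing Voxel spacing, mm.
#' @param root Physical start point, mm.
#' @param direction Initial growth direction.
#' @param params A [vessel_params()] list.
#' @param seed Integer seed for the growth randomness.
#' @param vessel Structure name used in messages.
#' @param clip_to_mask Clip the rasterized tube to `region_mask` (hepatic
#'   vein convention).
#' @return A list with `mask` (logical array) and `tree` (a `vessel_tree`
#'   with `trunk` and `branches` centerlines).
#' @export
generate_vessel_tree <- function(region_mask, spacing, root, direction,
                                 params = vessel_params(), seed = 1,
                                 vessel = "RHV", clip_to_mask = TRUE) {
  din <- distance_to_mask(!region_mask, spacing)
  dmax <- (dim(region_mask) - 1) * spacing
  allowed <- function(p, margin) {
    if (any(p < 0) || any(p > dmax)) return(FALSE)
    v <- grid_lookup(din, p, spacing)
    isTRUE(v >= margin)  # Inf clearance (all-inside region) is fine
  }
  tree <- with_seed(seed,
                    build_tree(vessel, root, direction, params, allowed))
  segs <- tree_all_segs(tree)
  mask <- .rasterize_capsules_cpp(dim(region_mask), as.numeric(spacing), segs)
  if (clip_to_mask) mask <- mask & region_mask
  mask <- array(mask, dim(region_mask))
  list(mask = mask, tree = tree)
}

condition_shape <- function(condition) {
  switch(condition,
         healthy = list(scale = 1.00, amp = 0.15),
         fatty = list(scale = 1.06, amp = 0.12),
         cirrhosis = list(scale = 0.88, amp = 0.30),
         stop("unknown liver condition: ", condition, call. = FALSE))
}

#' Resection plan as an oblique plane in physical space
#'
#' The remnant/resect partition is defined by a plane `n . p > offset`
#' (resect side), standing in for the assumed surgical planes; presets
#' remove roughly 35% (left), 60% (right) or 72% (extended right) of the
#' liver volume.
#'
#' @param type One of `"left"`, `"right"`, `"extended_right"`.
#' @param normal Plane normal (resect side is the positive side).
#' @param offset Plane offset in mm (filled in by [generate_phantom()]).
#' @param resect_fraction Target fraction of liver volume on the resect side.
#' @return A `resection_plan` object.
#' @export
resection_plan <- function(type = c("left", "right", "extended_right"),
                           normal = NULL, offset = NA_real_,
                           resect_fraction = NULL) {
  type <- match.arg(type)
  if (is.null(normal))
    normal <- switch(type,
                     left = c(-1, 0, 0.15),
                     right = c(1, 0, 0.15),
                     extended_right = c(1, 0, 0.10))
  structure(list(type = type, normal = normalize3(normal), offset = offset,
                 resect_fraction = resect_fraction),
            class = "resection_plan")
}

# Signed plane coordinate (positive = resect side) for the whole grid.
plane_side_array <- function(plan, d, spacing) {
  ax <- (seq_len(d[1]) - 1) * spacing[1] * plan$normal[1]
  ay <- (seq_len(d[2]) - 1) * spacing[2] * plan$normal[2]
  az <- (seq_len(d[3]) - 1) * spacing[3] * plan$normal[3]
  outer(outer(ax, ay, "+"), az, "+") - plan$offset
}

#' Generate one synthetic liver phantom
#'
#' Builds the ground-truth label volume for one synthetic patient: a
#' deformed-ellipsoid liver, the IVC landmark outside the liver, five
#' hepatic-vein trees and the portal system (MPV trunk entering at the
#' hilum, RPV/LPV branching inside), a lesion on the resect side, and the
#' remnant/resect plane partition. Vessel radii are calibrated so the
#' labeled blood pool matches `blood_fraction_target` of the liver volume
#' (within 25% relative). Identical `config` + `seed` give bit-identical
#' output.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @param id Patient identifier.
#' @param condition Liver condition (`healthy`, `fatty`, `cirrhosis`);
#'   sampled from `config$condition_mix` when `NULL`.
#' @param resection Resection type (`left`, `right`, `extended_right`);
#'   sampled from `config$resection_mix` when `NULL`.
#' @return A `patient_phantom`: id, condition, resection plan, ground-truth
#'   [label_volume], and the named list of ground-truth `vessel_tree`s.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L,
                             id = "P001", condition = NULL,
                             resection = NULL) {
  validate_phantom_config(config)
  with_seed(seed, {
    if (is.null(condition))
      condition <- sample(names(config$condition_mix), 1,
                          prob = config$condition_mix)
    if (is.null(resection))
      resection <- sample(names(config$resection_mix), 1,
                          prob = config$resection_mix)
    build_phantom(config, id, condition, resection, seed)
  })
}

build_phantom <- function(config, id, condition, resection, seed) {
  d <- config$grid_shape
  sp <- config$spacing
  shape <- condition_shape(condition)
  axes <- config$liver_axes * shape$scale
  extent <- (d - 1) * sp
  c0 <- extent / 2

  ax <- (seq_len(d[1]) - 1) * sp[1]
  ay <- (seq_len(d[2]) - 1) * sp[2]
  az <- (seq_len(d[3]) - 1) * sp[3]
  xx <- array(ax, d)
  yy <- array(rep(ay, each = d[1]), d)
  zz <- array(rep(az, each = d[1] * d[2]), d)

  q <- ((xx - c0[1]) / axes[1])^2 + ((yy - c0[2]) / axes[2])^2 +
       ((zz - c0[3]) / axes[3])^2
  deform <- smooth_field(d, 5)
  liver <- q < (1 + shape$amp * deform)^2
  nliver <- sum(liver)
  if (nliver < 1000)
    stop("infeasible geometry: liver does not fit the grid", call. = FALSE)

  din <- distance_to_mask(!liver, sp)
  allowed <- function(p, margin) {
    if (any(p < 0) || any(p > extent)) return(FALSE)
    v <- grid_lookup(din, p, sp)
    isTRUE(v >= margin)
  }

  # point on the segment c0 -> c0 + u*axes with clearance >= margin, as far
  # from the center as possible
  surface_point <- function(u, margin) {
    ts <- seq(1.3, 0.05, by = -0.025)
    for (t in ts) {
      p <- c0 + t * u * axes
      if (allowed(p, margin)) return(p)
    }
    stop("infeasible geometry: no interior point with clearance ", margin,
         " mm along the requested direction", call. = FALSE)
  }

  tr <- config$trunk_radii
  spec <- list(
    RHV = list(u = c(0.25, 0.80, 0.45), dir = c(0.75, -0.50, -0.35),
               r = tr[["RHV"]], len = 70, nb = 2),
    MHV = list(u = c(0.00, 0.85, 0.50), dir = c(-0.10, -0.75, -0.50),
               r = tr[["MHV"]], len = 70, nb = 2),
    LHV = list(u = c(-0.25, 0.80, 0.45), dir = c(-0.75, -0.50, -0.30),
               r = tr[["LHV"]], len = 70, nb = 2),
    SRHV = list(u = c(0.45, 0.75, 0.30), dir = c(0.55, -0.60, 0.25),
                r = tr[["SRHV"]], len = 45, nb = 1),
    IRHV = list(u = c(0.45, 0.80, -0.25), dir = c(0.50, -0.60, -0.40),
                r = tr[["IRHV"]], len = 45, nb = 1)
  )

  trees <- list()
  for (v in names(spec)) {
    s <- spec[[v]]
    root <- surface_point(normalize3(s$u), max(1, 0.6 * s$r) + 4)
    params <- vessel_params(radius = s$r, length = s$len, n_branches = s$nb,
                            taper = config$taper,
                            min_radius = config$min_radius,
                            branch_angle_range = config$branch_angle_range,
                            generations = config$generations)
    trees[[v]] <- build_tree(v, root, normalize3(s$dir), params, allowed)
  }

  # portal system: MPV enters at the hilum from outside; RPV/LPV branch at
  # its intrahepatic end
  u_hilum <- normalize3(c(0.10, -0.75, -0.35))
  entry <- surface_point(u_hilum, max(1, 0.6 * tr[["MPV"]]) + 3)
  dir_out <- normalize3(entry - c0)
  mpv_start <- entry + 16 * dir_out
  pre <- rbind(mpv_start, entry)
  params_mpv <- vessel_params(radius = tr[["MPV"]], length = 0.55 * axes[1],
                              n_branches = 0, taper = config$taper,
                              min_radius = config$min_radius,
                              generations = config$generations)
  trees$MPV <- build_tree("MPV", entry, -dir_out, params_mpv, allowed,
                          prefix_pts = matrix(mpv_start, ncol = 3))
  p0 <- tail(trees$MPV$trunk$points, 1)[1, ]
  for (v in c("RPV", "LPV")) {
    sgn <- if (v == "RPV") 1 else -1
    params_pv <- vessel_params(radius = tr[[v]], length = 55, n_branches = 2,
                               taper = config$taper,
                               min_radius = config$min_radius,
                               branch_angle_range = config$branch_angle_range,
                               generations = config$generations)
    trees[[v]] <- build_tree(v, p0, normalize3(c(sgn * 0.85, 0.15, 0.15)),
                             params_pv, allowed)
  }

  # rasterize with blood-pool calibration: scale radii until labeled vessel
  # voxels inside the liver reach the target fraction of liver volume
  hepatic <- hepatic_vein_names()
  rasterize_all <- function(trees) {
    masks <- list()
    for (v in names(trees)) {
      m <- .rasterize_capsules_cpp(d, sp, tree_all_segs(trees[[v]]))
      m <- array(m, d)
      if (v != "MPV") m <- m & liver
      masks[[v]] <- m
    }
    masks
  }
  masks <- rasterize_all(trees)
  frac <- NA_real_
  for (iter in 1:4) {
    vess_in <- Reduce(`|`, masks[setdiff(names(masks), "MPV")]) |
      (masks$MPV & liver)
    frac <- sum(vess_in) / nliver
    if (abs(frac - config$blood_fraction_target) <=
        0.1 * config$blood_fraction_target) break
    scale <- sqrt(config$blood_fraction_target / frac)
    scale <- min(1.4, max(0.7, scale))
    trees <- lapply(trees, scale_tree_radii, scale = scale,
                    floor_r = config$min_radius)
    masks <- rasterize_all(trees)
  }

  # IVC: vertical landmark tube just posterior to the liver, never inside it
  ymax <- max(yy[liver])
  ivc_xy <- c(c0[1], min(ymax + config$ivc_radius + 2, extent[2] - 1))
  zr <- range(zz[liver])
  ivc_seg <- matrix(c(ivc_xy[1], ivc_xy[2], max(0, zr[1] - 10),
                      ivc_xy[1], ivc_xy[2], min(extent[3], zr[2] + 10),
                      config$ivc_radius), nrow = 1)
  ivc <- array(.rasterize_capsules_cpp(d, sp, ivc_seg), d) & !liver

  # resection plane: offset chosen so the resect side holds the preset
  # fraction of liver voxels
  plan <- resection_plan(resection,
                         resect_fraction = config$resect_fractions[[resection]])
  proj <- plan$normal[1] * xx + plan$normal[2] * yy + plan$normal[3] * zz
  plan$offset <- unname(stats::quantile(proj[liver],
                                        1 - plan$resect_fraction))
  resect_side <- proj > plan$offset

  # lesion(s) on the resect side
  lesion <- array(FALSE, d)
  for (l in seq_len(config$lesion_count)) {
    lr <- runif(1, config$lesion_radius_range[1],
                config$lesion_radius_range[2])
    cand <- which(liver & resect_side & din >= 0.6 * lr)
    if (length(cand) == 0) cand <- which(liver & din >= 0.6 * lr)
    ci <- cand[sample.int(length(cand), 1)]
    cc <- voxel_coords_mm(ci, d, sp)
    lesion <- lesion |
      (((xx - cc[1])^2 + (yy - cc[2])^2 + (zz - cc[3])^2) <= lr^2 & liver)
  }

  # assemble the label grid: parenchyma, then lesion, then vessels
  # (first-wins among vessels), then the IVC
  codes <- structure_codes()
  grid <- array(0L, d)
  par <- liver & !lesion
  grid[par & !resect_side] <- codes[["REMNANT"]]
  grid[par & resect_side] <- codes[["RESECT"]]
  grid[lesion] <- codes[["LESION"]]
  taken <- array(FALSE, d)
  for (v in c(hepatic, "MPV", "RPV", "LPV")) {
    sel <- masks[[v]] & !taken
    grid[sel] <- codes[[v]]
    taken <- taken | masks[[v]]
  }
  grid[ivc & !taken & !liver] <- codes[["IVC"]]

  truth <- label_volume(grid, sp, codes)
  structure(list(id = id, condition = condition, resection = plan,
                 truth = truth, trees = trees,
                 blood_fraction = frac, seed = seed, config = config),
            class = "patient_phantom")
}

#' @export
print.patient_phantom <- function(x, ...) {
  cat(sprintf("<patient_phantom> %s: %s liver, %s hepatectomy, blood pool %.1f%%\n",
              x$id, x$condition, gsub("_", " ", x$resection$type),
              100 * x$blood_fraction))
  print(x$truth)
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Conditions and resection plans are drawn from the configured proportions
#' (default: 27/3/2 healthy/fatty/cirrhosis and 10/21/1
#' left/right/extended-right over 32 candidates); per-patient seeds are
#' derived deterministically from the master seed.
#'
#' @param n Number of patients (>= 1).
#' @param config A [phantom_config()].
#' @param seed Master seed.
#' @return A `phantom_cohort` (list of `patient_phantom`s).
#' @export
generate_cohort <- function(n, config = phantom_config(), seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  draws <- with_seed(seed, list(
    conditions = sample(names(config$condition_mix), n, replace = TRUE,
                        prob = config$condition_mix),
    resections = sample(names(config$resection_mix), n, replace = TRUE,
                        prob = config$resection_mix),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  phantoms <- lapply(seq_len(n), function(i) {
    generate_phantom(config, seed = draws$seeds[i],
                     id = sprintf("P%03d", i),
                     condition = draws$conditions[i],
                     resection = draws$resections[i])
  })
  structure(phantoms, class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d synthetic patients\n", length(x)))
  conds <- table(vapply(x, function(p) p$condition, ""))
  cat("  conditions:", paste(names(conds), conds, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
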