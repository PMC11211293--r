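#' Centerline: an ordered polyline in physical coordinates
#'
#' @param points Numeric matrix (n x 3) of mm coordinates, at least 2
#'   distinct consecutive points.
#' @return A `centerline` with fields `points` and `cumlen` (cumulative arc
#'   length, mm).
#' @export
centerline <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) >= 2) {
    steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
    keep <- c(TRUE, steps > 1e-9)
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 2)
    stop("a centerline needs at least 2 distinct points", call. = FALSE)
  steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  structure(list(points = points, cumlen = c(0, cumsum(steps))),
            class = "centerline")
}

#' @rdname centerline
#' @param line A `centerline`.
#' @export
centerline_length <- function(line) tail(line$cumlen, 1)

# Point on the centerline at arc position s (linear interpolation).
centerline_point <- function(line, s) {
  s <- min(max(s, 0), centerline_length(line))
  i <- findInterval(s, line$cumlen, rightmost.closed = TRUE)
  i <- min(i, nrow(line$points) - 1)
  t <- (s - line$cumlen[i]) / (line$cumlen[i + 1] - line$cumlen[i])
  line$points[i, ] + t * (line$points[i + 1, ] - line$points[i, ])
}

centerline_tangent <- function(line, s) {
  i <- findInterval(s, line$cumlen, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(line$points) - 1)
  normalize3(line$points[i + 1, ] - line$points[i, ])
}

# Resample at an even arc step; the two endpoints are always included.
resample_centerline <- function(line, step) {
  L <- centerline_length(line)
  s <- unique(c(seq(0, L, by = step), L))
  pts <- t(vapply(s, function(si) centerline_point(line, si), numeric(3)))
  list(points = pts, arc = s)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, %.1f mm\n", nrow(x$points),
              centerline_length(x)))
  invisible(x)
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %s: trunk %.1f mm (r = %.2f mm), %d primary branch(es)\n",
              x$vessel, centerline_length(x$trunk), x$radius,
              length(x$branches)))
  invisible(x)
}

#' Extract the centerline of a single tubular mask
#'
#' Intended as a validation cross-check of the phantom's ground-truth
#' polylines. The mask voxels are turned into a 26-connected graph weighted
#' by physical step length; the two mutually farthest voxels are taken as
#' the tube endpoints and the geodesic between them, lightly smoothed, is
#' the centerline. Disconnected or branched masks are rejected.
#'
#' @param mask Logical 3D array containing one tubular component.
#' @param spacing Voxel spacing, mm.
#' @return A [centerline].
#' @export
extract_centerline <- function(mask, spacing) {
  d <- dim(mask)
  nvox <- sum(mask)
  if (nvox < 8)
    stop("degenerate mask: only ", nvox, " voxels", call. = FALSE)
  idx <- array(0L, d)
  idx[mask] <- seq_len(nvox)

  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  offsets <- offsets[apply(offsets, 1, function(o) {
    o[1] > 0 || (o[1] == 0 && (o[2] > 0 || (o[2] == 0 && o[3] > 0)))
  }), ]

  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    xs <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    ys <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zs <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    A <- idx[xs, ys, zs, drop = FALSE]
    B <- idx[xs + o[1], ys + o[2], zs + o[3], drop = FALSE]
    sel <- A > 0L & B > 0L
    if (any(sel)) {
      from <- c(from, A[sel]); to <- c(to, B[sel])
      w <- c(w, rep(sqrt(sum((o * spacing)^2)), sum(sel)))
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("mask is not a single connected component (", comp$no,
         " components found)", call. = FALSE)

  d1 <- igraph::distances(g, v = 1)[1, ]
  e1 <- which.max(d1)
  d2 <- igraph::distances(g, v = e1)[1, ]
  e2 <- which.max(d2)
  path <- igraph::shortest_paths(g, from = e1, to = e2)$vpath[[1]]
  path <- as.integer(path)

  lin <- which(mask)
  coords <- voxel_coords_mm(lin, d, spacing)
  pts <- coords[path, , drop = FALSE]
  if (nrow(pts) < 3)
    stop("degenerate mask: centerline path too short", call. = FALSE)

  # branched tube check: voxels far from the geodesic beyond the local tube
  # radius indicate side branches
  radius_grid <- distance_to_mask(!mask, spacing)
  tube_r <- max(radius_grid[lin])  # largest inscribed radius of the tube
  pmask <- array(FALSE, d)
  pmask[lin[path]] <- TRUE
  dist_path <- distance_to_mask(pmask, spacing)
  off <- dist_path[lin] > 2 * tube_r + max(spacing)
  if (sum(off) > max(10, 0.02 * nvox))
    stop("mask appears branched: ", sum(off),
         " voxels lie beyond the tube around the main path", call. = FALSE)

  # the geodesic reaches the rounded cap tips; trim each end by the local
  # inscribed radius so the length tracks the tube axis
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(steps))
  keep <- arc >= tube_r - max(spacing) / 2 &
          arc <= max(arc) - tube_r + max(spacing) / 2
  if (sum(keep) >= 3) pts <- pts[keep, , drop = FALSE]

  # light smoothing against voxel zigzag before measuring length
  if (nrow(pts) >= 7) {
    sm <- pts
    for (a in 1:3)
      sm[, a] <- stats::filter(pts[, a], rep(1 / 5, 5), sides = 2)
    inner <- !is.na(sm[, 1])
    pts[inner, ] <- sm[inner, ]
  }
  centerline(pts)
}

#' Coverage profile of a centerline against a predicted mask
#'
#' Samples the line at an even arc step (half the smallest voxel spacing)
#' and marks each sample as covered when it lies within the predicted mask
#' dilated by `tolerance_mm` — the voxel analogue of "accurately annotated".
#'
#' @param line A [centerline].
#' @param pred_mask Logical 3D array (the predicted vessel voxels).
#' @param spacing Voxel spacing, mm.
#' @param tolerance_mm Dilation tolerance; defaults to one voxel
#'   (`min(spacing)`).
#' @return A `coverage_profile`: list with `covered` (logical), `arc` (mm
#'   positions) and `length` (total line length, mm).
#' @export
coverage_profile <- function(line, pred_mask, spacing,
                             tolerance_mm = min(spacing)) {
  step <- min(spacing) / 2
  rs <- resample_centerline(line, step)
  if (!any(pred_mask)) {
    covered <- rep(FALSE, length(rs$arc))
  } else {
    dist_grid <- distance_to_mask(pred_mask, spacing)
    dvals <- grid_lookup(dist_grid, rs$points, spacing)
    covered <- dvals <= tolerance_mm + 1e-9
  }
  structure(list(covered = covered, arc = rs$arc,
                 length = centerline_length(line)),
            class = "coverage_profile")
}

#' Arc length of the longest contiguous covered run
#'
#' Operationalizes "continuously annotated": only the longest maximal run
#' of covered samples counts.
#'
#' @param profile A [coverage_profile], or a logical vector together with
#'   `arc`.
#' @param arc Arc positions (mm) when `profile` is a plain logical vector.
#' @return Length in mm of the longest contiguous covered run.
#' @export
longest_covered_run <- function(profile, arc = NULL) {
  if (inherits(profile, "coverage_profile")) {
    covered <- profile$covered
    arc <- profile$arc
  } else {
    covered <- as.logical(profile)
    if (is.null(arc)) stop("`arc` positions required", call. = FALSE)
  }
  if (!any(covered)) return(0)
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  max(arc[ends[runs]] - arc[starts[runs]])
}

#' Classify a predicted vessel against the continuity criterion
#'
#' A vessel is classified as accurate when at least 3/4 of its trunk length
#' and at least 1/2 of the length of every primary branch are covered by
#' the prediction in one contiguous run (thresholds inclusive). Vessels
#' without branches (MPV, IVC) get `branches_accurate = NA`.
#'
#' @param tree A `vessel_tree` (ground-truth centerlines).
#' @param pred_volume A [label_volume] holding the predicted labels.
#' @param tolerance_mm Coverage tolerance; defaults to one voxel.
#' @return A one-row tibble: `vessel`, `trunk_accurate`, `branches_accurate`,
#'   `trunk_length_mm`, `trunk_covered_mm`, `n_branches`.
#' @export
classify_vessel <- function(tree, pred_volume, tolerance_mm = NULL) {
  stopifnot(inherits(tree, "vessel_tree"),
            inherits(pred_volume, "label_volume"))
  if (!(tree$vessel %in% names(pred_volume$label_map)))
    stop("unknown vessel label: ", tree$vessel, call. = FALSE)
  sp <- pred_volume$spacing
  if (is.null(tolerance_mm)) tolerance_mm <- min(sp)
  code <- pred_volume$label_map[[tree$vessel]]

  # distance-to-prediction restricted to the tree's bounding box; points in
  # the box are at most `tolerance_mm` from any relevant mask voxel
  allpts <- do.call(rbind, c(list(tree$trunk$points),
                             lapply(tree$branches, function(b) b$points)))
  d <- dim(pred_volume$grid)
  lo <- pmax(1, floor(apply(allpts, 2, min) / sp) + 1 -
                  ceiling((tolerance_mm + 3) / min(sp)))
  hi <- pmin(d, ceiling(apply(allpts, 2, max) / sp) + 1 +
                  ceiling((tolerance_mm + 3) / min(sp)))
  sub <- pred_volume$grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                          drop = FALSE] == code
  origin <- (lo - 1) * sp
  shift_line <- function(cl) centerline(sweep(cl$points, 2, origin, "-"))

  run_frac <- function(cl) {
    prof <- coverage_profile(shift_line(cl), sub, sp, tolerance_mm)
    list(run = longest_covered_run(prof), len = centerline_length(cl))
  }
  tk <- run_frac(tree$trunk)
  trunk_ok <- tk$run >= 0.75 * tk$len - 1e-9
  if (length(tree$branches) == 0) {
    branches_ok <- NA
  } else {
    branches_ok <- all(vapply(tree$branches, function(b) {
      rb <- run_frac(b)
      rb$run >= 0.5 * rb$len - 1e-9
    }, logical(1)))
  }
  tibble(vessel = tree$vessel, trunk_accurate = trunk_ok,
         branches_accurate = branches_ok,
         trunk_length_mm = tk$len, trunk_covered_mm = tk$run,
         n_branches = length(tree$branches))
}

#' Per-vessel classification accuracy with 95% confidence intervals
#'
#' Aggregates cohort classification results into the familiar
#' accuracy-table shape: one trunk row and one branches row per vessel,
#' accuracy as percent correct with a Wald 95% CI clipped to `[0, 100]`.
#' Vessels whose trees have no branches report `NA` on the branches row.
#'
#' @param results Tibble of [classify_vessel()] rows across a cohort.
#' @return A tibble: `vessel`, `measure`, `n`, `correct`, `accuracy_pct`,
#'   `ci_low`, `ci_high`.
#' @export
accuracy_table <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    stop("empty cohort: no classification results", call. = FALSE)
  summarize_one <- function(flags) {
    flags <- flags[!is.na(flags)]
    if (length(flags) == 0)
      return(tibble(n = 0L, correct = NA_integer_,
                    accuracy_pct = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_))
    k <- sum(flags); n <- length(flags)
    ci <- wald_ci(k, n)
    tibble(n = n, correct = as.integer(k), accuracy_pct = 100 * k / n,
           ci_low = ci[1], ci_high = ci[2])
  }
  results |>
    tidyr::pivot_longer(c("trunk_accurate", "branches_accurate"),
                        names_to = "measure", values_to = "accurate") |>
    dplyr::mutate(measure = ifelse(.data$measure == "trunk_accurate",
                                   "trunk", "branches")) |>
    dplyr::group_by(.data$vessel, .data$measure) |>
    dplyr::reframe(summarize_one(.data$accurate)) |>
    dplyr::arrange(.data$vessel, dplyr::desc(.data$measure))
}
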