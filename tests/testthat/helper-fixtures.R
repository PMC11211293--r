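# Shared fixtures, built once per test run. The desk-scale config trades a
# little spatial resolution for speed; geometry and physical extent match
# the default phantom.
.fixtures <- new.env(parent = emptyenv())

test_config <- function() {
  phantom_config(grid_shape = c(96, 96, 96), spacing = c(1.25, 1.25, 1.25),
                 liver_axes = c(54, 42, 35))
}

test_phantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- generate_phantom(test_config(), seed = 101,
                                          condition = "healthy",
                                          resection = "right")
  .fixtures$phantom
}

test_prediction <- function() {
  if (is.null(.fixtures$pred))
    .fixtures$pred <- perturb_segmentation(test_phantom(),
                                           perturbation_config(seed = 11))
  .fixtures$pred
}

# A straight axis-aligned tube (cylinder with capped ends) as a label
# volume, plus its ground-truth tree; used by the classification tests.
make_tube_volume <- function(len_mm = 100, radius = 3, spacing = 1,
                             cover_ranges = NULL, vessel = "MPV") {
  d <- c(ceiling(len_mm / spacing) + 21, 21, 21)
  sp <- rep(spacing, 3)
  y0 <- 10 * spacing
  p1 <- c(10 * spacing, y0, y0)
  p2 <- c(10 * spacing + len_mm, y0, y0)
  tree <- structure(list(vessel = vessel,
                         trunk = centerline(rbind(p1, p2)),
                         branches = list(),
                         trunk_segs = matrix(c(p1, p2, radius), nrow = 1),
                         branch_segs = list(),
                         radius = radius, branch_radii = numeric(0)),
                    class = "vessel_tree")
  grid <- array(0L, d)
  code <- structure_codes()[[vessel]]
  if (is.null(cover_ranges)) cover_ranges <- list(c(0, len_mm))
  ax <- (seq_len(d[1]) - 1) * spacing
  ay <- (seq_len(d[2]) - 1) * spacing
  rad2 <- outer((ay - y0)^2, (ay - y0)^2, "+")  # (y,z) radial distance^2
  for (rg in cover_ranges) {
    xs <- which(ax >= p1[1] + rg[1] & ax <= p1[1] + rg[2])
    for (i in xs) {
      sl <- grid[i, , ]
      sl[rad2 <= radius^2] <- code
      grid[i, , ] <- sl
    }
  }
  list(volume = label_volume(grid, sp), tree = tree, start = p1[1])
}
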