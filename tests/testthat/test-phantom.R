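test_that("phantom generation is deterministic and satisfies label invariants", {
  cfg <- test_config()
  a <- generate_phantom(cfg, seed = 17)
  b <- generate_phantom(cfg, seed = 17)
  expect_identical(a$truth$grid, b$truth$grid)
  expect_identical(a$condition, b$condition)
  expect_identical(a$resection$offset, b$resection$offset)

  v <- a$truth
  # every nonzero grid value is a known label
  expect_true(all(setdiff(unique(as.integer(v$grid)), 0L) %in% v$label_map))
  # remnant and resect are disjoint and tile the parenchyma
  rem <- structure_mask(v, "REMNANT"); res <- structure_mask(v, "RESECT")
  expect_equal(sum(rem & res), 0)
  expect_equal(sum(rem) + sum(res), sum(structure_mask(v, "PARENCHYMA")))
})

test_that("phantom blood pool is calibrated near 9% of the liver volume", {
  ph <- test_phantom()
  v <- ph$truth
  vessels_in <- intrahepatic_vessel_mask(v)
  frac <- sum(vessels_in) / sum(liver_mask(v))
  expect_gte(frac, 0.0675)  # 9% within 25% relative
  expect_lte(frac, 0.1125)
  expect_equal(frac, ph$blood_fraction, tolerance = 0.02)
})

test_that("phantom vessel geometry: veins enclosed by liver, IVC outside", {
  v <- test_phantom()$truth
  ref <- structure_mask(v, c("PARENCHYMA", "LESION"))
  hits <- flrvolumetry:::ray_hit_count(ref)
  hv <- structure_mask(v, "HEPATIC_VEINS")
  # hepatic veins were clipped to the liver: nearly all voxels are enclosed
  expect_gte(mean(hits[hv] >= 4), 0.95)
  ivc <- structure_mask(v, "IVC")
  expect_gt(sum(ivc), 0)
  expect_equal(sum(ivc & liver_mask(v)), 0)
  # no IVC voxel is fully enclosed by parenchyma
  expect_equal(sum(hits[ivc] == 6), 0)
})

test_that("tube radii respect the 2 mm diameter floor along centerlines", {
  ph <- test_phantom()
  v <- ph$truth
  for (tree in ph$trees) {
    expect_gte(tree$radius, 1.0)
    if (length(tree$branch_radii) > 0) {
      expect_true(all(tree$branch_radii >= 1.0))
      expect_true(all(tree$branch_radii <= tree$radius))  # monotone taper
    }
    mask <- structure_mask(v, tree$vessel)
    radius_grid <- flrvolumetry:::distance_to_mask(!mask, v$spacing)
    rs <- resample_points <- flrvolumetry:::resample_centerline(tree$trunk, 2)$points
    vals <- flrvolumetry:::grid_lookup(radius_grid, rs, v$spacing)
    # local tube radius at trunk centerline samples, allowing half-voxel
    # rasterization error and label competition near confluences
    expect_gte(stats::median(vals), 1.0)
  }
})

test_that("single-tube and branch growth follow the requested parameters", {
  region <- array(TRUE, c(60, 40, 40))
  out <- generate_vessel_tree(region, c(1, 1, 1), root = c(10, 20, 20),
                              direction = c(1, 0, 0),
                              params = vessel_params(radius = 3, length = 40,
                                                     n_branches = 0,
                                                     curvature = 0),
                              seed = 2)
  expect_length(out$tree$branches, 0)
  expect_lt(abs(centerline_length(out$tree$trunk) - 40), 2)
  # centerline lies inside the returned mask
  pts <- out$tree$trunk$points
  expect_true(all(flrvolumetry:::grid_lookup(out$mask, pts, c(1, 1, 1))))

  out2 <- generate_vessel_tree(region, c(1, 1, 1), root = c(10, 20, 20),
                               direction = c(1, 0, 0),
                               params = vessel_params(radius = 3, length = 35,
                                                      n_branches = 2,
                                                      taper = 0.5),
                               seed = 3)
  expect_length(out2$tree$branches, 2)
  expect_equal(out2$tree$branch_radii, c(1.5, 1.5))  # 0.5 * 3, above floor

  expect_error(
    generate_vessel_tree(region, c(1, 1, 1), root = c(-20, -20, -20),
                         direction = c(1, 0, 0), seed = 1),
    "outside the allowed region")
})

test_that("infeasible vessel configuration fails naming the constraint", {
  radii <- c(RHV = 4, MHV = 4, LHV = 4, SRHV = 0.8, IRHV = 2.5,
             MPV = 5.5, RPV = 4, LPV = 4)
  expect_error(phantom_config(trunk_radii = radii, min_radius = 1),
               "infeasible geometry.*SRHV")
  expect_error(phantom_config(min_radius = 0.5), "2 mm")
  expect_error(phantom_config(blood_fraction_target = 0.5), "0, 0.2")
})

test_that("cohort generation is deterministic with unique patient ids", {
  cfg <- test_config()
  co1 <- generate_cohort(5, cfg, seed = 7)
  co2 <- generate_cohort(5, cfg, seed = 7)
  expect_length(co1, 5)
  ids <- vapply(co1, function(p) p$id, "")
  expect_equal(anyDuplicated(ids), 0)
  expect_identical(vapply(co1, function(p) p$condition, ""),
                   vapply(co2, function(p) p$condition, ""))
  expect_identical(co1[[3]]$truth$grid, co2[[3]]$truth$grid)

  single <- generate_cohort(1, cfg, seed = 9)
  expect_length(single, 1)
  expect_error(generate_cohort(0, cfg, seed = 1), ">= 1")
})
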