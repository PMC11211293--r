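# A hand-built volume with known counts: a parenchyma box, an enclosed
# vessel block, a lesion on the resect side, split by a plane at x = x_cut.
make_box_volume <- function() {
  d <- c(30, 20, 20)
  grid <- array(0L, d)
  codes <- structure_codes()
  grid[3:27, 3:17, 3:17] <- codes[["REMNANT"]]        # parenchyma slab
  plan <- resection_plan("right", normal = c(1, 0, 0), offset = 14.5,
                         resect_fraction = NA)
  xx <- array((seq_len(d[1]) - 1), d)
  grid[grid != 0L & xx > 14.5] <- codes[["RESECT"]]
  list(grid = grid, plan = plan, codes = codes, d = d)
}

test_that("blood-free correction removes exactly the enclosed vessel voxels", {
  b <- make_box_volume()
  grid <- b$grid
  # 90 interior voxels relabelled as hepatic vein (fully enclosed)
  grid[10:12, 8:13, 8:12] <- b$codes[["RHV"]]
  expect_equal(sum(grid == b$codes[["RHV"]]), 90)
  v <- label_volume(grid, c(1, 1, 1))
  n_liver <- sum(liver_mask(v))
  free <- blood_free_masks(v)
  expect_equal(sum(liver_mask(free)), n_liver - 90)
  expect_equal(sum(free$grid == b$codes[["RHV"]]), 0)

  # no vessels: output identical
  v0 <- label_volume(b$grid, c(1, 1, 1))
  expect_identical(blood_free_masks(v0)$grid, v0$grid)

  # vessel voxels entirely outside the liver are untouched
  grid2 <- b$grid
  grid2[1, 1, 1:5] <- b$codes[["MPV"]]
  v2 <- label_volume(grid2, c(1, 1, 1))
  expect_identical(blood_free_masks(v2)$grid, grid2)

  lesion_only <- array(0L, c(5, 5, 5)); lesion_only[2, 2, 2] <- 3L
  expect_error(blood_free_masks(label_volume(lesion_only, c(1, 1, 1))),
               "no liver")
})

test_that("volumetry reproduces worked FLR% arithmetic", {
  # remnant 500, resect 900, lesion 100 -> FLR%_filled = 500/1400
  d <- c(30, 20, 20)
  codes <- structure_codes()
  grid <- array(0L, d)
  grid[3:7, 3:12, 3:12] <- codes[["REMNANT"]]          # 5*10*10 = 500
  grid[10:18, 3:12, 3:12] <- codes[["RESECT"]]         # 9*10*10 = 900
  grid[20:23, 3:7, 3:7] <- codes[["LESION"]]           # 4*5*5 = 100
  plan <- resection_plan("right", normal = c(1, 0, 0), offset = 7.5)
  v <- label_volume(grid, c(1, 1, 1))
  res <- volumetry(v, plan = plan)
  expect_equal(res$tlv_filled_ml, 1.5)
  expect_equal(res$v_lesion_ml, 0.1)
  expect_equal(res$flr_pct_filled, 100 * 500 / 1400)
  expect_equal(res$flr_pct_free, res$flr_pct_filled)   # no vessels

  # remnant = whole liver, no lesion -> both FLR% are 100
  g2 <- array(0L, d); g2[3:27, 3:17, 3:17] <- codes[["REMNANT"]]
  all_plan <- resection_plan("right", normal = c(1, 0, 0), offset = 1e6)
  res2 <- volumetry(label_volume(g2, c(1, 1, 1)), plan = all_plan)
  expect_equal(res2$flr_pct_filled, 100)
  expect_equal(res2$flr_pct_free, 100)

  # no parenchyma at all: nothing to measure
  g3 <- array(0L, d)
  g3[3:6, 3:6, 3:6] <- codes[["LESION"]]
  expect_error(volumetry(label_volume(g3, c(1, 1, 1)), plan = all_plan),
               "remnant/resect")
})

test_that("vessels confined to the resect side raise FLR% in the blood-free setting", {
  b <- make_box_volume()
  grid <- b$grid
  grid[20:24, 8:12, 8:12] <- b$codes[["RHV"]]   # enclosed, x > cut
  v <- label_volume(grid, c(1, 1, 1))
  res <- volumetry(v, plan = b$plan)
  expect_equal(res$flr_free_ml, res$flr_filled_ml)
  expect_lt(res$tlv_free_ml, res$tlv_filled_ml)
  expect_gt(res$flr_pct_free, res$flr_pct_filled)
})

test_that("phantom volumetry conserves voxels and obeys the blood-free identity", {
  ph <- test_phantom()
  v <- ph$truth
  res <- volumetry(ph)
  vv <- prod(v$spacing) / 1000

  # conservation: remnant + resect + lesion + intrahepatic vessels = liver
  n_liver <- sum(liver_mask(v))
  n_parts <- sum(structure_mask(v, "REMNANT")) +
    sum(structure_mask(v, "RESECT")) + sum(structure_mask(v, "LESION")) +
    sum(intrahepatic_vessel_mask(v))
  expect_identical(n_parts, n_liver)
  expect_equal(res$tlv_filled_ml, n_liver * vv)

  # blood-free identity: flr_filled - flr_free = vessel volume in remnant
  side <- flrvolumetry:::plane_side_array(ph$resection, dim(v$grid),
                                          v$spacing)
  n_ves_rem <- sum(intrahepatic_vessel_mask(v) & side <= 0)
  expect_equal(res$flr_filled_ml - res$flr_free_ml, n_ves_rem * vv)
  expect_lte(res$flr_free_ml, res$flr_filled_ml)
  expect_equal(res$tlv_free_ml,
               res$tlv_filled_ml - res$v_hv_ml - res$v_pv_ml)
})

test_that("volumetry is scale equivariant", {
  ph <- test_phantom()
  v <- ph$truth
  res1 <- volumetry(ph)
  v2 <- label_volume(v$grid, v$spacing * 2, v$label_map)
  plan2 <- ph$resection
  plan2$offset <- plan2$offset * 2  # the plane lives in physical units
  res2 <- volumetry(v2, plan = plan2)
  for (col in c("tlv_filled_ml", "tlv_free_ml", "v_lesion_ml", "v_hv_ml",
                "v_pv_ml", "flr_filled_ml", "flr_free_ml"))
    expect_equal(res2[[col]], 8 * res1[[col]])
  expect_equal(res2$flr_pct_filled, res1$flr_pct_filled)
  expect_equal(res2$flr_pct_free, res1$flr_pct_free)
})

test_that("candidacy uses strict per-condition thresholds", {
  expect_true(candidacy(35, "healthy")$candidate)
  expect_false(candidacy(35, "cirrhosis")$candidate)
  expect_false(candidacy(30, "fatty")$candidate)   # strictly larger than
  expect_true(candidacy(30.01, "fatty")$candidate)
  expect_error(candidacy(35, "unknown"), "condition")
  expect_error(candidacy(120, "healthy"), "0, 100")
  # monotone in FLR% for a fixed condition
  dec <- candidacy(seq(0, 100, by = 5), rep("fatty", 21))$candidate
  expect_true(all(diff(dec) >= 0))
})
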