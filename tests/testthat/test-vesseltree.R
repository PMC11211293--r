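test_that("longest covered run matches the all-pairs oracle on random profiles", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:200, 1)
    covered <- runif(n) < runif(1)
    arc <- cumsum(c(0, runif(n - 1, 0.2, 1)))
    expect_equal(longest_covered_run(covered, arc),
                 oracle_longest_run(covered, arc))
  }
  expect_equal(longest_covered_run(rep(TRUE, 11), seq(0, 100, by = 10)), 100)
  expect_equal(longest_covered_run(rep(FALSE, 5), 1:5), 0)
  # true on [0,40] and [60,100]: longest contiguous piece is 40
  arc <- seq(0, 100, by = 1)
  covered <- arc <= 40 | arc >= 60
  expect_equal(longest_covered_run(covered, arc), 40)
})

test_that("coverage profile marks deleted tube sections as uncovered", {
  full <- make_tube_volume(len_mm = 90, radius = 3)
  prof <- coverage_profile(full$tree$trunk,
                           structure_mask(full$volume, "MPV"),
                           full$volume$spacing)
  expect_true(all(prof$covered))

  gap <- make_tube_volume(len_mm = 90, radius = 3,
                          cover_ranges = list(c(0, 30), c(60, 90)))
  prof2 <- coverage_profile(gap$tree$trunk,
                            structure_mask(gap$volume, "MPV"),
                            gap$volume$spacing)
  mid <- prof2$arc > 32 & prof2$arc < 58
  expect_true(all(!prof2$covered[mid]))
  expect_true(all(prof2$covered[prof2$arc < 29]))
  expect_true(all(prof2$covered[prof2$arc > 61]))

  none <- coverage_profile(full$tree$trunk,
                           array(FALSE, dim(full$volume$grid)),
                           full$volume$spacing)
  expect_false(any(none$covered))
})

test_that("trunk criterion: 3/4 contiguous coverage, inclusive at the boundary", {
  # 100 mm trunk fully annotated for the first 80 mm -> accurate
  t80 <- make_tube_volume(100, cover_ranges = list(c(0, 80)))
  expect_true(classify_vessel(t80$tree, t80$volume)$trunk_accurate)
  # covered run of ~74 mm -> not accurate (73 mm of tube + 1 mm tolerance)
  t74 <- make_tube_volume(100, cover_ranges = list(c(0, 73)))
  cls74 <- classify_vessel(t74$tree, t74$volume)
  expect_false(cls74$trunk_accurate)
  expect_lt(cls74$trunk_covered_mm, 75)
  # exactly 75 mm (74 mm of tube + 1 mm dilation tolerance): inclusive
  t75 <- make_tube_volume(100, cover_ranges = list(c(0, 74)))
  cls75 <- classify_vessel(t75$tree, t75$volume)
  expect_equal(cls75$trunk_covered_mm, 75)
  expect_true(cls75$trunk_accurate)
  # two 45 mm runs with a gap: 90% total coverage but continuity violated
  tsplit <- make_tube_volume(100, cover_ranges = list(c(0, 44), c(55, 99)))
  expect_false(classify_vessel(tsplit$tree, tsplit$volume)$trunk_accurate)
  # trunk-only vessels report branches as not applicable
  expect_true(is.na(classify_vessel(t80$tree, t80$volume)$branches_accurate))
})

test_that("classification of the ground truth is all-accurate for every phantom vessel", {
  ph <- test_phantom()
  for (tree in ph$trees) {
    cls <- classify_vessel(tree, ph$truth)
    expect_true(cls$trunk_accurate, label = paste(tree$vessel, "trunk"))
    if (length(tree$branches) > 0)
      expect_true(cls$branches_accurate,
                  label = paste(tree$vessel, "branches"))
  }
  expect_error(
    classify_vessel(structure(list(vessel = "XYZ"), class = "vessel_tree"),
                    ph$truth),
    "unknown vessel label")
})

test_that("enlarging the prediction never flips an accurate flag off", {
  ph <- test_phantom()
  pred <- test_prediction()
  grown <- pred$grid
  # grow every vessel label by writing it into adjacent background voxels
  for (v in c(hepatic_vein_names(), portal_vein_names())) {
    m <- structure_mask(pred, v)
    dil <- m
    dil[-1, , ] <- dil[-1, , ] | m[-dim(m)[1], , ]
    dil[, -1, ] <- dil[, -1, ] | m[, -dim(m)[2], ]
    grown[dil & grown == 0L] <- pred$label_map[[v]]
  }
  vol_grown <- label_volume(grown, pred$spacing, pred$label_map)
  for (tree in ph$trees) {
    before <- classify_vessel(tree, pred)
    after <- classify_vessel(tree, vol_grown)
    if (isTRUE(before$trunk_accurate)) expect_true(after$trunk_accurate)
    if (isTRUE(before$branches_accurate))
      expect_true(after$branches_accurate)
  }
})

test_that("centerline extraction recovers tube axes within tolerance", {
  # axis-aligned 40 mm cylinder
  tube <- make_tube_volume(len_mm = 40, radius = 3)
  mask <- structure_mask(tube$volume, "MPV")
  cl <- extract_centerline(mask, tube$volume$spacing)
  expect_gte(centerline_length(cl), 36)
  expect_lte(centerline_length(cl), 44)

  # curved tube grown from a known polyline
  region <- array(TRUE, c(70, 50, 50))
  out <- generate_vessel_tree(region, c(1, 1, 1), root = c(10, 25, 25),
                              direction = c(1, 0.2, 0),
                              params = vessel_params(radius = 3, length = 45,
                                                     n_branches = 0,
                                                     curvature = 0.15),
                              seed = 5)
  cl2 <- extract_centerline(out$mask, c(1, 1, 1))
  truth_len <- centerline_length(out$tree$trunk)
  expect_lt(abs(centerline_length(cl2) - truth_len), 0.1 * truth_len)

  # degenerate and pathological masks are rejected
  tiny <- array(FALSE, c(10, 10, 10)); tiny[5, 5, 5:6] <- TRUE
  expect_error(extract_centerline(tiny, c(1, 1, 1)), "degenerate")
  two <- array(FALSE, c(20, 10, 10))
  two[2:5, 4:6, 4:6] <- TRUE; two[14:18, 4:6, 4:6] <- TRUE
  expect_error(extract_centerline(two, c(1, 1, 1)), "connected")
  branched <- structure_mask(make_tube_volume(40, radius = 2)$volume, "MPV")
  branched[30:31, 10:20, 10:11] <- TRUE  # perpendicular arm
  expect_error(extract_centerline(branched, c(1, 1, 1)), "branched")
})

test_that("accuracy table reproduces worked percentages with Wald intervals", {
  results <- tibble::tibble(
    vessel = rep(c("RHV", "LPV"), each = 178),
    trunk_accurate = c(rep(TRUE, 176), rep(FALSE, 2),
                       rep(TRUE, 145), rep(FALSE, 33)),
    branches_accurate = c(rep(TRUE, 178), rep(TRUE, 145), rep(FALSE, 33))
  )
  tab <- accuracy_table(results)
  rhv <- tab[tab$vessel == "RHV" & tab$measure == "trunk", ]
  expect_equal(round(rhv$accuracy_pct, 2), 98.88)
  expect_equal(rhv$ci_high, 100)
  lpv <- tab[tab$vessel == "LPV" & tab$measure == "trunk", ]
  expect_equal(round(lpv$accuracy_pct, 2), 81.46)

  zero <- accuracy_table(tibble::tibble(vessel = "MPV",
                                        trunk_accurate = rep(FALSE, 5),
                                        branches_accurate = NA))
  ztr <- zero[zero$measure == "trunk", ]
  expect_equal(ztr$accuracy_pct, 0)
  expect_equal(ztr$ci_low, 0)
  zbr <- zero[zero$measure == "branches", ]
  expect_true(is.na(zbr$accuracy_pct))
  expect_error(accuracy_table(tibble::tibble()), "empty")
})
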