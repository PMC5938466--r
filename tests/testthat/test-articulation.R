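# The articulation standardization procedures.

single_pair <- make_articulated_pair(n_specimens = 4, joint_type = "single",
                                     seed = 101)
double_pair <- make_articulated_pair(n_specimens = 4, joint_type = "double",
                                     seed = 102)

run_simple <- function(pair, angle) {
  simple_rotation(pair$structure1, pair$structure2,
                  land.a = 1, land.b = 2, land.c = 3,
                  land.d = 1, land.e = 2, land.f = 3, angle = angle)
}
run_double <- function(pair, angle) {
  double_rotation(pair$structure1, pair$structure2,
                  land.a = 1, land.b = 2, land.c = 3, land.d = 4,
                  land.e = 1, land.f = 2, land.g = 3, land.h = 4, angle = angle)
}

test_that("single-point standardization places both axes at the target angle", {
  for (target in c(0, 30, 45, 90, 135, 180)) {
    j <- run_simple(single_pair, target)
    parts <- split_joined(j)
    measured <- inter_axis_angle(parts$structure1, parts$structure2, 1, 2, 1, 2)
    expect_lt(max(abs(measured - target)), 1e-6)
    for (i in seq_len(dim(j)[3])) {
      m1 <- parts$structure1[, , i]
      # structure 1: articulation at the origin, axis on (1,0,0),
      # orientation landmark in the xy-plane at positive y
      expect_lt(max(abs(m1[1, ])), 1e-9)
      expect_lt(abs(vector_angle(m1[2, ], c(1, 0, 0))), 1e-9)
      expect_lt(abs(m1[3, 3]), 1e-9)
      expect_gt(m1[3, 2], 0)
      # structure 2: axis along the angle's unit vector
      a2 <- parts$structure2[2, , i]
      expect_lt(max(abs(a2 / sqrt(sum(a2^2)) - vector_from_angle(target))), 1e-9)
    }
  }
})

test_that("double-point standardization places both axes at the target angle", {
  for (target in c(0, 45, 90, 135, 180)) {
    rot <- run_double(double_pair, target)
    measured <- inter_axis_angle(rot$rotated1, rot$rotated2, 1, 2, 1, 2)
    expect_lt(max(abs(measured - target)), 1e-6)
    # torsion removed: orientation landmark of each structure in the
    # articulation plane
    for (i in seq_len(dim(rot$rotated1)[3])) {
      expect_lt(abs(rot$rotated1[3, 3, i]), 1e-9)
      expect_lt(abs(rot$rotated2[3, 3, i]), 1e-9)
    }
  }
  # target 0: axes parallel
  rot0 <- run_double(double_pair, 0)
  expect_lt(max(inter_axis_angle(rot0$rotated1, rot0$rotated2, 1, 2, 1, 2)), 1e-6)
})

test_that("standardization is invariant under random per-structure rigid motions", {
  ref_simple <- run_simple(single_pair, 90)
  ref_double <- run_double(double_pair, 45)
  set.seed(200)
  for (k in 1:50) {
    mangled <- single_pair
    mangled$structure1 <- apply_random_rigid(mangled$structure1)
    mangled$structure2 <- apply_random_rigid(mangled$structure2)
    expect_lt(max(abs(run_simple(mangled, 90) - ref_simple)), 1e-6)

    mangled <- double_pair
    mangled$structure1 <- apply_random_rigid(mangled$structure1)
    mangled$structure2 <- apply_random_rigid(mangled$structure2)
    out <- run_double(mangled, 45)
    expect_lt(max(abs(out$rotated1 - ref_double$rotated1)), 1e-6)
    expect_lt(max(abs(out$rotated2 - ref_double$rotated2)), 1e-6)
  }
})

test_that("standardizing an already-standardized pair is the identity", {
  j <- run_simple(single_pair, 90)
  parts <- split_joined(j)
  again <- simple_rotation(parts$structure1, parts$structure2,
                           1, 2, 3, 1, 2, 3, angle = 90)
  expect_lt(max(abs(again - j)), 1e-9)

  rot <- run_double(double_pair, 45)
  again2 <- double_rotation(rot$rotated1, rot$rotated2,
                            1, 2, 3, 4, 1, 2, 3, 4, angle = 45)
  expect_lt(max(abs(again2$rotated1 - rot$rotated1)), 1e-9)
  expect_lt(max(abs(again2$rotated2 - rot$rotated2)), 1e-9)
})

test_that("standardization preserves per-structure shape and handedness", {
  j <- run_simple(single_pair, 135)
  parts <- split_joined(j)
  for (i in seq_len(dim(j)[3])) {
    for (s in 1:2) {
      before <- matrix(single_pair[[paste0("structure", s)]][, , i], ncol = 3)
      after <- matrix(parts[[paste0("structure", s)]][, , i], ncol = 3)
      expect_lt(max(abs(pairwise_dists(after) - pairwise_dists(before))), 1e-9)
      expect_identical(vol_signs(after), vol_signs(before))
    }
  }
})

test_that("specimens missing from either structure are dropped with a warning", {
  d1 <- single_pair$structure1
  d2 <- single_pair$structure2[, , 1:3, drop = FALSE]
  expect_warning(j <- run_simple(list(structure1 = d1, structure2 = d2), 90),
                 class = "artirot_dropped_specimens")
  expect_identical(dimnames(j)[[3]], dimnames(d2)[[3]])
  # shared specimens standardized identically to the full run
  full <- run_simple(single_pair, 90)
  expect_lt(max(abs(j - full[, , 1:3])), 1e-12)
})

test_that("degenerate role landmarks raise errors naming the specimen", {
  broken <- single_pair
  broken$structure1[2, , 2] <- broken$structure1[1, , 2]  # axis pair coincides
  expect_error(suppressWarnings(run_simple(broken, 90)),
               "spec_02", class = "artirot_degenerate")

  broken2 <- single_pair
  m <- matrix(broken2$structure1[, , 3], ncol = 3)
  m[3, ] <- m[1, ] + 2 * (m[2, ] - m[1, ])               # orient on the axis
  broken2$structure1[, , 3] <- m
  expect_error(suppressWarnings(run_simple(broken2, 90)),
               "spec_03", class = "artirot_degenerate")
})

test_that("a mirror-digitized specimen raises a reflection error, never a silent fix", {
  reflected <- double_pair
  reflected$structure2[, 3, 2] <- -reflected$structure2[, 3, 2]
  expect_error(run_double(reflected, 45), "spec_02", class = "artirot_reflection")
})

test_that("quality screening flags fragile role choices and passes clean data", {
  spec <- articulation_spec(1:3, 1:3, 90)
  clean <- check_landmark_quality(single_pair$structure1, single_pair$structure2,
                                  spec)
  expect_identical(nrow(clean), 0L)
  dev <- attr(clean, "shared_coordinate_deviation")
  expect_identical(dim(dev), c(4L, 2L))
  expect_true(all(is.finite(dev)))

  collinear <- single_pair$structure1
  m <- matrix(collinear[, , 1], ncol = 3)
  m[3, ] <- m[1, ] + 0.25 * (m[2, ] - m[1, ])
  collinear[, , 1] <- m
  expect_warning(rep1 <- check_landmark_quality(collinear, single_pair$structure2,
                                                spec),
                 class = "artirot_quality")
  expect_identical(rep1$flag, "collinear_roles")
  expect_identical(rep1$specimen, "spec_01")

  coincident <- single_pair$structure1
  coincident[2, , 2] <- coincident[1, , 2]
  rep2 <- check_landmark_quality(coincident, single_pair$structure2, spec,
                                 warn = FALSE)
  expect_identical(rep2$flag, "coincident_axis_pair")
})

test_that("mirror correction puts the orientation landmark on the canonical side", {
  # diametrically opposite orientation landmark: a half-turn about the axis
  pts <- matrix(c(0, 0, 0,
                  2, 0, 0,
                  1, -0.8, 0,
                  0.5, 0.1, 0.4), ncol = 3, byrow = TRUE)
  out <- mirror_correct(pts, c(1, 0, 0), 3)
  expect_equal(unname(out[3, ]), c(1, 0.8, 0))
  expect_lt(max(abs(pairwise_dists(out) - pairwise_dists(pts))), 1e-9)

  # orientation landmark already on the positive side: identity
  ok <- pts; ok[3, 2] <- 0.8
  expect_equal(mirror_correct(ok, c(1, 0, 0), 3), ok)

  set.seed(201)
  for (k in 1:50) {
    m <- matrix(rnorm(24), ncol = 3)
    out <- mirror_correct(m, c(1, 0, 0), 5)
    expect_lt(abs(out[5, 3]), 1e-9 * max(1, abs(out[5, 2])))
    expect_gt(out[5, 2], 0)
    expect_lt(max(abs(pairwise_dists(out) - pairwise_dists(m))), 1e-9)
    expect_identical(vol_signs(out), vol_signs(m))
  }
})

test_that("post-rotation offsets displace a structure without deforming it", {
  rot <- run_double(double_pair, 45)
  moved <- offset_structure(rot$rotated2, 1, c(1.7, 0.1, 0))
  for (i in seq_len(dim(moved)[3])) {
    expect_equal(unname(moved[1, , i] - rot$rotated2[1, , i]), c(1.7, 0.1, 0))
    expect_lt(max(abs(pairwise_dists(matrix(moved[, , i], ncol = 3)) -
                        pairwise_dists(matrix(rot$rotated2[, , i], ncol = 3)))),
              1e-9)
  }
  expect_equal(offset_structure(rot$rotated2, 1, c(0, 0, 0)), rot$rotated2)
  expect_error(offset_structure(rot$rotated2, 99, c(1, 0, 0)),
               class = "artirot_index")

  # the offset structures can still be joined for export
  j <- join_arrays(rot$rotated1, moved)
  expect_identical(dim(j)[1], dim(rot$rotated1)[1] + dim(moved)[1])
})
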