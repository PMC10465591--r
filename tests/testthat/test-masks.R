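straight_tube <- function(x_to = 9, spacing = 0.5, radius = 0.75) {
  cv <- canal_curve(cbind(c(0, x_to), 0, 0))
  grid <- grid_for_curves(cv, spacing)
  list(curve = cv, mask = voxelize_tube(cv, grid, radius))
}

test_that("voxelize_tube foreground equals the exhaustive distance test", {
  tb <- straight_tube()
  want <- oracle_tube_mask(tb$curve$points, dim(tb$mask$values),
                           tb$mask$spacing, tb$mask$origin, 0.75)
  expect_identical(tb$mask$values, want)
  # the definitional invariant, spelled out for every voxel centre
  idx <- as.matrix(expand.grid(i = seq_len(dim(want)[1]) - 1,
                               j = seq_len(dim(want)[2]) - 1,
                               k = seq_len(dim(want)[3]) - 1))
  ctr <- sweep(idx %*% diag(tb$mask$spacing), 2, tb$mask$origin, `+`)
  d <- apply(ctr, 1, oracle_pt_polyline, verts = tb$curve$points)
  expect_true(all((d <= 0.75) == tb$mask$values[idx + 1]))
})

test_that("voxel centres the curve passes through are foreground", {
  cv <- canal_curve(cbind(c(0, 4), 0, 0))
  grid <- voxel_mask(array(FALSE, c(9, 5, 5)), spacing = c(0.5, 0.5, 0.5),
                     origin = c(0, -1, -1))
  m <- voxelize_tube(cv, grid, 0.75)
  on_axis <- cbind(0:8, 2, 2)  # centres at y = z = 0
  expect_true(all(m$values[on_axis + 1]))
})

test_that("a curve outside the grid is signalled, not silently empty", {
  cv <- canal_curve(cbind(c(100, 110), 0, 0))
  grid <- voxel_mask(array(FALSE, c(5, 5, 5)), spacing = rep(1, 3))
  expect_error(voxelize_tube(cv, grid), "outside the grid")
})

test_that("dsc follows the overlap formula and its edge cases", {
  sp <- rep(0.5, 3)
  a <- voxel_mask(array(FALSE, c(8, 8, 8)), sp)
  b <- a
  a$values[1:5, 1:5, 1:2] <- TRUE       # |A| = 50
  b$values[1:5, 1:5, 1:4] <- TRUE       # |B| = 100, A subset of B
  expect_equal(dsc(a, b), 100 / 150)
  expect_equal(dsc(b, a), dsc(a, b))
  expect_equal(dsc(a, a), 1)
  disj <- voxel_mask(array(FALSE, c(8, 8, 8)), sp)
  disj$values[7:8, 7:8, 7:8] <- TRUE
  expect_equal(dsc(a, disj), 0)
  empty <- voxel_mask(array(FALSE, c(8, 8, 8)), sp)
  expect_error(dsc(empty, empty), "empty")
  expect_error(dsc(a, voxel_mask(array(TRUE, c(4, 4, 4)), sp)), "grid")
})

test_that("dsc decreases monotonically as one tube translates away", {
  cv <- canal_curve(cbind(c(2, 14), 8, 8))
  grid <- voxel_mask(array(FALSE, c(33, 33, 33)), spacing = rep(0.5, 3))
  ref <- voxelize_tube(cv, grid, 0.75)
  vals <- sapply(seq(0, 4, by = 0.5), function(dy) {
    shifted <- canal_curve(sweep(cv$points, 2, c(0, dy, 0), `+`))
    dsc(ref, voxelize_tube(shifted, grid, 0.75))
  })
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[1], 1)
  expect_equal(vals[length(vals)], 0)
})

test_that("assd matches the exhaustive all-pairs surface oracle", {
  expect_equal(assd(straight_tube()$mask, straight_tube()$mask), 0)
  sp <- c(0.4, 0.4, 0.4)
  a <- voxel_mask(array(FALSE, c(6, 4, 4)), sp)
  b <- a
  a$values[2, 2, 2] <- TRUE
  b$values[3, 2, 2] <- TRUE
  expect_equal(assd(a, b), 0.4)
  set.seed(13)
  for (rep in 1:3) {
    va <- array(FALSE, c(20, 20, 20)); vb <- va
    ca <- sample(5:15, 3); cb <- sample(5:15, 3)
    for (i in 1:20) for (j in 1:20) for (k in 1:20) {
      va[i, j, k] <- sum((c(i, j, k) - ca)^2) <= 9
      vb[i, j, k] <- sum((c(i, j, k) - cb)^2) <= 16
    }
    sp2 <- c(0.3, 0.4, 0.5)
    ma <- voxel_mask(va, sp2); mb <- voxel_mask(vb, sp2)
    expect_equal(assd(ma, mb), oracle_assd(va, vb, sp2, c(0, 0, 0)))
    expect_equal(assd(ma, mb), assd(mb, ma))
  }
  empty <- voxel_mask(array(FALSE, c(6, 4, 4)), c(0.4, 0.4, 0.4))
  expect_error(assd(a, empty), "non-empty")
})

test_that("dsc and assd are symmetric on random voxelized tube pairs", {
  set.seed(19)
  grid <- voxel_mask(array(FALSE, c(30, 24, 24)), spacing = rep(0.5, 3),
                     origin = c(-1, -4, -4))
  for (rep in 1:10) {
    va <- rand_polyline(5); vb <- rand_polyline(5)
    ma <- voxelize_tube(canal_curve(va), grid)
    mb <- voxelize_tube(canal_curve(vb), grid)
    expect_identical(dsc(ma, mb), dsc(mb, ma))
    expect_identical(assd(ma, mb), assd(mb, ma))
  }
})

test_that("smcd and assd survive a shared rigid motion of both inputs", {
  set.seed(23)
  va <- rand_polyline(6); vb <- rand_polyline(6)
  ta <- rigid_transform(va); tb <- rigid_transform(vb)
  # curves: analytic invariance
  expect_equal(smcd(canal_curve(ta), canal_curve(tb)),
               smcd(canal_curve(va), canal_curve(vb)), tolerance = 1e-6)
  # masks re-voxelized from the transformed curves: invariance within one
  # voxel spacing
  sp <- 0.5
  g1 <- grid_for_curves(list(canal_curve(va), canal_curve(vb)), sp)
  g2 <- grid_for_curves(list(canal_curve(ta), canal_curve(tb)), sp)
  a1 <- assd(voxelize_tube(canal_curve(va), g1),
             voxelize_tube(canal_curve(vb), g1))
  a2 <- assd(voxelize_tube(canal_curve(ta), g2),
             voxelize_tube(canal_curve(tb), g2))
  expect_lt(abs(a1 - a2), sp)
})

test_that("nifti mask round-trip preserves grid and voxels", {
  tb <- straight_tube()
  path <- tempfile(fileext = ".nii.gz")
  write_mask(tb$mask, path)
  back <- read_mask(path)
  expect_identical(back$values, tb$mask$values)
  expect_equal(back$spacing, tb$mask$spacing)
  expect_equal(back$origin, tb$mask$origin)
  unlink(path)
})
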