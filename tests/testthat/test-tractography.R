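test_that("tensor-deflection step follows the blend formula", {
  p1 <- tracking_params(tend_f = 1)
  D <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  v <- c(sqrt(2) / 2, sqrt(2) / 2, 0)
  ## f = 1: pure eigenvector following, sign-aligned with the input
  out <- tend_step(v, D, p1)
  expect_equal(out, c(1, 0, 0), tolerance = 1e-12)
  out <- tend_step(-v, D, p1)
  expect_equal(out, c(-1, 0, 0), tolerance = 1e-12)

  ## isotropic tensor with tend_f = "fa" (FA = 0 so f = 0) and g = 1:
  ## Dhat is proportional to the identity, so the step returns v unchanged
  pfa <- tracking_params(tend_f = "fa", tend_g = 1)
  expect_equal(tend_step(v, diag(rep(1e-3, 3)), pfa), v, tolerance = 1e-12)

  ## f = 0.5, g = 1: independent step-by-step evaluation of the blend
  p5 <- tracking_params(tend_f = 0.5, tend_g = 1)
  out <- tend_step(v, D, p5)
  e1 <- c(1, 0, 0)
  Dhat <- D / 1.7e-3
  defl <- drop(Dhat %*% v); defl <- defl / sqrt(sum(defl^2))
  ref <- 0.5 * e1 + 0.5 * defl; ref <- ref / sqrt(sum(ref^2))
  expect_equal(out, ref, tolerance = 1e-12)

  ## degenerate inputs
  expect_equal(tend_step(v, matrix(0, 3, 3), p5), v)
  expect_error(tend_step(c(0, 0, 0), D, p5), "zero")
})

## build a uniform straight-z field on a small grid
uniform_field <- function(n = 15L, voxel = 2, fa = 0.7) {
  g <- vox_grid(rep(n, 3L), voxel)
  sp <- bundle_spec("z", rbind(g$origin + c(n, n, 0.2) * voxel / 2,
                               g$origin + c(n, n, 2 * n - 0.2) * voxel / 2),
                    radius = n * voxel, fa_target = fa)
  make_tensor_field(list(sp), g)
}

test_that("streamline propagation spans a uniform field and stops at bounds", {
  tf <- uniform_field()
  p <- tracking_params(min_length_mm = 5, max_length_mm = 500, step_mm = 1)
  sl <- propagate_streamline(c(0, 0, 0), tf, p)
  expect_identical(unname(sl$stop_reasons), c("bounds", "bounds"))
  ## spans the grid along z, straight
  expect_lt(max(abs(sl$points[, 1:2])), 1e-9)
  expect_gt(diff(range(sl$points[, 3])), 26)
  ## consecutive spacing equals step_mm within 1e-6
  seg <- sqrt(rowSums(diff(sl$points)^2))
  expect_true(all(abs(seg - p$step_mm) < 1e-6))
  expect_error(propagate_streamline(c(1e4, 0, 0), tf, p), "seed error")
})

test_that("propagation terminates on the angle rule at an orientation interface", {
  ## orientation rotates 30 degrees (in-plane) across the plane x = 0;
  ## propagation runs along +x so the streamline meets the interface head-on
  g <- vox_grid(c(16, 16, 16), 2)
  nv <- fourtract:::n_voxels(g)
  co <- fourtract:::grid_coords(g)
  th <- ifelse(co[, 1] < 0, 0, 30) * pi / 180
  lam <- fourtract:::axial_eigenvalues(0.7, 0.8e-3)
  lower <- matrix(0, nv, 6)
  tx <- cos(th); ty <- sin(th)
  dpar <- lam[, "par"] - lam[, "perp"]
  lower[, 1] <- lam[, "perp"] + dpar * tx^2
  lower[, 2] <- lam[, "perp"] + dpar * ty^2
  lower[, 3] <- lam[, "perp"]
  lower[, 4] <- dpar * tx * ty
  tf <- tensor_field(lower, g)
  p <- tracking_params(max_angle_deg = 20, min_length_mm = 5,
                       max_length_mm = 500)
  sl <- propagate_streamline(c(-9, 0, 0), tf, p)
  expect_true("angle" %in% sl$stop_reasons)
  ## the angle stop occurs within one step of the x = 0 interface
  end_x <- sl$points[c(1, nrow(sl$points)), 1]
  expect_true(any(abs(end_x) <= 1 + p$step_mm))
  ## at 50 degrees allowed, the same field is traversed
  sl2 <- propagate_streamline(c(-9, 0, 0), tf,
                              tracking_params(max_angle_deg = 50,
                                              min_length_mm = 5,
                                              max_length_mm = 500))
  expect_false("angle" %in% sl2$stop_reasons)
})

test_that("propagation terminates on the FA rule at an anisotropy step", {
  ## FA drops from 0.7 to 0.1 across the plane z = 10
  g <- vox_grid(c(12, 12, 24), 2)
  nv <- fourtract:::n_voxels(g)
  co <- fourtract:::grid_coords(g)
  fa_here <- ifelse(co[, 3] < 10, 0.7, 0.1)
  lam <- fourtract:::axial_eigenvalues(fa_here, 0.8e-3)
  lower <- matrix(0, nv, 6)
  lower[, 1] <- lam[, "perp"]
  lower[, 2] <- lam[, "perp"]
  lower[, 3] <- lam[, "par"]
  tf <- tensor_field(lower, g)
  p <- tracking_params(fa_min = 0.2, min_length_mm = 5, max_length_mm = 500)
  sl <- propagate_streamline(c(0, 0, -5), tf, p)
  expect_true("fa" %in% sl$stop_reasons)
  expect_lt(max(sl$points[, 3]), 10 + p$step_mm)
})

test_that("ROI-filtered tracking retains what it should", {
  ph <- get_phantom()
  p <- tracking_params()
  ## include ROI off-bundle: empty bundle, not an error
  off <- fourtract:::sphere_mask(ph$grid, c(-80, 80, 0), 5)
  b <- track_with_rois(ph$field, ph$masks$precentral, list(off), p)
  expect_s3_class(b, "bundle")
  expect_length(b$streamlines, 0)
  ## min length beyond any track: empty
  p_long <- tracking_params(min_length_mm = 240, max_length_mm = 250)
  b <- track_with_rois(ph$field, ph$masks$precentral,
                       list(ph$masks$cerebral_peduncle), p_long)
  expect_length(b$streamlines, 0)
  expect_error(track_with_rois(ph$field, array(FALSE, ph$grid$shape), list(), p),
               "ROI error")
  ## determinism: identical inputs give identical bundles
  b1 <- track_with_rois(ph$field, ph$masks$dentate_right,
                        list(ph$masks$red_nucleus_left), p)
  b2 <- track_with_rois(ph$field, ph$masks$dentate_right,
                        list(ph$masks$red_nucleus_left), p)
  expect_identical(b1$streamlines, b2$streamlines)
})

test_that("phantom CST tracks within one voxel of the ground truth", {
  ph <- get_phantom()
  cst <- get_bundles()$CST
  expect_gt(length(cst), 0)
  md <- vapply(cst$streamlines,
               function(s) mean(min_dist_to_points(s$points, ph$centerlines$CST)),
               0)
  expect_gte(mean(md < 2.5), 0.9)
})

test_that("retained streamlines obey the active parameter set", {
  for (p in list(tracking_params(), fallback_params())) {
    bs <- track_four(get_phantom()$field, get_phantom()$masks, params = p)
    cos_max <- cos(p$max_angle_deg * pi / 180)
    for (b in bs) for (s in b$streamlines) {
      len <- sum(sqrt(rowSums(diff(s$points)^2)))
      expect_gte(len, p$min_length_mm)
      expect_lte(len, p$max_length_mm)
      d <- diff(s$points)
      d <- d / sqrt(rowSums(d^2))
      if (nrow(d) > 1) {
        turn <- rowSums(d[-1, , drop = FALSE] * d[-nrow(d), , drop = FALSE])
        expect_gte(min(turn), cos_max - 1e-9)
      }
    }
  }
})

test_that("with f = 1 the tracker equals plain eigenvector streamlining", {
  ph <- get_phantom()
  p <- tracking_params(tend_f = 1, min_length_mm = 5)
  seeds <- rbind(c(13.75, -43.75, -41.25), c(-13.75, -43.75, -41.25),
                 c(23.75, -6.25, 58.75), c(21.25, -18.75, 58.75),
                 c(8.5, -9, -20), c(12, -4.6, 3))
  for (i in seq_len(nrow(seeds))) {
    sl <- propagate_streamline(seeds[i, ], ph$field, p)
    ref <- ref_e1_track(seeds[i, ], ph$field, p)
    expect_equal(dim(sl$points), dim(ref))
    expect_lt(max(abs(sl$points - ref)), 1e-9)
  }
})
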