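test_that("AC-PC frame construction, inversion, and rigid-motion invariance", {
  fr <- acpc_frame(c(0, 13, 0), c(0, -13, 0), c(0, 0, 40))
  expect_equal(fr$mcp, c(0, 0, 0))
  expect_equal(fr$acpc_length, 26)
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## A axis points from PC toward AC
  expect_equal(drop(fr$axes["A", ]), c(0, 1, 0))

  ## world -> ACPC -> world round trip
  set.seed(3)
  pts <- matrix(rnorm(300, sd = 30), 100, 3)
  back <- acpc_to_world(fr, world_to_acpc(fr, pts))
  expect_lt(max(abs(back - pts)), 1e-12)

  ## ACPC coordinates are invariant under a rigid motion of everything
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    tr <- rnorm(3, sd = 50)
    mv <- function(p) t(q %*% t(rbind(p)) + tr)
    fr2 <- acpc_frame(drop(mv(c(0, 13, 0))), drop(mv(c(0, -13, 0))),
                      drop(mv(c(0, 0, 40))))
    expect_lt(max(abs(world_to_acpc(fr2, mv(pts)) - world_to_acpc(fr, pts))),
              1e-9)
  }
  expect_error(acpc_frame(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)), "geometry")
  expect_error(acpc_frame(c(0, 13, 0), c(0, -13, 0), c(0, 5, 0)), "geometry")
})

test_that("indirect target follows the landmark formula and ventricle rule", {
  fr <- acpc_frame(c(0, 13, 0), c(0, -13, 0), c(0, 0, 40))
  t1 <- indirect_target(fr)
  expect_equal(c(t1$L, t1$A, t1$S), c(14, 6.5, 2))
  fr28 <- acpc_frame(c(0, 14, 0), c(0, -14, 0), c(0, 0, 40))
  expect_equal(indirect_target(fr28)$A, 7.0)
  ## enlarged ventricle: 10.5 mm (midpoint of 10-11) lateral to the wall
  expect_equal(indirect_target(fr, ventricle_wall_L = 5.0)$L, 15.5)
  ## the rule only ever widens L
  expect_equal(indirect_target(fr, ventricle_wall_L = 2.0)$L, 14)
})

## straight vertical test bundle at (L0, A0) in frame coordinates
straight_bundle <- function(name, L0, A0, z = seq(-10, 10, by = 1),
                            frame = acpc_frame(c(0, 13, 0), c(0, -13, 0),
                                               c(0, 0, 40))) {
  pts <- acpc_to_world(frame, cbind(L0, A0, z))
  bundle(name, list(structure(list(points = pts,
                                   stop_reasons = c(NA, NA)),
                              class = "streamline")))
}

test_that("confluence target: overlap, separation, and posterior selection", {
  fr <- acpc_frame(c(0, 13, 0), c(0, -13, 0), c(0, 0, 40))
  ## identical straight bundles: target at the in-plane centroid
  b1 <- straight_bundle("dDRTT", 13, 6)
  b2 <- straight_bundle("ndDRTT", 13, 6)
  tg <- confluence_target(b1, b2, fr, s_offset = 2)
  expect_equal(c(tg$L, tg$A, tg$S), c(13, 6, 2), tolerance = 0.51)
  ## parallel bundles 10 mm apart: confluence error
  expect_error(confluence_target(b1, straight_bundle("ndDRTT", 13, 16), fr, 2),
               "confluence error")
  ## a small gap (<= 2 mm) falls back to the closest-approach midpoint
  tg_gap <- confluence_target(b1, straight_bundle("ndDRTT", 13, 7.8), fr, 2)
  expect_equal(tg_gap$A, 6.9, tolerance = 0.3)
  ## empty slab: bundle entirely below the slab
  b_low <- straight_bundle("ndDRTT", 13, 6, z = seq(-10, -5))
  expect_error(confluence_target(b1, b_low, fr, 2), "confluence error")
})

test_that("phantom confluence is the most posterior intersection component", {
  bs <- get_bundles()
  fr <- get_frame()
  for (s_off in c(2, 4)) {
    tg <- confluence_target(bs$dDRTT, bs$ndDRTT, fr, s_offset = s_off)
    fp <- attr(tg, "footprint")
    expect_true(fourtract:::point_in_footprint(fp, tg$L, tg$A))
    ## exhaustive audit over labelled components: the returned target has
    ## the smallest centroid A
    if (!is.null(fp$components) && length(unique(fp$components[fp$components > 0])) > 1) {
      expect_true(all(tg$A <= fp$centroids[, "A"] + 1e-9))
    }
    ## target lies inside each bundle's own dilated slab footprint
    for (b in list(bs$dDRTT, bs$ndDRTT)) {
      pts <- world_to_acpc(fr, fourtract:::bundle_points(b))
      pts <- pts[abs(pts[, 3] - s_off) <= 0.75, , drop = FALSE]
      expect_lt(min(sqrt((pts[, 1] - tg$L)^2 + (pts[, 2] - tg$A)^2)), 1.5)
    }
  }
})

test_that("margin enforcement shifts candidates away from CST/ML", {
  fr <- acpc_frame(c(0, 13, 0), c(0, -13, 0), c(0, 0, 40))
  cst <- straight_bundle("CST", 20, 6)
  ml <- straight_bundle("ML", 13, -2)
  ## far candidate: unchanged
  r <- enforce_margins(acpc_point(13, 8, 2), cst, ml, fr, margin_mm = 2)
  expect_equal(c(r$target$L, r$target$A), c(13, 8))
  expect_gte(min(r$dist_cst, r$dist_ml), 2)
  ## candidate 1 mm anterior of the ML: pushed anteriorly to >= 2 mm
  r2 <- enforce_margins(acpc_point(13, -1, 2), cst, ml, fr, margin_mm = 2)
  expect_gte(r2$dist_ml, 2)
  expect_gt(r2$target$A, -1)          # shift direction is anterior
  expect_equal(r2$target$L, 13)       # purely in-plane along A
  ## infeasible: everything within 2 mm of the CST
  fp <- list(lattice = list(res = 0.5, L0 = 19, A0 = 5, nL = 5, nA = 5),
             cells = matrix(TRUE, 5, 5))
  expect_error(enforce_margins(acpc_point(20, 6, 2), cst, ml, fr,
                               margin_mm = 2, footprint = fp),
               "margin-infeasible")
})

test_that("target offset reproduces the published worked examples", {
  p <- acpc_point(14, 7.1, 0)
  expect_equal(target_offset(p, p, indirect_s = NULL), 0)
  ## case 1: indirect (14, 7.1) vs first target (13.8, 8.1, 2), indirect S = 2
  expect_equal(round(target_offset(acpc_point(14, 7.1, 0),
                                   acpc_point(13.8, 8.1, 2)), 2), 1.02)
  ## case 12: (14, 6.2) vs (9.7, 6.9, 1.4)
  expect_equal(round(target_offset(acpc_point(14, 6.2, 0),
                                   acpc_point(9.7, 6.9, 1.4)), 2), 4.40)
})

test_that("target offset is a metric when the S override is disabled", {
  set.seed(8)
  for (i in 1:40) {
    a <- acpc_point(rnorm(1, 13), rnorm(1, 7), rnorm(1, 2))
    b <- acpc_point(rnorm(1, 13), rnorm(1, 7), rnorm(1, 2))
    cc <- acpc_point(rnorm(1, 13), rnorm(1, 7), rnorm(1, 2))
    dab <- target_offset(a, b, indirect_s = NULL)
    dba <- target_offset(b, a, indirect_s = NULL)
    expect_equal(dab, dba, tolerance = 1e-12)
    dac <- target_offset(a, cc, indirect_s = NULL)
    dcb <- target_offset(cc, b, indirect_s = NULL)
    expect_lte(dab, dac + dcb + 1e-12)
  }
})

test_that("full plans respect the safety margin on the phantom", {
  bs <- get_bundles()
  fr <- get_frame()
  for (m in c(2, 4)) {
    plan <- make_plan(bs, fr, margin_mm = m)
    expect_s3_class(plan, "target_plan")
    expect_equal(plan$tract_target_1$S, 2)
    expect_equal(plan$tract_target_2$S, 4)
    expect_true(all(plan$margin_report$dist_cst_mm >= m))
    expect_true(all(plan$margin_report$dist_ml_mm >= m))
    expect_gt(plan$offset_mm, 0)
  }
  expect_error(make_plan(bs[c("CST", "dDRTT", "ndDRTT")], fr),
               "configuration error")
  bs_empty <- bs
  bs_empty$ML <- bundle("ML")
  expect_error(make_plan(bs_empty, fr), "configuration error")
})
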