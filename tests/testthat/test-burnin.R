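test_that("voxelization covers streamlines and respects the distance bound", {
  g <- vox_grid(c(20, 20, 20), 1)
  ## empty bundle: empty mask
  bm0 <- voxelize_bundle(bundle("none"), g)
  expect_false(any(bm0$mask))
  ## single straight streamline through voxel centres along z
  pts <- cbind(0.5, 0.5, seq(-8.5, 8.5, by = 1))
  b <- bundle("line", list(structure(list(points = pts,
                                          stop_reasons = c(NA, NA)),
                                     class = "streamline")))
  bm <- voxelize_bundle(b, g)
  hit <- which(bm$mask, arr.ind = TRUE)
  w <- fourtract:::voxel_to_world(g, hit - 1L)
  ## exactly the voxels whose centres are within 0.5 mm of the segment chain
  dmin <- vapply(seq_len(nrow(w)), function(i) {
    min(vapply(seq_len(nrow(pts) - 1L), function(k)
      point_segment_dist(w[i, ], pts[k, ], pts[k + 1L, ]), 0))
  }, 0)
  expect_true(all(dmin <= 0.5 + 1e-9))
  expect_true(all(abs(w[, 1] - 0.5) < 1e-9 & abs(w[, 2] - 0.5) < 1e-9))
  expect_equal(nrow(w), 18L)
})

test_that("phantom bundle masks satisfy the burn-in bounds", {
  bs <- get_bundles()
  dd <- bs$dDRTT
  g1 <- vox_grid(c(70, 110, 110), 1, origin = c(-20, -55, -50))
  bm <- voxelize_bundle(dd, g1)
  ## coverage: every streamline point lies inside the mask
  allp <- fourtract:::bundle_points(dd)
  inside <- fourtract:::in_grid(g1, allp)
  idx <- fourtract:::voxel_linear(g1, fourtract:::nearest_voxel(g1, allp[inside, ]))
  expect_true(all(bm$mask[idx]))
  ## distance audit: no mask voxel centre farther than 0.5 mm + half voxel
  ## diagonal from the bundle (screen with point distances, settle the
  ## borderline voxels with exact point-to-segment distances)
  bound <- 0.5 + fourtract:::half_diagonal(g1)
  centres <- fourtract:::mask_coords(g1, bm$mask)
  dpt <- min_dist_to_points(centres, allp)
  suspicious <- which(dpt > bound)
  for (i in suspicious) {
    dseg <- Inf
    for (s in dd$streamlines) {
      P <- s$points
      for (k in seq_len(nrow(P) - 1L))
        dseg <- min(dseg, point_segment_dist(centres[i, ], P[k, ], P[k + 1L, ]))
    }
    expect_lte(dseg, bound)
  }
})

test_that("mask union is commutative, associative, idempotent", {
  g <- vox_grid(c(10, 10, 10), 1)
  mk <- function(centre) {
    m <- fourtract:::sphere_mask(g, centre, 2)
    structure(list(mask = m, grid = g, source = "s", dilation_mm = 0.5),
              class = "burn_mask")
  }
  a <- mk(c(-2, 0, 0)); b <- mk(c(2, 0, 0)); cc <- mk(c(0, 2, 0))
  expect_identical(mask_union(a, b)$mask, mask_union(b, a)$mask)
  expect_identical(mask_union(mask_union(a, b), cc)$mask,
                   mask_union(a, mask_union(b, cc))$mask)
  expect_identical(mask_union(a, a)$mask, a$mask)
  g2 <- vox_grid(c(10, 10, 10), 2)
  b2 <- mk(c(2, 0, 0)); b2$grid <- g2
  expect_error(mask_union(a, b2), "different grids")
})

test_that("overlay burns a black CST/ML object and a white DRTT contour", {
  g <- vox_grid(c(16, 16, 16), 1)
  anat <- synthetic_anatomy(g)
  mk <- function(centre, r) {
    structure(list(mask = fourtract:::sphere_mask(g, centre, r), grid = g,
                   source = "s", dilation_mm = 0.5), class = "burn_mask")
  }
  empty <- mk(c(100, 100, 100), 1)
  expect_identical(compose_overlay(anat, empty, empty), anat)

  drtt <- mk(c(-3, 0, 0), 3); cstml <- mk(c(4, 2, 0), 2.5)
  ov <- compose_overlay(anat, drtt, cstml)
  ## off-mask voxels untouched
  off <- !(drtt$mask | cstml$mask)
  expect_identical(ov[off], anat[off])
  ## black fill and white contour at the volume extremes
  expect_true(all(ov[cstml$mask & !drtt$mask] %in%
                    c(min(anat), max(anat))))
  ## independent set-algebra oracle for the 6-connected surface
  surf_oracle <- drtt$mask & !{
    m <- drtt$mask
    er <- array(TRUE, dim(m))
    for (ax in 1:3) for (dirn in c(-1, 1)) {
      shifted <- array(FALSE, dim(m))
      src <- dst <- list(1:16, 1:16, 1:16)
      dst[[ax]] <- if (dirn == 1) 2:16 else 1:15
      src[[ax]] <- if (dirn == 1) 1:15 else 2:16
      shifted[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      er <- er & shifted
    }
    er
  }
  expect_true(all(ov[surf_oracle] == max(anat)))
  inner <- drtt$mask & !surf_oracle & !cstml$mask
  expect_identical(ov[inner], anat[inner])
  bad <- mk(c(0, 0, 0), 2); bad$grid <- vox_grid(c(16, 16, 16), 2)
  expect_error(compose_overlay(anat, drtt, bad), "different grids")
})
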