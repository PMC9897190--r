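## Shared fixtures, built once per test run. The default phantom, its DWI,
## the log-linear refit and the four tracked bundles are used across many
## tests; building them here keeps the suite well inside its time budget.

ph_cache <- new.env(parent = emptyenv())

get_phantom <- function(variant = "default") {
  key <- paste0("ph_", variant)
  if (is.null(ph_cache[[key]]))
    ph_cache[[key]] <- phantom_four_tract(variant)
  ph_cache[[key]]
}

get_dwi <- function() {
  if (is.null(ph_cache$dwi))
    ph_cache$dwi <- synthesize_dwi(get_phantom()$field, dwi_protocol())
  ph_cache$dwi
}

get_fit <- function() {
  if (is.null(ph_cache$fit))
    ph_cache$fit <- fit_tensor_loglinear(get_dwi())
  ph_cache$fit
}

get_bundles <- function() {
  if (is.null(ph_cache$bundles))
    ph_cache$bundles <- track_four(get_phantom()$field, get_phantom()$masks)
  ph_cache$bundles
}

get_frame <- function() {
  lm <- get_phantom()$landmarks
  acpc_frame(lm$ac, lm$pc, lm$midline, side = "left")
}

## a small 3-bundle-free grid for cheap unit tests
small_grid <- function(n = 12L, voxel = 2) vox_grid(rep(n, 3L), voxel)

## minimum distance from each row of P to the polyline points cl
min_dist_to_points <- function(P, cl) {
  vapply(seq_len(nrow(P)), function(i) {
    sqrt(min((cl[, 1] - P[i, 1])^2 + (cl[, 2] - P[i, 2])^2 +
             (cl[, 3] - P[i, 3])^2))
  }, 0)
}

## exact point-to-segment distance from point p to segment (a, b)
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

## independent plain principal-eigenvector streamline follower (oracle for
## tensor-deflection tracking with f = 1): nearest-neighbour lookup, fixed
## Euler step, same stopping rules, written without tend_step/propagate
ref_e1_track <- function(seed, field, params) {
  grid <- field$grid
  pdm <- field$principal_dir
  fav <- as.vector(field$fa)
  look <- function(pos) {
    ijk <- round((pos - grid$origin) / grid$voxel)
    if (any(ijk < 0) || any(ijk >= grid$shape)) return(NA_integer_)
    1 + ijk[1] + grid$shape[1] * (ijk[2] + grid$shape[2] * ijk[3])
  }
  cos_max <- cos(params$max_angle_deg * pi / 180)
  max_steps <- floor(params$max_length_mm / params$step_mm)
  e1 <- pdm[look(seed), ]
  run_half <- function(d0, budget) {
    pos <- seed; dirv <- d0; pts <- rbind(pos); n <- 0L
    while (n < budget) {
      v <- pdm[look(pos), ]
      if (sum(v * dirv) < 0) v <- -v
      if (nrow(pts) > 1 && sum(v * dirv) < cos_max) break
      nxt <- pos + params$step_mm * v
      idx <- look(nxt)
      if (is.na(idx)) break
      if (fav[idx] < params$fa_min) break
      pts <- rbind(pts, nxt); pos <- nxt; dirv <- v; n <- n + 1L
    }
    pts
  }
  fwd <- run_half(e1, max_steps)
  bwd <- run_half(-e1, max_steps - (nrow(fwd) - 1L))
  rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE], fwd)
}
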