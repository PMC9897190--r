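#' Deterministic tracking parameters
#'
#' Defaults are the published four-tract settings: FA threshold 0.2, minimum
#' fibre length 80 mm, maximum per-step angle 20 degrees. The fallback set
#' used when the decussating DRTT cannot be delineated is FA 0.11, minimum
#' length 40 mm, maximum angle 50 degrees (see
#' \code{\link{fallback_params}}). Step size, seeding density and the
#' tensor-deflection blend weights are implementation choices documented in
#' the package vignette.
#'
#' @param fa_min FA stopping threshold in (0, 1).
#' @param max_angle_deg maximum turning angle per step, degrees, in (0, 90].
#' @param min_length_mm minimum retained fibre length, mm.
#' @param max_length_mm maximum fibre length, mm (propagation stops there).
#' @param step_mm Euler integration step, mm, in (0, 2].
#' @param seeds_per_voxel seeds per seed-ROI voxel (1 = voxel centre; more
#'   adds reproducible jittered seeds).
#' @param tend_f deflection blend weight f in [0, 1], or \code{"fa"} to use
#'   the local FA (the default).
#' @param tend_g deflection blend weight g in [0, 1].
#' @param jitter_seed RNG seed for jittered seeding.
#' @param seed_jitter_frac jitter amplitude for extra seeds, as a fraction of
#'   the voxel size (uniform in +/- this fraction per axis).
#' @return object of class \code{tracking_params}.
#' @export
tracking_params <- function(fa_min = 0.2, max_angle_deg = 20,
                            min_length_mm = 80, max_length_mm = 250,
                            step_mm = 1.0, seeds_per_voxel = 9L,
                            tend_f = "fa", tend_g = 1.0,
                            jitter_seed = 42L, seed_jitter_frac = 0.35) {
  stopifnot(fa_min > 0, fa_min < 1,
            max_angle_deg > 0, max_angle_deg <= 90,
            step_mm > 0, step_mm <= 2,
            min_length_mm < max_length_mm,
            seeds_per_voxel >= 1,
            tend_g >= 0, tend_g <= 1,
            seed_jitter_frac >= 0, seed_jitter_frac <= 0.5)
  if (!identical(tend_f, "fa"))
    stopifnot(is.numeric(tend_f), tend_f >= 0, tend_f <= 1)
  structure(list(fa_min = fa_min, max_angle_deg = max_angle_deg,
                 min_length_mm = min_length_mm, max_length_mm = max_length_mm,
                 step_mm = step_mm, seeds_per_voxel = as.integer(seeds_per_voxel),
                 tend_f = tend_f, tend_g = tend_g,
                 jitter_seed = as.integer(jitter_seed),
                 seed_jitter_frac = seed_jitter_frac),
            class = "tracking_params")
}

#' Fallback tracking parameters for the dDRTT rescue cascade
#' @param base a \code{tracking_params} to inherit the non-threshold fields from.
#' @return \code{tracking_params} with FA 0.11, min length 40 mm, max angle 50.
#' @export
fallback_params <- function(base = tracking_params()) {
  base$fa_min <- 0.11
  base$min_length_mm <- 40
  base$max_angle_deg <- 50
  base
}

#' @export
print.tracking_params <- function(x, ...) {
  cat(sprintf(
    "<tracking_params> FA >= %g, length [%g, %g] mm, angle <= %g deg/step, step %g mm, f=%s g=%g\n",
    x$fa_min, x$min_length_mm, x$max_length_mm, x$max_angle_deg, x$step_mm,
    if (identical(x$tend_f, "fa")) "FA" else format(x$tend_f), x$tend_g))
  invisible(x)
}

#' Tensor-deflection propagation step
#'
#' Returns \code{normalize(f * e1 + (1 - f) * normalize((1 - g) * v_in +
#' g * Dhat \%*\% v_in))}, where \code{e1} is the principal eigenvector
#' sign-aligned with the incoming direction, \code{Dhat} is the tensor scaled
#' by its largest eigenvalue, \code{f} is the tensor's FA when
#' \code{tend_f = "fa"}, and \code{g} is the fixed deflection weight. A zero
#' tensor returns the incoming direction unchanged.
#'
#' @param v_in unit 3-vector, incoming direction.
#' @param D symmetric 3 x 3 tensor (or length-6 lower representation).
#' @param params a \code{tracking_params} (only tend_f/tend_g are used).
#' @return unit 3-vector.
#' @export
tend_step <- function(v_in, D, params = tracking_params()) {
  if (vnorm(v_in) == 0) stop("validation error: zero incoming direction",
                             call. = FALSE)
  v_in <- v_in / vnorm(v_in)
  lower <- as_lower6(if (is.matrix(D)) D else matrix(D, 1))
  m <- tensor_metrics(lower)
  if (all(lower == 0)) return(v_in)
  e1 <- m$principal_dir[1, ]
  if (sum(e1 * v_in) < 0) e1 <- -e1
  f <- if (identical(params$tend_f, "fa")) m$fa[1] else params$tend_f
  g <- params$tend_g
  Dhat <- lower_to_mat(lower) / m$evals[1, 1]
  defl <- (1 - g) * v_in + g * as.vector(Dhat %*% v_in)
  if (vnorm(defl) == 0) defl <- v_in else defl <- defl / vnorm(defl)
  out <- f * e1 + (1 - f) * defl
  if (vnorm(out) == 0) return(v_in)
  out / vnorm(out)
}

## internal lookup bundle used by the propagation inner loop: avoids
## re-deriving the eigensystem at every step
field_lookup <- function(field) {
  list(grid = field$grid,
       fa = as.vector(field$fa),
       pd = field$principal_dir,
       lower = field$lower,
       l1 = field$evals[, 1])
}

## one tensor-deflection direction update from precomputed lookups
tend_dir <- function(v_in, lk, idx, tf_fa, tf_num, g) {
  e1 <- lk$pd[idx, ]
  dp <- e1[1] * v_in[1] + e1[2] * v_in[2] + e1[3] * v_in[3]
  if (dp < 0) e1 <- -e1
  lo <- lk$lower[idx, ]
  l1 <- lk$l1[idx]
  if (l1 <= 0 || all(lo == 0)) return(v_in)
  f <- if (tf_fa) lk$fa[idx] else tf_num
  dv <- c(lo[1] * v_in[1] + lo[4] * v_in[2] + lo[5] * v_in[3],
          lo[4] * v_in[1] + lo[2] * v_in[2] + lo[6] * v_in[3],
          lo[5] * v_in[1] + lo[6] * v_in[2] + lo[3] * v_in[3]) / l1
  defl <- (1 - g) * v_in + g * dv
  nd <- sqrt(sum(defl^2))
  if (nd == 0) defl <- v_in else defl <- defl / nd
  out <- f * e1 + (1 - f) * defl
  no <- sqrt(sum(out^2))
  if (no == 0) v_in else out / no
}

#' Propagate a single streamline
#'
#' Fixed-step Euler propagation, bidirectional from the seed, with
#' nearest-neighbour tensor lookup. The initial directions are the seed
#' voxel's principal eigenvector and its negation; each half-track terminates
#' when the next position leaves the grid (\code{bounds}), when FA at the
#' next position falls below \code{fa_min} (\code{fa}), when the turning
#' angle between successive step directions exceeds \code{max_angle_deg}
#' (\code{angle}), or when total length would exceed \code{max_length_mm}
#' (\code{max_length}).
#'
#' @param seed world-mm point inside the grid.
#' @param field a \code{tensor_field}.
#' @param params a \code{tracking_params}.
#' @return object of class \code{streamline}: list with \code{points}
#'   (n x 3), \code{seed} and \code{stop_reasons} (forward, backward).
#' @export
propagate_streamline <- function(seed, field, params = tracking_params()) {
  stopifnot(inherits(field, "tensor_field"))
  if (!in_grid(field$grid, rbind(seed)))
    stop("seed error: seed lies outside the grid", call. = FALSE)
  lk <- field_lookup(field)
  sl <- propagate_streamline_lk(seed, lk, params)
  structure(sl, class = "streamline")
}

propagate_streamline_lk <- function(seed, lk, params) {
  grid <- lk$grid
  idx0 <- voxel_linear(grid, nearest_voxel(grid, seed))
  cos_max <- cos(params$max_angle_deg * pi / 180)
  tf_fa <- identical(params$tend_f, "fa")
  tf_num <- if (tf_fa) 0 else params$tend_f
  step <- params$step_mm
  max_steps_total <- floor(params$max_length_mm / step)
  e1 <- lk$pd[idx0, ]
  halves <- list()
  used_steps <- 0L
  reasons <- character(2)
  for (h in 1:2) {
    dirv <- if (h == 1) e1 else -e1
    pos <- as.numeric(seed)
    pts <- matrix(NA_real_, max_steps_total + 1L, 3)
    pts[1, ] <- pos
    np <- 1L
    reason <- "max_length"
    budget <- max_steps_total - used_steps
    while (np - 1L < budget) {
      v_new <- tend_dir(dirv, lk, idx0_cur(lk, pos, grid), tf_fa, tf_num,
                        params$tend_g)
      ## turning angle between successive step directions
      if (np > 1L &&
          sum(v_new * dirv) < cos_max) { reason <- "angle"; break }
      nxt <- pos + step * v_new
      if (!in_grid(grid, rbind(nxt))) { reason <- "bounds"; break }
      idx_n <- voxel_linear(grid, nearest_voxel(grid, nxt))
      if (lk$fa[idx_n] < params$fa_min) { reason <- "fa"; break }
      np <- np + 1L
      pts[np, ] <- nxt
      pos <- nxt
      dirv <- v_new
    }
    used_steps <- used_steps + (np - 1L)
    reasons[h] <- reason
    halves[[h]] <- pts[seq_len(np), , drop = FALSE]
  }
  fwd <- halves[[1]]; bwd <- halves[[2]]
  pts <- rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE], fwd)
  list(points = pts, seed = as.numeric(seed),
       stop_reasons = c(forward = reasons[1], backward = reasons[2]))
}

idx0_cur <- function(lk, pos, grid) {
  voxel_linear(grid, round((pos - grid$origin) / grid$voxel))
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("<streamline> %d points, length %.1f mm, stops (%s, %s)\n",
              nrow(x$points), streamline_length(x$points),
              x$stop_reasons[1], x$stop_reasons[2]))
  invisible(x)
}

streamline_length <- function(points) {
  if (nrow(points) < 2) return(0)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                    points[-nrow(points), , drop = FALSE])^2)))
}

#' Named bundle of streamlines
#'
#' @param name tract label.
#' @param streamlines list of \code{streamline} objects.
#' @param params the \code{tracking_params} used.
#' @param cascade_step integer provenance of the dDRTT rescue cascade
#'   (0 = defaults, see \code{\link{build_tract}}).
#' @return object of class \code{bundle}.
#' @export
bundle <- function(name, streamlines = list(), params = NULL,
                   cascade_step = 0L) {
  structure(list(name = name, streamlines = streamlines, params = params,
                 cascade_step = as.integer(cascade_step)),
            class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  lens <- vapply(x$streamlines, function(s) streamline_length(s$points), 0)
  cat(sprintf("<bundle> %s: %d streamlines%s, cascade step %d\n",
              x$name, length(x$streamlines),
              if (length(lens)) sprintf(", length %.0f-%.0f mm",
                                        min(lens), max(lens)) else "",
              x$cascade_step))
  invisible(x)
}

#' @export
length.bundle <- function(x) length(x$streamlines)

## all points of a bundle as one matrix
bundle_points <- function(b) {
  if (!length(b$streamlines)) return(matrix(0, 0, 3))
  do.call(rbind, lapply(b$streamlines, `[[`, "points"))
}

## does the polyline come within tol of any mask voxel centre?
intersects_mask <- function(points, mask_pts, tol) {
  if (!nrow(mask_pts)) return(FALSE)
  ## cheap pass: axis box prefilter, then exact distances in blocks
  for (i in seq_len(nrow(mask_pts))) {
    d2 <- (points[, 1] - mask_pts[i, 1])^2 +
          (points[, 2] - mask_pts[i, 2])^2 +
          (points[, 3] - mask_pts[i, 3])^2
    if (any(d2 <= tol^2)) return(TRUE)
  }
  FALSE
}

#' Seeded, ROI-filtered tractography
#'
#' Places one seed at the centre of every seed-ROI voxel (plus reproducible
#' jittered seeds when \code{seeds_per_voxel > 1}), propagates each, and
#' retains a streamline iff its length is at least \code{min_length_mm} and
#' it intersects every include ROI. A streamline intersects an ROI when any
#' of its points lies within half a voxel diagonal of a mask voxel centre.
#'
#' @param field a \code{tensor_field}.
#' @param seed_roi logical array on the field grid (non-empty).
#' @param include_rois list of logical arrays (may be empty).
#' @param params a \code{tracking_params}.
#' @param name bundle label.
#' @return a \code{bundle} (possibly empty — an empty result is not an error;
#'   the dDRTT cascade handles it).
#' @export
track_with_rois <- function(field, seed_roi, include_rois = list(),
                            params = tracking_params(), name = "tract") {
  stopifnot(inherits(field, "tensor_field"))
  grid <- field$grid
  if (!any(seed_roi)) stop("ROI error: empty seed ROI", call. = FALSE)
  seeds <- mask_coords(grid, seed_roi)
  if (params$seeds_per_voxel > 1L) {
    set.seed(params$jitter_seed)
    extra <- lapply(seq_len(params$seeds_per_voxel - 1L), function(i) {
      jit <- matrix(stats::runif(length(seeds), -params$seed_jitter_frac,
                                 params$seed_jitter_frac),
                    nrow(seeds), 3)
      seeds + sweep(jit, 2, grid$voxel, "*")
    })
    seeds <- do.call(rbind, c(list(seeds), extra))
  }
  tol <- half_diagonal(grid)
  inc_pts <- lapply(include_rois, function(m) mask_coords(grid, m))
  lk <- field_lookup(field)
  kept <- list()
  for (i in seq_len(nrow(seeds))) {
    if (!in_grid(grid, seeds[i, , drop = FALSE])) next
    sl <- propagate_streamline_lk(seeds[i, ], lk, params)
    if (streamline_length(sl$points) < params$min_length_mm) next
    ok <- TRUE
    for (mp in inc_pts) {
      if (!intersects_mask(sl$points, mp, tol)) { ok <- FALSE; break }
    }
    if (!ok) next
    sl$seed_index <- i
    kept[[length(kept) + 1L]] <- structure(sl, class = "streamline")
  }
  bundle(name, kept, params)
}
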