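#' Bundle specification for the synthetic phantom
#'
#' Describes one white-matter bundle as a smooth tube: a cubic interpolating
#' spline through control points, a radius, and the diffusion properties of
#' the tensors placed inside it. \code{fa_target} may be a single value or a
#' function of arc length (mm from the first control point), which is how the
#' low-FA decussation variant lowers anisotropy over one segment of the
#' decussating dentato-rubro-thalamic tract.
#'
#' @param name tract label.
#' @param control_points n x 3 matrix of world-mm points, n >= 2.
#' @param radius tube radius in mm (> 0).
#' @param fa_target fractional anisotropy in (0,1), scalar or function(s_mm).
#' @param mean_diffusivity mean diffusivity in mm^2/s (> 0).
#' @return an object of class \code{bundle_spec}.
#' @export
bundle_spec <- function(name, control_points, radius, fa_target = 0.7,
                        mean_diffusivity = 0.8e-3) {
  cp <- rbind(control_points)
  stopifnot(ncol(cp) == 3L)
  if (nrow(cp) < 2L) stop("need at least 2 control points", call. = FALSE)
  seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  if (any(seg < 1e-9))
    stop("degenerate geometry: coincident consecutive control points", call. = FALSE)
  if (!(radius > 0)) stop("radius must be > 0", call. = FALSE)
  if (is.numeric(fa_target)) {
    if (fa_target <= 0 || fa_target >= 1)
      stop("fa_target must lie in (0, 1)", call. = FALSE)
  } else if (!is.function(fa_target)) {
    stop("fa_target must be a number in (0,1) or a function of arc length",
         call. = FALSE)
  }
  if (!(mean_diffusivity > 0)) stop("mean_diffusivity must be > 0", call. = FALSE)
  structure(list(name = name, control_points = cp, radius = radius,
                 fa_target = fa_target, mean_diffusivity = mean_diffusivity),
            class = "bundle_spec")
}

## evaluate the spline of a bundle_spec at chord-length parameters tt,
## returning positions and unit tangents
spline_eval <- function(cp, tt) {
  seg <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  t0 <- c(0, cumsum(seg))
  if (nrow(cp) == 2L) {
    ## two points: straight line
    dirv <- (cp[2, ] - cp[1, ]) / t0[2]
    pos <- outer(tt, dirv) + matrix(cp[1, ], length(tt), 3, byrow = TRUE)
    tan <- matrix(dirv, length(tt), 3, byrow = TRUE)
  } else {
    fx <- stats::splinefun(t0, cp[, 1], method = "natural")
    fy <- stats::splinefun(t0, cp[, 2], method = "natural")
    fz <- stats::splinefun(t0, cp[, 3], method = "natural")
    pos <- cbind(fx(tt), fy(tt), fz(tt))
    tan <- cbind(fx(tt, deriv = 1), fy(tt, deriv = 1), fz(tt, deriv = 1))
  }
  tan <- tan / sqrt(rowSums(tan^2))
  list(pos = pos, tan = tan, total_chord = t0[length(t0)])
}

#' Sample a bundle centerline at uniform arc length
#'
#' Interpolates a natural cubic spline through the control points
#' (chord-length parameterization) and resamples it at approximately uniform
#' arc length no larger than \code{step}. Endpoints coincide with the first
#' and last control points.
#'
#' @param spec a \code{bundle_spec}.
#' @param step maximum arc-length spacing in mm (> 0).
#' @return a matrix of points (n x 3) with attributes \code{tangents}
#'   (n x 3 unit vectors) and \code{arc} (arc-length position of each point, mm).
#' @export
make_centerline <- function(spec, step = 0.5) {
  stopifnot(inherits(spec, "bundle_spec"))
  if (!(step > 0)) stop("step must be > 0", call. = FALSE)
  cp <- spec$control_points
  ## dense sampling in the chord parameter for arc-length quadrature
  dense <- spline_eval(cp, seq(0, spline_eval(cp, 0)$total_chord,
                               length.out = max(2000L, 20L * nrow(cp))))
  dl <- sqrt(rowSums((dense$pos[-1, , drop = FALSE] -
                      dense$pos[-nrow(dense$pos), , drop = FALSE])^2))
  s_dense <- c(0, cumsum(dl))
  L <- s_dense[length(s_dense)]
  n_seg <- max(1L, ceiling(L / step))
  s_want <- seq(0, L, length.out = n_seg + 1L)
  ## invert arc length -> chord parameter (s_dense is monotone)
  t_dense <- seq(0, dense$total_chord, length.out = nrow(dense$pos))
  t_want <- stats::approx(s_dense, t_dense, xout = s_want, ties = "ordered")$y
  ev <- spline_eval(cp, t_want)
  pts <- ev$pos
  pts[1, ] <- cp[1, ]
  pts[nrow(pts), ] <- cp[nrow(cp), ]
  structure(pts, tangents = ev$tan, arc = s_want)
}

## axially symmetric eigenvalue pair reproducing (fa, md) exactly:
## lambda_par = md + 2*delta/3, lambda_perp = md - delta/3,
## delta = md * fa * sqrt(3 / (1 - 2*fa^2/3))
axial_eigenvalues <- function(fa, md) {
  delta <- md * fa * sqrt(3 / (1 - 2 * fa^2 / 3))
  cbind(par = md + 2 * delta / 3, perp = md - delta / 3)
}

#' Build a synthetic tensor field from bundle specifications
#'
#' Voxels whose centre lies within \code{radius} of a bundle centerline get a
#' cylindrically symmetric tensor whose principal eigenvector is the local
#' centerline tangent and whose eigenvalue pair reproduces the bundle's FA and
#' mean diffusivity exactly. Where bundles overlap, the nearest centerline
#' wins. All remaining voxels get isotropic tensors at the background
#' diffusivity.
#'
#' @param specs list of \code{bundle_spec} (may be empty: all-isotropic field).
#' @param grid a \code{vox_grid}.
#' @param background_md background (isotropic) diffusivity, mm^2/s.
#' @param centerline_step arc-length sampling of the centerlines, mm.
#' @return a \code{tensor_field} (see \code{\link{fit_tensor_loglinear}}); the
#'   extra fields \code{bundle_id} (0 = background) and \code{bundle_names}
#'   record which spec claimed each voxel.
#' @export
make_tensor_field <- function(specs, grid, background_md = 0.7e-3,
                              centerline_step = 0.5) {
  stopifnot(inherits(grid, "vox_grid"))
  if (inherits(specs, "bundle_spec")) specs <- list(specs)
  nv <- n_voxels(grid)
  best_d2 <- rep(Inf, nv)
  best_id <- integer(nv)
  best_tan <- matrix(0, nv, 3)
  best_s <- numeric(nv)
  s <- grid$shape
  for (b in seq_along(specs)) {
    sp <- specs[[b]]
    cl <- make_centerline(sp, step = centerline_step)
    tans <- attr(cl, "tangents")
    arcs <- attr(cl, "arc")
    r_reach <- sp$radius + max(grid$voxel)   # local search box half-width
    nb <- ceiling(r_reach / grid$voxel)
    for (p in seq_len(nrow(cl))) {
      c_ijk <- round((cl[p, ] - grid$origin) / grid$voxel)
      lo <- pmax(c_ijk - nb, 0)
      hi <- pmin(c_ijk + nb, s - 1L)
      if (any(lo > hi)) next
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      ni <- length(ii); nj <- length(jj); nk <- length(kk)
      xi <- grid$origin[1] + ii * grid$voxel[1]
      yj <- grid$origin[2] + jj * grid$voxel[2]
      zk <- grid$origin[3] + kk * grid$voxel[3]
      d2 <- outer(outer((xi - cl[p, 1])^2, (yj - cl[p, 2])^2, "+"),
                  (zk - cl[p, 3])^2, "+")
      lin <- 1 + rep.int(ii, nj * nk) +
        s[1] * (rep.int(rep(jj, each = ni), nk) + s[2] * rep(kk, each = ni * nj))
      upd <- which(d2 < best_d2[lin] & d2 <= sp$radius^2)
      if (length(upd)) {
        li <- lin[upd]
        best_d2[li] <- d2[upd]
        best_id[li] <- b
        best_tan[li, ] <- matrix(tans[p, ], length(li), 3, byrow = TRUE)
        best_s[li] <- arcs[p]
      }
    }
  }
  lower <- matrix(0, nv, 6,
                  dimnames = list(NULL, c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")))
  lower[, 1:3] <- background_md
  inb <- which(best_id > 0L)
  if (length(inb)) {
    fa_v <- numeric(length(inb))
    md_v <- numeric(length(inb))
    for (b in seq_along(specs)) {
      sel <- best_id[inb] == b
      if (!any(sel)) next
      ft <- specs[[b]]$fa_target
      fa_here <- if (is.function(ft)) ft(best_s[inb][sel]) else rep(ft, sum(sel))
      if (any(fa_here <= 0 | fa_here >= 1))
        stop("fa_target must lie in (0, 1)", call. = FALSE)
      fa_v[sel] <- fa_here
      md_v[sel] <- specs[[b]]$mean_diffusivity
    }
    ev <- axial_eigenvalues(fa_v, md_v)
    tn <- best_tan[inb, , drop = FALSE]
    dpar <- ev[, "par"] - ev[, "perp"]
    lower[inb, 1] <- ev[, "perp"] + dpar * tn[, 1]^2
    lower[inb, 2] <- ev[, "perp"] + dpar * tn[, 2]^2
    lower[inb, 3] <- ev[, "perp"] + dpar * tn[, 3]^2
    lower[inb, 4] <- dpar * tn[, 1] * tn[, 2]
    lower[inb, 5] <- dpar * tn[, 1] * tn[, 3]
    lower[inb, 6] <- dpar * tn[, 2] * tn[, 3]
  }
  tf <- tensor_field(lower, grid)
  tf$bundle_id <- array(best_id, dim = grid$shape)
  tf$bundle_names <- vapply(specs, function(x) x$name, character(1))
  tf
}

#' DWI acquisition protocol for the phantom
#'
#' Defaults mirror a 32-direction, b = 800 s/mm^2 clinical DTI protocol.
#' Directions are generated deterministically on a Fibonacci sphere.
#'
#' @param b_value diffusion weighting, s/mm^2 (> 0).
#' @param n_dirs number of gradient directions (>= 6).
#' @param n_b0 number of unweighted volumes (>= 1).
#' @param s0 baseline signal.
#' @param noise_sigma Rician noise scale in signal units (>= 0).
#' @param seed integer seed for the noise generator (mandatory when
#'   \code{noise_sigma > 0}).
#' @return an object of class \code{dwi_protocol} with fields \code{bvals}
#'   (length n_b0 + n_dirs) and \code{bvecs} ((n_b0+n_dirs) x 3 unit rows,
#'   zero rows for b0).
#' @export
dwi_protocol <- function(b_value = 800, n_dirs = 32, n_b0 = 4, s0 = 1000,
                         noise_sigma = 0, seed = 1L) {
  if (!(b_value > 0)) stop("b_value must be > 0", call. = FALSE)
  if (n_dirs < 6) stop("need at least 6 gradient directions", call. = FALSE)
  if (n_b0 < 1) stop("need at least one b0 volume", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  bvals <- c(rep(0, n_b0), rep(b_value, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  structure(list(b_value = b_value, n_dirs = n_dirs, n_b0 = n_b0, s0 = s0,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 bvals = bvals, bvecs = bvecs),
            class = "dwi_protocol")
}

#' Synthesize a DWI dataset from a tensor field
#'
#' Noiseless signal per voxel and direction g is \code{s0 * exp(-b g' D g)};
#' b0 volumes equal s0. Rician noise of scale \code{noise_sigma} is applied
#' through two independent Gaussian channels, reproducibly from the protocol
#' seed.
#'
#' @param field a \code{tensor_field} (truth).
#' @param protocol a \code{dwi_protocol}.
#' @return a \code{dwi_dataset}: 4-D signal array plus gradient table.
#' @export
synthesize_dwi <- function(field, protocol) {
  stopifnot(inherits(field, "tensor_field"), inherits(protocol, "dwi_protocol"))
  grid <- field$grid
  nv <- n_voxels(grid)
  nvol <- length(protocol$bvals)
  sig <- matrix(protocol$s0, nv, nvol)
  g <- protocol$bvecs
  w <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  dwi_vols <- which(protocol$bvals > 0)
  ## g' D g for all voxels and weighted volumes in one product
  quad <- field$lower %*% t(w[dwi_vols, , drop = FALSE])
  sig[, dwi_vols] <- protocol$s0 *
    exp(-sweep(quad, 2, protocol$bvals[dwi_vols], "*"))
  if (protocol$noise_sigma > 0) {
    set.seed(protocol$seed)
    n1 <- matrix(stats::rnorm(nv * nvol, sd = protocol$noise_sigma), nv, nvol)
    n2 <- matrix(stats::rnorm(nv * nvol, sd = protocol$noise_sigma), nv, nvol)
    sig <- sqrt((sig + n1)^2 + n2^2)
  }
  dwi_dataset(array(sig, dim = c(grid$shape, nvol)),
              protocol$bvals, protocol$bvecs, grid)
}

#' The four-tract synthetic phantom
#'
#' Generates the full ground-truth phantom used throughout the package: an
#' AC-PC-aligned 96 x 96 x 60 lattice at 2.5 mm with four curved bundles
#' reproducing the relative geometry of the decussating and non-decussating
#' dentato-rubro-thalamic tracts (anterior and posterior to the red nucleus),
#' the corticospinal tract and the medial lemniscus, plus the ROI masks the
#' tract recipes resolve against and the AC/PC/midline landmarks.
#'
#' Variants: \code{"low_fa_decussation"} lowers the dDRTT FA to 0.15 over the
#' decussation segment (straddling the default 0.2 and fallback 0.11 tracking
#' thresholds); \code{"ddrtt_premotor"} reroutes the dDRTT cortical ending
#' from the precentral ROI to the premotor ROI (exercising the combined
#' motor-cortex cascade step).
#'
#' @param variant phantom variant, see Details.
#' @param side treated side; only "left" geometry is generated (the phantom is
#'   one-sided; the contralateral dentate exists for the dDRTT recipe).
#' @param shape,voxel_mm lattice definition.
#' @param fa,mean_diffusivity,radius bundle tensor/tube parameters.
#' @param background_md isotropic background diffusivity, mm^2/s.
#' @return a list of class \code{phantom_truth}: \code{grid}, \code{specs},
#'   \code{field} (truth tensor field), \code{centerlines}, \code{masks}
#'   (named list of logical arrays), \code{landmarks} (ac, pc, midline),
#'   \code{roi_table} (data.frame recording mask geometry).
#' @export
phantom_four_tract <- function(variant = c("default", "low_fa_decussation",
                                           "ddrtt_premotor"),
                               side = "left",
                               shape = c(96L, 96L, 60L), voxel_mm = 2.5,
                               fa = 0.7, mean_diffusivity = 0.8e-3,
                               radius = 4, background_md = 0.7e-3) {
  variant <- match.arg(variant)
  stopifnot(identical(side, "left"))
  grid <- vox_grid(shape, voxel_mm)

  ## world frame == AC-PC frame: AC (0,13,0), PC (0,-13,0), so the VIM
  ## target zone (A ~ 6.5 mm anterior of PC, L ~ 13-14) sits near world
  ## (13.5, -6.5, +2). The red nucleus lies infero-medial to it; the
  ## internal-capsule CST lateral; the medial lemniscus posterior.
  cst_cp <- rbind(c(6, -14, -50), c(8.5, -9, -20), c(15, -6, -8),
                  c(20, -6, 5), c(21, -7, 35), c(23.75, -6.25, 58.75))
  ml_cp <- rbind(c(7, -20, -45), c(9, -16, -16), c(12, -14, 0),
                 c(15, -13, 15), c(19, -16, 40), c(21.25, -18.75, 58.75))
  ## The two DRTT components flank the red nucleus at z = -4 (9 mm apart),
  ## then converge while sharing their lateral (x) motion -- the shared
  ## component keeps their mutual tangent angle well under the 20-degree
  ## stopping rule where the tubes start to overlap -- and run parallel,
  ## one voxel row apart in y (lattice-aligned so nearest-centerline tensor
  ## claims are clean), through the VIM confluence and on to motor cortex.
  ddrtt_upper <- if (variant == "ddrtt_premotor")
    rbind(c(15, 1, 35), c(21.25, 3.75, 58.75))
  else rbind(c(16, -4.5, 35), c(22, -7, 58.75))
  ddrtt_cp <- rbind(c(-13.75, -43.75, -41.25), c(-9, -36, -31),
                    c(-3.5, -26, -22), c(0.5, -17, -15),
                    c(6.25, -6.25, -8.75), c(8, -4.75, -5), c(10, -4, -1),
                    c(12, -3.75, 3), c(13.5, -3.75, 8), c(13.75, -3.75, 16),
                    ddrtt_upper)
  nddrtt_cp <- rbind(c(13.75, -43.75, -41.25), c(10, -36, -31),
                     c(8, -26, -22), c(7, -17, -15),
                     c(6.25, -11.25, -8.75), c(8, -8.5, -5), c(10, -6.5, -1),
                     c(12, -5.4, 3), c(13.5, -5.25, 8), c(13.75, -5.25, 16),
                     c(15.5, -6.5, 35), c(20.5, -10.5, 58.75))

  ddrtt_fa <- fa
  if (variant == "low_fa_decussation") {
    ## decussation segment of the dDRTT (midline crossing, arc 28-48 mm from
    ## the dentate end) dropped to 0.15: blocks the default FA 0.2 stopping
    ## rule but not the 0.11 fallback
    ddrtt_fa <- local({
      fa_hi <- fa
      function(s_mm) ifelse(s_mm >= 28 & s_mm <= 48, 0.15, fa_hi)
    })
  }

  specs <- list(
    bundle_spec("CST",    cst_cp,    radius, fa, mean_diffusivity),
    bundle_spec("ML",     ml_cp,     radius, fa, mean_diffusivity),
    bundle_spec("dDRTT",  ddrtt_cp,  radius, ddrtt_fa, mean_diffusivity),
    bundle_spec("ndDRTT", nddrtt_cp, radius, fa, mean_diffusivity))

  field <- make_tensor_field(specs, grid, background_md = background_md)
  centerlines <- lapply(specs, make_centerline, step = 0.5)
  names(centerlines) <- vapply(specs, `[[`, "", "name")

  roi <- list(
    dentate_left        = list(kind = "sphere", centre = c(13.75, -43.75, -41.25), size = 2),
    dentate_right       = list(kind = "sphere", centre = c(-13.75, -43.75, -41.25), size = 2),
    red_nucleus_left    = list(kind = "sphere", centre = c(6.25, -8.75, -8.75), size = 3),
    red_nucleus_right   = list(kind = "sphere", centre = c(-6.25, -8.75, -8.75), size = 3),
    cerebral_peduncle   = list(kind = "sphere", centre = c(8.5, -9, -20), size = 4),
    midbrain_dorsolateral = list(kind = "box", centre = c(10, -15, -12), size = c(4, 5, 5)),
    precentral          = list(kind = "sphere", centre = c(23, -7, 58.75), size = 3),
    postcentral         = list(kind = "sphere", centre = c(21.25, -18.75, 58.75), size = 2),
    supplementary_motor = list(kind = "box", centre = c(6.25, -3.75, 61.25), size = c(5, 6, 4)),
    premotor            = list(kind = "sphere", centre = c(21.25, 3.75, 58.75), size = 4),
    third_ventricle_wall_left  = list(kind = "box", centre = c(2, -3, 5),  size = c(0.6, 7, 5)),
    third_ventricle_wall_right = list(kind = "box", centre = c(-2, -3, 5), size = c(0.6, 7, 5)),
    ac_landmark         = list(kind = "sphere", centre = c(0, 13, 0),  size = 1.5),
    pc_landmark         = list(kind = "sphere", centre = c(0, -13, 0), size = 1.5))

  co <- grid_coords(grid)
  masks <- lapply(roi, function(r) {
    if (r$kind == "sphere") sphere_mask(grid, r$centre, r$size, coords = co)
    else box_mask(grid, r$centre, r$size, coords = co)
  })
  masks$combined_motor <- masks$precentral | masks$supplementary_motor |
    masks$premotor

  roi_table <- data.frame(
    name = names(roi),
    kind = vapply(roi, `[[`, "", "kind"),
    centre = vapply(roi, function(r) paste(r$centre, collapse = ","), ""),
    size = vapply(roi, function(r) paste(r$size, collapse = ","), ""),
    row.names = NULL)

  structure(list(grid = grid, specs = specs, field = field,
                 centerlines = centerlines, masks = masks,
                 landmarks = list(ac = c(0, 13, 0), pc = c(0, -13, 0),
                                  midline = c(0, 0, 40)),
                 side = side, variant = variant, roi_table = roi_table),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> variant '%s', %s voxels @ %g mm, %d bundles, %d masks\n",
              x$variant, paste(x$grid$shape, collapse = "x"), x$grid$voxel[1],
              length(x$specs), length(x$masks)))
  invisible(x)
}
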