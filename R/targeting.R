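#' AC-PC stereotactic frame
#'
#' Builds the orthonormal (lateral, anterior, superior) triad from the
#' anterior commissure, posterior commissure and a mid-sagittal point. The
#' anterior axis points from PC toward AC; the superior axis is the
#' component of (midline point - mid-commissural point) orthogonal to the
#' anterior axis; the lateral axis is their cross product. AC-PC coordinates
#' follow the treatment-planning convention: L is the signed lateral
#' distance from the mid-sagittal plane (treated side positive), A is mm
#' anterior relative to PC, S is mm superior relative to the AC-PC plane.
#'
#' @param ac,pc world-mm landmark points (distinct).
#' @param midline_point world-mm point in the mid-sagittal plane, off the
#'   AC-PC line, superior to it.
#' @param side treated side, \code{"left"} or \code{"right"}: fixes which
#'   lateral direction is positive.
#' @return object of class \code{acpc_frame}.
#' @export
acpc_frame <- function(ac, pc, midline_point, side = "left") {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  midline_point <- as.numeric(midline_point)
  if (vnorm(ac - pc) < 1e-9)
    stop("geometry error: AC and PC coincide", call. = FALSE)
  A <- unitize(ac - pc)
  mcp <- (ac + pc) / 2
  w <- midline_point - mcp
  s_raw <- w - sum(w * A) * A
  if (vnorm(s_raw) < 1e-9)
    stop("geometry error: midline point lies on the AC-PC line", call. = FALSE)
  S <- unitize(s_raw)
  L <- c(A[2] * S[3] - A[3] * S[2],
         A[3] * S[1] - A[1] * S[3],
         A[1] * S[2] - A[2] * S[1])
  side <- match.arg(side, c("left", "right"))
  structure(list(ac = ac, pc = pc, midline_point = midline_point,
                 axes = rbind(L = L, A = A, S = S), mcp = mcp,
                 acpc_length = vnorm(ac - pc), side = side,
                 side_sign = if (side == "left") 1 else -1),
            class = "acpc_frame")
}

#' @export
print.acpc_frame <- function(x, ...) {
  cat(sprintf("<acpc_frame> AC-PC length %.1f mm, MCP (%s) mm, treated side %s\n",
              x$acpc_length, paste(round(x$mcp, 2), collapse = ", "), x$side))
  invisible(x)
}

#' An AC-PC coordinate point
#'
#' @param L mm lateral (signed, treated side positive).
#' @param A mm anterior relative to PC.
#' @param S mm superior relative to the AC-PC plane.
#' @return object of class \code{acpc_point}.
#' @export
acpc_point <- function(L, A, S) {
  stopifnot(is.finite(L), is.finite(A), is.finite(S))
  structure(list(L = unname(L), A = unname(A), S = unname(S)),
            class = "acpc_point")
}

#' @export
print.acpc_point <- function(x, ...) {
  cat(sprintf("L = %.2f mm, A = %.2f mm, S = %.2f mm\n", x$L, x$A, x$S))
  invisible(x)
}

#' Convert between world and AC-PC coordinates
#'
#' The conversion is exact and invertible: \code{world = pc + A*Ahat +
#' S*Shat + side_sign*L*Lhat}.
#'
#' @param frame an \code{acpc_frame}.
#' @param pts n x 3 world-mm matrix, or an \code{acpc_point} / n x 3
#'   (L, A, S) matrix for the inverse.
#' @return the converted coordinates (n x 3 matrix; \code{world_to_acpc}
#'   columns are L, A, S).
#' @export
world_to_acpc <- function(frame, pts) {
  pts <- rbind(pts)
  rel <- sweep(pts, 2, frame$pc, "-")
  out <- rel %*% t(frame$axes)
  out[, 1] <- out[, 1] * frame$side_sign
  colnames(out) <- c("L", "A", "S")
  out
}

#' @rdname world_to_acpc
#' @export
acpc_to_world <- function(frame, pts) {
  if (inherits(pts, "acpc_point")) pts <- cbind(pts$L, pts$A, pts$S)
  pts <- rbind(pts)
  las <- pts
  las[, 1] <- las[, 1] * frame$side_sign
  sweep(las %*% frame$axes, 2, frame$pc, "+")
}

#' Indirect (landmark-based) target
#'
#' The standard indirect VIM target modified to start above the AC-PC plane:
#' 14 mm lateral to the mid-commissural point, 25 percent of the AC-PC
#' length anterior to the PC, 2 mm above the AC-PC plane. When the lateral
#' position of the third-ventricle wall is supplied, the enlarged-ventricle
#' correction places the target 10.5 mm (midpoint of the published 10-11 mm
#' range) lateral to the wall, but only ever more lateral than 14 mm, never
#' less.
#'
#' @param frame an \code{acpc_frame}.
#' @param ventricle_wall_L lateral position (mm) of the third-ventricle
#'   wall on the treated side, or NULL.
#' @param lateral_mm,s_mm the standard lateral offset and the height above
#'   the AC-PC plane.
#' @return an \code{acpc_point}.
#' @export
indirect_target <- function(frame, ventricle_wall_L = NULL,
                            lateral_mm = 14, s_mm = 2) {
  stopifnot(inherits(frame, "acpc_frame"))
  L <- lateral_mm
  if (!is.null(ventricle_wall_L)) L <- max(L, ventricle_wall_L + 10.5)
  acpc_point(L = L, A = 0.25 * frame$acpc_length, S = s_mm)
}

## rasterize bundle points inside an axial AC-PC slab at `res` mm in-plane.
## Returns a logical matrix over a common (L, A) lattice plus the lattice.
slab_raster <- function(pts_acpc, s_centre, half_thick, lattice) {
  sel <- pts_acpc[, 3] >= s_centre - half_thick &
         pts_acpc[, 3] <= s_centre + half_thick
  m <- matrix(FALSE, lattice$nL, lattice$nA)
  if (!any(sel)) return(m)
  iL <- floor((pts_acpc[sel, 1] - lattice$L0) / lattice$res) + 1L
  iA <- floor((pts_acpc[sel, 2] - lattice$A0) / lattice$res) + 1L
  ok <- iL >= 1 & iL <= lattice$nL & iA >= 1 & iA <= lattice$nA
  m[cbind(iL[ok], iA[ok])] <- TRUE
  m
}

dilate2d <- function(m) {
  d <- dim(m); out <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    out[xs, ys] <- out[xs, ys] | m[xs - dx, ys - dy]
  }
  out
}

## 8-connected component labelling of a logical matrix (iterative flood fill)
label2d <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  todo <- which(m & lab == 0L)
  nr <- nrow(m)
  while (length(todo)) {
    cur <- cur + 1L
    queue <- todo[1]
    lab[queue] <- cur
    while (length(queue)) {
      idx <- queue[1]; queue <- queue[-1]
      i <- (idx - 1L) %% nr + 1L
      j <- (idx - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > ncol(m)) next
        k <- ii + nr * (jj - 1L)
        if (m[k] && lab[k] == 0L) { lab[k] <- cur; queue <- c(queue, k) }
      }
    }
    todo <- which(m & lab == 0L)
  }
  lab
}

#' Tractography target at the posterior confluence of the DRTT components
#'
#' Within an axial AC-PC slab 1.5 mm thick centred at \code{s_offset}, both
#' bundles are rasterized at 0.5 mm in-plane resolution, each footprint is
#' dilated by one raster cell, and the footprints are intersected. The
#' in-plane centroid of the 8-connected intersection component whose
#' centroid is most posterior (smallest A) becomes the target, at
#' \code{S = s_offset}. If the footprints do not intersect but the in-slab
#' gap between the bundles is at most 2 mm, the midpoint of the closest
#' approach pair is used instead.
#'
#' @param ddrtt,nddrtt non-empty \code{bundle}s.
#' @param frame an \code{acpc_frame}.
#' @param s_offset target height above the AC-PC plane, mm.
#' @param res in-plane raster resolution, mm.
#' @param half_thick slab half-thickness, mm.
#' @return an \code{acpc_point}; the attribute \code{footprint} carries the
#'   dilated intersection raster (used by the margin search).
#' @export
confluence_target <- function(ddrtt, nddrtt, frame, s_offset = 2,
                              res = 0.5, half_thick = 0.75) {
  if (!length(ddrtt) || !length(nddrtt))
    stop("confluence error: empty bundle", call. = FALSE)
  pd <- world_to_acpc(frame, bundle_points(ddrtt))
  pn <- world_to_acpc(frame, bundle_points(nddrtt))
  seld <- abs(pd[, 3] - s_offset) <= half_thick
  seln <- abs(pn[, 3] - s_offset) <= half_thick
  if (!any(seld) || !any(seln))
    stop(sprintf("confluence error: a bundle has no points in the S = %g slab",
                 s_offset), call. = FALSE)
  allp <- rbind(pd[seld, , drop = FALSE], pn[seln, , drop = FALSE])
  lattice <- list(res = res,
                  L0 = floor(min(allp[, 1]) / res) * res - 2 * res,
                  A0 = floor(min(allp[, 2]) / res) * res - 2 * res)
  lattice$nL <- ceiling((max(allp[, 1]) - lattice$L0) / res) + 3L
  lattice$nA <- ceiling((max(allp[, 2]) - lattice$A0) / res) + 3L
  md <- dilate2d(slab_raster(pd, s_offset, half_thick, lattice))
  mn <- dilate2d(slab_raster(pn, s_offset, half_thick, lattice))
  inter <- md & mn
  if (!any(inter)) {
    dd <- pd[seld, , drop = FALSE]; nn <- pn[seln, , drop = FALSE]
    best <- c(Inf, 0, 0)
    for (i in seq_len(nrow(dd))) {
      d2 <- (nn[, 1] - dd[i, 1])^2 + (nn[, 2] - dd[i, 2])^2
      j <- which.min(d2)
      if (d2[j] < best[1]) best <- c(d2[j], i, j)
    }
    gap <- sqrt(best[1])
    if (gap > 2)
      stop(sprintf(
        "confluence error: bundle footprints do not intersect at S = %g (gap %.1f mm)",
        s_offset, gap), call. = FALSE)
    mid <- (dd[best[2], 1:2] + nn[best[3], 1:2]) / 2
    tgt <- acpc_point(mid[1], mid[2], s_offset)
    attr(tgt, "footprint") <- list(lattice = lattice, cells = inter)
    return(tgt)
  }
  lab <- label2d(inter)
  cl <- sort(unique(lab[lab > 0]))
  cent <- t(vapply(cl, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(L = lattice$L0 + (mean(idx[, 1]) - 0.5) * res,
      A = lattice$A0 + (mean(idx[, 2]) - 0.5) * res)
  }, c(L = 0, A = 0)))
  pick <- which.min(cent[, "A"])   # most posterior confluence
  tgt <- acpc_point(cent[pick, "L"], cent[pick, "A"], s_offset)
  attr(tgt, "footprint") <- list(lattice = lattice, cells = inter,
                                 components = lab, picked = cl[pick],
                                 centroids = cent)
  tgt
}

point_in_footprint <- function(fp, L, A) {
  iL <- floor((L - fp$lattice$L0) / fp$lattice$res) + 1L
  iA <- floor((A - fp$lattice$A0) / fp$lattice$res) + 1L
  if (iL < 1 || iL > nrow(fp$cells) || iA < 1 || iA > ncol(fp$cells))
    return(FALSE)
  fp$cells[iL, iA]
}

#' Enforce the CST / ML safety margin
#'
#' Computes the minimum Euclidean distance from the candidate to all CST and
#' ML streamline points (in AC-PC mm, isometric to world mm). If the margin
#' holds the candidate is returned unchanged; otherwise it is shifted
#' in-plane in 0.25 mm increments directly away from the nearest violating
#' point, constrained to stay inside the DRTT intersection footprint, until
#' the margin holds. Distances are measured to the streamlines themselves;
#' burned-in masks read about 0.5 mm larger (see
#' \code{\link{voxelize_bundle}}).
#'
#' @param candidate an \code{acpc_point}.
#' @param cst,ml \code{bundle}s to stay clear of.
#' @param frame an \code{acpc_frame}.
#' @param margin_mm required clearance, mm, in [0, 5].
#' @param footprint the footprint attribute of a
#'   \code{\link{confluence_target}} (or NULL to search unconstrained).
#' @param max_travel_mm give up after this much in-plane travel.
#' @return list with \code{target} (the accepted \code{acpc_point}),
#'   \code{dist_cst}, \code{dist_ml}, \code{shift_mm}.
#' @export
enforce_margins <- function(candidate, cst, ml, frame, margin_mm = 2,
                            footprint = NULL, max_travel_mm = 3) {
  stopifnot(margin_mm >= 0, margin_mm <= 5)
  avoid <- list(cst = world_to_acpc(frame, bundle_points(cst)),
                ml = world_to_acpc(frame, bundle_points(ml)))
  mind <- function(p, pts) {
    if (!nrow(pts)) return(Inf)
    sqrt(min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2))
  }
  pos <- c(candidate$L, candidate$A, candidate$S)
  start <- pos
  step <- 0.25
  repeat {
    d_cst <- mind(pos, avoid$cst)
    d_ml <- mind(pos, avoid$ml)
    if (min(d_cst, d_ml) >= margin_mm) break
    if (vnorm(pos - start) + step > max_travel_mm + 1e-9)
      stop(sprintf(
        "margin-infeasible error: no admissible point within %g mm of travel (margin %g mm)",
        max_travel_mm, margin_mm), call. = FALSE)
    ## nearest violating point, in-plane escape direction
    all_av <- rbind(avoid$cst, avoid$ml)
    d2 <- (all_av[, 1] - pos[1])^2 + (all_av[, 2] - pos[2])^2 +
          (all_av[, 3] - pos[3])^2
    nearest <- all_av[which.min(d2), ]
    dirv <- c(pos[1] - nearest[1], pos[2] - nearest[2])
    if (vnorm(dirv) < 1e-9) dirv <- c(0, 1)   # coincident: shift anteriorly
    dirv <- dirv / vnorm(dirv)
    cand <- pos + step * c(dirv, 0)
    if (!is.null(footprint) &&
        !point_in_footprint(footprint, cand[1], cand[2]))
      stop(sprintf(
        "margin-infeasible error: margin %g mm cannot be met inside the DRTT footprint",
        margin_mm), call. = FALSE)
    pos <- cand
  }
  list(target = acpc_point(pos[1], pos[2], pos[3]),
       dist_cst = mind(pos, avoid$cst), dist_ml = mind(pos, avoid$ml),
       shift_mm = vnorm(pos - start))
}

#' Euclidean offset between an indirect and a tractography target
#'
#' 3-D Euclidean distance over (L, A, S). Following the published table
#' convention, the indirect target's S coordinate is taken as
#' \code{indirect_s} (default 2 mm above the AC-PC plane) regardless of its
#' stored value; pass \code{indirect_s = NULL} to use the stored coordinate
#' (in which case the offset is a true metric).
#'
#' @param indirect,tract \code{acpc_point}s in the same frame.
#' @param indirect_s override for the indirect S coordinate (mm), or NULL.
#' @return distance in mm.
#' @export
target_offset <- function(indirect, tract, indirect_s = 2) {
  si <- if (is.null(indirect_s)) indirect$S else indirect_s
  sqrt((indirect$L - tract$L)^2 + (indirect$A - tract$A)^2 +
       (si - tract$S)^2)
}

#' Compose a full treatment plan
#'
#' Indirect target, tractography targets at 2 and 4 mm above the AC-PC
#' plane (each at the most posterior dDRTT/ndDRTT confluence, each pushed to
#' the CST/ML safety margin), and the indirect-to-first-target offset.
#'
#' @param bundles named list with elements CST, ML, dDRTT, ndDRTT (all
#'   non-empty \code{bundle}s).
#' @param frame an \code{acpc_frame}.
#' @param margin_mm CST/ML clearance, mm (2 by default; some sites use 4).
#' @param ventricle_wall_L optional third-ventricle wall position, mm.
#' @param levels_mm heights of the tractography targets above the AC-PC
#'   plane.
#' @return object of class \code{target_plan}.
#' @export
make_plan <- function(bundles, frame, margin_mm = 2,
                      ventricle_wall_L = NULL, levels_mm = c(2, 4)) {
  need <- c("CST", "ML", "dDRTT", "ndDRTT")
  miss <- setdiff(need, names(bundles))
  if (length(miss))
    stop(sprintf("configuration error: missing bundle(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (nm in need)
    if (!length(bundles[[nm]]))
      stop(sprintf("configuration error: bundle %s is empty", nm),
           call. = FALSE)
  indirect <- indirect_target(frame, ventricle_wall_L)
  targets <- vector("list", length(levels_mm))
  margins <- vector("list", length(levels_mm))
  for (i in seq_along(levels_mm)) {
    lev <- levels_mm[i]
    tgt <- tryCatch(
      confluence_target(bundles$dDRTT, bundles$ndDRTT, frame, s_offset = lev),
      error = function(e) stop(sprintf("level S=%g mm: %s", lev,
                                       conditionMessage(e)), call. = FALSE))
    mr <- tryCatch(
      enforce_margins(tgt, bundles$CST, bundles$ML, frame, margin_mm,
                      footprint = attr(tgt, "footprint")),
      error = function(e) stop(sprintf("level S=%g mm: %s", lev,
                                       conditionMessage(e)), call. = FALSE))
    targets[[i]] <- mr$target
    attr(targets[[i]], "footprint") <- attr(tgt, "footprint")
    margins[[i]] <- mr
  }
  structure(list(indirect = indirect,
                 tract_target_1 = targets[[1]],
                 tract_target_2 = if (length(targets) > 1) targets[[2]] else NULL,
                 margin_mm = margin_mm,
                 margin_report = data.frame(
                   level_S_mm = levels_mm,
                   dist_cst_mm = vapply(margins, `[[`, 0, "dist_cst"),
                   dist_ml_mm = vapply(margins, `[[`, 0, "dist_ml"),
                   shift_mm = vapply(margins, `[[`, 0, "shift_mm")),
                 offset_mm = target_offset(indirect, targets[[1]]),
                 frame = frame),
            class = "target_plan")
}

#' @export
print.target_plan <- function(x, ...) {
  cat("<target_plan>\n  indirect target:      ")
  print(x$indirect)
  cat("  tract target (S=+2):  ")
  print(x$tract_target_1)
  if (!is.null(x$tract_target_2)) {
    cat("  tract target (S=+4):  ")
    print(x$tract_target_2)
  }
  cat(sprintf("  margin %g mm; clearances (mm):\n", x$margin_mm))
  print(round(x$margin_report, 2))
  cat(sprintf("  indirect -> first target offset: %.2f mm\n", x$offset_mm))
  invisible(x)
}
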