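#' Diffusion-weighted dataset
#'
#' @param signal 4-D array (x, y, z, volume).
#' @param bvals numeric per-volume b values, s/mm^2.
#' @param bvecs per-volume 3-vectors (unit norm where b > 0; zero rows for b0).
#' @param grid a \code{vox_grid} (voxel-to-world map of the first 3 dims).
#' @param mask optional logical array restricting the fit.
#' @return an object of class \code{dwi_dataset}.
#' @export
dwi_dataset <- function(signal, bvals, bvecs, grid, mask = NULL) {
  stopifnot(length(dim(signal)) == 4L, inherits(grid, "vox_grid"))
  bvecs <- rbind(bvecs)
  nvol <- dim(signal)[4]
  if (length(bvals) != nvol || nrow(bvecs) != nvol)
    stop(sprintf("gradient table length (%d bvals, %d bvecs) does not match %d volumes",
                 length(bvals), nrow(bvecs), nvol), call. = FALSE)
  if (!any(bvals == 0)) stop("need at least one b0 volume", call. = FALSE)
  nb <- sqrt(rowSums(bvecs^2))
  bad <- which(bvals > 0 & abs(nb - 1) > 1e-3)
  if (length(bad))
    stop(sprintf("non-unit b-vector for volume(s) %s (norm %s)",
                 paste(bad, collapse = ", "),
                 paste(format(nb[bad], digits = 4), collapse = ", ")),
         call. = FALSE)
  if (!identical(dim(signal)[1:3], as.integer(grid$shape)))
    stop("signal dimensions do not match the grid", call. = FALSE)
  structure(list(signal = signal, bvals = as.numeric(bvals), bvecs = bvecs,
                 grid = grid, mask = mask),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat(sprintf("<dwi_dataset> %s voxels, %d volumes (%d b0 + %d weighted, b = %s)\n",
              paste(dim(x$signal)[1:3], collapse = "x"), length(x$bvals),
              sum(x$bvals == 0), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = "/")))
  invisible(x)
}

## ---- vectorized analytic eigensystem of symmetric 3x3 tensors -------------

## lower: n x 6 (dxx, dyy, dzz, dxy, dxz, dyz). Returns n x 3 eigenvalues,
## sorted descending, via the trigonometric closed form.
eig3_values <- function(lower) {
  dxx <- lower[, 1]; dyy <- lower[, 2]; dzz <- lower[, 3]
  dxy <- lower[, 4]; dxz <- lower[, 5]; dyz <- lower[, 6]
  q <- (dxx + dyy + dzz) / 3
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 +
    2 * (dxy^2 + dxz^2 + dyz^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q
  nz <- which(p > 0)
  if (length(nz)) {
    pn <- p[nz]
    bxx <- (dxx[nz] - q[nz]) / pn; byy <- (dyy[nz] - q[nz]) / pn
    bzz <- (dzz[nz] - q[nz]) / pn
    bxy <- dxy[nz] / pn; bxz <- dxz[nz] / pn; byz <- dyz[nz] / pn
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * pn * cos(phi)
    l3[nz] <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

## principal eigenvector per row: for symmetric D, the matrix
## (D - l2 I)(D - l3 I) equals (l1-l2)(l1-l3) e1 e1'; any nonzero column is
## proportional to e1. Sign fixed so the first component of magnitude
## > 1e-12 is positive. Near-degenerate rows fall back to eigen().
eig3_principal <- function(lower, evals) {
  n <- nrow(lower)
  dxx <- lower[, 1]; dyy <- lower[, 2]; dzz <- lower[, 3]
  dxy <- lower[, 4]; dxz <- lower[, 5]; dyz <- lower[, 6]
  l2 <- evals[, 2]; l3 <- evals[, 3]
  ## C = (D - l2 I)(D - l3 I), computed columnwise
  a11 <- dxx - l2; a22 <- dyy - l2; a33 <- dzz - l2
  b11 <- dxx - l3; b22 <- dyy - l3; b33 <- dzz - l3
  c11 <- a11 * b11 + dxy * dxy + dxz * dxz
  c21 <- dxy * b11 + a22 * dxy + dyz * dxz
  c31 <- dxz * b11 + dyz * dxy + a33 * dxz
  c12 <- a11 * dxy + dxy * b22 + dxz * dyz
  c22 <- dxy * dxy + a22 * b22 + dyz * dyz
  c32 <- dxz * dxy + dyz * b22 + a33 * dyz
  c13 <- a11 * dxz + dxy * dyz + dxz * b33
  c23 <- dxy * dxz + a22 * dyz + dyz * b33
  c33 <- dxz * dxz + dyz * dyz + a33 * b33
  n1 <- c11^2 + c21^2 + c31^2
  n2 <- c12^2 + c22^2 + c32^2
  n3 <- c13^2 + c23^2 + c33^2
  pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
  v <- cbind(ifelse(pick == 1, c11, ifelse(pick == 2, c12, c13)),
             ifelse(pick == 1, c21, ifelse(pick == 2, c22, c23)),
             ifelse(pick == 1, c31, ifelse(pick == 2, c32, c33)))
  nv <- sqrt(rowSums(v^2))
  scale <- pmax(abs(evals[, 1]), abs(evals[, 3]), .Machine$double.xmin)
  degen <- nv <= 1e-10 * scale^2 | !is.finite(nv)
  ok <- which(!degen)
  v[ok, ] <- v[ok, ] / nv[ok]
  if (any(degen)) {
    ## (near-)isotropic tensors have no meaningful principal direction:
    ## deterministic placeholder. Rank-deficient but anisotropic rows
    ## (lambda1 ~ lambda2 > lambda3) get an exact eigen() fallback.
    q <- (dxx + dyy + dzz) / 3
    dev2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 +
      2 * (dxy^2 + dxz^2 + dyz^2)
    iso <- degen & (dev2 <= (1e-8 * scale)^2 | !is.finite(dev2))
    v[iso, ] <- matrix(c(1, 0, 0), sum(iso), 3, byrow = TRUE)
    for (i in which(degen & !iso)) {
      D <- matrix(c(dxx[i], dxy[i], dxz[i],
                    dxy[i], dyy[i], dyz[i],
                    dxz[i], dyz[i], dzz[i]), 3, 3)
      if (!all(is.finite(D))) { v[i, ] <- c(1, 0, 0); next }
      e <- eigen(D, symmetric = TRUE)
      v[i, ] <- e$vectors[, 1]
    }
  }
  ## deterministic sign: first non-zero component positive
  sgn <- ifelse(abs(v[, 1]) > 1e-12, sign(v[, 1]),
                ifelse(abs(v[, 2]) > 1e-12, sign(v[, 2]),
                       ifelse(abs(v[, 3]) > 1e-12, sign(v[, 3]), 1)))
  v * sgn
}

## FA from tensor invariants: FA = sqrt(3/2) * sqrt(1 - 3*md^2 / |D|_F^2),
## algebraically identical to the eigenvalue formula but exact in the
## tensor elements; 0 where the tensor vanishes.
fa_from_lower <- function(lower) {
  md <- (lower[, 1] + lower[, 2] + lower[, 3]) / 3
  fro2 <- lower[, 1]^2 + lower[, 2]^2 + lower[, 3]^2 +
    2 * (lower[, 4]^2 + lower[, 5]^2 + lower[, 6]^2)
  fa <- sqrt(1.5) * sqrt(pmax(0, 1 - 3 * md^2 / fro2))
  fa[fro2 == 0] <- 0
  pmin(fa, 1)
}

#' Tensor field
#'
#' Per-voxel symmetric diffusion tensors with their derived eigensystem.
#' Constructed by \code{\link{make_tensor_field}} (ground truth) or
#' \code{\link{fit_tensor_loglinear}} (fitted).
#'
#' @param lower n_voxels x 6 matrix of unique tensor elements
#'   (dxx, dyy, dzz, dxy, dxz, dyz), mm^2/s.
#' @param grid a \code{vox_grid}.
#' @param fit_ok optional logical vector flagging trustworthy voxels.
#' @return object of class \code{tensor_field} with fields \code{lower},
#'   \code{fa} (3-D array in [0,1]), \code{principal_dir} (n x 3 unit rows),
#'   \code{evals} (n x 3, descending), \code{fit_ok}.
#' @export
tensor_field <- function(lower, grid, fit_ok = NULL) {
  stopifnot(ncol(lower) == 6L, nrow(lower) == n_voxels(grid))
  evals <- eig3_values(lower)
  pd <- eig3_principal(lower, evals)
  fa <- fa_from_lower(lower)
  if (is.null(fit_ok)) fit_ok <- rep(TRUE, nrow(lower))
  structure(list(grid = grid, lower = lower,
                 fa = array(fa, dim = grid$shape),
                 principal_dir = pd, evals = evals,
                 fit_ok = fit_ok),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s voxels; FA range [%.3f, %.3f]; %d voxels flagged\n",
              paste(x$grid$shape, collapse = "x"), min(x$fa), max(x$fa),
              sum(!x$fit_ok)))
  invisible(x)
}

#' @export
summary.tensor_field <- function(object, ...) {
  fa <- as.vector(object$fa)
  out <- list(n_voxels = length(fa),
              fa_quartiles = stats::quantile(fa, c(0, .25, .5, .75, 1)),
              mean_md = mean(rowMeans(object$lower[, 1:3])),
              n_flagged = sum(!object$fit_ok))
  class(out) <- "summary.tensor_field"
  out
}

#' @export
print.summary.tensor_field <- function(x, ...) {
  cat(sprintf("tensor field: %d voxels, %d flagged\n", x$n_voxels, x$n_flagged))
  cat("FA quartiles:\n"); print(round(x$fa_quartiles, 4))
  cat(sprintf("mean MD: %.4g mm^2/s\n", x$mean_md))
  invisible(x)
}

#' Log-linear least-squares tensor fit
#'
#' Per voxel, solves the ordinary (unweighted) least-squares system
#' \code{ln S_i = ln S0 - b_i g_i' D g_i} for the six tensor elements and
#' \code{ln S0}. Non-positive signals are clamped to \code{1e-3} of the
#' voxel's mean b0 signal before the log (those voxels are flagged).
#' Voxels with strongly negative fitted eigenvalues
#' (\code{lambda3 < -0.1 * |lambda1|}) keep their tensors but are flagged
#' \code{fit_ok = FALSE}: transparency over silent repair.
#'
#' @param dwi a \code{dwi_dataset} with >= 1 b0 and >= 6 weighted volumes.
#' @return a \code{tensor_field}; the attribute \code{s0} holds the fitted
#'   baseline signal map.
#' @export
fit_tensor_loglinear <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  nvol <- length(dwi$bvals)
  n_dwi <- sum(dwi$bvals > 0)
  n_b0 <- sum(dwi$bvals == 0)
  if (n_b0 < 1 || n_dwi < 6 || nvol < 7)
    stop(sprintf(
      "protocol error: need >= 1 b0 and >= 6 weighted volumes (got %d b0, %d weighted)",
      n_b0, n_dwi), call. = FALSE)
  grid <- dwi$grid
  nv <- n_voxels(grid)
  sig <- matrix(dwi$signal, nv, nvol)
  vox_sel <- if (is.null(dwi$mask)) seq_len(nv) else which(as.vector(dwi$mask))
  s <- sig[vox_sel, , drop = FALSE]
  s0_est <- rowMeans(s[, dwi$bvals == 0, drop = FALSE])
  floor_val <- pmax(1e-3 * s0_est, .Machine$double.xmin)
  clamped <- rowSums(s <= 0) > 0
  s <- pmax(s, matrix(floor_val, nrow(s), ncol(s)))
  g <- dwi$bvecs; b <- dwi$bvals
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12)
    stop("protocol error: gradient scheme is degenerate for a tensor fit",
         call. = FALSE)
  beta <- solve(xtx, crossprod(X, t(log(s))))   # 7 x nsel
  lower_sel <- t(beta[2:7, , drop = FALSE])
  ## tensors at pure numerical-noise scale (orders below any physiological
  ## diffusivity) are zeroed: FA is scale-invariant, so leaving them would
  ## turn solver residue into arbitrary anisotropy
  tiny <- apply(abs(lower_sel), 1, max) < 1e-10
  lower_sel[tiny, ] <- 0
  colnames(lower_sel) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  lower <- matrix(0, nv, 6, dimnames = list(NULL, colnames(lower_sel)))
  lower[vox_sel, ] <- lower_sel
  tf <- tensor_field(lower, grid)
  ok <- rep(TRUE, nv)
  bad_eval <- tf$evals[, 3] < -0.1 * abs(tf$evals[, 1])
  ok[vox_sel] <- !clamped
  ok <- ok & !bad_eval
  if (!is.null(dwi$mask)) ok[-vox_sel] <- FALSE
  tf$fit_ok <- ok
  s0map <- rep(NA_real_, nv); s0map[vox_sel] <- exp(beta[1, ])
  attr(tf, "s0") <- array(s0map, dim = grid$shape)
  tf
}

#' Eigensystem metrics of symmetric tensors
#'
#' Eigen-decomposition with eigenvalues sorted descending, fractional
#' anisotropy \code{FA = sqrt(3/2) sqrt(sum((l_i - mean)^2)) / sqrt(sum l_i^2)}
#' (0 for a vanishing tensor), and the principal eigenvector with a
#' deterministic sign (first non-zero component positive).
#'
#' @param tensors an n x 6 matrix of unique elements
#'   (dxx, dyy, dzz, dxy, dxz, dyz), a single symmetric 3 x 3 matrix, or a
#'   3 x 3 x n array of symmetric matrices.
#' @return list with \code{fa} (length n), \code{principal_dir} (n x 3),
#'   \code{evals} (n x 3, descending).
#' @export
tensor_metrics <- function(tensors) {
  lower <- as_lower6(tensors)
  evals <- eig3_values(lower)
  list(fa = fa_from_lower(lower),
       principal_dir = eig3_principal(lower, evals),
       evals = evals)
}

as_lower6 <- function(tensors) {
  if (is.matrix(tensors) && all(dim(tensors) == c(3, 3))) {
    tensors <- array(tensors, dim = c(3, 3, 1))
  }
  if (is.array(tensors) && length(dim(tensors)) == 3L &&
      all(dim(tensors)[1:2] == c(3, 3))) {
    n <- dim(tensors)[3]
    asym <- apply(tensors, 3, function(m) max(abs(m - t(m))))
    scale <- apply(tensors, 3, function(m) max(abs(m), 1e-300))
    if (any(asym > 1e-8 * scale))
      stop("validation error: input tensors are not symmetric", call. = FALSE)
    return(cbind(tensors[1, 1, ], tensors[2, 2, ], tensors[3, 3, ],
                 tensors[1, 2, ], tensors[1, 3, ], tensors[2, 3, ]))
  }
  tensors <- rbind(tensors)
  if (ncol(tensors) != 6L)
    stop("tensors must be n x 6, 3 x 3, or 3 x 3 x n", call. = FALSE)
  tensors
}

## expand n x 6 lower representation to a single 3x3 (row i)
lower_to_mat <- function(lower, i = 1L) {
  matrix(c(lower[i, 1], lower[i, 4], lower[i, 5],
           lower[i, 4], lower[i, 2], lower[i, 6],
           lower[i, 5], lower[i, 6], lower[i, 3]), 3, 3)
}
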