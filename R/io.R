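#' Read a DWI dataset from NIfTI + FSL-style gradient files
#'
#' @param nifti path to a 4-D NIfTI volume.
#' @param bval,bvec paths to FSL-style text files (one row of b values; three
#'   rows of direction components).
#' @param mask optional path to a 3-D NIfTI mask.
#' @return a validated \code{dwi_dataset}.
#' @export
load_dwi <- function(nifti, bval, bvec, mask = NULL) {
  img <- RNifti::readNifti(nifti)
  if (length(dim(img)) != 4L)
    stop("format error: DWI volume must be 4-D", call. = FALSE)
  bvals <- scan(bval, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec))
  if (nrow(bv) == 3L) bv <- t(bv)
  if (length(bvals) != dim(img)[4])
    stop(sprintf("format error: %d b values for %d volumes",
                 length(bvals), dim(img)[4]), call. = FALSE)
  if (nrow(bv) != dim(img)[4])
    stop(sprintf("format error: %d b vectors for %d volumes",
                 nrow(bv), dim(img)[4]), call. = FALSE)
  grid <- grid_from_affine(RNifti::xform(img), dim(img)[1:3])
  mk <- NULL
  if (!is.null(mask)) {
    mimg <- RNifti::readNifti(mask)
    mk <- array(as.logical(mimg > 0), dim = dim(mimg))
  }
  dwi_dataset(array(as.numeric(img), dim = dim(img)), bvals, bv, grid, mk)
}

#' Write a DWI dataset (or any array on a grid) as NIfTI
#'
#' @param dwi a \code{dwi_dataset}; gradient files are written alongside.
#' @param path output .nii.gz path.
#' @return invisibly, the paths written.
#' @export
write_dwi <- function(dwi, path) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  write_nifti_grid(dwi$signal, dwi$grid, path)
  base <- sub("\\.nii(\\.gz)?$", "", path)
  writeLines(paste(format(dwi$bvals, trim = TRUE), collapse = " "),
             paste0(base, ".bval"))
  writeLines(apply(t(dwi$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
    paste0(base, ".bvec"))
  invisible(c(path, paste0(base, ".bval"), paste0(base, ".bvec")))
}

#' @rdname write_dwi
#' @param x numeric or logical 3-D/4-D array.
#' @param grid the \code{vox_grid} of the first three dimensions.
#' @export
write_nifti_grid <- function(x, grid, path) {
  img <- RNifti::asNifti(x + 0)   # logical -> numeric
  aff <- structure(grid_affine(grid), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D NIfTI volume back onto a vox_grid
#' @param path NIfTI file.
#' @return list with \code{data} (array) and \code{grid}.
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       grid = grid_from_affine(RNifti::xform(img), dim(img)[1:3]))
}

## ---- TCK (MRtrix) streamline files ---------------------------------------

#' Write a bundle as a TCK streamline file
#'
#' MRtrix track format: text header, then Float32LE point triplets with
#' NaN-triplet separators and an Inf-triplet terminator. Coordinates are
#' world mm.
#'
#' @param bundle a \code{bundle} (possibly empty).
#' @param path output .tck path.
#' @return invisibly, the path.
#' @export
write_tck <- function(bundle, path) {
  stopifnot(inherits(bundle, "bundle"))
  n <- length(bundle$streamlines)
  hdr_body <- c("mrtrix tracks",
                "datatype: Float32LE",
                sprintf("count: %d", n),
                sprintf("name: %s", bundle$name))
  ## the 'file: . <offset>' line must state the byte offset of the binary
  ## section, which depends on its own width; two passes settle it
  offset <- 0L
  for (i in 1:3) {
    hdr <- c(hdr_body, sprintf("file: . %d", offset), "END")
    new_offset <- sum(nchar(hdr, type = "bytes")) + length(hdr)  # + newlines
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  for (sl in bundle$streamlines) {
    writeBin(as.vector(t(sl$points)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK streamline file as a bundle
#'
#' @param path .tck file.
#' @param name bundle label (default: the header's name field, if present).
#' @return a \code{bundle} whose streamlines carry points only.
#' @export
read_tck <- function(path, name = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks"))
    stop("format error: not a TCK file (bad magic line)", call. = FALSE)
  fields <- list()
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("format error: TCK header has no END", call. = FALSE)
    if (identical(ln, "END")) break
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[kv[2]]] <- kv[3]
  }
  if (!is.null(fields[["file"]]))
    offset <- as.integer(sub("^\\. *", "", fields[["file"]]))
  if (is.na(offset)) stop("format error: TCK header lacks a file offset",
                          call. = FALSE)
  dt <- fields[["datatype"]]
  if (!is.null(dt) && !identical(dt, "Float32LE"))
    stop(sprintf("format error: unsupported TCK datatype %s", dt), call. = FALSE)
  seek(con, offset)
  raw_n <- file.size(path) - offset
  vals <- readBin(con, "numeric", n = raw_n %/% 4L, size = 4L,
                  endian = "little")
  if (length(vals) %% 3L != 0L)
    stop("format error: truncated TCK binary section", call. = FALSE)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  term <- which(apply(pts, 1, function(r) all(is.infinite(r))))
  if (!length(term))
    stop("format error: truncated TCK file (no terminator)", call. = FALSE)
  pts <- pts[seq_len(term[1] - 1L), , drop = FALSE]
  seps <- c(0L, which(apply(pts, 1, function(r) all(is.nan(r)))),
            nrow(pts) + 1L)
  strs <- list()
  for (i in seq_len(length(seps) - 1L)) {
    rng <- (seps[i] + 1L):(seps[i + 1L] - 1L)
    if (length(rng) < 1L || rng[1] > rng[length(rng)]) next
    strs[[length(strs) + 1L]] <-
      structure(list(points = pts[rng, , drop = FALSE],
                     seed = NULL,
                     stop_reasons = c(forward = NA, backward = NA)),
                class = "streamline")
  }
  expected <- suppressWarnings(as.integer(fields[["count"]]))
  if (!is.na(expected) && expected != length(strs))
    stop(sprintf("format error: header count %d but %d streamlines found",
                 expected, length(strs)), call. = FALSE)
  bundle(if (is.null(name)) fields[["name"]] %||% "tract" else name, strs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- landmarks and plan JSON ----------------------------------------------

#' Read / write AC-PC landmarks as JSON
#' @param path JSON file with fields ac, pc, midline (3-vectors, world mm).
#' @return list(ac, pc, midline).
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::fromJSON(path)
  for (k in c("ac", "pc", "midline"))
    if (is.null(lm[[k]]) || length(lm[[k]]) != 3L)
      stop(sprintf("format error: landmark '%s' missing or not a 3-vector", k),
           call. = FALSE)
  lapply(lm[c("ac", "pc", "midline")], as.numeric)
}

#' @rdname read_landmarks
#' @param landmarks list(ac, pc, midline).
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks[c("ac", "pc", "midline")], path, digits = NA)
  invisible(path)
}

plan_to_list <- function(plan) {
  pt <- function(p) if (is.null(p)) NULL else {
    w <- acpc_to_world(plan$frame, p)
    list(acpc = list(L = p$L, A = p$A, S = p$S),
         world = as.numeric(w))
  }
  list(indirect = pt(plan$indirect),
       tract_target_1 = pt(plan$tract_target_1),
       tract_target_2 = pt(plan$tract_target_2),
       margin_mm = plan$margin_mm,
       margin_report = plan$margin_report,
       offset_mm = plan$offset_mm,
       acpc_length_mm = plan$frame$acpc_length,
       side = plan$frame$side)
}

#' Write a target plan as JSON (AC-PC and world coordinates)
#' @param plan a \code{target_plan}.
#' @param path output path.
#' @param provenance optional named list appended verbatim.
#' @return invisibly, the path.
#' @export
write_plan <- function(plan, path, provenance = NULL) {
  out <- plan_to_list(plan)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

## ---- phantom export and the end-to-end pipeline ---------------------------

#' Write a phantom dataset to disk
#'
#' DWI as 4-D NIfTI with bval/bvec, ROI masks as uint8-style NIfTI volumes,
#' centerlines as TCK, landmarks and bundle specs as JSON.
#'
#' @param phantom a \code{phantom_truth}.
#' @param protocol a \code{dwi_protocol}.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_phantom <- function(phantom, protocol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  dwi <- synthesize_dwi(phantom$field, protocol)
  write_dwi(dwi, file.path(dir, "dwi.nii.gz"))
  for (nm in names(phantom$masks))
    write_nifti_grid(phantom$masks[[nm]], phantom$grid,
                     file.path(dir, "masks", paste0(nm, ".nii.gz")))
  for (nm in names(phantom$centerlines)) {
    cl <- phantom$centerlines[[nm]]
    write_tck(bundle(nm, list(structure(list(points = unclass(cl)[seq_len(nrow(cl)), ],
                                             stop_reasons = c(NA, NA)),
                                        class = "streamline"))),
              file.path(dir, paste0("centerline_", nm, ".tck")))
  }
  write_landmarks(phantom$landmarks, file.path(dir, "landmarks.json"))
  specs <- lapply(phantom$specs, function(sp)
    list(name = sp$name, control_points = sp$control_points,
         radius = sp$radius,
         fa_target = if (is.function(sp$fa_target)) "profile" else sp$fa_target,
         mean_diffusivity = sp$mean_diffusivity))
  jsonlite::write_json(list(specs = specs, variant = phantom$variant,
                            roi_table = phantom$roi_table),
                       file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Run the full targeting pipeline
#'
#' Tensor fit, four-tract delineation, target planning and burn-in overlay,
#' end to end, writing \code{plan.json}, \code{overlay.nii.gz}, per-tract
#' TCK bundles, burn masks and \code{report.tsv} (the bundled-cohort
#' report) under \code{out_dir}. Deterministic: rerunning with the same
#' inputs and seed reproduces \code{plan.json} byte for byte.
#'
#' @param config list with elements \code{dwi}, \code{bval}, \code{bvec},
#'   \code{masks_dir}, \code{landmarks} (paths), and optionally
#'   \code{margin_mm}, \code{side}, \code{seed}, \code{anat_voxel_mm},
#'   \code{params} (a \code{tracking_params}).
#' @param out_dir output directory.
#' @return invisibly, a list with the fitted field, bundles, plan and paths.
#' @export
run_pipeline <- function(config, out_dir) {
  for (k in c("dwi", "bval", "bvec", "masks_dir", "landmarks"))
    if (is.null(config[[k]]) || !file.exists(config[[k]]))
      stop(sprintf("validation error: config path '%s' missing or nonexistent", k),
           call. = FALSE)
  margin <- config$margin_mm %||% 2
  side <- config$side %||% "left"
  seed <- config$seed %||% 1L
  params <- config$params %||% tracking_params(jitter_seed = as.integer(seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  message("[fit] loading DWI and fitting tensors")
  dwi <- load_dwi(config$dwi, config$bval, config$bvec)
  field <- fit_tensor_loglinear(dwi)

  message("[track-four] delineating CST, ML, ndDRTT, dDRTT")
  mask_files <- list.files(config$masks_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE)
  masks <- lapply(mask_files, function(f) {
    v <- read_nifti_grid(f)
    if (!same_grid(v$grid, field$grid))
      stop(sprintf("validation error: mask %s not on the DWI grid", basename(f)),
           call. = FALSE)
    array(v$data > 0, dim = field$grid$shape)
  })
  names(masks) <- sub("\\.nii(\\.gz)?$", "", basename(mask_files))
  bundles <- track_four(field, masks, side = side, params = params)
  for (nm in names(bundles)) {
    write_tck(bundles[[nm]], file.path(out_dir, paste0(nm, ".tck")))
    message(sprintf("  %s: %d streamlines (cascade step %d)", nm,
                    length(bundles[[nm]]), bundles[[nm]]$cascade_step))
  }

  message("[plan] AC-PC frame and targeting")
  lm <- read_landmarks(config$landmarks)
  frame <- acpc_frame(lm$ac, lm$pc, lm$midline, side = side)
  plan <- make_plan(bundles, frame, margin_mm = margin)

  message("[burnin] composing overlay")
  anat_vox <- config$anat_voxel_mm %||% 1.0
  anat_grid <- vox_grid(round(field$grid$shape * field$grid$voxel / anat_vox),
                        anat_vox)
  drtt <- mask_union(voxelize_bundle(bundles$dDRTT, anat_grid),
                     voxelize_bundle(bundles$ndDRTT, anat_grid))
  cstml <- mask_union(voxelize_bundle(bundles$CST, anat_grid),
                      voxelize_bundle(bundles$ML, anat_grid))
  overlay <- compose_overlay(synthetic_anatomy(anat_grid), drtt, cstml)
  write_nifti_grid(overlay, anat_grid, file.path(out_dir, "overlay.nii.gz"))
  write_nifti_grid(drtt$mask, anat_grid, file.path(out_dir, "drtt_mask.nii.gz"))
  write_nifti_grid(cstml$mask, anat_grid, file.path(out_dir, "cstml_mask.nii.gz"))

  message("[report] bundled cohort report")
  rep <- cohort_report()
  write_cohort_report(rep, file.path(out_dir, "report.tsv"))

  cfg_json <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                               force = TRUE)
  prov <- list(package = "fourtract",
               version = as.character(utils::packageVersion("fourtract")),
               config_hash = config_hash(cfg_json),
               margin_mm = margin, side = side, seed = seed,
               params = unclass(params),
               cascade_steps = as.list(vapply(bundles, `[[`, 0L, "cascade_step")),
               streamline_counts = as.list(vapply(bundles, length, 0L)))
  write_plan(plan, file.path(out_dir, "plan.json"), provenance = prov)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[done] plan offset %.2f mm; outputs in %s", plan$offset_mm,
                  out_dir))
  invisible(list(field = field, bundles = bundles, plan = plan,
                 out_dir = out_dir))
}

config_hash <- function(json_string) {
  f <- tempfile()
  writeLines(as.character(json_string), f)
  unname(tools::md5sum(f))
}
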