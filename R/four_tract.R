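#' The four tract recipes
#'
#' Encodes the ROI recipes of four-tract delineation: the corticospinal
#' tract (precentral seed, ipsilateral cerebral peduncle waypoint), the
#' medial lemniscus (postcentral seed, dorso-lateral midbrain waypoint), the
#' non-decussating DRTT (ipsilateral dentate seed, ipsilateral red nucleus
#' and precentral waypoints) and the decussating DRTT (contralateral dentate
#' seed, ipsilateral red nucleus and precentral waypoints).
#'
#' @param side treated side ("left" supported by the bundled phantom).
#' @param default_params,fallback defaults and the rescue parameter set.
#' @return named list of recipes (class \code{tract_recipe} each).
#' @export
tract_recipes <- function(side = "left",
                          default_params = tracking_params(),
                          fallback = fallback_params(default_params)) {
  ipsi <- side
  contra <- if (side == "left") "right" else "left"
  mk <- function(name, seed, include) {
    structure(list(name = name, seed_roi = seed, include_rois = include,
                   side = side, default_params = default_params,
                   fallback_params = fallback),
              class = "tract_recipe")
  }
  list(
    CST = mk("CST", "precentral", "cerebral_peduncle"),
    ML = mk("ML", "postcentral", "midbrain_dorsolateral"),
    ndDRTT = mk("ndDRTT", paste0("dentate_", ipsi),
                c(paste0("red_nucleus_", ipsi), "precentral")),
    dDRTT = mk("dDRTT", paste0("dentate_", contra),
               c(paste0("red_nucleus_", ipsi), "precentral")))
}

#' @export
print.tract_recipe <- function(x, ...) {
  cat(sprintf("<tract_recipe> %s (%s): seed %s; include %s\n", x$name, x$side,
              x$seed_roi, paste(x$include_rois, collapse = ", ")))
  invisible(x)
}

resolve_roi <- function(masks, name) {
  if (is.null(masks[[name]]))
    stop(sprintf("configuration error: ROI '%s' not found in mask set", name),
         call. = FALSE)
  masks[[name]]
}

#' Build one tract, with the dDRTT rescue cascade
#'
#' Runs \code{\link{track_with_rois}} with the recipe's default parameters
#' (cascade step 0). If the result is empty and the recipe is the
#' decussating DRTT, the published rescue cascade is applied in order:
#' step 1 re-examines the red-nucleus ROI (operationalized as a one-voxel
#' dilation) and retries; step 2 retries with the fallback parameters
#' (FA 0.11, minimum length 40 mm, maximum angle 50 degrees); step 3
#' substitutes the combined motor-cortex ROI (precentral + supplementary
#' motor + premotor) for the precentral waypoint and retries with the
#' fallback parameters. The first non-empty bundle is returned with its
#' cascade step recorded; if all steps fail an empty bundle with
#' cascade step 3 is returned.
#'
#' @param recipe a \code{tract_recipe} (from \code{\link{tract_recipes}}).
#' @param field a \code{tensor_field}.
#' @param masks named list of logical ROI arrays on the field grid; the
#'   dDRTT rescue additionally requires \code{combined_motor}.
#' @return a \code{bundle} with \code{cascade_step} provenance.
#' @export
build_tract <- function(recipe, field, masks) {
  if (!inherits(recipe, "tract_recipe"))
    stop("configuration error: not a tract recipe", call. = FALSE)
  seed <- resolve_roi(masks, recipe$seed_roi)
  include <- lapply(recipe$include_rois, resolve_roi, masks = masks)
  names(include) <- recipe$include_rois
  b <- track_with_rois(field, seed, include, recipe$default_params,
                       name = recipe$name)
  b$cascade_step <- 0L
  if (length(b) > 0L || recipe$name != "dDRTT") return(b)

  rn_name <- grep("^red_nucleus_", recipe$include_rois, value = TRUE)
  ## step 1: check/adjust the red nucleus ROI (one-voxel dilation)
  inc1 <- include
  if (length(rn_name)) inc1[[rn_name]] <- dilate_mask(include[[rn_name]])
  b <- track_with_rois(field, seed, inc1, recipe$default_params,
                       name = recipe$name)
  b$cascade_step <- 1L
  if (length(b) > 0L) return(b)

  ## step 2: fallback tracking parameters
  b <- track_with_rois(field, seed, inc1, recipe$fallback_params,
                       name = recipe$name)
  b$cascade_step <- 2L
  if (length(b) > 0L) return(b)

  ## step 3: combined motor-cortex ROI replaces the precentral waypoint
  inc3 <- inc1
  if (!is.null(inc3[["precentral"]]))
    inc3[["precentral"]] <- resolve_roi(masks, "combined_motor")
  b <- track_with_rois(field, seed, inc3, recipe$fallback_params,
                       name = recipe$name)
  b$cascade_step <- 3L
  b
}

#' Delineate all four tracts
#'
#' @param field a \code{tensor_field}.
#' @param masks named list of ROI masks.
#' @param side treated side.
#' @param params default \code{tracking_params}.
#' @return named list of four \code{bundle}s (CST, ML, ndDRTT, dDRTT).
#' @export
track_four <- function(field, masks, side = "left",
                       params = tracking_params()) {
  recipes <- tract_recipes(side, default_params = params,
                           fallback = fallback_params(params))
  lapply(recipes, build_tract, field = field, masks = masks)
}
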