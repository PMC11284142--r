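# Labeled landmark sets for one axial slice of one tibia.

#' Controlled structure vocabularies per slice
#'
#' The proximal slice (taken at the level of the growth plate) carries the
#' medial and lateral plateau arcs and the posterior margin points; the
#' ankle slice (the first axial section through the talar body, distal
#' fibular epiphysis and medial malleolus) carries the two malleolus point
#' sets and the two talar facet point sets.
#'
#' @format A named list with elements `proximal` and `ankle`, each a
#'   character vector of required structure labels.
#' @export
slice_structures <- list(
  proximal = c("medial_plateau", "lateral_plateau", "posterior_margin"),
  ankle = c("medial_malleolus", "lateral_malleolus",
            "talus_medial_facet", "talus_lateral_facet")
)

# minimum point counts per structure label
.structure_min_points <- c(
  medial_plateau = 3L, lateral_plateau = 3L, posterior_margin = 2L,
  medial_malleolus = 1L, lateral_malleolus = 1L,
  talus_medial_facet = 2L, talus_lateral_facet = 2L
)

#' Construct a labeled landmark set for one slice of one tibia
#'
#' @param subject_id Subject identifier (character scalar).
#' @param side `"left"` or `"right"`.
#' @param slice `"proximal"` or `"ankle"`.
#' @param structures Named list mapping each required structure label for
#'   the slice to an ordered point set (anything [as_points()] accepts).
#' @param rater,session Optional provenance (rater identifier, session
#'   number) carried through to measurements.
#' @return An object of class `"landmark_set"`.
#' @export
landmark_set <- function(subject_id, side, slice, structures,
                         rater = NA, session = NA_integer_) {
  side <- check_side(side)
  if (length(slice) != 1L || !slice %in% names(slice_structures)) {
    stop("slice must be \"proximal\" or \"ankle\"", call. = FALSE)
  }
  required <- slice_structures[[slice]]
  if (!is.list(structures) || is.null(names(structures))) {
    stop("structures must be a named list of point sets", call. = FALSE)
  }
  unknown <- setdiff(names(structures), required)
  if (length(unknown)) {
    stop(sprintf("unknown structure label(s) for %s slice: %s",
                 slice, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(required, names(structures))
  if (length(missing)) {
    stop(sprintf("missing structure label(s) for %s slice of %s/%s: %s",
                 slice, subject_id, side, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  structures <- lapply(structures, as_points)
  for (lab in required) {
    need <- .structure_min_points[[lab]]
    if (nrow(structures[[lab]]) < need) {
      stop(sprintf("structure '%s' of %s/%s needs >= %d points, got %d",
                   lab, subject_id, side, need, nrow(structures[[lab]])),
           call. = FALSE)
    }
  }
  structure(
    list(subject_id = as.character(subject_id), side = side, slice = slice,
         structures = structures[required], rater = rater,
         session = as.integer(session)),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  npts <- vapply(x$structures, nrow, integer(1))
  cat(sprintf("<landmark_set> %s / %s / %s slice (rater %s, session %s)\n",
              x$subject_id, x$side, x$slice, x$rater, x$session))
  cat(paste(sprintf("  %s: %d points", names(npts), npts), collapse = "\n"), "\n")
  invisible(x)
}

#' Rigidly transform every point of a landmark set
#'
#' Rotation (about a center) and/or mirroring about a vertical line, applied
#' to all structures; used by the simulator and by symmetry checks.
#'
#' @param lm A `"landmark_set"`.
#' @param theta_deg Counterclockwise rotation in degrees (applied first).
#' @param center Rotation center.
#' @param mirror_x0 If non-`NULL`, mirror about the vertical line `x = mirror_x0`
#'   after rotating, and swap the recorded side.
#' @return The transformed `"landmark_set"`.
#' @export
transform_landmarks <- function(lm, theta_deg = 0, center = c(0, 0),
                                mirror_x0 = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  lm$structures <- lapply(lm$structures, rotate_points,
                          theta_deg = theta_deg, center = center)
  if (!is.null(mirror_x0)) {
    lm$structures <- lapply(lm$structures, mirror_points, x0 = mirror_x0)
    lm$side <- if (lm$side == "left") "right" else "left"
  }
  lm
}
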