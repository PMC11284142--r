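# The four named axial angle measures and the derived torsion angles.
#
# All four measures share the same skeleton: construct an axis from the
# slice's landmarks, take its raw angle to the horizontal, then apply the
# anatomical sign convention (internal rotation negative) for the recorded
# side.

new_angle_measurement <- function(method, value, lm) {
  structure(
    list(method = method, value = value, subject_id = lm$subject_id,
         side = lm$side, rater = lm$rater, session = lm$session),
    class = "angle_measurement"
  )
}

#' @export
print.angle_measurement <- function(x, ...) {
  cat(sprintf("%s = %.3f deg  (%s / %s, rater %s, session %s)\n",
              x$method, x$value, x$subject_id, x$side, x$rater, x$session))
  invisible(x)
}

#' @export
as.numeric.angle_measurement <- function(x, ...) x$value

check_slice <- function(lm, slice, method) {
  stopifnot(inherits(lm, "landmark_set"))
  if (lm$slice != slice) {
    stop(sprintf("%s requires a %s slice, got %s (subject %s/%s)",
                 method, slice, lm$slice, lm$subject_id, lm$side),
         call. = FALSE)
  }
  lm
}

#' Proximal transtibial angle (PTTA)
#'
#' Fits one circle to each tibial plateau arc (medial and lateral); the
#' transtibial axis runs through the two fitted centers and the PTTA is its
#' signed anatomical angle to the horizontal.
#'
#' @param lm A proximal-slice `"landmark_set"`.
#' @return An `"angle_measurement"` with method `"PTTA"`.
#' @export
measure_ptta <- function(lm) {
  check_slice(lm, "proximal", "PTTA")
  cm <- fit_circle(lm$structures$medial_plateau, label = "medial_plateau")
  cl <- fit_circle(lm$structures$lateral_plateau, label = "lateral_plateau")
  sep <- cl$center - cm$center
  if (sqrt(sum(sep^2)) < 1e-9) {
    stop(sprintf("PTTA: coincident plateau circle centers for %s/%s",
                 lm$subject_id, lm$side), call. = FALSE)
  }
  ax <- new_axis(cm$center, sep)
  new_angle_measurement("PTTA", anatomical_sign(axis_angle(ax), lm$side), lm)
}

#' Posterior margin tibial plateau angle (PMTPA)
#'
#' Total-least-squares line through the posterior-margin points of the
#' tibial plateau, signed anatomically.
#'
#' @param lm A proximal-slice `"landmark_set"`.
#' @return An `"angle_measurement"` with method `"PMTPA"`.
#' @export
measure_pmtpa <- function(lm) {
  check_slice(lm, "proximal", "PMTPA")
  ax <- fit_line(lm$structures$posterior_margin, label = "posterior_margin")
  new_angle_measurement("PMTPA", anatomical_sign(axis_angle(ax), lm$side), lm)
}

#' Intermalleolar angle (IMA)
#'
#' The intermalleolar axis runs through the centroid of the medial
#' (tibial) malleolus points and the centroid of the lateral (fibular)
#' malleolus points; the IMA is its signed anatomical angle to the
#' horizontal.
#'
#' @param lm An ankle-slice `"landmark_set"`.
#' @return An `"angle_measurement"` with method `"IMA"`.
#' @export
measure_ima <- function(lm) {
  check_slice(lm, "ankle", "IMA")
  m <- colMeans(lm$structures$medial_malleolus)
  l <- colMeans(lm$structures$lateral_malleolus)
  if (sqrt(sum((l - m)^2)) < 1e-9) {
    stop(sprintf("IMA: coincident malleolar centroids for %s/%s",
                 lm$subject_id, lm$side), call. = FALSE)
  }
  ax <- new_axis(m, l - m)
  new_angle_measurement("IMA", anatomical_sign(axis_angle(ax), lm$side), lm)
}

#' Talar angle (TA)
#'
#' Tangent lines are fitted to the medial and lateral talar facet points;
#' the talar axis is the perpendicular to the bisector of the two tangents
#' (the anteroposterior bisector), and the TA is the talar axis' signed
#' anatomical angle to the horizontal. The talar axis approximates the
#' geometric axis of the tibiotalar joint and is insensitive to fibular
#' position.
#'
#' Two bisectors of the tangent pair exist, 90 degrees apart. The
#' anteroposterior one is identified from the facet labels: the talar axis
#' is the bisector representative better aligned with the medial-to-lateral
#' facet direction, which stays correct at any talar rotation (a
#' closest-to-vertical rule would flip by 90 degrees once the talar axis
#' tilts past 45 degrees). When the facet centroids coincide the
#' near-horizontal representative is used.
#'
#' @param lm An ankle-slice `"landmark_set"`.
#' @return An `"angle_measurement"` with method `"TA"`.
#' @export
measure_ta <- function(lm) {
  check_slice(lm, "ankle", "TA")
  tm <- fit_line(lm$structures$talus_medial_facet, label = "talus_medial_facet")
  tl <- fit_line(lm$structures$talus_lateral_facet, label = "talus_lateral_facet")
  bis <- bisector_direction(tm, tl)
  cand <- perpendicular(bis)  # talar-axis candidate; `bis` is the other one
  m2l <- colMeans(lm$structures$talus_lateral_facet) -
    colMeans(lm$structures$talus_medial_facet)
  talar_axis <- if (sqrt(sum(m2l^2)) > 1e-9 &&
                    abs(sum(bis * m2l)) > abs(sum(cand * m2l))) bis else cand
  new_angle_measurement("TA", anatomical_sign(axis_angle(talar_axis), lm$side), lm)
}

#' Tibial torsion angle from a proximal and a distal angle measurement
#'
#' Torsion is the distal angle minus the proximal angle, so external
#' torsion is positive. TTA1 pairs the posterior-margin angle (PMTPA) with
#' the intermalleolar angle (IMA); TTA2 pairs the PMTPA with the talar
#' angle (TA).
#'
#' @param proximal An `"angle_measurement"` (PMTPA or PTTA) or a numeric
#'   angle in degrees.
#' @param distal An `"angle_measurement"` (IMA or TA) or a numeric angle.
#' @return Torsion in degrees (numeric scalar).
#' @examples
#' compute_torsion(-7.6, 23.0)  # 30.6 degrees of external torsion
#' @export
compute_torsion <- function(proximal, distal) {
  if (inherits(proximal, "angle_measurement") &&
      inherits(distal, "angle_measurement")) {
    if (!identical(proximal$subject_id, distal$subject_id) ||
        !identical(proximal$side, distal$side)) {
      stop(sprintf(
        "torsion pairing error: proximal is %s/%s but distal is %s/%s",
        proximal$subject_id, proximal$side, distal$subject_id, distal$side),
        call. = FALSE)
    }
  }
  angle_value(distal) - angle_value(proximal)
}

angle_value <- function(x) {
  if (inherits(x, "angle_measurement")) x$value else as.numeric(x)
}

#' Measure one tibia from its two slices
#'
#' @param proximal,ankle The proximal- and ankle-slice `"landmark_set"`s of
#'   one tibia (matching subject and side).
#' @return A one-row data frame with columns `subject_id`, `side`, `ptta`,
#'   `pmtpa`, `ima`, `ta`, `tta1`, `tta2`, `rater`, `session`.
#' @export
measure_tibia <- function(proximal, ankle) {
  check_slice(proximal, "proximal", "measure_tibia")
  check_slice(ankle, "ankle", "measure_tibia")
  if (!identical(proximal$subject_id, ankle$subject_id) ||
      !identical(proximal$side, ankle$side)) {
    stop(sprintf("slice pairing error: proximal %s/%s vs ankle %s/%s",
                 proximal$subject_id, proximal$side,
                 ankle$subject_id, ankle$side), call. = FALSE)
  }
  ptta <- measure_ptta(proximal)$value
  pmtpa <- measure_pmtpa(proximal)$value
  ima <- measure_ima(ankle)$value
  ta <- measure_ta(ankle)$value
  data.frame(
    subject_id = proximal$subject_id, side = proximal$side,
    ptta = ptta, pmtpa = pmtpa, ima = ima, ta = ta,
    tta1 = ima - pmtpa, tta2 = ta - pmtpa,
    rater = proximal$rater, session = proximal$session,
    stringsAsFactors = FALSE
  )
}

#' Measure a batch of tibias
#'
#' Groups landmark sets by (subject, side, rater, session), measures every
#' tibia that has both slices, and collects per-tibia failures (missing
#' slice, degenerate geometry) instead of aborting the batch.
#'
#' @param sets A list of `"landmark_set"` objects (both slices per tibia).
#' @return An object of class `"torsion_cohort"`: a list with `records`
#'   (data frame, one row per measured tibia, ordered by subject then side)
#'   and `exclusions` (data frame of tibias that could not be measured,
#'   with the reason).
#' @export
measure_cohort <- function(sets) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  stopifnot(is.list(sets), all(vapply(sets, inherits, logical(1), "landmark_set")))
  keys <- vapply(sets, function(s) {
    paste(s$subject_id, s$side, s$rater, s$session, sep = "\r")
  }, character(1))
  groups <- split(sets, keys)
  rec_list <- list()
  exc <- list()
  for (key in sort(names(groups))) {
    g <- groups[[key]]
    slices <- vapply(g, `[[`, character(1), "slice")
    id <- g[[1L]]$subject_id
    side <- g[[1L]]$side
    res <- tryCatch({
      if (sum(slices == "proximal") != 1L || sum(slices == "ankle") != 1L) {
        stop(sprintf("tibia %s/%s: expected one proximal and one ankle slice, got %s",
                     id, side, paste(slices, collapse = "+")), call. = FALSE)
      }
      measure_tibia(g[[which(slices == "proximal")]], g[[which(slices == "ankle")]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exc[[length(exc) + 1L]] <- data.frame(
        subject_id = id, side = side, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rec_list[[length(rec_list) + 1L]] <- res
    }
  }
  records <- if (length(rec_list)) do.call(rbind, rec_list) else
    data.frame(subject_id = character(), side = character(), ptta = numeric(),
               pmtpa = numeric(), ima = numeric(), ta = numeric(),
               tta1 = numeric(), tta2 = numeric(), rater = character(),
               session = integer(), stringsAsFactors = FALSE)
  ord <- order(records$subject_id, records$side, records$rater, records$session)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  exclusions <- if (length(exc)) do.call(rbind, exc) else
    data.frame(subject_id = character(), side = character(),
               reason = character(), stringsAsFactors = FALSE)
  structure(list(records = records, exclusions = exclusions),
            class = "torsion_cohort")
}

#' @export
print.torsion_cohort <- function(x, ...) {
  cat(sprintf("<torsion_cohort> %d tibia(s) measured, %d excluded\n",
              nrow(x$records), nrow(x$exclusions)))
  if (nrow(x$records)) {
    print(utils::head(x$records, 6L))
    if (nrow(x$records) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x$records) - 6L))
  }
  if (nrow(x$exclusions)) {
    cat("excluded:\n")
    print(x$exclusions)
  }
  invisible(x)
}

#' @export
summary.torsion_cohort <- function(object, ...) {
  angle_summary_table(object$records)
}
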