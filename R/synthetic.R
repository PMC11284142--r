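# Synthetic landmark cohorts with known ground-truth angles.
#
# The simulator realizes the measurement geometry exactly: a canonical
# zero-angle template per slice is rigidly rotated by the true angles, the
# fibular (lateral) malleolus is additionally displaced along its malleolar
# arc to create a controlled IMA - TA offset, and rater placement noise is
# isotropic Gaussian jitter on landmark coordinates (mm), so reliability
# statistics reflect geometry-propagated error as in the manual protocol.

#' Canonical zero-angle proximal slice template
#'
#' Medial plateau arc on a circle of radius 12 mm centered at (-20, 0),
#' lateral arc on radius 11 mm centered at (20, 0), posterior margin points
#' on the horizontal line y = -14 mm. By construction PTTA = PMTPA = 0 and
#' the transtibial axis is parallel to the posterior margin.
#'
#' @param subject_id,side,rater,session Provenance fields for the returned
#'   set.
#' @param n_arc Points per plateau arc (>= 3; default 10).
#' @param n_margin Points on the posterior margin (>= 2; default 5).
#' @return A proximal-slice `"landmark_set"`.
#' @export
make_proximal_template <- function(subject_id = "template", side = "right",
                                   rater = NA, session = NA_integer_,
                                   n_arc = 10L, n_margin = 5L) {
  arc <- function(center, r, from_deg, to_deg, n) {
    th <- seq(from_deg, to_deg, length.out = n) * DEG2RAD
    cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
  }
  landmark_set(
    subject_id, side, "proximal",
    structures = list(
      medial_plateau = arc(c(-20, 0), 12, 120, 240, n_arc),
      lateral_plateau = arc(c(20, 0), 11, -60, 60, n_arc),
      posterior_margin = cbind(seq(-15, 15, length.out = n_margin), -14)
    ),
    rater = rater, session = session
  )
}

#' Canonical zero-angle ankle slice template
#'
#' Malleolar point clusters are regular rings whose centroids sit exactly at
#' (-25, 0) (medial/tibial) and (25, 0) (lateral/fibular), both 25 mm from
#' the talar center at the origin; talar facet points lie on near-sagittal
#' lines through (-10, 0) and (10, 0) tilted symmetrically (100 and 80
#' degrees from horizontal), so the facet bisector is vertical and
#' IMA = TA = 0 by construction.
#'
#' @inheritParams make_proximal_template
#' @param n_malleolus Points per malleolar cluster (default 6).
#' @param n_facet Points per talar facet (default 8).
#' @return An ankle-slice `"landmark_set"`.
#' @export
make_ankle_template <- function(subject_id = "template", side = "right",
                                rater = NA, session = NA_integer_,
                                n_malleolus = 6L, n_facet = 8L) {
  ring <- function(center, r, n) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
  }
  seg <- function(through, angle_deg, half_len, n) {
    s <- seq(-half_len, half_len, length.out = n)
    d <- c(cos(angle_deg * DEG2RAD), sin(angle_deg * DEG2RAD))
    cbind(through[1L] + s * d[1L], through[2L] + s * d[2L])
  }
  landmark_set(
    subject_id, side, "ankle",
    structures = list(
      medial_malleolus = ring(c(-25, 0), 4, n_malleolus),
      lateral_malleolus = ring(c(25, 0), 3.5, n_malleolus),
      talus_medial_facet = seg(c(-10, 0), 100, 8, n_facet),
      talus_lateral_facet = seg(c(10, 0), 80, 8, n_facet)
    ),
    rater = rater, session = session
  )
}

#' Synthesize one tibia's landmark sets with known true angles
#'
#' The proximal template is rotated by the proximal angle, so
#' PMTPA = PTTA = `proximal`. On the ankle slice the talus and medial
#' malleolus are rotated by `distal_talar` while the lateral (fibular)
#' malleolus is rotated by `distal_talar + 2 * fibular_offset` about the
#' talar center; because both malleolar centroids lie on the same 25 mm
#' circle, the chord direction through them then makes exactly
#' `distal_talar + fibular_offset` with the horizontal, i.e.
#' IMA = TA + `fibular_offset`. Both slices are constructed in the
#' right-side layout and mirrored about x = 0 for left tibias, so the
#' anatomical angles equal the requested truths for either side.
#'
#' @param proximal True proximal angle (PMTPA = PTTA), degrees.
#' @param distal_talar True talar angle (TA), degrees.
#' @param fibular_offset Fibular contribution to IMA - TA, degrees.
#' @param side `"left"` or `"right"`.
#' @param subject_id,rater,session Provenance fields.
#' @return A list with elements `proximal` and `ankle` (two
#'   `"landmark_set"`s).
#' @export
synthesize_tibia <- function(proximal, distal_talar, fibular_offset = 0,
                             side = "right", subject_id = "synthetic",
                             rater = NA, session = NA_integer_) {
  side <- check_side(side)
  stopifnot(abs(proximal) < 90, abs(distal_talar) < 90,
            abs(distal_talar + fibular_offset) < 90)
  prox <- make_proximal_template(subject_id, "right", rater, session)
  prox <- transform_landmarks(prox, theta_deg = proximal)
  ank <- make_ankle_template(subject_id, "right", rater, session)
  st <- ank$structures
  st$medial_malleolus <- rotate_points(st$medial_malleolus, distal_talar)
  st$talus_medial_facet <- rotate_points(st$talus_medial_facet, distal_talar)
  st$talus_lateral_facet <- rotate_points(st$talus_lateral_facet, distal_talar)
  st$lateral_malleolus <- rotate_points(st$lateral_malleolus,
                                        distal_talar + 2 * fibular_offset)
  ank$structures <- st
  if (side == "left") {
    prox <- transform_landmarks(prox, mirror_x0 = 0)
    ank <- transform_landmarks(ank, mirror_x0 = 0)
  }
  list(proximal = prox, ankle = ank)
}

#' Specification of a simulated measurement cohort
#'
#' Defaults emulate the statistical structure of a 200-tibia pediatric
#' reference cohort: proximal angles centered near -7.6 degrees (SD 14.2),
#' talar angles near 17.2 degrees (SD 16.9), a fibular positional offset of
#' 5.8 degrees (SD 4) that makes the IMA systematically larger than the TA,
#' and 0.5 mm isotropic rater placement noise, with two raters and two
#' sessions so both reliability designs are available.
#'
#' @param n_subjects Number of subjects; each contributes two tibias.
#' @param proximal_mean,proximal_sd True proximal angle distribution (deg).
#' @param distal_mean,distal_sd True talar angle distribution (deg).
#' @param fibular_offset_mean,fibular_offset_sd Fibular IMA-minus-TA offset
#'   distribution (deg).
#' @param rater_noise_sd Isotropic landmark jitter SD in mm (0 = noiseless).
#' @param raters,sessions Number of raters and of sessions per rater.
#' @param proximal_skew Skew-normal shape parameter for the proximal truth
#'   distribution (0 = normal); lets simulated proximal angles fail the
#'   normality gate the way real plateau angles can.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 100L,
                        proximal_mean = -7.6, proximal_sd = 14.2,
                        distal_mean = 17.2, distal_sd = 16.9,
                        fibular_offset_mean = 5.8, fibular_offset_sd = 4,
                        rater_noise_sd = 0.5,
                        raters = 2L, sessions = 2L,
                        proximal_skew = 0, seed = 1L) {
  stopifnot(n_subjects >= 1L, proximal_sd >= 0, distal_sd >= 0,
            fibular_offset_sd >= 0, rater_noise_sd >= 0,
            raters >= 1L, sessions >= 1L)
  structure(
    list(n_subjects = as.integer(n_subjects),
         proximal_mean = proximal_mean, proximal_sd = proximal_sd,
         distal_mean = distal_mean, distal_sd = distal_sd,
         fibular_offset_mean = fibular_offset_mean,
         fibular_offset_sd = fibular_offset_sd,
         rater_noise_sd = rater_noise_sd,
         raters = as.integer(raters), sessions = as.integer(sessions),
         proximal_skew = proximal_skew, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_spec> %d subjects (%d tibias), %d rater(s) x %d session(s), seed %d\n",
    "  proximal N(%g, %g^2), talar N(%g, %g^2), fibular offset N(%g, %g^2) deg\n",
    "  rater landmark noise SD %g mm, proximal skew %g\n"),
    x$n_subjects, 2L * x$n_subjects, x$raters, x$sessions, x$seed,
    x$proximal_mean, x$proximal_sd, x$distal_mean, x$distal_sd,
    x$fibular_offset_mean, x$fibular_offset_sd, x$rater_noise_sd,
    x$proximal_skew))
  invisible(x)
}

# Skew-normal draws standardized to the requested mean/sd (shape = 0 gives
# exactly rnorm).
rskewnorm <- function(n, mean, sd, shape) {
  if (shape == 0) return(stats::rnorm(n, mean, sd))
  delta <- shape / sqrt(1 + shape^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  z <- delta * z0 + sqrt(1 - delta^2) * z1
  mz <- delta * sqrt(2 / pi)
  sz <- sqrt(1 - 2 * delta^2 / pi)
  mean + sd * (z - mz) / sz
}

jitter_landmarks <- function(lm, sd) {
  if (sd == 0) return(lm)
  lm$structures <- lapply(lm$structures, function(p) {
    p + matrix(stats::rnorm(length(p), 0, sd), nrow(p), 2L)
  })
  lm
}

#' Simulate a full landmark cohort with known ground truth
#'
#' Per-tibia true angles are drawn independently from the spec's
#' distributions (rejection-sampled into (-89, 89) degrees so every axis is
#' geometrically identifiable), each tibia's landmark geometry is built with
#' [synthesize_tibia()], and one jittered copy is emitted per rater x
#' session. Everything is reproducible from `spec$seed`.
#'
#' @param spec A `"cohort_spec"`.
#' @param out_dir Optional directory: if given, writes `landmarks.csv` (all
#'   raters/sessions, long format) and `truth.csv` there.
#' @return An object of class `"cohort_truth"`: list with `spec`, `truth`
#'   (data frame: `subject_id`, `side`, `proximal`, `distal_talar`,
#'   `fibular_offset`, `true_ima`) and `landmarks` (flat list of
#'   `"landmark_set"`s, two slices per tibia per rater per session).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_tibias <- 2L * spec$n_subjects
  ids <- sprintf("S%03d", rep(seq_len(spec$n_subjects), each = 2L))
  sides <- rep(c("left", "right"), spec$n_subjects)

  draw <- function(n) {
    data.frame(
      proximal = rskewnorm(n, spec$proximal_mean, spec$proximal_sd,
                           spec$proximal_skew),
      distal_talar = stats::rnorm(n, spec$distal_mean, spec$distal_sd),
      fibular_offset = stats::rnorm(n, spec$fibular_offset_mean,
                                    spec$fibular_offset_sd))
  }
  truth <- draw(n_tibias)
  bad <- function(tr) {
    abs(tr$proximal) >= 89 | abs(tr$distal_talar) >= 89 |
      abs(tr$distal_talar + tr$fibular_offset) >= 89
  }
  while (any(i <- bad(truth))) truth[i, ] <- draw(sum(i))
  truth <- cbind(data.frame(subject_id = ids, side = sides,
                            stringsAsFactors = FALSE), truth)
  truth$true_ima <- truth$distal_talar + truth$fibular_offset

  landmarks <- vector("list", n_tibias * spec$raters * spec$sessions * 2L)
  k <- 0L
  for (i in seq_len(n_tibias)) {
    clean <- synthesize_tibia(truth$proximal[i], truth$distal_talar[i],
                              truth$fibular_offset[i], side = truth$side[i],
                              subject_id = truth$subject_id[i])
    for (r in seq_len(spec$raters)) {
      for (s in seq_len(spec$sessions)) {
        for (slice in c("proximal", "ankle")) {
          lm <- clean[[slice]]
          lm$rater <- r
          lm$session <- s
          lm <- jitter_landmarks(lm, spec$rater_noise_sd)
          k <- k + 1L
          landmarks[[k]] <- lm
        }
      }
    }
  }
  out <- structure(list(spec = spec, truth = truth, landmarks = landmarks),
                   class = "cohort_truth")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_landmarks(out$landmarks, file.path(out_dir, "landmarks.csv"))
    write_table_csv(out$truth, file.path(out_dir, "truth.csv"))
  }
  out
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d tibias x %d rater(s) x %d session(s) (%d landmark sets)\n",
              nrow(x$truth), x$spec$raters, x$spec$sessions, length(x$landmarks)))
  invisible(x)
}

#' Extract one rater/session replicate of a simulated cohort
#'
#' @param cohort A `"cohort_truth"`.
#' @param rater,session Which replicate to keep.
#' @param tibias Optional character vector of tibia keys
#'   (`"subject_id/side"`) to keep.
#' @return A list of `"landmark_set"`s for that replicate.
#' @export
cohort_replicate <- function(cohort, rater = 1L, session = 1L, tibias = NULL) {
  stopifnot(inherits(cohort, "cohort_truth"))
  if (rater > cohort$spec$raters || session > cohort$spec$sessions) {
    stop(sprintf("cohort has %d rater(s) x %d session(s); replicate (%d, %d) unavailable",
                 cohort$spec$raters, cohort$spec$sessions, rater, session),
         call. = FALSE)
  }
  keep <- vapply(cohort$landmarks, function(lm) {
    lm$rater == rater && lm$session == session &&
      (is.null(tibias) || paste(lm$subject_id, lm$side, sep = "/") %in% tibias)
  }, logical(1))
  cohort$landmarks[keep]
}
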