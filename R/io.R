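# Landmark and record serialization.
#
# CSV is the canonical interchange: one landmark point per row with columns
# subject_id, side, slice, structure, point_index, x_mm, y_mm, rater,
# session. JSON mirrors the same content hierarchically (one object per
# landmark set with a structures mapping). Angle outputs are written with 3
# decimal places; coordinates with 10 (sub-nanometre, i.e. exact for any
# realistic landmark).

landmark_csv_columns <- c("subject_id", "side", "slice", "structure",
                          "point_index", "x_mm", "y_mm", "rater", "session")

# deterministic CSV writer (no scientific notation surprises, LF endings)
write_table_csv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                   format = "f"))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Convert landmark sets to the long one-point-per-row table
#'
#' @param sets A `"landmark_set"` or list of them.
#' @return A data frame with the canonical landmark columns.
#' @export
landmarks_to_table <- function(sets) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  rows <- lapply(sets, function(lm) {
    do.call(rbind, lapply(names(lm$structures), function(lab) {
      p <- lm$structures[[lab]]
      data.frame(
        subject_id = lm$subject_id, side = lm$side, slice = lm$slice,
        structure = lab, point_index = seq_len(nrow(p)),
        x_mm = p[, 1L], y_mm = p[, 2L],
        rater = lm$rater, session = lm$session,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_landmark_table <- function(df, path = "<data>") {
  missing_cols <- setdiff(landmark_csv_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  fail <- function(rows, what) {
    stop(sprintf("%s: %s at row(s) %s", path, what,
                 paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
  }
  for (col in c("x_mm", "y_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) fail(bad, sprintf("non-numeric %s", col))
    df[[col]] <- v
  }
  bad <- which(!df$side %in% c("left", "right"))
  if (length(bad)) fail(bad, "invalid side label")
  bad <- which(!df$slice %in% names(slice_structures))
  if (length(bad)) fail(bad, "invalid slice label")
  ok_struct <- mapply(function(sl, st) {
    sl %in% names(slice_structures) && st %in% slice_structures[[sl]]
  }, df$slice, df$structure)
  bad <- which(!ok_struct)
  if (length(bad)) {
    fail(bad, sprintf("unknown structure label '%s' for %s slice",
                      df$structure[bad[1L]], df$slice[bad[1L]]))
  }
  key <- do.call(paste, c(df[c("subject_id", "side", "slice", "structure",
                               "point_index", "rater", "session")],
                          sep = "\r"))
  bad <- which(duplicated(key))
  if (length(bad)) fail(bad, "duplicate (subject, side, slice, structure, point, rater, session) key")
  df
}

table_to_landmarks <- function(df) {
  grp_key <- do.call(paste, c(df[c("subject_id", "side", "slice", "rater",
                                   "session")], sep = "\r"))
  lapply(split(df, grp_key), function(g) {
    structures <- lapply(split(g, g$structure), function(s) {
      s <- s[order(s$point_index), , drop = FALSE]
      cbind(s$x_mm, s$y_mm)
    })
    landmark_set(g$subject_id[1L], g$side[1L], g$slice[1L], structures,
                 rater = g$rater[1L], session = g$session[1L])
  })
}

#' Write landmark sets to CSV or JSON
#'
#' @param sets A list of `"landmark_set"`s (or one), or an already-long
#'   landmark data frame.
#' @param path Output path; format inferred from the extension unless
#'   `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(sets, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  df <- if (is.data.frame(sets)) sets else landmarks_to_table(sets)
  if (format == "csv") {
    df$x_mm <- formatC(df$x_mm, digits = 10L, format = "f")
    df$y_mm <- formatC(df$y_mm, digits = 10L, format = "f")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    if (is.data.frame(sets)) sets <- table_to_landmarks(validate_landmark_table(sets))
    if (inherits(sets, "landmark_set")) sets <- list(sets)
    payload <- lapply(unname(sets), function(lm) {
      list(subject_id = lm$subject_id, side = lm$side, slice = lm$slice,
           rater = lm$rater, session = lm$session,
           structures = lapply(lm$structures, function(p) {
             lapply(seq_len(nrow(p)), function(i) c(p[i, 1L], p[i, 2L]))
           }))
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else
    stop(sprintf("cannot infer landmark format from extension '%s' of %s; pass format=",
                 ext, path), call. = FALSE)
}

#' Read landmark sets from CSV or JSON
#'
#' Validates labels, coordinates and key uniqueness (errors name the file
#' and row), then groups rows into `"landmark_set"`s by
#' (subject, side, slice, rater, session). Row order never affects results.
#'
#' @param path Input file.
#' @param format `"csv"` or `"json"` (default: inferred from extension).
#' @return A list of `"landmark_set"`s.
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    raw <- jsonlite::read_json(path)
    df <- do.call(rbind, lapply(raw, function(lm) {
      do.call(rbind, lapply(names(lm$structures), function(lab) {
        pts <- lm$structures[[lab]]
        data.frame(
          subject_id = lm$subject_id, side = lm$side, slice = lm$slice,
          structure = lab, point_index = seq_along(pts),
          x_mm = vapply(pts, function(q) as.character(q[[1L]]), character(1)),
          y_mm = vapply(pts, function(q) as.character(q[[2L]]), character(1)),
          rater = if (is.null(lm$rater)) NA else lm$rater,
          session = if (is.null(lm$session)) NA_integer_ else lm$session,
          stringsAsFactors = FALSE)
      }))
    }))
  }
  df <- validate_landmark_table(df, path = path)
  table_to_landmarks(df)
}

#' Write torsion records to CSV
#'
#' Angle columns are written with 3 decimal places.
#'
#' @param cohort A `"torsion_cohort"` or its `records` data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_torsion_records <- function(cohort, path) {
  records <- if (inherits(cohort, "torsion_cohort")) cohort$records else cohort
  angle_cols <- intersect(c("ptta", "pmtpa", "ima", "ta", "tta1", "tta2"),
                          names(records))
  records[angle_cols] <- lapply(records[angle_cols],
                                function(x) formatC(x, digits = 3L, format = "f"))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a torsion-record CSV
#'
#' @param path CSV written by [write_torsion_records()] (or with the same
#'   columns).
#' @return A data frame of torsion records.
#' @export
read_torsion_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "side", "ptta", "pmtpa", "ima", "ta")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing method/record column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}
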