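## Readers/writers: versioned JSON recording schema, force-frame CSV/JSON,
## assessment report JSON. All units fixed at this boundary:
## metres, seconds, newtons, degrees.

RECORDING_SCHEMA_VERSION <- 1L

clip_to_list <- function(cl) {
  out <- list(
    motion_id = cl$motion_id,
    side = cl$side,
    fs = cl$fs,
    body = list(t = cl$body$t, joints = lapply(cl$body$joints, unname))
  )
  if (!is.null(cl$hand)) {
    n <- length(cl$hand$t)
    frames <- lapply(seq_len(n), function(i) cl$hand$landmarks[i, , ])
    out$hand <- list(t = cl$hand$t, landmarks = frames)
  }
  out
}

clip_from_list <- function(x) {
  joints <- lapply(x$body$joints, function(m) {
    m <- if (is.list(m)) do.call(rbind, m) else as.matrix(m)
    matrix(as.numeric(m), ncol = 3)
  })
  body <- body_track(as.numeric(x$body$t), joints)
  hand <- NULL
  if (!is.null(x$hand)) {
    t <- as.numeric(x$hand$t)
    lm <- array(NA_real_, dim = c(length(t), 21, 3))
    for (i in seq_along(t)) {
      fr <- x$hand$landmarks[[i]]
      fr <- if (is.list(fr)) do.call(rbind, fr) else as.matrix(fr)
      lm[i, , ] <- matrix(as.numeric(fr), ncol = 3)
    }
    hand <- hand_track(t, lm)
  }
  motion_clip(x$motion_id, x$side, as.numeric(x$fs), body, hand)
}

#' Write a recording to a JSON file
#'
#' @param rec a [fma_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fma_recording"))
  doc <- list(
    schema_version = RECORDING_SCHEMA_VERSION,
    subject_id = rec$subject_id,
    affected_side = rec$affected_side,
    clips = lapply(rec$clips, clip_to_list),
    force_frames = lapply(rec$force_frames, function(f) {
      list(motion_id = f$motion_id, side = f$side, t = f$t,
           grid = as.numeric(t(f$grid)))   # row-major, 256 values
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a recording from a JSON file
#'
#' Parses the versioned recording schema, validates every invariant
#' (strictly increasing time stamps, finite coordinates, paired sides) and
#' optionally canonicalises left-limb clips to right-limb geometry.
#'
#' @param path path to a recording JSON file.
#' @param canonicalise mirror left-limb clips at load time (default `TRUE`)
#'   so downstream kinematics can assume a right limb.
#' @return A [fma_recording()].
#' @export
read_recording <- function(path, canonicalise = TRUE) {
  if (!file.exists(path)) {
    stop_autofma("recording file does not exist: %s", path,
                 class = "autofma_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  for (field in c("schema_version", "subject_id", "affected_side", "clips")) {
    if (is.null(doc[[field]])) {
      stop_autofma("recording schema violation: missing field '%s'", field,
                   class = "autofma_parse_error")
    }
  }
  clips <- lapply(seq_along(doc$clips), function(i) {
    tryCatch(clip_from_list(doc$clips[[i]]),
             autofma_error = function(e) {
               stop_autofma("clip %d: %s", i, conditionMessage(e),
                            class = "autofma_parse_error")
             })
  })
  frames <- lapply(doc$force_frames, function(f) {
    force_frame(as.numeric(f$t), as.numeric(f$grid), f$motion_id, f$side)
  })
  rec <- fma_recording(doc$subject_id, doc$affected_side, clips, frames)
  if (canonicalise) rec <- canonicalise_recording(rec)
  rec
}

#' Read pressure-grid force frames
#'
#' Accepts either a CSV (`motion_id,side,t,c1..c256` per row, cells in
#' row-major order) or a JSON array of frame objects.
#'
#' @param path input file; format chosen from the extension
#'   (`.csv` vs `.json`).
#' @return List of [force_frame()] objects.
#' @export
read_force_frames <- function(path) {
  if (!file.exists(path)) {
    stop_autofma("force file does not exist: %s", path, class = "autofma_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    return(lapply(doc, function(f) {
      force_frame(as.numeric(f$t), as.numeric(f$grid), f$motion_id, f$side)
    }))
  }
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) != 259) {
    stop_autofma("force CSV must have 259 columns (motion_id, side, t, 256 cells); got %d",
                 ncol(tab), class = "autofma_dimension_error")
  }
  lapply(seq_len(nrow(tab)), function(i) {
    force_frame(as.numeric(tab[i, 3]), as.numeric(unlist(tab[i, 4:259])),
                as.character(tab[i, 1]), as.character(tab[i, 2]))
  })
}

#' Write pressure-grid force frames to CSV
#'
#' @param frames list of [force_frame()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_frames <- function(frames, path) {
  cells <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f$grid))))
  tab <- data.frame(
    motion_id = vapply(frames, `[[`, "", "motion_id"),
    side = vapply(frames, `[[`, "", "side"),
    t = vapply(frames, `[[`, 0, "t"),
    cells, check.names = FALSE
  )
  names(tab) <- c("motion_id", "side", "t", paste0("c", 1:256))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write an assessment report to JSON
#'
#' @param report an `fma_report` as returned by [assess()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fma_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an assessment report from JSON
#'
#' @param path path written by [write_report()].
#' @return An `fma_report` object.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(doc, class = "fma_report")
}
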