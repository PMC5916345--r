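#' Frame schedules for dynamic PET acquisitions
#'
#' Build the dynamic acquisition frame schedule for either tracer protocol:
#' the 90-min FMT protocol (25 frames: 5 x 1, 3 x 2, 3 x 3, 14 x 5 min) used
#' for irreversible-trapping tracers, or the 60-min raclopride protocol
#' (19 frames: 5 x 1, 3 x 2, 3 x 3, 8 x 5 min) used for reversible D2/3
#' ligands. Frames are contiguous and non-overlapping.
#'
#' @param tracer `"FMT"` (dopamine-synthesis tracer, 90 min) or `"RAC"`
#'   (raclopride, 60 min).
#' @return A `frame_schedule` object: a data frame with columns `start`,
#'   `duration` and `mid` (all minutes).
#' @examples
#' sched <- frame_schedule("FMT")
#' nrow(sched)              # 25
#' sum(sched$duration)      # 90
#' @export
frame_schedule <- function(tracer = c("FMT", "RAC")) {
  tracer <- match.arg(tracer)
  durations <- switch(tracer,
    FMT = c(rep(1, 5), rep(2, 3), rep(3, 3), rep(5, 14)),
    RAC = c(rep(1, 5), rep(2, 3), rep(3, 3), rep(5, 8))
  )
  new_frame_schedule(durations, tracer = tracer)
}

#' Construct a frame schedule from frame durations
#'
#' @param durations positive frame durations in minutes; frames are laid out
#'   contiguously from time 0.
#' @param tracer optional protocol tag stored as an attribute.
#' @return A `frame_schedule` data frame (`start`, `duration`, `mid`, minutes).
#' @export
new_frame_schedule <- function(durations, tracer = NA_character_) {
  durations <- as.numeric(durations)
  if (length(durations) == 0L || any(!is.finite(durations)) || any(durations <= 0)) {
    stop("frame durations must be finite and > 0")
  }
  starts <- cumsum(c(0, durations[-length(durations)]))
  out <- data.frame(
    start = starts,
    duration = durations,
    mid = starts + durations / 2
  )
  class(out) <- c("frame_schedule", "data.frame")
  attr(out, "tracer") <- tracer
  out
}

#' @export
print.frame_schedule <- function(x, ...) {
  tr <- attr(x, "tracer")
  cat(sprintf(
    "Frame schedule%s: %d frames, 0-%g min\n",
    if (!is.na(tr)) paste0(" [", tr, "]") else "", nrow(x),
    x$start[nrow(x)] + x$duration[nrow(x)]
  ))
  print.data.frame(x, ...)
  invisible(x)
}

end_time <- function(schedule) {
  schedule$start[nrow(schedule)] + schedule$duration[nrow(schedule)]
}

same_schedule <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    max(abs(a$start - b$start), abs(a$duration - b$duration)) <= tol
}

#' Time-activity curves
#'
#' A time-activity curve (TAC) is the activity concentration of a region (or
#' voxel) in each frame of a dynamic PET acquisition. Frame values are
#' interpreted as frame-duration averages of the underlying continuous
#' concentration.
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric activity per frame (kBq/mL, arbitrary scale); must
#'   match the number of frames and be finite.
#' @param region optional region name tag.
#' @return A `tac` object (list with `schedule` and `activity`).
#' @examples
#' sched <- frame_schedule("RAC")
#' tac(sched, rep(1, nrow(sched)))
#' @export
tac <- function(schedule, activity, region = NA_character_) {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != nrow(schedule)) {
    stop("activity length must equal the number of frames")
  }
  if (any(!is.finite(activity))) stop("activity must be finite")
  structure(
    list(schedule = schedule, activity = activity, region = region),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf(
    "TAC%s: %d frames, 0-%g min, activity range [%.4g, %.4g]\n",
    if (!is.na(x$region)) paste0(" '", x$region, "'") else "",
    nrow(x$schedule), end_time(x$schedule),
    min(x$activity), max(x$activity)
  ))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(
    frame_start_min = x$schedule$start,
    frame_duration_min = x$schedule$duration,
    activity = x$activity
  )
}

#' Read and write TAC CSV files
#'
#' The on-disk TAC format is a CSV with columns `frame_start_min`,
#' `frame_duration_min` and `activity`.
#'
#' @param x a [tac()] object.
#' @param path file path.
#' @return `read_tac_csv()` returns a `tac`; `write_tac_csv()` returns `path`
#'   invisibly.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame_start_min", "frame_duration_min", "activity")
  if (!all(need %in% names(d))) {
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  }
  sched <- new_frame_schedule(d$frame_duration_min)
  if (max(abs(sched$start - d$frame_start_min)) > 1e-6) {
    stop("frames are not contiguous from time 0")
  }
  tac(sched, d$activity)
}
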