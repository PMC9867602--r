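# Session I/O.
#
# On-disk layout of a session directory:
#   stack.tif       multi-page 32-bit float TIFF, frames normalized to [0,1]
#   stack_meta.json affine scale/offset restoring raw units, fs_hz, t0
#   mask.tif        single-page TIFF, 0/1
#   photometry.csv  header: time_s,f465,f405
#   events.csv      header: time_s,label
#   behavior.csv    optional, header: time_s,motion_roi[,pupil_diameter]
#
# TIFF stores 32-bit floats in [0, 1]; raw fluorescence is restored through
# the recorded affine transform, so round-trip fidelity is float32
# (~1e-7 relative).

#' Save a session bundle to a directory
#'
#' Writes the widefield movie (multi-page float TIFF plus a JSON sidecar
#' with the affine scale, frame rate and t0), the cortical mask, the
#' two-channel photometry CSV and the event CSV.
#'
#' @param session A list with `stack` ([widefield_stack()]) and
#'   `photometry` (a `photometry_recording`), e.g. the output of
#'   [generate_spontaneous_session()] or a `session_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_session <- function(session, dir) {
  stopifnot(inherits(session$stack, "widefield_stack"),
            inherits(session$photometry, "photometry_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- session$stack
  d <- dim(st$frames)
  lo <- min(st$frames)
  hi <- max(st$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(t) (st$frames[, , t] - lo) / scale)
  suppressWarnings(tiff::writeTIFF(pages, file.path(dir, "stack.tif"),
                                   bits.per.sample = 32L))
  jsonlite::write_json(
    list(offset = lo, scale = scale, fs_hz = st$fs, t0 = st$t0,
         height = d[1], width = d[2], n_frames = d[3]),
    file.path(dir, "stack_meta.json"), auto_unbox = TRUE, digits = NA)
  suppressWarnings(tiff::writeTIFF(matrix(as.numeric(st$mask), d[1], d[2]),
                                   file.path(dir, "mask.tif"),
                                   bits.per.sample = 8L))
  ph <- session$photometry
  utils::write.csv(
    data.frame(time_s = trace_times(ph$f465), f465 = ph$f465$samples,
               f405 = ph$f405$samples),
    file.path(dir, "photometry.csv"), row.names = FALSE)
  utils::write.csv(ph$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(session$behavior)) {
    utils::write.csv(
      data.frame(time_s = trace_times(session$behavior),
                 motion_roi = session$behavior$samples),
      file.path(dir, "behavior.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Load a session bundle from a directory
#'
#' Reads and validates the files written by [save_session()] (or assembled
#' by hand in the same layout). The photometry CSV must carry the exact
#' header `time_s,f465,f405`; timestamps must be strictly increasing; the
#' mask must match the stack frame size; events outside the recording are
#' rejected with counts.
#'
#' @param dir Session directory.
#' @return A `session_bundle`: list with `stack`, `photometry`, optional
#'   `behavior`, and `provenance` (an append-only character vector of
#'   applied operations).
#' @export
load_session <- function(dir) {
  need <- c("stack.tif", "stack_meta.json", "mask.tif", "photometry.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0)
    stop("load_session: missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "stack_meta.json"),
                              simplifyVector = TRUE)
  pages <- suppressWarnings(tiff::readTIFF(file.path(dir, "stack.tif"),
                                           all = TRUE))
  frames <- array(0, c(meta$height, meta$width, meta$n_frames))
  if (length(pages) != meta$n_frames)
    stop("load_session: stack page count does not match metadata",
         call. = FALSE)
  for (t in seq_along(pages))
    frames[, , t] <- pages[[t]] * meta$scale + meta$offset
  mask <- suppressWarnings(tiff::readTIFF(file.path(dir, "mask.tif")))
  mask <- mask > 0.5
  if (!identical(dim(mask), dim(frames)[1:2]))
    stop("load_session: mask shape does not match the stack", call. = FALSE)
  stack <- widefield_stack(frames, meta$fs_hz, mask, meta$t0)

  ph <- utils::read.csv(file.path(dir, "photometry.csv"))
  if (!identical(names(ph)[1:3], c("time_s", "f465", "f405")))
    stop("load_session: photometry.csv must have header time_s,f465,f405",
         call. = FALSE)
  dt <- diff(ph$time_s)
  if (any(dt <= 0))
    stop("load_session: photometry timestamps are not strictly increasing",
         call. = FALSE)
  fs_p <- 1 / stats::median(dt)
  events <- if (file.exists(file.path(dir, "events.csv"))) {
    utils::read.csv(file.path(dir, "events.csv"),
                    colClasses = c("numeric", "character"))
  } else data.frame(time_s = numeric(0), label = character(0))
  t_end <- ph$time_s[length(ph$time_s)]
  out_of_range <- events$time_s < ph$time_s[1] | events$time_s > t_end
  if (any(out_of_range)) {
    warning(sprintf("load_session: rejected %d event(s) outside the recording",
                    sum(out_of_range)))
    events <- events[!out_of_range, , drop = FALSE]
  }
  photometry <- photometry_recording(
    fp_trace(ph$f465, fs_p, t0 = ph$time_s[1]),
    fp_trace(ph$f405, fs_p, t0 = ph$time_s[1]),
    events)
  behavior <- NULL
  bf <- file.path(dir, "behavior.csv")
  if (file.exists(bf)) {
    bh <- utils::read.csv(bf)
    if (!all(c("time_s", "motion_roi") %in% names(bh)))
      stop("load_session: behavior.csv must have columns time_s,motion_roi",
           call. = FALSE)
    behavior <- fp_trace(bh$motion_roi, 1 / stats::median(diff(bh$time_s)),
                         t0 = bh$time_s[1])
  }
  structure(list(stack = stack, photometry = photometry,
                 behavior = behavior,
                 provenance = sprintf("loaded from %s", dir)),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>\n  ")
  print(x$stack)
  cat("  ")
  print(x$photometry)
  invisible(x)
}

# write a numeric matrix (NA allowed) as CSV without row names
write_map_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
}
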