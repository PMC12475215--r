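# Fixed local standard time used for all internal timestamps. "Etc/GMT-1" is
# UTC+1 (the POSIX sign convention is inverted); civil DST labels are a
# display-layer conversion only.
MOTACT_TZ <- "Etc/GMT-1"

#' Ordered grayscale frame sequence
#'
#' Container for a fixed-geometry grayscale frame sequence with per-frame
#' timestamps, the raw input to the motion analysis. Frames are numeric
#' matrices (rows = image height, columns = width) with 8-bit intensities in
#' `[0, 255]`.
#'
#' If the nominal `fps` disagrees with the frame rate implied by the
#' timestamps by more than 1%, the timestamp-derived rate wins and a message
#' is emitted.
#'
#' @param frames list of numeric matrices sharing one geometry.
#' @param timestamps `POSIXct` vector (or ISO 8601 strings), strictly
#'   increasing, one per frame. Parsed/kept in fixed UTC+1.
#' @param fps nominal frames per second (default 14, the recorder's rate).
#' @return An object of class `frame_series` with elements `frames`,
#'   `timestamps`, `fps` and `geometry` (`c(width, height)`).
#' @export
frame_series <- function(frames, timestamps, fps = 14) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (!all(vapply(frames, is.matrix, TRUE)))
    stop("all frames must be 2-D matrices (use to_grayscale() first)")
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), TRUE)
  if (!all(same)) stop("all frames must share one geometry")
  timestamps <- as_motact_time(timestamps)
  if (length(timestamps) != length(frames))
    stop("need exactly one timestamp per frame")
  if (length(timestamps) > 1L && any(diff(as.numeric(timestamps)) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  if (length(timestamps) > 1L) {
    fps_ts <- 1 / stats::median(diff(as.numeric(timestamps)))
    if (abs(fps_ts - fps) / fps > 0.01) {
      message(sprintf(
        "frame_series: nominal fps %.3f disagrees with timestamps (%.3f); using %.3f",
        fps, fps_ts, fps_ts))
      fps <- fps_ts
    }
  }
  structure(
    list(frames = frames, timestamps = timestamps, fps = fps,
         geometry = c(width = ncol(frames[[1L]]), height = nrow(frames[[1L]]))),
    class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames, %dx%d px, %.3f fps\n  %s .. %s\n",
              length(x$frames), x$geometry[["width"]], x$geometry[["height"]],
              x$fps, format(x$timestamps[1L]), format(x$timestamps[length(x$timestamps)])))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

# Parse timestamps into POSIXct in the fixed standard-time zone.
as_motact_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- MOTACT_TZ
    return(x)
  }
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = MOTACT_TZ))
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = MOTACT_TZ, format = "%Y-%m-%d %H:%M:%OS")
  if (anyNA(out)) stop("unparseable timestamp(s): ", paste(utils::head(x[is.na(out)], 3L), collapse = ", "))
  out
}

#' Convert a frame to 8-bit grayscale
#'
#' Single-channel frames pass through unchanged (night-time IR material is
#' already gray); 3-channel frames are combined with the ITU-R BT.601 luma
#' weights (0.299, 0.587, 0.114) and rounded to the nearest integer, putting
#' daylight colour and night IR material on one intensity scale.
#'
#' @param frame numeric matrix (grayscale) or height x width x 3 array (RGB),
#'   8-bit values in `[0, 255]`.
#' @return Numeric matrix with the same geometry.
#' @export
to_grayscale <- function(frame) {
  if (!is.numeric(frame)) stop("frame must be numeric")
  rng <- range(frame)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255)
    stop("unsupported bit depth: intensities must lie in [0, 255]")
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3L && d[3L] == 1L) return(array(frame, d[1:2]))
  if (length(d) != 3L || d[3L] != 3L)
    stop("unsupported channel count: expected 1 or 3 channels")
  round(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L])
}

# ---- plain-text frame I/O (PGM) ----------------------------------------

#' Read a PGM image
#'
#' Reads portable graymap files, the plain-text (P2) or binary (P5) flavour,
#' the package's canonical on-disk frame format. If the `png` package is
#' installed, `.png` files are accepted too.
#'
#' @param path file path.
#' @return Numeric matrix of intensities in `[0, maxval]`.
#' @export
read_frame <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG frames requires the 'png' package; use PGM instead")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE]
    return(to_grayscale(round(img * 255)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (P2/P5): ", path)
  # header tokens: width height maxval, '#' comments allowed
  toks <- integer(0)
  buf <- character(0)
  while (length(toks) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header: ", path)
    if (ch == "#") { # skip comment line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) buf <- c(buf, ch)
    else if (length(buf)) { toks <- c(toks, as.integer(paste(buf, collapse = ""))); buf <- character(0) }
  }
  w <- toks[1L]; h <- toks[2L]; maxval <- toks[3L]
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(scan(text = txt, what = integer(), n = w * h, quiet = TRUE))
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a frame as plain-text PGM (P2)
#'
#' @param frame numeric matrix, values in `[0, 255]`.
#' @param path output path.
#' @export
write_frame <- function(frame, path) {
  stopifnot(is.matrix(frame))
  frame <- round(frame)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(frame), nrow(frame)), "255"), con)
  utils::write.table(frame, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a directory of numbered frames plus a timestamp table
#'
#' The directory holds frames named so that lexicographic order is frame
#' order (`frame_000001.pgm`, ...) and a delimited text file `timestamps.csv`
#' with one ISO 8601 instant per row (column `timestamp`), one row per frame.
#'
#' @param dir directory path.
#' @param timestamp_file name of the timestamp table inside `dir`.
#' @param fps nominal frames per second recorded in the container metadata.
#' @return A [frame_series()].
#' @export
read_frame_dir <- function(dir, timestamp_file = "timestamps.csv", fps = 14) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  paths <- sort(list.files(dir, pattern = "\\.(pgm|png)$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(paths) == 0L) stop("no frames (*.pgm / *.png) found in ", dir)
  tsf <- file.path(dir, timestamp_file)
  if (!file.exists(tsf)) stop("missing timestamp table: ", tsf)
  ts <- utils::read.csv(tsf, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(ts)) stop("timestamp table needs a 'timestamp' column")
  frames <- lapply(paths, read_frame)
  frame_series(frames, ts$timestamp, fps = fps)
}
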