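# In-memory image stacks and plain-text (ASCII PGM) frame I/O.
#
# The primary container is a list of integer matrices; on disk a stack is a
# directory of numbered .pgm frames (portable graymap, "P2" ASCII variant)
# plus a timestamps CSV (columns: frame, t_s). PGM keeps the deliverable
# text-only while remaining a real image format any viewer opens.

#' Time-lapse image stack
#'
#' @param frames List of numeric matrices of identical dimensions (grayscale
#'   intensities, conventionally 0-255).
#' @param timestamps Strictly increasing numeric vector, seconds, one per
#'   frame.
#' @param pixel_size Optional pixel size, mm per pixel.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(frames, timestamps, pixel_size = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions")
  if (length(timestamps) != length(frames))
    stop("one timestamp per frame required")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, t = %g..%g s\n",
              length(x$frames), d[1], d[2],
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Read / write a single ASCII PGM (P2) frame
#'
#' @param path File path ending in `.pgm`.
#' @return `read_pgm`: an integer matrix.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- scan(text = paste(lines, collapse = " "), what = character(),
                 quiet = TRUE)
  if (tokens[1] != "P2") stop("only ASCII PGM (P2) files are supported")
  vals <- as.integer(tokens[-1])
  w <- vals[1]; h <- vals[2]  # maxval = vals[3]
  px <- vals[-(1:3)]
  if (length(px) != w * h) stop("corrupt PGM: pixel count mismatch")
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param frame Numeric matrix; values clamped to \[0, maxval\] and rounded.
#' @param maxval Maximum gray value (default 255).
#' @export
write_pgm <- function(frame, path, maxval = 255) {
  m <- pmin(pmax(round(frame), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply(m, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read / write an image stack as a directory of PGM frames
#'
#' Frames are stored as `frame_0001.pgm`, ... with a `times.csv`
#' (columns `frame`, `t_s`) alongside.
#'
#' @param dir Directory path.
#' @return `read_stack`: an [image_stack()].
#' @export
read_stack <- function(dir) {
  times_path <- file.path(dir, "times.csv")
  if (!file.exists(times_path)) stop("missing timestamps file: ", times_path)
  times <- utils::read.csv(times_path)
  if (!all(c("frame", "t_s") %in% names(times)))
    stop("times.csv must have columns frame, t_s")
  times <- times[order(times$frame), ]
  frames <- lapply(times$frame, function(i)
    read_pgm(file.path(dir, sprintf("frame_%04d.pgm", i))))
  image_stack(frames, times$t_s)
}

#' @rdname read_stack
#' @param stack An [image_stack()].
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$frames))
    write_pgm(stack$frames[[i]], file.path(dir, sprintf("frame_%04d.pgm", i)))
  utils::write.csv(data.frame(frame = seq_along(stack$frames),
                              t_s = stack$timestamps),
                   file.path(dir, "times.csv"), row.names = FALSE)
  invisible(dir)
}
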