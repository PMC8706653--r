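#' @include windowset.R
NULL

# Parse a whitespace-separated numeric text file into a matrix, enforcing
# a fixed number of values per row. Fatal on ragged rows, with the index.
readFixedWidthMatrix <- function(file, valuesPerRow = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("'%s' contains no data rows", file))
  rows <- strsplit(trimws(lines), "[[:space:]]+")
  lens <- lengths(rows)
  if (is.null(valuesPerRow)) valuesPerRow <- lens[1]
  bad <- which(lens != valuesPerRow)
  if (length(bad))
    stop(sprintf("row %d of '%s' has %d values; expected %d",
                 bad[1], file, lens[bad[1]], valuesPerRow))
  vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
  if (anyNA(vals)) stop(sprintf("non-numeric value in '%s'", file))
  matrix(vals, nrow = length(rows), ncol = valuesPerRow, byrow = TRUE)
}

uciChannelFiles <- function(split, accelSource = c("total", "body")) {
  accelSource <- match.arg(accelSource)
  acc <- if (accelSource == "total") "total_acc" else "body_acc"
  paste0(c(paste0(acc, "_", c("x", "y", "z"))),
         "_", split, ".txt") -> accf
  gyrf <- paste0("body_gyro_", c("x", "y", "z"), "_", split, ".txt")
  c(accf, gyrf)
}

#' Read a split of the public smartphone inertial-signal layout
#'
#' Reads the raw "Inertial Signals" text layout of the public 30-subject
#' smartphone dataset: six whitespace-separated channel files (one window
#' of 128 samples per row) plus a label file `y_<split>.txt` (one integer
#' per row) and, when present, `subject_<split>.txt`. Row r of every
#' channel file becomes window r, so parsing is order-preserving.
#'
#' By default the total-acceleration channels are combined with the
#' gyroscope channels as the six axes; set `accelSource = "body"` for the
#' gravity-removed body-acceleration variant.
#'
#' @param directory dataset root containing `train/` and `test/`
#'   subdirectories (each with an `Inertial Signals/` folder), or a single
#'   split directory.
#' @param split `"train"` or `"test"`.
#' @param accelSource `"total"` (default) or `"body"`.
#' @return A \linkS4class{WindowSet} with source `"uci"`.
#' @export
readUciInertial <- function(directory, split = c("train", "test"),
                            accelSource = c("total", "body")) {
  split <- match.arg(split)
  accelSource <- match.arg(accelSource)
  splitDir <- file.path(directory, split)
  if (!dir.exists(splitDir)) splitDir <- directory
  sigDir <- file.path(splitDir, "Inertial Signals")
  if (!dir.exists(sigDir)) sigDir <- splitDir
  files <- file.path(sigDir, uciChannelFiles(split, accelSource))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing channel file(s): ", paste(basename(missing), collapse = ", "))
  labFile <- file.path(splitDir, paste0("y_", split, ".txt"))
  if (!file.exists(labFile)) stop("missing label file: ", labFile)

  chans <- lapply(files, readFixedWidthMatrix)
  L <- ncol(chans[[1]])
  nrows <- vapply(chans, nrow, 1L)
  if (length(unique(nrows)) != 1L)
    stop("row-count mismatch across channel files: ",
         paste(nrows, collapse = ", "))
  if (any(vapply(chans, ncol, 1L) != L))
    stop("window-length mismatch across channel files")

  labs <- readLines(labFile, warn = FALSE)
  labs <- as.integer(labs[nzchar(trimws(labs))])
  if (length(labs) == 0L) stop("label file is empty: ", labFile)
  if (length(labs) != nrows[1])
    stop(sprintf("label file has %d rows; channel files have %d",
                 length(labs), nrows[1]))
  if (anyNA(labs) || any(labs < 1L | labs > 6L))
    stop("labels must be integers in 1..6")

  subjFile <- file.path(splitDir, paste0("subject_", split, ".txt"))
  subjects <- if (file.exists(subjFile)) {
    s <- readLines(subjFile, warn = FALSE)
    trimws(s[nzchar(trimws(s))])
  } else rep("unknown", nrows[1])

  n <- nrows[1]
  arr <- array(0, dim = c(L, 6L, n))
  for (c in 1:6) arr[, c, ] <- t(chans[[c]])
  WindowSet(arr, labels = labs, subjects = subjects,
            samplingRate = 50, source = "uci")
}

#' Read flattened device windows
#'
#' Reads the device text dialect: one window per row, `6 * window_len`
#' numbers laid out as six channel blocks (AX | AY | AZ | GX | GY | GZ),
#' followed by an integer label column (or given in a companion label
#' file). This is the inverse of [writeFlatWindows()].
#'
#' @param file path to the flattened-window text file.
#' @param windowLen samples per channel per window (150 for the 3-s, 50 Hz
#'   device windows, giving 900 features).
#' @param labelsFile optional companion file with one integer label per
#'   row; when `NULL` the last column of `file` is taken as the label.
#' @param samplingRate recorded sampling rate; default 50.
#' @return A \linkS4class{WindowSet} with source `"device"`.
#' @export
readFlatWindows <- function(file, windowLen, labelsFile = NULL,
                            samplingRate = 50) {
  m <- readFixedWidthMatrix(file)
  nval <- ncol(m)
  if (is.null(labelsFile)) {
    if (nval - 1L != 6L * windowLen)
      stop(sprintf(
        "row 1: %d feature values cannot be split into 6 blocks of %d",
        nval - 1L, windowLen))
    labs <- as.integer(m[, nval])
    feat <- m[, -nval, drop = FALSE]
  } else {
    if (nval != 6L * windowLen)
      stop(sprintf(
        "row 1: %d feature values cannot be split into 6 blocks of %d",
        nval, windowLen))
    labs <- as.integer(readLines(labelsFile, warn = FALSE))
    if (length(labs) != nrow(m))
      stop("label file row count does not match window file")
    feat <- m
  }
  # rows are channel-blocked flat windows; columns of t(feat) are windows
  WindowSet(t(feat), labels = labs, subjects = "unknown",
            samplingRate = samplingRate, source = "device",
            windowLen = as.integer(windowLen))
}

#' Write flattened device windows
#'
#' Serializes a \linkS4class{WindowSet} in the device dialect: one row per
#' window containing the channel-blocked flat window in scientific
#' notation with 7 decimal digits, followed by the integer label.
#' `readFlatWindows(writeFlatWindows(ws))` reproduces the values to 7
#' significant digits.
#'
#' @param ws a nonempty \linkS4class{WindowSet}.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFlatWindows <- function(ws, file) {
  stopifnot(is(ws, "WindowSet"))
  if (nWindows(ws) == 0L) stop("refusing to write an empty WindowSet")
  flat <- assay(ws, "signal")
  labs <- activityLabels(ws)
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (i in seq_len(ncol(flat))) {
    writeLines(paste(c(sprintf("%.7e", flat[, i]), labs[i]), collapse = " "),
               con)
  }
  invisible(file)
}

#' Write a window set in the public inertial-signal text layout
#'
#' Emits a UCI-style split directory (six channel files under
#' `Inertial Signals/` plus `y_<split>.txt` and `subject_<split>.txt`),
#' mainly so reader tests and offline demos have a realistic fixture.
#'
#' @param ws a \linkS4class{WindowSet}.
#' @param directory dataset root; `<directory>/<split>` is created.
#' @param split `"train"` or `"test"`.
#' @return The split directory, invisibly.
#' @export
writeUciInertial <- function(ws, directory, split = c("train", "test")) {
  split <- match.arg(split)
  splitDir <- file.path(directory, split)
  sigDir <- file.path(splitDir, "Inertial Signals")
  dir.create(sigDir, recursive = TRUE, showWarnings = FALSE)
  arr <- windowArray(ws)
  files <- uciChannelFiles(split, "total")
  for (c in 1:6) {
    m <- t(arr[, c, ])                      # one window per row
    write.table(format(m, digits = 8, scientific = TRUE),
                file.path(sigDir, files[c]),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  writeLines(as.character(activityLabels(ws)),
             file.path(splitDir, paste0("y_", split, ".txt")))
  writeLines(subjectIds(ws),
             file.path(splitDir, paste0("subject_", split, ".txt")))
  invisible(splitDir)
}
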