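#' Read a C3D motion-capture file
#'
#' Minimal reader for the standard C3D binary format (Intel/PC processor
#' type, integer-scaled or floating-point point and analog data), covering
#' the subset the pipeline needs: 3D point trajectories, point labels, rates
#' from the header, and analog (EMG) channels. Point units are converted to
#' metres using `POINT:UNITS` (`"mm"` divides by 1000). Analog values are
#' scaled with `ANALOG:GEN_SCALE`/`ANALOG:SCALE`/`ANALOG:OFFSET` when
#' present.
#'
#' @param path Path to a C3D file.
#' @param schema A [marker_schema()]; every mapped label must exist in the
#'   file (a missing required label is an error naming the label).
#' @param emg_labels Optional character vector: which analog channels to keep
#'   as EMG (default: all).
#' @param ... Trial metadata passed to [gait_trial()].
#' @return A [gait_trial()] with marker positions in metres.
#' @export
read_c3d <- function(path, schema = default_marker_schema(),
                     emg_labels = NULL, ...) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 512L || as.integer(raw[2]) != 0x50L)
    abort(sprintf("'%s' is not a C3D file (bad header magic)", path))
  con <- rawConnection(raw)
  on.exit(close(con))
  hdr <- read_c3d_header(con)
  par <- read_c3d_params(raw, hdr$param_block)
  assert_that(par$processor == 84L,
              "only Intel/PC processor C3D files are supported")

  labels <- par$point_labels
  if (length(labels) < hdr$n_points)
    labels <- c(labels, sprintf("PT%02d", seq_len(hdr$n_points - length(labels))))
  labels <- labels[seq_len(hdr$n_points)]
  unit_div <- if (identical(tolower(par$point_units), "mm")) 1000 else 1

  n_frames <- hdr$last_frame - hdr$first_frame + 1L
  dat <- read_c3d_data(con, hdr, n_frames)
  markers <- lapply(seq_len(hdr$n_points), function(i)
    dat$points[, , i, drop = TRUE] / unit_div)
  names(markers) <- labels

  # schema check: every mapped label must resolve
  mapped <- unname(unclass(schema))
  missing_lab <- setdiff(mapped, labels)
  if (length(missing_lab))
    abort(sprintf("C3D file is missing schema label(s): %s",
                  paste(missing_lab, collapse = ", ")))

  emg <- list()
  if (hdr$n_analog_chan > 0L) {
    alabs <- par$analog_labels
    if (length(alabs) < hdr$n_analog_chan)
      alabs <- c(alabs,
                 sprintf("AN%02d", seq_len(hdr$n_analog_chan - length(alabs))))
    alabs <- alabs[seq_len(hdr$n_analog_chan)]
    emg <- lapply(seq_len(hdr$n_analog_chan), function(j) {
      v <- dat$analog[, j]
      if (!hdr$is_float) {
        sc <- par$analog_gen_scale * par$analog_scale[min(j, length(par$analog_scale))]
        off <- par$analog_offset[min(j, length(par$analog_offset))]
        v <- (v - off) * sc
      }
      v
    })
    names(emg) <- alabs
    if (!is.null(emg_labels)) emg <- emg[intersect(emg_labels, alabs)]
  }

  emg_rate <- if (hdr$analog_per_frame > 0L)
    hdr$point_rate * hdr$analog_per_frame else 1110
  gait_trial(markers = markers, marker_rate = hdr$point_rate,
             emg = emg, emg_rate = emg_rate,
             t0 = (hdr$first_frame - 1L) / hdr$point_rate, ...)
}

read_c3d_header <- function(con) {
  seek(con, 0L)
  w1 <- readBin(con, "raw", n = 2L)
  param_block <- as.integer(w1[1])
  n_points <- readBin(con, "integer", size = 2L, endian = "little")
  analog_total <- readBin(con, "integer", size = 2L, endian = "little")
  first_frame <- readBin(con, "integer", size = 2L, endian = "little")
  last_frame <- readBin(con, "integer", size = 2L, endian = "little")
  readBin(con, "integer", size = 2L, endian = "little") # max gap
  scale <- readBin(con, "numeric", size = 4L, endian = "little")
  data_block <- readBin(con, "integer", size = 2L, endian = "little")
  analog_per_frame <- readBin(con, "integer", size = 2L, endian = "little")
  point_rate <- readBin(con, "numeric", size = 4L, endian = "little")
  n_chan <- if (analog_per_frame > 0L) analog_total %/% analog_per_frame else 0L
  list(param_block = param_block, n_points = n_points,
       n_analog_chan = n_chan, analog_per_frame = max(analog_per_frame, 0L),
       first_frame = first_frame, last_frame = last_frame,
       scale = abs(scale), is_float = scale < 0,
       data_block = data_block, point_rate = point_rate)
}

read_c3d_params <- function(raw, param_block) {
  base <- (param_block - 1L) * 512L
  processor <- as.integer(raw[base + 4L])
  out <- list(processor = processor, point_labels = character(0),
              point_units = "m", analog_labels = character(0),
              analog_gen_scale = 1, analog_scale = 1, analog_offset = 0)
  groups <- character(0) # id -> name
  pos <- base + 5L       # 1-based index of first record byte
  n <- length(raw)
  int8 <- function(b) { v <- as.integer(b); if (v > 127L) v - 256L else v }
  while (pos + 1L <= n) {
    nchar_name <- int8(raw[pos])
    gid <- int8(raw[pos + 1L])
    len <- abs(nchar_name)
    if (len == 0L) break
    name <- rawToChar(raw[(pos + 2L):(pos + 1L + len)])
    off_pos <- pos + 2L + len
    offset <- readBin(raw[off_pos:(off_pos + 1L)], "integer", size = 2L,
                      endian = "little")
    if (gid < 0L) {
      groups[as.character(-gid)] <- name
    } else {
      gname <- groups[as.character(gid)] %||% ""
      body <- off_pos + 2L
      type <- int8(raw[body])
      ndim <- as.integer(raw[body + 1L])
      dims <- if (ndim > 0L)
        as.integer(raw[(body + 2L):(body + 1L + ndim)]) else integer(0)
      dstart <- body + 2L + ndim
      count <- prod(c(dims, 1L))
      val <- read_c3d_value(raw, dstart, type, count, dims)
      key <- paste(gname, name, sep = ":")
      if (key == "POINT:LABELS") out$point_labels <- val
      if (key == "POINT:UNITS") out$point_units <- trimws(val)
      if (key == "ANALOG:LABELS") out$analog_labels <- val
      if (key == "ANALOG:GEN_SCALE") out$analog_gen_scale <- val[1]
      if (key == "ANALOG:SCALE") out$analog_scale <- val
      if (key == "ANALOG:OFFSET") out$analog_offset <- val
    }
    if (offset <= 0L) break
    pos <- off_pos + offset
  }
  out
}

read_c3d_value <- function(raw, start, type, count, dims) {
  if (type == -1L) { # char; first dim = string length
    if (length(dims) <= 1L) {
      return(trimws(rawToChar(raw[start:(start + count - 1L)])))
    }
    slen <- dims[1]
    nstr <- prod(dims[-1])
    vapply(seq_len(nstr), function(i) {
      s <- start + (i - 1L) * slen
      trimws(rawToChar(raw[s:(s + slen - 1L)]))
    }, character(1))
  } else if (type == 1L) {
    as.integer(raw[start:(start + count - 1L)])
  } else if (type == 2L) {
    readBin(raw[start:(start + 2L * count - 1L)], "integer", n = count,
            size = 2L, endian = "little")
  } else if (type == 4L) {
    readBin(raw[start:(start + 4L * count - 1L)], "numeric", n = count,
            size = 4L, endian = "little")
  } else {
    abort(sprintf("unsupported C3D parameter type %d", type))
  }
}

read_c3d_data <- function(con, hdr, n_frames) {
  seek(con, (hdr$data_block - 1L) * 512L)
  np <- hdr$n_points
  napc <- hdr$analog_per_frame
  nch <- hdr$n_analog_chan
  per_frame <- np * 4L + nch * napc
  vals <- if (hdr$is_float) {
    readBin(con, "numeric", n = per_frame * n_frames, size = 4L,
            endian = "little")
  } else {
    readBin(con, "integer", n = per_frame * n_frames, size = 2L,
            endian = "little")
  }
  m <- matrix(vals, nrow = per_frame, ncol = n_frames)
  pts <- array(0, dim = c(n_frames, 3L, np))
  for (i in seq_len(np)) {
    rows <- (i - 1L) * 4L + 1:3
    pmat <- t(m[rows, , drop = FALSE])
    if (!hdr$is_float) pmat <- pmat * hdr$scale
    pts[, , i] <- pmat
  }
  analog <- matrix(0, nrow = n_frames * max(napc, 1L), ncol = max(nch, 0L))
  if (nch > 0L && napc > 0L) {
    arows <- np * 4L + seq_len(nch * napc)
    a <- m[arows, , drop = FALSE] # (chan fastest within sample) x frames
    # stored sample-major: sample1 ch1..chN, sample2 ch1..chN, ...
    a <- array(a, dim = c(nch, napc, n_frames))
    for (j in seq_len(nch)) analog[, j] <- as.numeric(a[j, , ])
  }
  list(points = pts, analog = analog)
}

# Minimal C3D writer (Intel float storage), internal: used to build binary
# test fixtures in code. `markers` named list of frames x 3 matrices (metres
# or millimetres per `units`); `analog` named list of vectors sampled at
# `rate * analog_per_frame`.
write_minimal_c3d <- function(path, markers, rate,
                              analog = list(), analog_per_frame = 0L,
                              units = "m") {
  np <- length(markers)
  n_frames <- nrow(markers[[1]])
  nch <- length(analog)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  f4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  pad_to <- function(nbytes) {
    here <- seek(con)
    if (here < nbytes) writeBin(raw(nbytes - here), con)
  }
  # header block
  writeBin(as.raw(c(2L, 0x50L)), con)
  w2(np); w2(nch * analog_per_frame); w2(1L); w2(n_frames); w2(10L)
  f4(-1.0)                      # scale < 0: float data
  w2(3L)                        # data start block
  w2(analog_per_frame)
  f4(rate)
  pad_to(512L)
  # parameter section (1 block)
  writeBin(as.raw(c(2L, 0x50L, 1L, 84L)), con)
  wrec_group <- function(id, name) {
    writeBin(as.raw(c(nchar(name), bitwAnd(256L - id, 255L))), con)
    writeBin(charToRaw(name), con)
    w2(3L)                      # offset: int16 + desc byte
    writeBin(as.raw(0L), con)   # empty description
  }
  wrec_param <- function(gid, name, type, dims, data_raw) {
    writeBin(as.raw(c(nchar(name), gid)), con)
    writeBin(charToRaw(name), con)
    body <- 2L + 1L + 1L + length(dims) + length(data_raw) + 1L
    w2(body)
    writeBin(as.raw(if (type < 0) 256L + type else type), con, size = 1L)
    writeBin(as.raw(length(dims)), con)
    if (length(dims)) writeBin(as.raw(dims), con)
    if (length(data_raw)) writeBin(data_raw, con)
    writeBin(as.raw(0L), con)
  }
  str_block <- function(labels, width = 16L) {
    padded <- vapply(labels, function(s)
      formatC(s, width = -width, flag = " "), character(1))
    charToRaw(paste(substr(padded, 1L, width), collapse = ""))
  }
  wrec_group(1L, "POINT")
  wrec_param(1L, "LABELS", -1L, c(16L, np), str_block(names(markers)))
  wrec_param(1L, "UNITS", -1L, c(4L),
             charToRaw(formatC(units, width = -4L)))
  wrec_param(1L, "RATE", 4L, integer(0),
             writeBin(as.numeric(rate), raw(), size = 4L, endian = "little"))
  if (nch > 0L) {
    wrec_group(2L, "ANALOG")
    wrec_param(2L, "LABELS", -1L, c(16L, nch), str_block(names(analog)))
  }
  # terminator record
  writeBin(as.raw(c(0L, 0L)), con)
  pad_to(1024L)
  # data section: per frame, per point x/y/z/residual, then analog samples
  for (fr in seq_len(n_frames)) {
    for (i in seq_len(np)) f4(c(markers[[i]][fr, ], 0))
    if (nch > 0L && analog_per_frame > 0L) {
      for (s in seq_len(analog_per_frame)) {
        idx <- (fr - 1L) * analog_per_frame + s
        for (j in seq_len(nch)) f4(analog[[j]][idx])
      }
    }
  }
  invisible(path)
}
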