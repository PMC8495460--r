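# Stack and trace I/O.
#
# Stacks are stored as multi-page 32-bit IEEE float TIFF (little-endian,
# one strip per page, no compression), one page per time frame, with a JSON
# sidecar ("<file>.json") carrying the frame interval and channel. Float32
# is used instead of 16-bit integer so that quantization cannot interact
# with the z-transform. The writer/reader below implement exactly this
# baseline-TIFF float layout; general-purpose TIFF readers open the files.

TAG_WIDTH <- 256L; TAG_LENGTH <- 257L; TAG_BITS <- 258L
TAG_COMPRESSION <- 259L; TAG_PHOTOMETRIC <- 262L
TAG_STRIP_OFFSETS <- 273L; TAG_SPP <- 277L; TAG_ROWS_PER_STRIP <- 278L
TAG_STRIP_COUNTS <- 279L; TAG_SAMPLE_FORMAT <- 339L

#' Write a stack as a multi-page float32 TIFF
#'
#' One page per time frame, 32-bit IEEE float samples, little-endian,
#' uncompressed. A JSON sidecar `<path>.json` records the frame interval,
#' channel, and pixel format, so [read_stack()] can restore the stack
#' losslessly (bit-identical at float32 precision).
#'
#' @param stack a [dynamic_stack()].
#' @param path output file path (conventionally `*.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "dynamic_stack"))
  d <- dim(stack$data)
  h <- d[1L]; w <- d[2L]; nf <- d[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  ifd_entry_n <- 10L
  ifd_size <- 2L + ifd_entry_n * 12L + 4L
  page_bytes <- h * w * 4L
  data_off <- integer(nf); ifd_off <- integer(nf)
  pos <- 8L
  for (f in seq_len(nf)) {
    data_off[f] <- pos
    ifd_off[f] <- pos + page_bytes
    pos <- pos + page_bytes + ifd_size
  }
  writeBin(ifd_off[1L], con, size = 4L, endian = "little")
  w_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT: value left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (f in seq_len(nf)) {
    frame <- stack$data[, , f]
    writeBin(as.numeric(t(frame)), con, size = 4L, endian = "little")
    writeBin(ifd_entry_n, con, size = 2L, endian = "little")
    w_entry(TAG_WIDTH, 4L, 1L, w)
    w_entry(TAG_LENGTH, 4L, 1L, h)
    w_entry(TAG_BITS, 3L, 1L, 32L)
    w_entry(TAG_COMPRESSION, 3L, 1L, 1L)
    w_entry(TAG_PHOTOMETRIC, 3L, 1L, 1L)
    w_entry(TAG_STRIP_OFFSETS, 4L, 1L, data_off[f])
    w_entry(TAG_SPP, 3L, 1L, 1L)
    w_entry(TAG_ROWS_PER_STRIP, 4L, 1L, h)
    w_entry(TAG_STRIP_COUNTS, 4L, 1L, page_bytes)
    w_entry(TAG_SAMPLE_FORMAT, 3L, 1L, 3L)
    writeBin(if (f < nf) ifd_off[f + 1L] else 0L, con, size = 4L,
             endian = "little")
  }
  jsonlite::write_json(
    list(frame_interval = stack$frame_interval,
         channel = if (is.null(stack$channel)) NA else stack$channel,
         n_frames = nf, height = h, width = w,
         pixel_format = "float32", byte_order = "little-endian"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multi-page float32 TIFF stack
#'
#' Reads uncompressed single-sample TIFF pages (32-bit float or 8/16/32-bit
#' unsigned integer). The frame interval comes from the JSON sidecar written
#' by [write_stack()], or from the `frame_interval` argument when no sidecar
#' exists.
#'
#' @param path TIFF file path.
#' @param frame_interval seconds between frames; required when `<path>.json`
#'   is absent.
#' @return A [dynamic_stack()].
#' @export
read_stack <- function(path, frame_interval = NULL) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  channel <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval
    if (!is.null(meta$channel) && !is.na(meta$channel)) channel <- meta$channel
  }
  assert_that(!is.null(frame_interval),
              paste("frame interval unknown: provide `frame_interval` or a",
                    "JSON sidecar '<path>.json' with a frame_interval field"))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  endian <- if (identical(rawToChar(magic), "II")) "little"
            else if (identical(rawToChar(magic), "MM")) "big"
            else stop_hepaclear("not a TIFF file", "hepaclear_invalid_input")
  stopifnot(readBin(con, "integer", 1L, 2L, endian = endian) == 42L)
  ifd_off <- readBin(con, "integer", 1L, 4L, endian = endian)
  frames <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n_entries <- readBin(con, "integer", 1L, 2L, endian = endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      tag <- readBin(con, "integer", 1L, 2L, endian = endian, signed = FALSE)
      type <- readBin(con, "integer", 1L, 2L, endian = endian)
      count <- readBin(con, "integer", 1L, 4L, endian = endian)
      raw4 <- readBin(con, "raw", 4L)
      value <- if (type == 3L && count == 1L) {
        readBin(raw4[if (endian == "little") 1:2 else 3:4], "integer",
                1L, 2L, endian = endian, signed = FALSE)
      } else if (count == 1L) {
        readBin(raw4, "integer", 1L, 4L, endian = endian)
      } else {
        readBin(raw4, "integer", 1L, 4L, endian = endian)  # offset
      }
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = value, raw = raw4)
    }
    next_ifd <- readBin(con, "integer", 1L, 4L, endian = endian)
    need <- function(tag, default = NULL) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) {
        assert_that(!is.null(default), sprintf("missing TIFF tag %d", tag))
        return(default)
      }
      e$value
    }
    w <- need(TAG_WIDTH); h <- need(TAG_LENGTH)
    bits <- need(TAG_BITS, 1L)
    fmt <- need(TAG_SAMPLE_FORMAT, 1L)
    assert_that(need(TAG_COMPRESSION, 1L) == 1L,
                "compressed TIFF is not supported")
    assert_that(need(TAG_SPP, 1L) == 1L,
                "multi-sample TIFF is not supported")
    # strip offsets/counts may be inline (count 1) or stored out-of-line
    read_long_vec <- function(tag) {
      e <- tags[[as.character(tag)]]
      if (e$count == 1L) return(e$value)
      seek(con, e$value)
      readBin(con, "integer", e$count, 4L, endian = endian)
    }
    offs <- read_long_vec(TAG_STRIP_OFFSETS)
    cnts <- read_long_vec(TAG_STRIP_COUNTS)
    buf <- raw(0L)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      buf <- c(buf, readBin(con, "raw", cnts[s]))
    }
    vals <- if (fmt == 3L) {
      assert_that(bits == 32L, "only 32-bit float samples are supported")
      readBin(buf, "double", h * w, size = 4L, endian = endian)
    } else {
      readBin(buf, "integer", h * w, size = bits / 8L, endian = endian,
              signed = bits > 8L)
    }
    frames[[length(frames) + 1L]] <- matrix(vals, h, w, byrow = TRUE)
    ifd_off <- next_ifd
  }
  assert_that(length(frames) >= 1L, "TIFF file contains no pages")
  dims <- vapply(frames, dim, integer(2L))
  assert_that(all(dims[1L, ] == dims[1L, 1L]) && all(dims[2L, ] == dims[2L, 1L]),
              "ragged page shapes are not supported")
  arr <- array(unlist(frames), c(dim(frames[[1L]]), length(frames)))
  dynamic_stack(arr, frame_interval, channel)
}

#' Read/write an ROI mask as a single-page TIFF (nonzero = inside)
#'
#' @param roi logical matrix.
#' @param path file path.
#' @return For `write_roi_mask`, `path` invisibly; for `read_roi_mask`, a
#'   logical matrix.
#' @export
write_roi_mask <- function(roi, path) {
  write_stack(dynamic_stack(array(as.numeric(roi), c(dim(roi), 1L)),
                            frame_interval = 1, channel = "roi"),
              path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  st <- read_stack(path, frame_interval = 1)
  st$data[, , 1L] != 0
}

#' Write or read intensity traces as CSV
#'
#' Column layout `time_min,intensity,roi_id,animal_id` (RFC-4180, header
#' row). `read_traces` returns one [intensity_trace()] per `roi_id`.
#'
#' @param traces a single [intensity_trace()] or list of them.
#' @param path CSV file path.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("time_min", "intensity", "roi_id", "animal_id") %in% names(df)),
              "trace CSV must have columns time_min,intensity,roi_id,animal_id")
  lapply(split(df, df$roi_id), function(d) {
    d <- d[order(d$time_min), ]
    intensity_trace(d$time_min, d$intensity, d$roi_id[1L], d$animal_id[1L])
  })
}
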