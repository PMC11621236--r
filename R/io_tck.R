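#' Streamline sets
#'
#' A streamline is an ordered polyline of 3D world coordinates
#' (millimetres, RAS). A streamline set is a list of n x 3 coordinate
#' matrices carrying the class `streamline_set`.
#'
#' @param streamlines list of numeric matrices, each n x 3 with n >= 2 and
#'   finite coordinates.
#' @return a `streamline_set`.
#' @export
streamline_set <- function(streamlines) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3L) stop("streamline points must be n x 3")
    if (nrow(s) < 2L) stop("a streamline needs at least 2 points")
    if (!all(is.finite(s))) stop("streamline coordinates must be finite")
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  structure(streamlines, class = "streamline_set", space = "RAS mm")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x, nrow, integer(1))
  cat("streamline_set:", length(x), "streamlines,",
      if (length(x)) paste0(min(np), "-", max(np)) else 0, "points each\n")
  invisible(x)
}

#' Read an MRtrix .tck streamline file
#'
#' Parses the MRtrix dialect: a textual `key: value` header terminated by
#' `END`, then float32 little-endian coordinate triplets with a NaN triplet
#' separating streamlines and an Inf triplet terminating the file.
#'
#' @param path path to a `.tck` file.
#' @return a [streamline_set()].
#' @export
read_tck <- function(path) {
  if (!file.exists(path)) stop("no such tck file: ", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(10L))
  # parse the textual header line by line up to END
  header <- character()
  offset <- NA_integer_
  prev <- 0L
  for (pos in nl) {
    line <- rawToChar(bytes[seq.int(prev + 1L, pos - 1L)])
    prev <- pos
    if (length(header) == 0L && !identical(line, "mrtrix tracks")) {
      stop("not an MRtrix tck file (bad magic line): ", path)
    }
    header <- c(header, line)
    if (grepl("^file:", line)) {
      offset <- as.integer(sub("^file:\\s*\\.\\s+", "", line))
    }
    if (identical(line, "END")) break
    if (pos == nl[length(nl)]) stop("truncated tck header: ", path)
  }
  if (length(header) == 0L) stop("not an MRtrix tck file (empty): ", path)
  if (is.na(offset)) stop("tck header lacks a file: offset: ", path)
  dt <- grep("^datatype:", header, value = TRUE)
  if (length(dt) && !grepl("Float32LE", dt[1])) {
    stop("unsupported tck datatype (expected Float32LE): ", dt[1])
  }
  nfloat <- (length(bytes) - offset) %/% 4L
  raw <- readBin(bytes[-seq_len(offset)], "numeric", size = 4L,
                 endian = "little", n = nfloat)
  if (length(raw) %% 3L != 0L) stop("truncated tck coordinate data: ", path)
  trip <- matrix(raw, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- 0L  # start of current streamline (row before first point)
  i <- 1L
  terminated <- FALSE
  while (i <= nrow(trip)) {
    row <- trip[i, ]
    if (all(is.infinite(row))) {
      if (i - 1L > cur) {
        stop("tck file ", path, ": unterminated streamline ",
             length(streamlines) + 1L, " before EOF marker")
      }
      terminated <- TRUE
      break
    }
    if (all(is.nan(row))) {
      if (i - 1L == cur) stop("tck file ", path, ": empty streamline at index ",
                              length(streamlines) + 1L)
      streamlines[[length(streamlines) + 1L]] <- trip[(cur + 1L):(i - 1L), ,
                                                      drop = FALSE]
      cur <- i
    } else if (any(is.nan(row)) || any(is.infinite(row))) {
      stop("tck file ", path, ": malformed separator triplet at row ", i)
    }
    i <- i + 1L
  }
  if (!terminated) stop("tck file ", path, ": missing Inf end-of-file marker")
  streamline_set(streamlines)
}

#' Write an MRtrix .tck streamline file
#'
#' @param ss a [streamline_set()] (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(ss, path) {
  if (!inherits(ss, "streamline_set")) ss <- streamline_set(ss)
  head1 <- c("mrtrix tracks",
             "datatype: Float32LE",
             paste0("count: ", length(ss)),
             "twdfc: streamline set")
  # the file: line length affects the offset it states; fix by iteration
  offset <- 0L
  for (trial in 1:3) {
    lines <- c(head1, paste0("file: . ", offset), "END")
    new_offset <- sum(nchar(lines, type = "bytes") + 1L)
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  for (s in ss) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}
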