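# Minimal NRRD reader/writer for 3-D scalar grids.  Supports exactly the
# subset used for field exchange: dimension 3, type float/double, encodings
# ascii and raw (little endian), per-axis "spacings" and "axis mins".

#' Write a sampled 3-D field as NRRD
#'
#' Serializes primal-vertex samples of a field (values in cell enumeration
#' order, x fastest) together with grid spacing and origin.
#'
#' @param values numeric vector of length prod(counts).
#' @param counts grid vertex counts per axis.
#' @param spacing grid spacing.
#' @param origin coordinate of the first vertex.
#' @param path output file.
#' @param encoding `"raw"` (little-endian double) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(values, counts, spacing, origin = c(0, 0, 0), path,
                       encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  counts <- as.integer(counts)
  stopifnot(length(values) == prod(counts))
  hdr <- c("NRRD0004",
           "# 3-D scalar level-set field",
           "type: double",
           "dimension: 3",
           paste("sizes:", paste(counts, collapse = " ")),
           paste("spacings:", paste(rep(spacing, 3), collapse = " ")),
           paste("axis mins:", paste(origin, collapse = " ")),
           "endian: little",
           paste("encoding:", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(values), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(values, digits = 17), collapse = "\n"), con)
  }
  invisible(path)
}

#' Read a 3-D NRRD scalar grid
#'
#' Parses the subset of NRRD written by [write_nrrd()] (plus gzip-free raw or
#' ascii encodings from other tools): returns samples, counts, spacing and
#' origin.
#'
#' @param path NRRD file.
#' @return list with `values`, `counts`, `spacing`, `origin`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    l <- readLines(con, n = 1, warn = FALSE)
    if (!length(l) || l == "") break
    lines <- c(lines, l)
  }
  if (!length(lines) || !startsWith(lines[1], "NRRD"))
    stop("not an NRRD file: ", path)
  lines <- lines[!startsWith(lines, "#")][-1]
  fields <- strsplit(lines, ":\\s*")
  keys <- tolower(vapply(fields, `[`, "", 1))
  vals <- vapply(fields, function(f) paste(f[-1], collapse = ":"), "")
  getf <- function(key) vals[match(key, keys)]
  if (!is.na(getf("dimension")) && as.integer(getf("dimension")) != 3L)
    stop("only 3-D NRRD grids are supported")
  counts <- as.integer(strsplit(trimws(getf("sizes")), "\\s+")[[1]])
  spac <- getf("spacings")
  spacing <- if (!is.na(spac)) as.numeric(strsplit(trimws(spac), "\\s+")[[1]])[1] else 1
  am <- getf("axis mins")
  origin <- if (!is.na(am)) as.numeric(strsplit(trimws(am), "\\s+")[[1]]) else c(0, 0, 0)
  type <- trimws(getf("type"))
  enc <- trimws(getf("encoding"))
  n <- prod(counts)
  values <- if (identical(enc, "raw")) {
    size <- if (type %in% c("float", "float32")) 4L else 8L
    readBin(con, "double", n = n, size = size, endian = "little")
  } else if (identical(enc, "ascii") || identical(enc, "text") || identical(enc, "txt")) {
    scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(values) != n) stop("truncated NRRD data in ", path)
  list(values = values, counts = counts, spacing = spacing, origin = origin)
}

#' Turn grid samples into a scalar field by trilinear interpolation
#'
#' Builds an evaluator from primal-vertex samples (as returned by
#' [read_nrrd()]), so externally produced density maps can enter the same
#' pipeline as analytic fields.  Outside the sampled box the value of the
#' nearest box point is used.
#'
#' @param values samples in enumeration order (x fastest).
#' @param counts,spacing,origin grid geometry.
#' @return a [scalar_field()].
#' @export
field_from_samples <- function(values, counts, spacing, origin = c(0, 0, 0)) {
  counts <- as.integer(counts)
  stopifnot(length(values) == prod(counts))
  arr <- array(values, dim = counts)
  scalar_field(function(p) {
    tx <- pmin(pmax((p[, 1] - origin[1]) / spacing, 0), counts[1] - 1)
    ty <- pmin(pmax((p[, 2] - origin[2]) / spacing, 0), counts[2] - 1)
    tz <- pmin(pmax((p[, 3] - origin[3]) / spacing, 0), counts[3] - 1)
    i <- pmin(floor(tx), counts[1] - 2); fx <- tx - i
    j <- pmin(floor(ty), counts[2] - 2); fy <- ty - j
    k <- pmin(floor(tz), counts[3] - 2); fz <- tz - k
    at <- function(di, dj, dk)
      arr[cbind(i + 1 + di, j + 1 + dj, k + 1 + dk)]
    (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
                fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
      fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
            fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
  }, "sampled", list(counts = counts, spacing = spacing, origin = origin))
}
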