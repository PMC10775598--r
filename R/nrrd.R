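#' Minimal NRRD reader/writer
#'
#' Dose grids and masks travel as NRRD volumes (one file per volume, masks as
#' uint8, displacement fields as a 4D volume with the vector component as the
#' fastest axis). Only the small subset of NRRD needed here is supported:
#' `raw` and `ascii` encodings, little-endian, types `double`/`float`/`uint8`,
#' attached data. No R NRRD package is available in the target environment, so
#' the format is handled directly.
#'
#' @param x a [grid3d()], [mask3d()], or a plain numeric array.
#' @param path file path ending in `.nrrd`.
#' @param encoding `"raw"` (default) or `"ascii"`.
#' @return `write_nrrd` returns `path` invisibly; `read_nrrd` returns a
#'   `grid3d` (double data), `mask3d` (uint8 data) or a bare array (4D data).
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  if (inherits(x, "grid3d")) {
    arr <- x$values; type <- "double"; spacing <- x$spacing; origin <- x$origin
    extra <- character()
  } else if (inherits(x, "mask3d")) {
    arr <- x$flags + 0L; type <- "uint8"; spacing <- x$spacing
    origin <- c(0, 0, 0)
    extra <- c(sprintf("structure_name:=%s", x$name),
               sprintf("structure_role:=%s", x$role))
  } else {
    arr <- x; type <- "double"
    spacing <- attr(x, "spacing") %||% rep(1, length(dim(x)))
    origin <- attr(x, "origin") %||% rep(0, length(dim(x)))
    extra <- character()
  }
  nd <- length(dim(arr))
  # NRRD sizes are fastest-first; R arrays are column-major so dim() is
  # already fastest-first and element order matches NRRD data order.
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           sprintf("dimension: %d", nd),
           sprintf("sizes: %s", paste(dim(arr), collapse = " ")),
           sprintf("spacings: %s", paste(format(rev(spacing), digits = 12,
                                                trim = TRUE),
                                         collapse = " ")),
           sprintf("axis mins: %s", paste(format(rev(origin), digits = 12,
                                                 trim = TRUE),
                                          collapse = " ")),
           sprintf("encoding: %s", encoding),
           "endian: little",
           extra,
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(arr), digits = 17), collapse = " "), con)
  } else if (type == "uint8") {
    writeBin(as.integer(arr), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list(); kv <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl(":=", line, fixed = TRUE)) {
      p <- strsplit(line, ":=", fixed = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
    } else {
      p <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(p[1])]] <- trimws(p[2])
    }
  }
  type <- fields$type
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  n <- prod(sizes)
  enc <- fields$encoding
  if (enc == "ascii") {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else if (type == "uint8") {
    vals <- readBin(con, "integer", n = n, size = 1, signed = FALSE,
                    endian = "little")
  } else if (type == "float") {
    vals <- readBin(con, "double", n = n, size = 4, endian = "little")
  } else {
    vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  }
  arr <- array(vals, dim = sizes)
  spacing <- if (!is.null(fields$spacings))
    rev(as.numeric(strsplit(fields$spacings, "\\s+")[[1]])) else rep(1, length(sizes))
  origin <- if (!is.null(fields[["axis mins"]]))
    rev(as.numeric(strsplit(fields[["axis mins"]], "\\s+")[[1]])) else rep(0, length(sizes))
  if (length(sizes) != 3L) {
    attr(arr, "spacing") <- spacing; attr(arr, "origin") <- origin
    return(arr)
  }
  if (type == "uint8") {
    mask3d(arr > 0, name = kv$structure_name %||% "structure",
           role = kv$structure_role %||% "DERIVED", spacing = spacing)
  } else {
    grid3d(arr, spacing = spacing, origin = origin)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
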