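# Volume file I/O: NPY (raw array), NRRD (spacing honoured) and multi-page
# TIFF (one page per z-slice). Arrays are [x, y, z] with x fastest in
# memory, so raw little-endian files written here have z as the slowest
# axis. NPY and NRRD are simple enough formats that they are read and
# written directly.

npy_dtypes <- list(
  "<f4" = list(what = "numeric",  size = 4, signed = TRUE),
  "<f8" = list(what = "numeric",  size = 8, signed = TRUE),
  "<i4" = list(what = "integer",  size = 4, signed = TRUE),
  "<i2" = list(what = "integer",  size = 2, signed = TRUE),
  "|i1" = list(what = "integer",  size = 1, signed = TRUE),
  "<u2" = list(what = "integer",  size = 2, signed = FALSE),
  "|u1" = list(what = "integer",  size = 1, signed = FALSE)
)

#' Read a NPY array file
#'
#' Supports version 1.0/2.0 headers, little-endian integer and float dtypes,
#' C or Fortran element order.
#'
#' @param path file path.
#' @return an array (3D volumes come back as `[x, y, z]`).
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not a NPY file: ", path, call. = FALSE)
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  dt <- npy_dtypes[[descr]]
  if (is.null(dt)) stop("unsupported NPY dtype: ", descr, call. = FALSE)
  n <- prod(shape)
  x <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
               endian = "little")
  # C order with shape (nz,...,nx) stores x fastest, exactly like a
  # column-major array with the reversed shape
  dim(x) <- if (fortran) shape else rev(shape)
  x
}

#' Write a NPY array file
#'
#' @param path file path.
#' @param arr array to write.
#' @param dtype one of `"float32"`, `"float64"`, `"int32"`, `"int16"`,
#'   `"uint8"`.
#' @export
write_npy <- function(path, arr,
                      dtype = c("float32", "float64", "int32", "int16", "uint8")) {
  dtype <- match.arg(dtype)
  descr <- switch(dtype, float32 = "<f4", float64 = "<f8",
                  int32 = "<i4", int16 = "<i2", uint8 = "|u1")
  size <- switch(dtype, float32 = 4, float64 = 8, int32 = 4, int16 = 2, uint8 = 1)
  shape <- dim(arr) %||% length(arr)
  head <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                  descr, paste0(paste(rev(shape), collapse = ", "),
                                if (length(shape) == 1) "," else ""))
  pad <- 64 - ((10 + nchar(head) + 1) %% 64)
  head <- paste0(head, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(head)), con, size = 2, endian = "little")
  writeChar(head, con, eos = NULL)
  v <- as.vector(arr)
  if (dtype %in% c("float32", "float64"))
    writeBin(as.numeric(v), con, size = size, endian = "little")
  else
    writeBin(as.integer(v), con, size = size, endian = "little")
  invisible(path)
}

nrrd_types <- c("unsigned char" = "|u1", uchar = "|u1", uint8 = "|u1",
                "signed char" = "|i1", int8 = "|i1",
                short = "<i2", int16 = "<i2", "unsigned short" = "<u2", uint16 = "<u2",
                int = "<i4", int32 = "<i4",
                float = "<f4", double = "<f8")

#' Read a NRRD volume
#'
#' Raw-encoded, little-endian NRRD with an attached header. Per-axis
#' spacing is taken from `spacings` or the diagonal of `space directions`.
#'
#' @param path file path.
#' @return list with `data` (array) and `spacing` (numeric(3) or `NULL`).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  magic <- readLines(con, 1)
  if (!grepl("^NRRD000", magic)) stop("not a NRRD file: ", path, call. = FALSE)
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  enc <- fields$encoding %||% "raw"
  if (enc != "raw") stop("only raw NRRD encoding is supported", call. = FALSE)
  if (!is.null(fields$endian) && fields$endian != "little")
    stop("only little-endian NRRD supported", call. = FALSE)
  descr <- nrrd_types[[fields$type]]
  if (is.null(descr)) stop("unsupported NRRD type: ", fields$type, call. = FALSE)
  dt <- npy_dtypes[[descr]]
  x <- readBin(con, dt$what, prod(sizes), size = dt$size, signed = dt$signed,
               endian = "little")
  dim(x) <- sizes  # NRRD sizes are fastest axis first, matching [x, y, z]
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  list(data = x, spacing = spacing)
}

#' Write a NRRD volume
#'
#' @param path file path.
#' @param arr 3D array.
#' @param dtype storage type, as in [write_npy].
#' @param spacing per-axis voxel size, written to the `spacings` field.
#' @export
write_nrrd <- function(path, arr,
                       dtype = c("float32", "float64", "int32", "int16", "uint8"),
                       spacing = c(1, 1, 1)) {
  dtype <- match.arg(dtype)
  type <- switch(dtype, float32 = "float", float64 = "double",
                 int32 = "int", int16 = "short", uint8 = "uint8")
  size <- switch(dtype, float32 = 4, float64 = 8, int32 = 4, int16 = 2, uint8 = 1)
  spacing <- check_spacing(spacing)
  d <- dim(check_volume3d(arr))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("spacings: ", paste(format(spacing, digits = 15), collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  writeChar(paste0(hdr, "\n", collapse = ""), con, eos = NULL)
  v <- as.vector(arr)
  if (dtype %in% c("float32", "float64"))
    writeBin(as.numeric(v), con, size = size, endian = "little")
  else
    writeBin(as.integer(v), con, size = size, endian = "little")
  invisible(path)
}

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vol <- array(0, c(nx, ny, length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- t(pages[[z]])
  vol
}

write_tiff_volume <- function(path, arr, bits = 8L) {
  d <- dim(check_volume3d(arr))
  # writeTIFF stores real values scaled to the sample range
  scale <- 2^bits - 1
  pages <- lapply(seq_len(d[3]), function(z) t(arr[, , z]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("tiff", "nrrd", "npy")))
  switch(tolower(tools::file_ext(path)),
         tif = , tiff = "tiff", nrrd = "nrrd", npy = "npy",
         stop("cannot infer volume format from extension of ", path, call. = FALSE))
}

read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(infer_format(path, format),
         tiff = list(data = read_tiff_volume(path), spacing = NULL),
         nrrd = read_nrrd(path),
         npy  = list(data = read_npy(path), spacing = NULL))
}

#' Load a segmentation sample stack from files
#'
#' Reads one label volume per file; all volumes must share dimensions and
#' integer labels. NRRD spacing is honoured when present (first file wins);
#' otherwise 1.0 isotropic unless `spacing` is supplied.
#'
#' @param paths character vector of file paths.
#' @param format `"tiff"`, `"nrrd"` or `"npy"`; inferred from extension
#'   when `NULL`.
#' @param classes optional declared class set; labels outside it error.
#' @param spacing optional explicit voxel spacing, overriding headers.
#' @return a [seg_sample_stack].
#' @export
load_samples <- function(paths, format = NULL, classes = NULL, spacing = NULL) {
  if (length(paths) < 1) stop("no sample files given", call. = FALSE)
  vols <- vector("list", length(paths))
  hdr_spacing <- NULL
  for (k in seq_along(paths)) {
    v <- read_volume(paths[k], format)
    if (!is_wholenumber(v$data))
      stop(sprintf("sample %d (%s) contains non-integer voxel values",
                   k, paths[k]), call. = FALSE)
    if (k == 1) hdr_spacing <- v$spacing
    vols[[k]] <- v$data
  }
  seg_sample_stack(vols, classes = classes,
                   spacing = spacing %||% hdr_spacing %||% c(1, 1, 1))
}

#' Load / save a probability map
#'
#' Maps are stored as a single 32-bit float volume (the foreground-class map
#' of a binary problem) in NPY or NRRD format. On load, values outside
#' `[0, 1]` by more than `tol` are rejected; smaller excursions (lossy float
#' storage) are clamped.
#'
#' @param path file path (`.npy` or `.nrrd`).
#' @param format `"npy"` or `"nrrd"`; inferred from extension when `NULL`.
#' @param classes two-element class set the map describes; the larger label
#'   is the foreground the stored values refer to.
#' @param spacing optional explicit voxel spacing.
#' @param tol out-of-range tolerance beyond which loading fails.
#' @return a [probability_map].
#' @export
load_probability_map <- function(path, format = NULL, classes = c(0, 1),
                                 spacing = NULL, tol = 1e-6) {
  v <- read_volume(path, format)
  x <- v$data
  lo <- min(x); hi <- max(x)
  if (lo < -tol || hi > 1 + tol)
    stop(sprintf("probability map %s has %d voxels outside [0, 1] beyond tolerance %g (range [%g, %g])",
                 path, sum(x < -tol | x > 1 + tol), tol, lo, hi), call. = FALSE)
  x <- pmin(pmax(x, 0), 1)
  dim(x) <- dim(v$data)
  probability_map(x, classes = classes,
                  spacing = spacing %||% v$spacing %||% c(1, 1, 1))
}

#' @rdname load_probability_map
#' @param map a [probability_map]; for multi-class maps supply `class_i`.
#' @param class_i which class map to store (default foreground).
#' @export
save_probability_map <- function(map, path, format = NULL, class_i = NULL) {
  stopifnot(inherits(map, "probability_map"))
  eps <- class_map(map, class_i)
  switch(infer_format(path, format),
         npy  = write_npy(path, eps, "float32"),
         nrrd = write_nrrd(path, eps, "float32", spacing = map$spacing),
         stop("probability maps are stored as npy or nrrd", call. = FALSE))
  invisible(path)
}
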