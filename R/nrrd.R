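# Minimal NRRD (.nrrd, attached data) reader/writer covering the
# subset this package emits: 3-D scalar lattices, raw or gzip encoding,
# little-endian, types uint8/int16/int32/float/double, spacing via
# "space directions" or "spacings", origin via "space origin".
# NRRD stores the first axis fastest, which matches R's column-major
# arrays directly.

.nrrd_types <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double",  size = 4L, signed = TRUE),
  double = list(what = "double",  size = 8L, signed = TRUE)
)

.nrrd_type_aliases <- c(
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8_t" = "uint8",
  "short" = "int16", "signed short" = "int16", "int16_t" = "int16",
  "int" = "int32", "signed int" = "int32", "int32_t" = "int32"
)

normalize_nrrd_type <- function(type) {
  type <- tolower(trimws(type))
  if (type %in% names(.nrrd_type_aliases)) type <- .nrrd_type_aliases[[type]]
  if (!type %in% names(.nrrd_types))
    stop("unsupported NRRD type: ", type)
  type
}

parse_nrrd_vectors <- function(txt) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" -> NA entry
  parts <- regmatches(txt, gregexpr("\\(([^)]*)\\)|none", txt))[[1]]
  lapply(parts, function(p) {
    if (p == "none") return(NA_real_)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop("not an NRRD file (bad magic '", magic, "'): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("truncated NRRD header (no blank separator line): ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(name) {
    if (is.null(fields[[name]]))
      stop("NRRD header missing required field '", name, "': ", path)
    fields[[name]]
  }
  ndim <- as.integer(need("dimension"))
  if (!identical(ndim, 3L))
    stop("expected 3-D volume, got ", ndim, "-D data in ", path)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L || any(is.na(sizes)) || any(sizes < 1L))
    stop("invalid NRRD header field 'sizes': ", path)
  type <- normalize_nrrd_type(need("type"))
  enc <- tolower(need("encoding"))
  if (!enc %in% c("raw", "gzip", "gz"))
    stop("unsupported NRRD encoding '", enc, "': ", path)

  spacing <- NULL
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    dirs <- dirs[!vapply(dirs, function(d) all(is.na(d)), logical(1))]
    if (length(dirs) == 3L)
      spacing <- vapply(dirs, function(d) sqrt(sum(d^2)), numeric(1))
  }
  if (is.null(spacing) && !is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  if (is.null(spacing))
    stop("missing spacing in NRRD header (field 'space directions' or ",
         "'spacings'): ", path)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive spacing in NRRD header field 'space directions': ",
         path)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    ov <- parse_nrrd_vectors(fields[["space origin"]])
    if (length(ov) == 1L && length(ov[[1]]) == 3L) origin <- abs(ov[[1]])
  }
  endian <- tolower(fields[["endian"]] %||% "little")

  n <- prod(sizes)
  spec <- .nrrd_types[[type]]
  if (enc %in% c("gzip", "gz")) {
    payload <- readBin(con, "raw", n = file.info(path)$size)
    data_raw <- memDecompress(payload, type = "gzip")
    values <- readBin(data_raw, spec$what, n = n, size = spec$size,
                      signed = spec$signed, endian = endian)
  } else {
    values <- readBin(con, spec$what, n = n, size = spec$size,
                      signed = spec$signed, endian = endian)
  }
  if (length(values) != n)
    stop("NRRD data shorter than header sizes promise: ", path)
  list(voxels = array(as.numeric(values), sizes), spacing = spacing,
       origin = origin)
}

write_nrrd <- function(voxels, path, spacing, origin = c(0, 0, 0),
                       type = c("double", "uint8", "int16", "int32", "float"),
                       encoding = c("gzip", "raw")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  sizes <- dim(voxels)
  stopifnot(length(sizes) == 3L)
  spec <- .nrrd_types[[type]]
  dirs <- sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                  spacing[1], spacing[2], spacing[3])
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(sizes, collapse = " ")),
    paste0("space directions: ", dirs),
    "kinds: domain domain domain",
    "endian: little",
    paste0("encoding: ", encoding),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            origin[1], origin[2], origin[3]),
    "")
  vals <- as.vector(voxels)
  if (spec$what == "integer") vals <- as.integer(vals)
  payload <- writeBin(vals, raw(), size = spec$size, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
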