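## Minimal NRRD scalar-image reader/writer.  No installed R package handles
## NRRD, so the subset this package needs is implemented here: 3D scalar
## images, raw or gzip encodings, little/big endian, `spacings` or diagonal
## `space directions` headers.  Reference: the NRRD format definition
## (teem.sourceforge.net/nrrd/format.html).

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8"        = list(what = "integer", size = 1, signed = TRUE),
  "uchar"       = list(what = "integer", size = 1, signed = FALSE),
  "uint8"       = list(what = "integer", size = 1, signed = FALSE),
  "short"       = list(what = "integer", size = 2, signed = TRUE),
  "int16"       = list(what = "integer", size = 2, signed = TRUE),
  "ushort"      = list(what = "integer", size = 2, signed = FALSE),
  "uint16"      = list(what = "integer", size = 2, signed = FALSE),
  "int"         = list(what = "integer", size = 4, signed = TRUE),
  "int32"       = list(what = "integer", size = 4, signed = TRUE),
  "uint"        = list(what = "integer", size = 4, signed = TRUE),  # R lacks uint32; values < 2^31 only
  "uint32"      = list(what = "integer", size = 4, signed = TRUE),
  "float"       = list(what = "numeric", size = 4, signed = TRUE),
  "double"      = list(what = "numeric", size = 8, signed = TRUE)
)

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8 || rawToChar(raw_all[1:4]) != "NRRD")
    stop(sprintf("format error: '%s' is not a NRRD file", path), call. = FALSE)
  ## header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    seg <- p - prev  # length of line incl. newline
    if (seg == 1L || (seg == 2L && raw_all[p - 1L] == as.raw(13L))) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("format error: NRRD header has no terminating blank line",
                           call. = FALSE)
  hdr_lines <- strsplit(rawToChar(raw_all[1:(hdr_end - 1L)]), "\r?\n")[[1]]
  hdr_lines <- hdr_lines[-1]                       # drop magic
  hdr_lines <- hdr_lines[!grepl("^\\s*(#|$)", hdr_lines)]
  fields <- list()
  for (ln in hdr_lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop(sprintf("format error: NRRD header missing '%s'", key), call. = FALSE)
    fields[[key]]
  }
  ndim <- as.integer(need("dimension"))
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type_key <- tolower(need("type"))
  tinfo <- nrrd_types[[type_key]]
  if (is.null(tinfo))
    stop(sprintf("format error: unsupported NRRD type '%s'", type_key), call. = FALSE)
  spacings <- rep(1, ndim)
  if (!is.null(fields$spacings)) {
    spacings <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    sp <- vapply(seq_along(vecs), function(i) {
      v <- as.numeric(strsplit(gsub("[()]", "", vecs[i]), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))
    if (length(sp) == ndim) spacings <- sp
  }
  endian <- tolower(fields[["endian"]] %||% "little")
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop(sprintf("format error: unsupported NRRD encoding '%s'", encoding), call. = FALSE)
  }
  n <- prod(sizes)
  vals <- readBin(payload, what = tinfo$what, n = n, size = tinfo$size,
                  signed = if (tinfo$size < 4) tinfo$signed else TRUE,
                  endian = if (endian == "big") "big" else "little")
  if (length(vals) != n)
    stop("format error: NRRD payload shorter than declared sizes", call. = FALSE)
  list(data = array(as.double(vals), sizes), spacings = spacings, type = type_key)
}

## `a` arrives in canonical (slice, row, col); stored fastest-axis-first as
## (col, row, slice), mirroring how the NIfTI writer lays out axes.
write_nrrd <- function(a, spacing, path, integer_type = FALSE) {
  xyz <- aperm(a, c(3, 2, 1))
  type <- if (integer_type) "uint8" else "double"
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           sprintf("dimension: %d", length(dim(xyz))),
           sprintf("sizes: %s", paste(dim(xyz), collapse = " ")),
           sprintf("spacings: %s", paste(format(rev(spacing), digits = 17), collapse = " ")),
           "endian: little",
           "encoding: raw",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (integer_type) {
    writeBin(as.integer(xyz), con, size = 1, endian = "little")
  } else {
    writeBin(as.double(xyz), con, size = 8, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
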