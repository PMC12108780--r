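# Dataset container: NPZ (a zip of NumPy .npy members, stored uncompressed),
# with fixed keys X, y, subject, fs and a format version tag. Implemented
# natively so datasets interchange with NumPy's savez/load without any
# external dependency.

u16 <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                            endian = "little")
u32 <- function(v) c(u16(v %% 65536), u16(v %/% 65536))

npy_bytes <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  scalar <- is.null(dim(x)) && length(x) == 1L && !is.null(attr(x, "npy_scalar"))
  shape <- if (scalar) "()"
           else if (length(d) == 1L) sprintf("(%d,)", d)
           else sprintf("(%s)", paste(d, collapse = ", "))
  if (is.integer(x)) {
    descr <- "<i8"
    v <- if (is.null(dim(x))) x else as.vector(aperm(x, rev(seq_along(d))))
    # int64 as little-endian (low word, sign-extension word) pairs
    data <- writeBin(as.vector(rbind(as.integer(v),
                                     as.integer(ifelse(v < 0L, -1L, 0L)))),
                     raw(), size = 4L, endian = "little")
  } else {
    descr <- "<f8"
    v <- if (is.null(dim(x))) as.numeric(x)
         else as.vector(aperm(x, rev(seq_along(d))))
    data <- writeBin(v, raw(), size = 8L, endian = "little")
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  c(charToRaw("\x93NUMPY"), as.raw(c(1L, 0L)), u16(nchar(header)),
    charToRaw(header), data)
}

parse_npy <- function(bytes) {
  if (!identical(bytes[1:6], charToRaw("\x93NUMPY")))
    stop("container: member is not NumPy format", call. = FALSE)
  hlen <- as.integer(bytes[9]) + 256L * as.integer(bytes[10])
  header <- rawToChar(bytes[11:(10 + hlen)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- if (nchar(trimws(shape_s)) == 0L) integer(0)
           else as.integer(strsplit(gsub("\\s|,$", "", shape_s), ",")[[1L]])
  data <- bytes[(10L + hlen + 1L):length(bytes)]
  n <- if (length(shape) == 0L) 1L else prod(shape)
  v <- switch(descr,
    "<f8" = readBin(data, "double", n, size = 8L, endian = "little"),
    "<i8" = {
      words <- readBin(data, "integer", 2L * n, size = 4L, endian = "little")
      words[seq(1L, 2L * n, by = 2L)]   # low word; values assumed < 2^31
    },
    "<i4" = readBin(data, "integer", n, size = 4L, endian = "little"),
    stop("container: unsupported dtype '", descr, "'", call. = FALSE))
  if (length(shape) > 1L) {
    if (fortran) {
      dim(v) <- shape
    } else {
      dim(v) <- rev(shape)
      v <- aperm(v, rev(seq_along(shape)))
    }
  }
  v
}

write_npz <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  centrals <- list()
  pos <- 0L
  for (nm in names(entries)) {
    fname <- paste0(nm, ".npy")
    payload <- npy_bytes(entries[[nm]])
    crc <- crc32_raw(payload, 0)
    fn <- charToRaw(fname)
    local_hdr <- c(u32(67324752), u16(20), u16(0), u16(0), u16(0), u16(0),
                   u32(crc), u32(length(payload)), u32(length(payload)),
                   u16(length(fn)), u16(0), fn)
    writeBin(local_hdr, con)
    writeBin(payload, con)
    centrals[[nm]] <- c(u32(33639248), u16(20), u16(20), u16(0), u16(0),
                        u16(0), u16(0), u32(crc), u32(length(payload)),
                        u32(length(payload)), u16(length(fn)), u16(0),
                        u16(0), u16(0), u16(0), u32(0), u32(pos), fn)
    pos <- pos + length(local_hdr) + length(payload)
  }
  cd <- do.call(c, unname(centrals))
  writeBin(cd, con)
  writeBin(c(u32(101010256), u16(0), u16(0), u16(length(centrals)),
             u16(length(centrals)), u32(length(cd)), u32(pos), u16(0)), con)
  invisible(path)
}

read_u16 <- function(b, off) as.integer(b[off]) + 256L * as.integer(b[off + 1L])
read_u32 <- function(b, off) {
  as.numeric(b[off]) + 256 * as.numeric(b[off + 1L]) +
    65536 * as.numeric(b[off + 2L]) + 16777216 * as.numeric(b[off + 3L])
}

read_npz <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  # find end-of-central-directory signature scanning backwards
  eocd <- NA
  for (i in seq(length(b) - 21L, max(1L, length(b) - 65557L))) {
    if (b[i] == as.raw(0x50) && b[i + 1L] == as.raw(0x4b) &&
        b[i + 2L] == as.raw(0x05) && b[i + 3L] == as.raw(0x06)) {
      eocd <- i; break
    }
  }
  if (is.na(eocd)) stop("container: not a zip file (no end record)",
                        call. = FALSE)
  n_entries <- read_u16(b, eocd + 10L)
  cd_off <- read_u32(b, eocd + 16L) + 1L
  entries <- list()
  off <- cd_off
  for (e in seq_len(n_entries)) {
    if (read_u32(b, off) != 33639248)
      stop("container: corrupt central directory", call. = FALSE)
    method <- read_u16(b, off + 10L)
    csize <- read_u32(b, off + 20L)
    fnlen <- read_u16(b, off + 28L)
    extlen <- read_u16(b, off + 30L)
    cmtlen <- read_u16(b, off + 32L)
    lho <- read_u32(b, off + 42L) + 1L
    fname <- rawToChar(b[(off + 46L):(off + 45L + fnlen)])
    if (method != 0L)
      stop("container: member '", fname, "' is compressed; only stored ",
           "(uncompressed) NPZ is supported", call. = FALSE)
    lfn <- read_u16(b, lho + 26L)
    lex <- read_u16(b, lho + 28L)
    dstart <- lho + 30L + lfn + lex
    key <- sub("\\.npy$", "", fname)
    entries[[key]] <- parse_npy(b[dstart:(dstart + csize - 1L)])
    off <- off + 46L + fnlen + extlen + cmtlen
  }
  entries
}

#' Save an EEG dataset to an NPZ container
#'
#' The container holds named arrays \code{X} (trials x channels x
#' timepoints, float64), \code{y} and \code{subject} (int64) plus scalars
#' \code{fs} and \code{version}, readable by NumPy
#' (\code{numpy.load("data.npz")}) and by [load_dataset()].
#'
#' @param dataset An [eeg_dataset()].
#' @param path Output path (conventionally \code{.npz}).
#' @return \code{path}, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  fs <- dataset$fs; attr(fs, "npy_scalar") <- TRUE
  ver <- 1L; attr(ver, "npy_scalar") <- TRUE
  write_npz(list(X = dataset$X, y = as.integer(dataset$y),
                 subject = as.integer(dataset$subject), fs = fs,
                 version = ver), path)
  invisible(path)
}

#' Load an EEG dataset from an NPZ container
#'
#' Validates the schema (keys X, y, subject, fs) and all dataset invariants
#' (finite X, matching lengths, label range, every subject covering every
#' class), raising distinct errors for each violation.
#'
#' @param path Path to a container written by [save_dataset()] (or
#'   NumPy's \code{savez} with the same keys, uncompressed).
#' @return An [eeg_dataset()].
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("load_dataset: no such file: ", path,
                               call. = FALSE)
  entries <- read_npz(path)
  for (key in c("X", "y", "subject", "fs"))
    if (is.null(entries[[key]]))
      stop("load_dataset: container is missing required key '", key, "'",
           call. = FALSE)
  eeg_dataset(entries$X, entries$y, entries$subject, as.numeric(entries$fs))
}
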