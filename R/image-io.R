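#' Read a grayscale mammogram raster
#'
#' Reads a PGM (P2 ASCII or P5 binary, the dialect MIAS distributes) or a
#' grayscale PNG file and normalizes it into the package's internal image
#' model: a numeric matrix of intensities in \[0, 1\], indexed
#' `[row, col]` with row 1 at the top. Intensities are rescaled by dividing
#' by `2^depth - 1`, where the bit depth (8 or 16) comes from the file's
#' maxval (PGM) or sample depth (PNG); the original depth is kept in the
#' `source_depth` attribute.
#'
#' @param path Path to the image file.
#' @param dialect `"auto"` (default, sniff the magic bytes), `"pgm"` or
#'   `"png"`.
#' @return A numeric matrix in \[0, 1\] with attribute `source_depth`.
#' @seealso [write_mask()], [write_image()]
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_image(matrix(runif(64), 8, 8), f)
#' img <- read_image(f)
#' range(img)
#' @export
read_image <- function(path, dialect = c("auto", "pgm", "png")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort_pectoseg("pectoseg_io_error", sprintf("file not found: %s", path))
  if (dialect == "auto") {
    magic <- readBin(path, "raw", n = 8L)
    png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
    dialect <- if (length(magic) >= 8L && identical(magic, png_sig)) "png"
               else if (length(magic) >= 2L && magic[1] == charToRaw("P") &&
                        rawToChar(magic[2]) %in% c("2", "5")) "pgm"
               else abort_pectoseg("pectoseg_format_error",
                 sprintf("unrecognized format at byte offset 0: %s",
                         paste(format(magic[1:2]), collapse = " ")))
  }
  switch(dialect, pgm = read_pgm(path), png = read_png_gray(path))
}

# PGM (P2/P5) parser. MIAS ships 8-bit 1024x1024 P5 files but P2 and 16-bit
# maxvals occur in the wild; both are accepted. 16-bit P5 samples are
# big-endian per the Netpbm specification.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.size(path))
  if (length(raw_all) < 2L || rawToChar(raw_all[1]) != "P")
    abort_pectoseg("pectoseg_format_error",
                   "not a PGM file: bad magic at byte offset 0")
  kind <- rawToChar(raw_all[2])
  if (!kind %in% c("2", "5"))
    abort_pectoseg("pectoseg_format_error",
                   sprintf("unsupported PNM type P%s at byte offset 1", kind))

  # Header tokenizer: whitespace-separated integers, '#' comments to EOL.
  pos <- 3L
  n_raw <- length(raw_all)
  next_token <- function() {
    repeat {
      while (pos <= n_raw && rawToChar(raw_all[pos]) %in%
             c(" ", "\t", "\r", "\n")) pos <<- pos + 1L
      if (pos <= n_raw && rawToChar(raw_all[pos]) == "#") {
        while (pos <= n_raw && rawToChar(raw_all[pos]) != "\n") pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n_raw && !rawToChar(raw_all[pos]) %in%
           c(" ", "\t", "\r", "\n", "#")) pos <<- pos + 1L
    if (start > n_raw)
      abort_pectoseg("pectoseg_format_error",
                     sprintf("truncated PGM header at byte offset %d", start - 1L))
    rawToChar(raw_all[start:(pos - 1L)])
  }
  width  <- suppressWarnings(as.integer(next_token()))
  height <- suppressWarnings(as.integer(next_token()))
  maxval <- suppressWarnings(as.integer(next_token()))
  if (any(is.na(c(width, height, maxval))) || width < 1L || height < 1L ||
      maxval < 1L || maxval > 65535L)
    abort_pectoseg("pectoseg_format_error",
                   sprintf("invalid PGM header near byte offset %d", pos - 1L))
  depth <- if (maxval > 255L) 16L else 8L
  n_px <- width * height

  if (kind == "5") {
    pos <- pos + 1L  # single whitespace byte after maxval
    bytes_per <- if (depth == 16L) 2L else 1L
    need <- n_px * bytes_per
    if (n_raw - pos + 1L < need)
      abort_pectoseg("pectoseg_format_error",
        sprintf("truncated PGM pixel data at byte offset %d (need %d bytes)",
                pos - 1L, need))
    payload <- raw_all[pos:(pos + need - 1L)]
    vals <- if (depth == 16L) {
      readBin(payload, "integer", n = n_px, size = 2L,
              signed = FALSE, endian = "big")
    } else {
      as.integer(payload)
    }
  } else {
    vals <- integer(n_px)
    for (i in seq_len(n_px))
      vals[i] <- suppressWarnings(as.integer(next_token()))
    if (anyNA(vals))
      abort_pectoseg("pectoseg_format_error", "non-numeric P2 pixel token")
  }
  if (any(vals > maxval))
    abort_pectoseg("pectoseg_format_error", "PGM sample exceeds maxval")
  # PGM is row-major, top row first; R matrices are column-major.
  m <- matrix(vals / maxval, nrow = height, ncol = width, byrow = TRUE)
  attr(m, "source_depth") <- depth
  m
}

read_png_gray <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 2L) {
      arr <- arr[, , 1L]  # gray + alpha: drop alpha
    } else {
      abort_pectoseg("pectoseg_channel_error",
        sprintf("expected a grayscale PNG, got %d channels", nc))
    }
  }
  depth <- if (!is.null(info$bit.depth) && info$bit.depth > 8L) 16L else 8L
  m <- unclass(arr)
  attributes(m) <- list(dim = dim(arr))
  attr(m, "source_depth") <- depth
  m
}

#' Write a binary mask as an 8-bit raster
#'
#' Encodes a 0/1 mask as 8-bit \{0, 255\} in either binary PGM (P5) or
#' grayscale PNG; `read_image()` on the written file followed by `> 0.5`
#' thresholding recovers the mask bit-exactly.
#'
#' @param mask Binary 0/1 matrix.
#' @param path Destination path; format chosen by extension (`.png` writes
#'   PNG, anything else PGM).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  write_image(mask, path, depth = 8L)
}

#' Write a grayscale image
#'
#' Quantizes intensities in \[0, 1\] to the requested bit depth and writes a
#' binary PGM (P5) or grayscale PNG, chosen by the file extension.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path Destination path.
#' @param depth Bit depth, 8 (default) or 16.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path, depth = 8L) {
  if (!is.matrix(image) || !is.numeric(image))
    abort_pectoseg("pectoseg_type_error", "`image` must be a numeric matrix")
  if (min(image) < 0 || max(image) > 1)
    abort_pectoseg("pectoseg_range_error", "`image` intensities must lie in [0, 1]")
  if (!depth %in% c(8L, 16L))
    abort_pectoseg("pectoseg_config_error", "`depth` must be 8 or 16")
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    ok <- tryCatch({
      png::writePNG(image, path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      abort_pectoseg("pectoseg_io_error", sprintf("cannot write %s", path))
    return(invisible(path))
  }
  maxval <- bitwShiftL(1L, depth) - 1L
  vals <- as.integer(round(image * maxval))
  con <- tryCatch(file(path, "wb"), error = function(e)
    abort_pectoseg("pectoseg_io_error", sprintf("cannot open %s for writing", path)))
  on.exit(close(con))
  writeLines(sprintf("P5\n%d %d\n%d", ncol(image), nrow(image), maxval), con,
             sep = "\n")
  row_major <- as.vector(t(matrix(vals, nrow(image), ncol(image))))
  if (depth == 16L) {
    # writeBin() cannot emit unsigned 16-bit, so split into big-endian bytes.
    bytes <- as.raw(rbind(row_major %/% 256L, row_major %% 256L))
    writeBin(bytes, con)
  } else {
    writeBin(as.raw(row_major), con)
  }
  invisible(path)
}
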