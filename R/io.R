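#' Read curve control points from a file
#'
#' Accepts plain JSON (an array of `[x, y]` or `[x, y, z]` coordinates),
#' labelme-style annotation JSON (the `points` list of a named shape), or
#' CSV/TSV with one point per row. Coordinates are 0-based with `x` the
#' column direction (the labelme convention).
#'
#' @param path input file path.
#' @param shape for labelme files: the `label` of the shape to read
#'   (default: the first shape).
#' @return A [ControlPoints-class].
#' @export
readCurve <- function(path, shape = NULL) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.list(obj) && !is.null(obj$shapes)) {
      shp <- obj$shapes
      pts <- if (is.data.frame(shp)) {
        row <- if (is.null(shape)) 1L else match(shape, shp$label)
        if (is.na(row)) stop("labelme file has no shape labeled '", shape, "'")
        shp$points[[row]]
      } else {
        idx <- if (is.null(shape)) 1L
               else which(vapply(shp, function(s) identical(s$label, shape), TRUE))[1L]
        if (is.na(idx) || idx > length(shp))
          stop("labelme file has no shape labeled '", shape, "'")
        do.call(rbind, shp[[idx]]$points)
      }
      if (is.null(pts)) stop("malformed labelme file: missing 'points' field")
      return(controlPoints(as.matrix(pts)))
    }
    if (!is.numeric(obj) && !is.matrix(obj))
      stop("malformed curve JSON in ", path, ": expected an array of points")
    return(controlPoints(as.matrix(obj)))
  }
  if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    first <- readLines(path, n = 1L)
    has_header <- any(is.na(suppressWarnings(
      as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]]))))
    tab <- utils::read.table(path, sep = sep, header = has_header)
    return(controlPoints(as.matrix(tab)))
  }
  stop("unsupported curve file extension: .", ext)
}

# --- minimal writers for sample formats not covered by installed readers ---

crc32_tab <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L))
        bitwXor(-306674912L, bitwShiftR(bitwAnd(cc, -2L), 1L))
      else bitwShiftR(bitwAnd(cc, -2L), 1L)
    tab[i + 1L] <- cc
  }
  tab
})

crc32_bytes <- function(bytes) {
  cc <- -1L
  for (b in as.integer(bytes))
    cc <- bitwXor(crc32_tab[bitwAnd(bitwXor(cc, b), 255L) + 1L],
                  bitwShiftR(bitwAnd(cc, -256L), 8L))
  bitwXor(cc, -1L)
}

be32 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(be32(length(data)), td, be32(crc32_bytes(td)))
}

write_png16 <- function(x, path) {
  # 16-bit grayscale PNG; x in [0,1], rows = image rows
  q <- round(pmin(pmax(x, 0), 1) * 65535)
  h <- nrow(q); w <- ncol(q)
  m <- t(q)
  inter <- as.raw(rbind(as.integer(m %/% 256), as.integer(m %% 256)))
  dim(inter) <- c(2L * w, h)
  scan <- rbind(matrix(as.raw(0L), 1L, h), inter)   # filter byte 0 per row
  zlib <- memCompress(as.raw(scan), type = "gzip")  # R emits a zlib stream
  ihdr <- c(be32(w), be32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
}

write_tiff_float32 <- function(x, path) {
  # single-strip uncompressed little-endian 32-bit float grayscale TIFF
  h <- nrow(x); w <- ncol(x)
  con <- file(path, "wb"); on.exit(close(con))
  nbytes <- w * h * 4L
  datoff <- 8L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(datoff + nbytes), con, size = 4L, endian = "little")
  writeBin(as.vector(t(x)), con, size = 4L, endian = "little")
  tags <- list(c(256L, 4L, 1L, w), c(257L, 4L, 1L, h), c(258L, 3L, 1L, 32L),
               c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, datoff),
               c(277L, 3L, 1L, 1L), c(278L, 4L, 1L, h),
               c(279L, 4L, 1L, nbytes), c(339L, 3L, 1L, 3L))
  writeBin(length(tags), con, size = 2L, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1L]), con, size = 2L, endian = "little")
    writeBin(as.integer(tg[2L]), con, size = 2L, endian = "little")
    writeBin(as.integer(tg[3L]), con, size = 4L, endian = "little")
    if (tg[2L] == 3L) {
      writeBin(as.integer(tg[4L]), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else writeBin(as.integer(tg[4L]), con, size = 4L, endian = "little")
  }
  writeBin(0L, con, size = 4L, endian = "little")
}

#' Write a heatmap to disk
#'
#' The format follows the file extension: float TIFF (`.tif`/`.tiff`,
#' 32-bit IEEE samples, lossless at float precision), 16-bit grayscale PNG
#' (`.png`, values quantized to 1/65535, valid for peak-mode maps in
#' `[0, 1]`), or NIfTI (`.nii`/`.nii.gz`, 2D or 3D, stored as doubles,
#' bit-exact round trip). PNG and TIFF accept 2D maps only.
#'
#' @param hm a [Heatmap-class] or numeric matrix/array.
#' @param path output file path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
writeHeatmap <- function(hm, path) {
  x <- if (is(hm, "Heatmap")) heatmapValues(hm) else as.array(hm)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  nd <- length(dim(x))
  if (ext %in% c("tif", "tiff")) {
    if (nd != 2L) stop("TIFF output supports 2D heatmaps only")
    write_tiff_float32(x, path)
  } else if (ext == "png") {
    if (nd != 2L) stop("PNG output supports 2D heatmaps only")
    if (max(x) > 1 + 1e-9)
      warning("PNG output clips values above 1 (use TIFF/NIfTI for pdf-mode maps)")
    write_png16(x, path)
  } else if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"), path)
  } else {
    stop("unsupported heatmap format: .", ext,
         " (supported: .tif/.tiff, .png, .nii[.gz])")
  }
  invisible(path)
}

#' Read a heatmap written by [writeHeatmap()]
#'
#' @param path input file path (.tif/.tiff, .png or .nii[.gz]).
#' @return A [Heatmap-class].
#' @export
readHeatmap <- function(path) {
  if (!file.exists(path)) stop("heatmap file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  x <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else if (ext == "nii") {
    v <- RNifti::readNifti(path)
    array(as.numeric(v), dim = dim(v))
  } else stop("unsupported heatmap format: .", ext)
  asHeatmap(x)
}
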