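## On-disk formats: float32 multi-page TIFF for projection stacks (with a
## plain-text scale sidecar, since the TIFF writer stores [0, 1] floats),
## a uint8-style mask TIFF, 16-bit PNG depth frames in tenth-millimeters,
## and MHD/RAW float32 volumes.

#' Write / read a projection stack as multi-page TIFF
#'
#' Values are divided by a per-file scale (written to `<path>.scale`, plain
#' text) so the float TIFF stays in [0, 1]; the mask goes to a sidecar
#' `<stem>_mask.tif` as 0/1 pages. Reading reassembles the stack against a
#' geometry.
#'
#' @param stack a `projection_stack`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_projection_stack <- function(stack, path) {
  sc <- max(stack$data, 1e-12)
  pages <- lapply(seq_len(dim(stack$data)[3]), function(k)
    t(stack$data[, , k]) / sc)             # TIFF rows = detector rows
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(format(sc, digits = 17), paste0(path, ".scale"))
  mpages <- lapply(seq_len(dim(stack$mask)[3]), function(k)
    t(stack$mask[, , k]) * 1)
  tiff::writeTIFF(mpages, .mask_path(path), bits.per.sample = 8L)
  invisible(path)
}

.mask_path <- function(path) sub("(\\.tiff?)?$", "_mask.tif", path,
                                 ignore.case = TRUE)

#' @rdname write_projection_stack
#' @param geom the [cone_beam_geometry()] the stack was simulated with.
#' @return `read_projection_stack` returns a `projection_stack`.
#' @export
read_projection_stack <- function(path, geom) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- as.numeric(readLines(paste0(path, ".scale"))[1])
  data <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- t(pages[[k]]) * sc
  mask <- array(FALSE, dim(data))
  mp <- .mask_path(path)
  if (file.exists(mp)) {
    mpages <- tiff::readTIFF(mp, all = TRUE)
    if (!is.list(mpages)) mpages <- list(mpages)
    for (k in seq_along(mpages)) mask[, , k] <- t(mpages[[k]]) > 0.5
  }
  projection_stack(data, geom, mask)
}

# CRC32 (PNG chunk checksums), table-driven on R's 32-bit integers
.png_env <- new.env(parent = emptyenv())

.crc_table <- function() {
  if (is.null(.png_env$tab)) {
    tab <- integer(256)
    poly <- -306674912L                     # 0xEDB88320
    for (n in 0:255) {
      cc <- n
      for (k in 1:8)
        cc <- if (bitwAnd(cc, 1L)) bitwXor(poly, bitwShiftR(cc, 1L)) else
          bitwShiftR(cc, 1L)
      tab[n + 1L] <- cc
    }
    .png_env$tab <- tab
  }
  .png_env$tab
}

.crc32 <- function(bytes) {
  tab <- .crc_table()
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

.be32 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.be32(length(data)), body, .be32(.crc32(body)))
}

#' Write / read depth frames as 16-bit grayscale PNG (tenth-millimeters)
#'
#' Depth is quantized to 0.1 mm (uint16) and written as a plain 16-bit
#' grayscale PNG (own minimal encoder; the pre-built `png` reader only
#' writes 8-bit).
#'
#' @param frame a `depth_frame`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(frame, path) {
  q <- round(pmin(pmax(frame$depth, 0) * 10, 65535))
  w <- nrow(q); h <- ncol(q)
  B <- matrix(0L, 1L + 2L * w, h)          # filter byte + 2 bytes/pixel
  B[2L * seq_len(w), ] <- q %/% 256
  B[2L * seq_len(w) + 1L, ] <- q %% 256
  idat <- memCompress(as.raw(B), type = "gzip")   # zlib stream
  ihdr <- c(.be32(w), .be32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' @rdname write_depth_png
#' @param camera the [depth_camera()] the frame was rendered with.
#' @return `read_depth_png` returns a `depth_frame`.
#' @export
read_depth_png <- function(path, camera) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  structure(list(depth = t(round(img * 65535)) / 10, camera = camera),
            class = "depth_frame")
}

#' Write a volume as MHD/RAW (float32)
#'
#' Minimal MetaImage pair: a plain-text `.mhd` header and a little-endian
#' float32 `.raw` file.
#'
#' @param vol a `ct_volume`.
#' @param path output `.mhd` path.
#' @return `path`, invisibly.
#' @export
write_volume_mhd <- function(vol, path) {
  raw_path <- sub("\\.mhd$", ".raw", path)
  d <- dim(vol$data)
  sp <- vol$spec$voxel_mm
  org <- vol$spec$center - (d - 1) / 2 * sp
  writeLines(c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g", sp, sp, sp),
    sprintf("Offset = %g %g %g", org[1], org[2], org[3]),
    "ElementType = MET_FLOAT",
    sprintf("ElementDataFile = %s", basename(raw_path))
  ), path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  invisible(path)
}
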