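## Readers and writers for 2D slices (PNG, MetaImage, NIfTI), the
## annotation CSV format, intensity windowing, and coordinate
## conversion. Convention everywhere: 0-based (row, col) pixel indices
## with pixel centers at integer coordinates; spacing/origin enter only
## through the world<->voxel conversions.

#' A 2D image slice with spatial metadata
#'
#' @param values numeric H x W matrix of intensities.
#' @param spacing mm per pixel, (row, col).
#' @param origin optional world coordinates of pixel (0, 0).
#' @return object of class `"image_slice"`.
#' @export
image_slice <- function(values, spacing = c(1, 1), origin = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) stop("empty image")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = origin), class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice> %dx%d, spacing (%g, %g) mm, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              min(x$values), max(x$values)))
  invisible(x)
}

# ---- 16-bit grayscale PNG (write side; png::readPNG reads 16-bit) ---------

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- cpp_crc32(body)
  if (crc > 2147483647) crc <- crc - 4294967296 # two's complement for writeBin
  c(writeBin(length(data), raw(), size = 4, endian = "big"),
    body,
    writeBin(as.integer(crc), raw(), size = 4, endian = "big"))
}

#' Write a matrix as 16-bit grayscale PNG
#'
#' Values in `[0, 1]` are quantized to 16 bits. 8-bit PNG loses the
#' intensity resolution of low-noise phantoms, so the generator's image
#' channel uses this writer; [png::readPNG()] reads it back as
#' `round(values * 65535) / 65535`.
#'
#' @param values numeric matrix in `[0, 1]`.
#' @param path output file.
#' @export
write_png16 <- function(values, path) {
  v <- pmin(pmax(values, 0), 1)
  u <- matrix(as.integer(round(v * 65535)), nrow(v), ncol(v))
  H <- nrow(u); W <- ncol(u)
  ihdr <- c(writeBin(W, raw(), size = 4, endian = "big"),
            writeBin(H, raw(), size = 4, endian = "big"),
            as.raw(c(16, 0, 0, 0, 0))) # bit depth 16, grayscale
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  scan <- raw(H * (1 + 2 * W))
  for (r in seq_len(H)) {
    off <- (r - 1) * (1 + 2 * W)
    row <- u[r, ]
    scan[off + 1] <- as.raw(0)
    scan[off + 1 + seq(1, 2 * W, by = 2)] <- as.raw(row %/% 256L)
    scan[off + 1 + seq(2, 2 * W, by = 2)] <- as.raw(row %% 256L)
  }
  idat <- memCompress(scan, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

# ---- MetaImage (.mhd + .raw) ----------------------------------------------

met_types <- c(MET_UCHAR = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_INT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
met_sizes <- c(MET_UCHAR = 1, MET_SHORT = 2, MET_USHORT = 2, MET_INT = 4,
               MET_FLOAT = 4, MET_DOUBLE = 8)

read_mhd <- function(path, slice = NULL) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (l in lines) {
    parts <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
    }
  }
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  et <- kv$ElementType
  if (!et %in% names(met_types)) stop("unsupported ElementType: ", et)
  spacing <- if (!is.null(kv$ElementSpacing)) {
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]])
  } else rep(1, length(dims))
  offset <- if (!is.null(kv$Offset)) {
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]])
  } else NULL
  raw_file <- file.path(dirname(path), kv$ElementDataFile)
  con <- file(raw_file, "rb")
  on.exit(close(con))
  n <- prod(dims)
  vals <- readBin(con, what = met_types[[et]], n = n, size = met_sizes[[et]],
                  endian = "little",
                  signed = !(et %in% c("MET_UCHAR", "MET_USHORT")))
  # MetaImage stores x (cols) fastest; our matrices are (row, col)
  if (length(dims) == 2) {
    values <- t(matrix(vals, dims[1], dims[2]))
  } else if (length(dims) == 3) {
    if (is.null(slice)) slice <- 1L
    if (slice < 1 || slice > dims[3]) {
      stop("slice index ", slice, " out of range [1, ", dims[3], "]")
    }
    plane <- vals[((slice - 1) * dims[1] * dims[2] + 1):(slice * dims[1] * dims[2])]
    values <- t(matrix(plane, dims[1], dims[2]))
  } else {
    stop("only 2D/3D MetaImage supported")
  }
  image_slice(values, spacing = rev(spacing[1:2]),
              origin = if (!is.null(offset)) rev(offset[1:2]) else NULL)
}

write_mhd <- function(slice, path) {
  v <- slice$values
  base <- sub("\\.mhd$", "", basename(path))
  raw_name <- paste0(base, ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 2",
    sprintf("DimSize = %d %d", ncol(v), nrow(v)),
    "ElementType = MET_DOUBLE",
    sprintf("ElementSpacing = %g %g", slice$spacing[2], slice$spacing[1]),
    if (!is.null(slice$origin)) {
      sprintf("Offset = %g %g", slice$origin[2], slice$origin[1])
    },
    "ElementByteOrderMSB = False",
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(v)), con, size = 8, endian = "little")
  invisible(path)
}

# ---- dispatching reader/writer --------------------------------------------

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.png$", low)) "png"
  else if (grepl("\\.mhd$", low)) "metaimage"
  else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else stop("cannot guess format of ", path)
}

#' Read a 2D slice from PNG, MetaImage or NIfTI
#'
#' For volumetric inputs a `slice` index extracts one 2D plane; spacing
#' metadata is preserved where the format carries it.
#'
#' @param path input file (`.png`, `.mhd`, `.nii`, `.nii.gz`).
#' @param format override the extension-based format guess.
#' @param slice 1-based plane index for volumetric formats.
#' @return an [image_slice()].
#' @export
read_slice <- function(path, format = NULL, slice = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_format(path)
  switch(format,
    png = {
      v <- png::readPNG(path)
      if (length(dim(v)) == 3) v <- v[, , 1]
      image_slice(v)
    },
    metaimage = read_mhd(path, slice = slice),
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- as.array(img)
      sp <- RNifti::pixdim(img)
      if (length(dim(arr)) >= 3) {
        if (is.null(slice)) slice <- 1L
        if (slice < 1 || slice > dim(arr)[3]) {
          stop("slice index ", slice, " out of range [1, ", dim(arr)[3], "]")
        }
        arr <- arr[, , slice]
      }
      v <- matrix(as.numeric(arr), dim(arr)[1], dim(arr)[2])
      image_slice(v, spacing = if (length(sp) >= 2) sp[1:2] else c(1, 1))
    },
    stop("unknown format: ", format)
  )
}

#' Write a 2D slice to PNG (16-bit), MetaImage or NIfTI
#'
#' @param slice an [image_slice()] or plain matrix.
#' @param path output file.
#' @param format override the extension-based format guess.
#' @export
write_slice <- function(slice, path, format = NULL) {
  if (!inherits(slice, "image_slice")) slice <- image_slice(slice)
  format <- format %||% guess_format(path)
  switch(format,
    png = write_png16(slice$values, path),
    metaimage = write_mhd(slice, path),
    nifti = {
      img <- RNifti::asNifti(slice$values)
      RNifti::pixdim(img) <- slice$spacing
      RNifti::writeNifti(img, path)
    },
    stop("unknown format: ", format)
  )
  invisible(path)
}

# ---- intensity windowing --------------------------------------------------

#' Window and normalize CT intensities
#'
#' Clips to `[low, high]` Hounsfield units and maps affinely to
#' `[0, 1]`. The default window (-1000, 400) spans air to bone.
#'
#' @param values numeric grid of raw intensities.
#' @param window length-2 `(low, high)` in HU, `low < high`.
#' @return grid in `[0, 1]`.
#' @examples
#' normalize_hu(-300, c(-1000, 400)) # 0.5
#' @export
normalize_hu <- function(values, window = c(-1000, 400)) {
  if (window[1] >= window[2]) stop("inverted window: low must be < high")
  pmin(pmax((values - window[1]) / (window[2] - window[1]), 0), 1)
}

# ---- coordinates ----------------------------------------------------------

#' World <-> voxel conversion
#'
#' Pixel indices are 0-based (row, col) with centers at integer
#' coordinates; world coordinates are `(x, y) = origin + index * spacing`
#' with x along columns and y along rows.
#'
#' @param xy matrix or vector of world `(x, y)` pairs.
#' @param spacing mm per pixel (row, col).
#' @param origin world coordinates of pixel (0, 0) as `(x, y)`.
#' @return (row, col) indices (0-based), or world coordinates.
#' @export
world_to_voxel <- function(xy, spacing, origin) {
  xy <- matrix(xy, ncol = 2)
  cbind(row = (xy[, 2] - origin[2]) / spacing[1],
        col = (xy[, 1] - origin[1]) / spacing[2])
}

#' @rdname world_to_voxel
#' @param rc matrix or vector of 0-based (row, col) indices.
#' @export
voxel_to_world <- function(rc, spacing, origin) {
  rc <- matrix(rc, ncol = 2)
  cbind(x = origin[1] + rc[, 2] * spacing[2],
        y = origin[2] + rc[, 1] * spacing[1])
}

# ---- annotations ----------------------------------------------------------

#' Read / write nodule annotation tables
#'
#' Pixel mode expects the header `id,center_row,center_col,diameter`
#' (0-based pixel coordinates, lossless round trip). World mode expects
#' `id,x_mm,y_mm,diameter_mm` and converts through `spacing`/`origin`;
#' the diameter is divided by the mean spacing. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file.
#' @param spacing,origin required for world-mode files.
#' @return data frame with columns `id`, `center_row`, `center_col`,
#'   `diameter` (pixels) and `contrast` (NA when absent).
#' @export
read_annotations <- function(path, spacing = NULL, origin = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pixel_cols <- c("id", "center_row", "center_col", "diameter")
  world_cols <- c("id", "x_mm", "y_mm", "diameter_mm")
  if (all(pixel_cols %in% names(df))) {
    num <- df[, c("center_row", "center_col", "diameter")]
    bad <- which(!stats::complete.cases(num) |
                   !vapply(seq_len(nrow(num)), function(i) {
                     all(is.finite(as.numeric(num[i, ])))
                   }, logical(1)) | num$diameter <= 0)
    if (length(bad)) {
      stop("malformed annotation rows at line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path)
    }
    out <- data.frame(id = as.integer(df$id),
                      center_row = as.numeric(df$center_row),
                      center_col = as.numeric(df$center_col),
                      diameter = as.numeric(df$diameter))
  } else if (all(world_cols %in% names(df))) {
    if (is.null(spacing) || is.null(origin)) {
      stop("world-coordinate annotations need spacing and origin")
    }
    rc <- world_to_voxel(cbind(df$x_mm, df$y_mm), spacing, origin)
    out <- data.frame(id = df$id, center_row = rc[, "row"],
                      center_col = rc[, "col"],
                      diameter = df$diameter_mm / mean(spacing))
  } else {
    stop("unrecognized annotation header in ", path,
         " (expected ", paste(pixel_cols, collapse = ","), " or ",
         paste(world_cols, collapse = ","), ")")
  }
  out$contrast <- if ("contrast" %in% names(df)) as.numeric(df$contrast)
                  else rep(NA_real_, nrow(out))
  out
}

#' @rdname read_annotations
#' @param annotations data frame with pixel-mode columns.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("id", "center_row", "center_col", "diameter")
  stopifnot(all(cols %in% names(annotations)))
  df <- annotations[, cols, drop = FALSE]
  if ("contrast" %in% names(annotations)) df$contrast <- annotations$contrast
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
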