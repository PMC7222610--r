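# Tissue label vocabulary and the fixed mask palette used on disk.
TISSUE_LEVELS <- c("liver", "kidney", "other")
MASK_PALETTE <- c(other = 0L, liver = 1L, kidney = 2L, ignore = 255L)
CHANNEL_NAMES <- c("fat", "water", "ip", "op")
FEATURE_COLS <- c("fat_s", "water_s", "ip_s", "op_s", "x", "y")

# 3x3 smoothing kernel applied to every MR channel before feature
# extraction: eight neighbours at 0.1, centre at 0.2 (weights sum to 1,
# so constant tissue intensity is preserved).
CK3 <- matrix(c(0.1, 0.1, 0.1,
                0.1, 0.2, 0.1,
                0.1, 0.1, 0.1), nrow = 3, byrow = TRUE)

#' Construct a four-channel MR volume set
#'
#' Bundles the four co-registered Dixon channel images (fat, water,
#' in-phase, opposed-phase) of one 2-D abdominal slice together with the
#' physical pixel spacing.
#'
#' @param channels Named list with exactly the elements `fat`, `water`,
#'   `ip` and `op`, each a numeric matrix of identical dimensions.
#' @param pixel_spacing Numeric pair `(row_mm, col_mm)`, both positive.
#' @param case_id Character identifier for the case.
#' @return An object of class `mr_volume_set`.
#' @export
mr_volume_set <- function(channels, pixel_spacing = c(1, 1), case_id = "case") {
  if (!is.list(channels)) stop("`channels` must be a named list of matrices")
  missing <- setdiff(CHANNEL_NAMES, names(channels))
  if (length(missing) > 0L) {
    stop("missing channel: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(channels), CHANNEL_NAMES)
  if (length(extra) > 0L) {
    stop("unknown channel: ", paste(extra, collapse = ", "))
  }
  channels <- lapply(channels[CHANNEL_NAMES], function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("shape mismatch between channels: ",
         paste(sprintf("%s=%dx%d", CHANNEL_NAMES, dims[1, ], dims[2, ]),
               collapse = ", "))
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be two strictly positive numbers (row_mm, col_mm)")
  }
  structure(list(channels = channels, pixel_spacing = pixel_spacing,
                 case_id = as.character(case_id)),
            class = "mr_volume_set")
}

#' @export
print.mr_volume_set <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mr_volume_set '%s': 4 channels %dx%d, spacing %.3gx%.3g mm>\n",
              x$case_id, d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

read_channel_image <- function(path, slice = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) > 2L) {
      extra <- dim(a)[-(1:2)]
      if (all(extra == 1L)) {
        a <- array(a, dim = dim(a)[1:2])
      } else if (!is.null(slice)) {
        a <- a[, , slice]
      } else {
        stop("multi-slice NIfTI volume requires an explicit `slice` index: ",
             path)
      }
    }
    return(matrix(as.numeric(a), nrow = dim(a)[1]))
  }
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) > 2L) stop("expected a grayscale PNG: ", path)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    # readPNG scales to [0,1]; restore the stored integer code values.
    return(img * (2^depth - 1))
  }
  if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) > 2L) stop("expected a grayscale TIFF: ", path)
    m <- matrix(as.numeric(img), nrow = nrow(img))
    return(m)
  }
  stop("unsupported image format (need .nii/.nii.gz/.png/.tif): ", path)
}

#' Load a four-channel MR volume set from disk
#'
#' Reads the four Dixon channel images from NIfTI-1 (`.nii`, `.nii.gz`)
#' or 8/16-bit grayscale PNG/TIFF files. Intensities are returned as
#' stored, without rescaling.
#'
#' @param paths Named character vector or list mapping each of `fat`,
#'   `water`, `ip`, `op` to a file path.
#' @param pixel_spacing Numeric pair `(row_mm, col_mm)`.
#' @param case_id Case identifier; defaults to the common dirname.
#' @param slice Optional slice index for multi-slice NIfTI volumes.
#' @return An `mr_volume_set`.
#' @export
load_volume_set <- function(paths, pixel_spacing = c(1, 1),
                            case_id = NULL, slice = NULL) {
  paths <- as.list(paths)
  missing <- setdiff(CHANNEL_NAMES, names(paths))
  if (length(missing) > 0L) {
    stop("missing channel: ", paste(missing, collapse = ", "))
  }
  channels <- lapply(paths[CHANNEL_NAMES], read_channel_image, slice = slice)
  if (is.null(case_id)) case_id <- basename(dirname(as.character(paths[[1]])))
  mr_volume_set(channels, pixel_spacing, case_id)
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel bounds framing the area to classify.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels; both at least 3 so the 3x3
#'   smoothing kernel has interior support.
#' @return An object of class `roi`.
#' @export
roi <- function(row0, col0, height, width) {
  vals <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (any(vals != round(vals))) stop("ROI bounds must be integers")
  if (row0 < 0 || col0 < 0) stop("ROI origin must be non-negative")
  if (height < 3 || width < 3) stop("ROI height and width must be >= 3")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

validate_roi <- function(r, dims) {
  stopifnot(inherits(r, "roi"))
  if (r$row0 + r$height > dims[1] || r$col0 + r$width > dims[2]) {
    stop(sprintf("ROI %d+%d x %d+%d exceeds image %dx%d",
                 r$row0, r$height, r$col0, r$width, dims[1], dims[2]))
  }
  invisible(r)
}

#' Smooth one MR channel with the fixed 3x3 kernel
#'
#' Correlates the image with the kernel (0.1 on the eight neighbours,
#' 0.2 at the centre). Borders use replicate-edge padding so the output
#' has the same shape as the input and no artificial zero intensities
#' are introduced.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_channel <- function(image) {
  image <- as.matrix(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image must be at least 3x3")
  out <- matrix(0, nr, nc)
  for (dr in -1:1) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    for (dc in -1:1) {
      ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      out <- out + CK3[dr + 2L, dc + 2L] * image[ri, ci, drop = FALSE]
    }
  }
  out
}

#' Per-pixel feature table
#'
#' The universal exchange type: a numeric feature matrix with optional
#' tissue labels. Image-derived tables carry the canonical six columns
#' `fat_s, water_s, ip_s, op_s, x, y` (four smoothed channel intensities
#' plus physical pixel coordinates in millimetres); solver-level fixtures
#' may carry any dimension.
#'
#' @param X Numeric matrix, one row per pixel/sample; all entries finite.
#' @param labels Optional character/factor vector of length `nrow(X)`.
#' @param case_id Provenance: originating case.
#' @param roi Provenance: originating [roi()], or `NULL`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(X, labels = NULL, case_id = NA_character_, roi = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("feature matrix contains non-finite entries")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(X)) {
      stop("labels length (", length(labels), ") does not match rows (",
           nrow(X), ")")
    }
  }
  structure(list(X = X, labels = labels, case_id = case_id, roi = roi),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d rows x %d features%s>\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$labels)) "" else
                paste0(", labels {", paste(names(table(x$labels)),
                                           collapse = ", "), "}")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- as.data.frame(x$X)
  if (!is.null(x$labels)) df$label <- x$labels
  df
}

decode_mask_values <- function(mask) {
  # Accepts an integer palette-code matrix or a character matrix.
  if (is.character(mask)) {
    bad <- setdiff(unique(as.vector(mask)), c(TISSUE_LEVELS, "ignore"))
    if (length(bad) > 0L) stop("unknown mask labels: ", paste(bad, collapse = ", "))
    return(mask)
  }
  code <- round(as.vector(mask))
  lut <- character(256)
  lut[MASK_PALETTE + 1L] <- names(MASK_PALETTE)
  lab <- lut[code + 1L]
  if (any(is.na(lab) | lab == "")) {
    stop("mask contains values outside the palette {0,1,2,255}")
  }
  matrix(lab, nrow = nrow(mask))
}

#' Extract six-dimensional pixel features from a volume set
#'
#' Smooths each channel with [smooth_channel()], then assembles one row
#' per ROI pixel in row-major order: the four smoothed intensities plus
#' physical coordinates `x = col * col_mm`, `y = row * row_mm` (0-based
#' pixel indices). Pixels marked `ignore` in the mask are dropped; other
#' mask values become labels.
#'
#' @param vol An [mr_volume_set()].
#' @param roi An [roi()] inside the image.
#' @param mask Optional label image of the same shape as the channels:
#'   either palette codes (`other=0, liver=1, kidney=2, ignore=255`) or a
#'   character matrix over `{liver, kidney, other, ignore}`.
#' @return A [feature_table()] with the six canonical columns.
#' @export
extract_features <- function(vol, roi, mask = NULL) {
  stopifnot(inherits(vol, "mr_volume_set"))
  dims <- dim(vol$channels[[1]])
  validate_roi(roi, dims)
  smoothed <- lapply(vol$channels, smooth_channel)

  rows0 <- roi$row0 + seq_len(roi$height) - 1L   # 0-based
  cols0 <- roi$col0 + seq_len(roi$width) - 1L
  # row-major: row varies slowest
  rr <- rep(rows0, each = roi$width)
  cc <- rep(cols0, times = roi$height)
  pix <- cbind(rr + 1L, cc + 1L)

  keep <- rep(TRUE, nrow(pix))
  labels <- NULL
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dims)) stop("mask shape does not match channels")
    lab <- decode_mask_values(mask)[pix]
    keep <- lab != "ignore"
    labels <- lab[keep]
  }
  if (!any(keep)) stop("ROI is empty after masking")

  X <- cbind(
    fat_s   = smoothed$fat[pix][keep],
    water_s = smoothed$water[pix][keep],
    ip_s    = smoothed$ip[pix][keep],
    op_s    = smoothed$op[pix][keep],
    x       = cc[keep] * vol$pixel_spacing[2],
    y       = rr[keep] * vol$pixel_spacing[1]
  )
  feature_table(X, labels = labels, case_id = vol$case_id, roi = roi)
}

#' Write a label mask image
#'
#' Renders per-pixel predictions for an ROI into a full-size mask image
#' with the fixed palette `other=0, liver=1, kidney=2, ignore=255`;
#' pixels outside the ROI are set to `ignore`. Written as an 8-bit
#' grayscale PNG of palette codes, or as NIfTI if the path ends in
#' `.nii`/`.nii.gz`.
#'
#' @param labels Character vector over `{liver, kidney, other}` of length
#'   `height * width` of the ROI, in row-major order.
#' @param roi The [roi()] the predictions cover.
#' @param shape Integer pair: full image `(rows, cols)`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(labels, roi, shape, path) {
  labels <- as.character(labels)
  if (length(labels) != roi$height * roi$width) {
    stop("labels length (", length(labels), ") does not equal ROI pixel count (",
         roi$height * roi$width, ")")
  }
  bad <- setdiff(unique(labels), TISSUE_LEVELS)
  if (length(bad) > 0L) stop("unknown labels: ", paste(bad, collapse = ", "))
  validate_roi(roi, shape)
  code <- matrix(MASK_PALETTE[["ignore"]], shape[1], shape[2])
  rr <- rep(roi$row0 + seq_len(roi$height) - 1L, each = roi$width) + 1L
  cc <- rep(roi$col0 + seq_len(roi$width) - 1L, times = roi$height) + 1L
  code[cbind(rr, cc)] <- MASK_PALETTE[labels]
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) {
    RNifti::writeNifti(RNifti::asNifti(code), path)
  } else {
    png::writePNG(code / 255, path)
  }
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path PNG or NIfTI mask path.
#' @return Integer matrix of palette codes.
#' @export
read_label_mask <- function(path) {
  m <- read_channel_image(path)
  code <- round(m)
  matrix(as.integer(code), nrow = nrow(code))
}

#' Serialize a feature table to CSV
#'
#' Header `fat_s,water_s,ip_s,op_s,x,y[,label]` for image-derived tables
#' (generic column names otherwise).
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  feature_table(as.matrix(df), labels = labels)
}
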