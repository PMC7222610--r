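# ---------------------------------------------------------------------
# Synthetic abdominal phantom: elliptical organs on an "other"-tissue
# background, four Dixon-like channels with tissue-dependent mean
# intensities plus i.i.d. Gaussian noise. Default geometry and contrast
# emulate a moderate-SNR abdominal Dixon slice: each tissue pair is well
# separated on at least two of the four channels and overlaps on the
# rest.
# ---------------------------------------------------------------------

default_organs <- function(height, width) {
  h <- height; w <- width
  list(
    list(label = "liver", center = c(0.34 * h, 0.34 * w),
         axes = c(0.22 * h, 0.20 * w), angle = 15),
    list(label = "kidney", center = c(0.75 * h, 0.28 * w),
         axes = c(0.10 * h, 0.06 * w), angle = -20),
    list(label = "kidney", center = c(0.75 * h, 0.72 * w),
         axes = c(0.10 * h, 0.06 * w), angle = 20)
  )
}

default_channel_means <- function() {
  # rows: tissue; cols: fat, water, ip, op (arbitrary intensity units)
  m <- rbind(liver  = c(60, 150, 160, 120),
             kidney = c(50, 170, 150, 110),
             other  = c(140, 90, 160, 115))
  colnames(m) <- CHANNEL_NAMES
  m
}

#' Specify a synthetic abdominal phantom
#'
#' @param height,width Image size in pixels.
#' @param organs List of organs, each a list with `label` ("liver" or
#'   "kidney"), `center` `(row, col)`, `axes` (semi-axes in pixels) and
#'   `angle` (degrees); defaults place one liver and two kidneys.
#' @param channel_means Tissue x channel matrix of mean intensities
#'   (rows liver/kidney/other, columns fat/water/ip/op).
#' @param noise_sd Per-channel additive Gaussian noise SD (same units as
#'   the means).
#' @param pixel_spacing `(row_mm, col_mm)`.
#' @param seed Integer seed; the phantom is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L, organs = NULL,
                         channel_means = default_channel_means(),
                         noise_sd = 20, pixel_spacing = c(1.5, 1.5),
                         seed = 0L) {
  if (height < 8L || width < 8L) stop("phantom must be at least 8x8")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(organs)) organs <- default_organs(height, width)
  channel_means <- as.matrix(channel_means)
  if (!all(TISSUE_LEVELS %in% rownames(channel_means)) ||
      !all(CHANNEL_NAMES %in% colnames(channel_means))) {
    stop("channel_means needs rows {liver,kidney,other} and columns {fat,water,ip,op}")
  }
  for (o in organs) {
    if (!o$label %in% c("liver", "kidney")) stop("organ label must be liver or kidney")
    r <- max(o$axes)
    if (o$center[1] - r < 0 || o$center[1] + r > height ||
        o$center[2] - r < 0 || o$center[2] + r > width) {
      stop("organ ellipse extends outside the image")
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 organs = organs, channel_means = channel_means,
                 noise_sd = noise_sd, pixel_spacing = pixel_spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# TRUE for pixels inside the rotated ellipse; rows/cols are 0-based
# pixel-center coordinates.
inside_ellipse <- function(rows, cols, center, axes, angle) {
  th <- angle * pi / 180
  dr <- rows - center[1]; dc <- cols - center[2]
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Generate a phantom volume set and its ground-truth mask
#'
#' Rasterizes the organ ellipses onto an "other" background (liver and
#' kidney regions must be disjoint), then draws each channel as tissue
#' mean plus i.i.d. `N(0, noise_sd^2)` noise under the stored seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (an [mr_volume_set()]) and `mask`
#'   (character matrix over the tissue labels).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  rows <- matrix(rep(0:(h - 1L), times = w), h, w)
  cols <- matrix(rep(0:(w - 1L), each = h), h, w)
  mask <- matrix("other", h, w)
  for (o in spec$organs) {
    inside <- inside_ellipse(rows, cols, o$center, o$axes, o$angle)
    clash <- inside & mask != "other" & mask != o$label
    if (any(clash)) stop("overlapping liver/kidney ellipses in phantom spec")
    mask[inside] <- o$label
  }
  channels <- withr::with_seed(spec$seed, {
    lapply(CHANNEL_NAMES, function(ch) {
      base <- matrix(spec$channel_means[mask, ch], h, w)
      base + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    })
  })
  names(channels) <- CHANNEL_NAMES
  vol <- mr_volume_set(channels, spec$pixel_spacing,
                       case_id = sprintf("phantom-%d", spec$seed))
  list(volume = vol, mask = mask)
}

#' Gaussian blob feature tables for solver-level fixtures
#'
#' Isotropic Gaussian clusters with the given centers and common SD.
#'
#' @param n_per_class Samples per class.
#' @param d Feature dimension.
#' @param centers Class x d matrix of cluster centers (>= 2 rows).
#' @param sd Isotropic standard deviation.
#' @param seed Integer seed.
#' @param labels Optional class labels (default `class1`, `class2`, ...).
#' @return A labeled [feature_table()].
#' @export
generate_blobs <- function(n_per_class, d, centers, sd = 1, seed = 1L,
                           labels = NULL) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k < 2L) stop("need at least 2 classes")
  if (ncol(centers) != d) stop("centers must have d columns")
  if (is.null(labels)) labels <- paste0("class", seq_len(k))
  if (length(labels) != k) stop("labels must match the number of centers")
  X <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(n_per_class * d, sd = sd), n_per_class, d) +
        matrix(centers[i, ], n_per_class, d, byrow = TRUE)
    }))
  })
  feature_table(X, labels = rep(labels, each = n_per_class),
                case_id = "blobs")
}

#' Default phantom benchmark with disjoint train/test split
#'
#' Generates one large phantom (the default spec scaled up until its
#' pixel pool can supply the request), extracts the full six-feature
#' table, then samples `n_total` training rows uniformly without
#' replacement and a disjoint test set: 16,896 rows when the remaining
#' pool allows, otherwise 20% of the pool.
#'
#' @param n_total Number of training rows (>= 600).
#' @param seed Integer seed driving phantom noise and the split.
#' @param noise_sd Phantom noise level (default spec value).
#' @return List with `train` and `test` [feature_table()]s.
#' @export
default_benchmark <- function(n_total, seed = 0L, noise_sd = 20) {
  if (n_total < 600L) stop("n_total must be at least 600")
  target_pool <- max(ceiling(n_total * 1.25), n_total + 600L)
  scale <- ceiling(sqrt(target_pool / (128 * 128)))
  spec <- phantom_spec(height = 128L * scale, width = 128L * scale,
                       noise_sd = noise_sd, seed = seed)
  ph <- generate_phantom(spec)
  vol <- ph$volume
  tab <- extract_features(vol, roi(0L, 0L, spec$height, spec$width),
                          mask = ph$mask)
  pool <- nrow(tab$X)
  if (n_total > floor(0.8 * pool)) stop("n_total exceeds 80% of the pixel pool")
  test_n <- if (pool - n_total >= 16896L) 16896L else floor(0.2 * pool)
  idx <- withr::with_seed(seed + 1L, {
    train_idx <- sample.int(pool, n_total)
    rest <- setdiff(seq_len(pool), train_idx)
    test_idx <- sample(rest, test_n)
    list(train = train_idx, test = test_idx)
  })
  list(
    train = feature_table(tab$X[idx$train, , drop = FALSE],
                          labels = tab$labels[idx$train],
                          case_id = vol$case_id, roi = tab$roi),
    test = feature_table(tab$X[idx$test, , drop = FALSE],
                         labels = tab$labels[idx$test],
                         case_id = vol$case_id, roi = tab$roi)
  )
}
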