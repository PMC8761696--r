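#' Segmentation configuration
#'
#' Parameters of the gradient-based ridge/valley pixel classification used
#' to segment brightfield organoids.
#'
#' @param sigma Gaussian pre-blur SD in pixels (default 1.3).
#' @param background_magnitude_threshold gradient-magnitude cutoff below
#'   which a pixel is Background; `"auto"` (default) picks the threshold by
#'   Otsu's method on the magnitude histogram.
#' @param neighbor_step sampling distance (pixels) along the local gradient
#'   direction for the neighbour comparison; samples are bilinearly
#'   interpolated.
#' @param erosion_iterations binary erosions (3x3 cross) applied to the
#'   Rising/Falling bands to better approximate object boundaries.
#' @param boundary_erosion_iterations binary erosions of the filled object
#'   mask, applied after hole filling and before size exclusion; corrects
#'   the outward bias of the blur-widened edge bands (default 1).
#' @param min_area size-exclusion threshold in pixels^2: smaller connected
#'   components are treated as debris and removed (default 500).
#' @param fill_holes fill interiors enclosed by boundary classes (default TRUE).
#' @param gradient_operator `"central"` (default) or `"sobel"`.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(sigma = 1.3,
                       background_magnitude_threshold = "auto",
                       neighbor_step = 1.0,
                       erosion_iterations = 1L,
                       boundary_erosion_iterations = 1L,
                       min_area = 500,
                       fill_holes = TRUE,
                       gradient_operator = c("central", "sobel")) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (min_area < 0) stop("min_area must be >= 0", call. = FALSE)
  structure(list(sigma = sigma,
                 background_magnitude_threshold = background_magnitude_threshold,
                 neighbor_step = neighbor_step,
                 erosion_iterations = as.integer(erosion_iterations),
                 boundary_erosion_iterations = as.integer(boundary_erosion_iterations),
                 min_area = min_area, fill_holes = isTRUE(fill_holes),
                 gradient_operator = match.arg(gradient_operator)),
            class = "seg_config")
}

#' Pixel class labels
#'
#' Integer codes used in class maps: 0 Background, 1 Ridge, 2 Valley,
#' 3 Rising, 4 Falling.
#' @export
PIXEL_CLASSES <- c(Background = 0L, Ridge = 1L, Valley = 2L,
                   Rising = 3L, Falling = 4L)

# reflect (half-sample symmetric) index into 1..n
reflect_index <- function(i, n) {
  i <- ((i - 1) %% (2 * n))
  ifelse(i >= n, 2 * n - 1 - i, i) + 1
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with half-sample symmetric (reflecting)
#' boundary handling.  The kernel is sampled at integer offsets out to
#' `ceiling(4 * sigma)` and normalized to unit sum, so a constant image is
#' unchanged and total intensity is preserved on images with locally
#' symmetric borders.
#'
#' @param image numeric matrix; all values must be finite.
#' @param sigma SD in pixels, > 0.
#' @return smoothed matrix, same dimension.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!all(is.finite(image))) stop("image contains non-finite pixels", call. = FALSE)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {  # convolve along rows (dim 1)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      out <- out + k[j] * m[reflect_index(seq_len(n) + off, n), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(image))))
}

#' Image gradient
#'
#' Per-pixel gradient magnitude and direction.  The direction convention
#' follows image axes: `x` increases with column index, `y` with row index,
#' and the angle is `atan2(dI/dy, dI/dx)` in `(-pi, pi]`.  Pixels with zero
#' magnitude get direction 0.  `"central"` uses central differences with
#' replicated edges; `"sobel"` the 3x3 Sobel operator (same boundary rule).
#'
#' @param image numeric matrix, at least 3x3.
#' @param operator `"central"` or `"sobel"`.
#' @return list with matrices `magnitude` and `direction`.
#' @export
compute_gradient <- function(image, operator = c("central", "sobel")) {
  operator <- match.arg(operator)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop("image must be at least 3x3", call. = FALSE)
  n <- nrow(image); m <- ncol(image)
  up    <- image[c(1, seq_len(n - 1)), , drop = FALSE]
  down  <- image[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  left  <- image[, c(1, seq_len(m - 1)), drop = FALSE]
  right <- image[, c(seq_len(m - 1) + 1, m), drop = FALSE]
  if (operator == "central") {
    gy <- (down - up) / 2
    gx <- (right - left) / 2
  } else {
    shift <- function(M, dr, dc) {
      ri <- pmin(pmax(seq_len(n) + dr, 1), n)
      ci <- pmin(pmax(seq_len(m) + dc, 1), m)
      M[ri, ci, drop = FALSE]
    }
    gx <- (shift(image, -1, 1) + 2 * shift(image, 0, 1) + shift(image, 1, 1) -
           shift(image, -1, -1) - 2 * shift(image, 0, -1) - shift(image, 1, -1)) / 8
    gy <- (shift(image, 1, -1) + 2 * shift(image, 1, 0) + shift(image, 1, 1) -
           shift(image, -1, -1) - 2 * shift(image, -1, 0) - shift(image, -1, 1)) / 8
  }
  mag <- sqrt(gx^2 + gy^2)
  dir <- atan2(gy, gx)
  dir[mag == 0] <- 0
  list(magnitude = mag, direction = dir)
}

#' Otsu threshold
#'
#' Histogram-based threshold maximizing between-class variance; used for the
#' automatic Background cutoff on the gradient-magnitude distribution.
#' Degenerate (constant) inputs return `Inf` so that everything is below
#' threshold.
#'
#' @param x numeric vector or matrix.
#' @param n_bins histogram resolution.
#' @return threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(Inf)
  h <- tabulate(pmin(as.integer((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins),
                n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b2)]
}

# bilinear sample of matrix at fractional (row, col) positions, clamped
bilinear_sample <- function(image, rows, cols) {
  n <- nrow(image); m <- ncol(image)
  rows <- pmin(pmax(rows, 1), n)
  cols <- pmin(pmax(cols, 1), m)
  r0 <- pmin(floor(rows), n - 1); c0 <- pmin(floor(cols), m - 1)
  fr <- rows - r0; fc <- cols - c0
  i00 <- (c0 - 1) * n + r0
  v00 <- image[i00];         v10 <- image[i00 + 1]
  v01 <- image[i00 + n];     v11 <- image[i00 + n + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Classify pixels by local gradient profile
#'
#' A pixel is Background when the gradient magnitude is below the threshold
#' both at the pixel and at its two samples `+/- neighbor_step` along the
#' local direction: ridge crests and valley troughs have near-zero central
#' magnitude but high-magnitude flanks, so the flank test keeps them in the
#' foreground while flat noise stays Background.  For foreground pixels the
#' smoothed intensity is sampled (bilinear) at `+/- neighbor_step` pixels
#' along the local gradient direction; with
#' `b`, `c`, `f` the backward, center and forward samples:
#' `c` above both neighbours is Ridge, below both is Valley, a monotone
#' increase along the direction is Rising and a monotone decrease Falling.
#' A neighbour equal to the center (within 1e-9) defers to the sign of the
#' one strict difference; a fully flat profile is Background.  The five
#' labels partition the image.
#'
#' @param smoothed blurred intensity matrix.
#' @param magnitude,direction from [compute_gradient()] on `smoothed`.
#' @param config a [seg_config()].
#' @return integer matrix of codes per [PIXEL_CLASSES].
#' @export
classify_pixels <- function(smoothed, magnitude, direction, config = seg_config()) {
  stopifnot(all(dim(smoothed) == dim(magnitude)),
            all(dim(smoothed) == dim(direction)))
  eps <- 1e-9
  thr <- config$background_magnitude_threshold
  if (identical(thr, "auto")) thr <- otsu_threshold(magnitude)
  n <- nrow(smoothed); m <- ncol(smoothed)
  rows <- matrix(rep(seq_len(n), m), n, m)
  cols <- matrix(rep(seq_len(m), each = n), n, m)
  dy <- sin(direction) * config$neighbor_step
  dx <- cos(direction) * config$neighbor_step
  f <- bilinear_sample(smoothed, rows + dy, cols + dx)
  b <- bilinear_sample(smoothed, rows - dy, cols - dx)
  df <- f - smoothed   # forward minus center
  db <- smoothed - b   # center minus backward
  out <- matrix(PIXEL_CLASSES[["Background"]], n, m)
  mag_f <- bilinear_sample(magnitude, rows + dy, cols + dx)
  mag_b <- bilinear_sample(magnitude, rows - dy, cols - dx)
  fg <- magnitude >= thr | mag_f >= thr | mag_b >= thr
  ridge  <- fg & df < -eps & db > eps
  valley <- fg & df > eps & db < -eps
  flat <- fg & abs(df) <= eps & abs(db) <= eps
  rest <- fg & !ridge & !valley & !flat
  slope <- df + db  # = f - b
  out[ridge] <- PIXEL_CLASSES[["Ridge"]]
  out[valley] <- PIXEL_CLASSES[["Valley"]]
  out[rest & slope > eps] <- PIXEL_CLASSES[["Rising"]]
  out[rest & slope < -eps] <- PIXEL_CLASSES[["Falling"]]
  # rest with |f - b| <= eps is symmetric but not ridge/valley/flat: Background
  out
}

#' Clean up a class map and extract the organoid mask
#'
#' Applies, in order: (1) removal of Ridge/Valley connected components whose
#' neighbourhood contains only Background (noise that never touches an
#' object edge); (2) binary erosion of the Rising/Falling bands
#' (`erosion_iterations` passes of a 3x3 cross) so edge bands hug object
#' boundaries; (3) hole filling of the combined boundary map, turning closed
#' organoid outlines into filled interiors; (4) size exclusion dropping
#' components below `min_area` (debris).
#'
#' @param classmap integer matrix from [classify_pixels()].
#' @param config a [seg_config()].
#' @return list with `mask` (logical matrix) and `components`
#'   (data.frame: `component_id`, `area_px2`).
#' @export
cleanup_and_fill <- function(classmap, config = seg_config()) {
  ridge_valley <- classmap == PIXEL_CLASSES[["Ridge"]] |
                  classmap == PIXEL_CLASSES[["Valley"]]
  bands <- classmap == PIXEL_CLASSES[["Rising"]] |
           classmap == PIXEL_CLASSES[["Falling"]]
  # rule 1: drop ridge/valley components adjacent only to Background
  lab <- .cc_label(ridge_valley, 8L)
  if (max(lab) > 0) {
    n <- nrow(classmap); m <- ncol(classmap)
    touches <- logical(max(lab))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ri <- pmin(pmax(seq_len(n) + dr, 1), n)
      ci <- pmin(pmax(seq_len(m) + dc, 1), m)
      nb <- bands[ri, ci, drop = FALSE]
      ids <- lab[ridge_valley & nb]
      touches[unique(ids)] <- TRUE
    }
    keep <- matrix(FALSE, n, m)
    keep[ridge_valley] <- touches[lab[ridge_valley]]
    ridge_valley <- keep
  }
  # rule 2: erode rising/falling bands
  if (config$erosion_iterations > 0)
    bands <- .binary_erode(bands, config$erosion_iterations)
  combined <- ridge_valley | bands
  # rule 3: fill enclosed interiors, then trim the blur-widened boundary
  if (config$fill_holes) combined <- .fill_holes(combined)
  if (config$boundary_erosion_iterations > 0)
    combined <- .binary_erode(combined, config$boundary_erosion_iterations)
  # rule 4: size exclusion
  lab <- .cc_label(combined, 8L)
  areas <- if (max(lab) > 0) tabulate(lab[lab > 0], max(lab)) else integer(0)
  small <- which(areas < config$min_area)
  if (length(small)) {
    combined[matrix(lab %in% small, nrow(lab), ncol(lab))] <- FALSE
    lab[matrix(lab %in% small, nrow(lab), ncol(lab))] <- 0L
  }
  keep_ids <- which(areas >= config$min_area)
  comp <- data.frame(component_id = seq_along(keep_ids),
                     area_px2 = areas[keep_ids])
  list(mask = combined, components = comp)
}

#' Segment a time-lapse stack
#'
#' Runs blur, gradient, pixel classification and clean-up on every frame and
#' reports the total organoid-covered area per time point.  Deterministic
#' for a fixed configuration.
#'
#' @param stack an [image_stack()].
#' @param config a [seg_config()].
#' @return list with `masks` (per-frame logical matrices), `components`
#'   (data.frame `frame`, `component_id`, `area_px2`), `total_area`
#'   (numeric, pixels^2 per frame), `classmaps` (per-frame label matrices)
#'   and `times`.
#' @export
segment_stack <- function(stack, config = seg_config()) {
  stopifnot(inherits(stack, "image_stack"))
  masks <- vector("list", length(stack))
  classmaps <- vector("list", length(stack))
  comp_list <- vector("list", length(stack))
  total <- numeric(length(stack))
  for (f in seq_along(stack$frames)) {
    res <- tryCatch({
      sm <- gaussian_smooth(stack$frames[[f]], config$sigma)
      gr <- compute_gradient(sm, config$gradient_operator)
      cm <- classify_pixels(sm, gr$magnitude, gr$direction, config)
      cl <- cleanup_and_fill(cm, config)
      list(cm = cm, cl = cl)
    }, error = function(e) {
      stop(sprintf("frame %d: %s", f, conditionMessage(e)), call. = FALSE)
    })
    classmaps[[f]] <- res$cm
    masks[[f]] <- res$cl$mask
    total[f] <- sum(res$cl$components$area_px2)
    if (nrow(res$cl$components))
      comp_list[[f]] <- cbind(frame = f, res$cl$components)
  }
  comps <- if (length(cc <- Filter(Negate(is.null), comp_list)))
    do.call(rbind, cc)
  else data.frame(frame = integer(0), component_id = integer(0),
                  area_px2 = numeric(0))
  list(masks = masks, components = comps, total_area = total,
       classmaps = classmaps, times = stack$times)
}
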