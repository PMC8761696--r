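#' Specification of a synthetic organoid well
#'
#' Describes a simulated brightfield well: round organoids drawn as a dark
#' rim (annulus) enclosing a bright lumen on a mid-gray background, with
#' programmed per-organoid area growth, small debris particles and additive
#' Gaussian pixel noise.  Defaults emulate a typical 96-well FIS acquisition:
#' 25-30 organoids per well imaged at 10-min intervals over 60 min.
#'
#' @param image_shape integer (H, W) in pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval minutes between frames.
#' @param n_organoids organoid count; default drawn uniformly in 25:30.
#' @param initial_radius length-2 range of initial radii, pixels.
#' @param growth_rate fractional area increase per hour, per organoid
#'   (0.5 means +50\% area after 60 min).
#' @param rim_width rim (annulus) thickness, pixels.
#' @param rim_intensity,lumen_intensity,background_intensity grayscale
#'   values in \[0, 1\]; the rim must be darker than both background and lumen.
#' @param noise_sigma additive Gaussian noise SD (grayscale units).
#' @param n_debris number of small debris disks.
#' @param debris_radius length-2 range of debris radii, pixels; the maximum
#'   must rasterize below the segmentation size-exclusion threshold.
#' @param seed integer seed; all randomness is drawn from R's Mersenne-Twister
#'   generator seeded with this value, and the seed is recorded in the output
#'   metadata.
#' @return An object of class `well_spec`.
#' @export
well_spec <- function(image_shape = c(512L, 512L),
                      n_frames = 7L,
                      frame_interval = 10,
                      n_organoids = NULL,
                      initial_radius = c(14, 22),
                      growth_rate = 0.5,
                      rim_width = 4,
                      rim_intensity = 0.15,
                      lumen_intensity = 0.85,
                      background_intensity = 0.5,
                      noise_sigma = 0.01,
                      n_debris = 5L,
                      debris_radius = c(2, 6),
                      seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape), n_frames = as.integer(n_frames),
               frame_interval = frame_interval, n_organoids = n_organoids,
               initial_radius = initial_radius, growth_rate = growth_rate,
               rim_width = rim_width, rim_intensity = rim_intensity,
               lumen_intensity = lumen_intensity,
               background_intensity = background_intensity,
               noise_sigma = noise_sigma, n_debris = as.integer(n_debris),
               debris_radius = debris_radius, seed = as.integer(seed))
  if (spec$n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  ints <- c(rim_intensity, lumen_intensity, background_intensity)
  if (any(ints < 0) || any(ints > 1))
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (rim_intensity >= background_intensity || rim_intensity >= lumen_intensity)
    stop("rim must be darker than background and lumen", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (pi * max(debris_radius)^2 >= 500)
    stop("debris_radius max must rasterize below the default min_area (500 px^2)",
         call. = FALSE)
  class(spec) <- "well_spec"
  spec
}

# pixel-center disk rasterization; centers are in (row, col) pixel units
rasterize_disk <- function(shape, center, radius) {
  rows <- seq_len(shape[1]); cols <- seq_len(shape[2])
  dr2 <- (rows - center[1])^2
  dc2 <- (cols - center[2])^2
  outer(dr2, dc2, "+") <= radius^2
}

#' Generate a synthetic organoid time-lapse with ground truth
#'
#' Draws each organoid as a dark annulus of width `rim_width` around a
#' bright lumen, grows its area linearly in time at `growth_rate` per hour,
#' scatters sub-threshold debris disks, and adds clipped Gaussian noise.
#' Organoids and debris are placed without overlap by rejection sampling
#' (margin reserved for the final-frame radius); placement failing after
#' bounded retries is an error.
#'
#' The returned ground truth contains per-frame binary masks of the organoid
#' disks (debris excluded), a frames-by-organoid pixel-area table counted on
#' the rasterized masks, and the total-area series normalized to 100 at t=0.
#'
#' @param spec a [well_spec()].
#' @return list with elements `stack` ([image_stack()]) and `truth`
#'   (class `ground_truth`: `masks`, `per_organoid_area`, `true_normalized`,
#'   `debris_masks`, `spec`).
#' @export
generate_organoid_stack <- function(spec) {
  stopifnot(inherits(spec, "well_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  shape <- spec$image_shape
  n_org <- if (is.null(spec$n_organoids)) sample(25:30, 1L) else spec$n_organoids
  r0 <- stats::runif(n_org, spec$initial_radius[1], spec$initial_radius[2])
  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_interval
  # linear area growth: A(t) = A0 * (1 + g * t/60) => r(t) = r0 * sqrt(.)
  growth <- 1 + spec$growth_rate * times / 60
  r_final <- r0 * sqrt(max(growth))

  place <- function(radii, occupied_centers, occupied_radii, margin = 2) {
    centers <- matrix(NA_real_, length(radii), 2)
    for (i in seq_along(radii)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        cand <- c(stats::runif(1, radii[i] + 1, shape[1] - radii[i]),
                  stats::runif(1, radii[i] + 1, shape[2] - radii[i]))
        all_c <- rbind(occupied_centers, centers[seq_len(i - 1L), , drop = FALSE])
        all_r <- c(occupied_radii, radii[seq_len(i - 1L)])
        if (nrow(all_c) == 0L ||
            all(sqrt((all_c[, 1] - cand[1])^2 + (all_c[, 2] - cand[2])^2) >
                all_r + radii[i] + margin)) {
          centers[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place objects without overlap; reduce count or radii",
                    call. = FALSE)
    }
    centers
  }
  centers <- place(r_final, matrix(numeric(0), 0, 2), numeric(0))
  deb_r <- if (spec$n_debris > 0)
    stats::runif(spec$n_debris, spec$debris_radius[1], spec$debris_radius[2])
  else numeric(0)
  deb_centers <- place(deb_r, centers, r_final)

  frames <- vector("list", spec$n_frames)
  masks <- vector("list", spec$n_frames)
  debris_masks <- vector("list", spec$n_frames)
  areas <- matrix(0, spec$n_frames, n_org)
  for (f in seq_len(spec$n_frames)) {
    img <- matrix(spec$background_intensity, shape[1], shape[2])
    mask <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(n_org)) {
      r <- r0[i] * sqrt(growth[f])
      disk <- rasterize_disk(shape, centers[i, ], r)
      lumen <- rasterize_disk(shape, centers[i, ], max(r - spec$rim_width, 0))
      img[disk] <- spec$rim_intensity
      img[lumen] <- spec$lumen_intensity
      mask <- mask | disk
      areas[f, i] <- sum(disk)
    }
    dmask <- matrix(FALSE, shape[1], shape[2])
    for (j in seq_along(deb_r)) {
      dd <- rasterize_disk(shape, deb_centers[j, ], deb_r[j])
      img[dd] <- spec$rim_intensity
      dmask <- dmask | dd
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
    frames[[f]] <- pmin(pmax(img, 0), 1)
    masks[[f]] <- mask
    debris_masks[[f]] <- dmask
  }
  total <- rowSums(areas)
  truth <- structure(list(masks = masks,
                          per_organoid_area = areas,
                          true_normalized = 100 * total / total[1],
                          debris_masks = debris_masks,
                          spec = spec),
                     class = "ground_truth")
  list(stack = image_stack(frames, times), truth = truth)
}

#' Write a synthetic well to disk
#'
#' Writes the stack as multi-frame 16-bit TIFF, the ground-truth masks as a
#' multi-frame TIFF, the per-organoid areas as CSV
#' (`frame, organoid_id, area_px2`) and the full spec (including the seed)
#' as a JSON sidecar.
#'
#' @param well result of [generate_organoid_stack()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_well <- function(well, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tiff_stack(well$stack, file.path(dir, "stack.tif"))
  write_tiff_stack(lapply(well$truth$masks, function(m) m * 1), file.path(dir, "masks.tif"))
  ar <- well$truth$per_organoid_area
  df <- data.frame(frame = rep(seq_len(nrow(ar)), ncol(ar)),
                   organoid_id = rep(seq_len(ncol(ar)), each = nrow(ar)),
                   area_px2 = as.vector(ar))
  write.csv(df, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(well$truth$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
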