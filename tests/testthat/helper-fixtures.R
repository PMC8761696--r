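# Shared fixture builders; everything is generated in code at test time.

# single centered annulus+lumen organoid on background
disk_image <- function(size = 101L, radius = 20, rim_width = 4,
                       background = 0.5, rim = 0.15, lumen = 0.85) {
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  img <- matrix(background, size, size)
  img[d <= radius] <- rim
  img[d <= radius - rim_width] <- lumen
  img
}

disk_truth_mask <- function(size = 101L, radius = 20) {
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  d <= radius
}

# small quick well for end-to-end tests
small_well_spec <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(256L, 256L), n_organoids = 8L,
         initial_radius = c(14, 20)),
    list(...))
  do.call(well_spec, args)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# static trajectory repeating the reference coordinates
static_traj <- function(ref, n_frames = 3L) {
  trajectory(ref, array(rep(ref$xyz, n_frames),
                        c(nrow(ref$xyz), 3, n_frames)))
}

# brute-force minimum cross-pair distance
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# brute-force optimal-superposition RMSD: coarse Euler-angle grid followed
# by Nelder-Mead refinement; independent of the Kabsch path under test.
brute_superpose_rmsd <- function(mobile, reference, grid_step = 15) {
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  A0 <- sweep(mobile, 2, colMeans(mobile))
  B0 <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) sqrt(mean(rowSums((A0 %*% t(rot(ang)) - B0)^2)))
  gr <- seq(0, 2 * pi, by = grid_step * pi / 180)
  gr2 <- seq(-pi / 2, pi / 2, by = grid_step * pi / 180)
  best <- c(0, 0, 0); best_v <- obj(best)
  for (a in gr) for (b in gr2) for (c in gr) {
    v <- obj(c(a, b, c))
    if (v < best_v) { best_v <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
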