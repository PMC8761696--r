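#' Generate a linear reference chain
#'
#' Builds an idealized extended chain with one C-alpha per residue advancing
#' along x with a constant consecutive CA-CA distance (default 3.8 A, the
#' trans CA-CA distance).  The chain zigzags slightly in y so that it is not
#' collinear and can serve as a superposition reference.
#' Residue numbering is 1-based and can be offset to match a biological
#' numbering convention (e.g. `first_resid = 630` for an R-domain segment).
#' With `sidechains = TRUE`, residues alternate LYS / GLU and carry dummy
#' side-chain NZ / OE1 atoms 1.5 A off the backbone, for salt-bridge tests.
#'
#' @param n_residues number of residues (>= 1).
#' @param spacing consecutive CA-CA distance, Angstroms (> 0).
#' @param first_resid residue number of the first residue.
#' @param chain chain identifier.
#' @param sidechains add alternating basic-N / acidic-O dummy atoms.
#' @return a [structure_model()].
#' @export
generate_reference_structure <- function(n_residues, spacing = 3.8,
                                         first_resid = 1L, chain = "A",
                                         sidechains = FALSE) {
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  resids <- seq.int(first_resid, length.out = n_residues)
  # zigzag with |step| = spacing: dy alternates, dx fixed
  dy <- 0.25 * spacing
  dx <- sqrt(spacing^2 - dy^2)
  ys <- c(0, cumsum(rep_len(c(dy, -dy), max(n_residues - 1L, 0))))
  rows <- list()
  xyz <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    resname <- if (sidechains) (if (i %% 2 == 1) "LYS" else "GLU") else "ALA"
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = "CA", resname = resname,
      resid = resids[i], chain = chain, element = "C")
    xyz[[length(xyz) + 1L]] <- c((i - 1) * dx, ys[i], 0)
    if (sidechains) {
      serial <- serial + 1L
      sc_name <- if (i %% 2 == 1) "NZ" else "OE1"
      sc_elem <- if (i %% 2 == 1) "N" else "O"
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = sc_name, resname = resname,
        resid = resids[i], chain = chain, element = sc_elem)
      xyz[[length(xyz) + 1L]] <- c((i - 1) * dx, ys[i] + 1.5, 0)
    }
  }
  structure_model(do.call(rbind, rows), do.call(rbind, xyz))
}

#' Specification of programmed trajectory fluctuations
#'
#' Describes a synthetic trajectory: per-residue isotropic Gaussian noise
#' (one SD per residue, applied to each coordinate of each atom of that
#' residue) on top of an optional rigid-body drift accumulated per frame.
#'
#' @param n_frames number of frames.
#' @param per_residue_sigma numeric vector, one noise SD (Angstroms) per
#'   residue of the reference; all >= 0.
#' @param rigid_translation_per_frame length-3 vector, Angstroms per frame.
#' @param rigid_rotation_per_frame rotation per frame, degrees.
#' @param rotation_axis length-3 axis for the rigid rotation.
#' @param seed integer seed (Mersenne-Twister).
#' @return object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(n_frames,
                             per_residue_sigma,
                             rigid_translation_per_frame = c(0, 0, 0),
                             rigid_rotation_per_frame = 0,
                             rotation_axis = c(0, 0, 1),
                             seed = 1L) {
  if (any(per_residue_sigma < 0)) stop("sigmas must be >= 0", call. = FALSE)
  structure(list(n_frames = as.integer(n_frames),
                 per_residue_sigma = per_residue_sigma,
                 rigid_translation_per_frame = rigid_translation_per_frame,
                 rigid_rotation_per_frame = rigid_rotation_per_frame,
                 rotation_axis = rotation_axis / sqrt(sum(rotation_axis^2)),
                 seed = as.integer(seed)),
            class = "fluctuation_spec")
}

rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic trajectory around a reference
#'
#' Frame `f` (1-based) has coordinates
#' `R^(f-1) x_ref + (f-1) t + noise`, where `R` is the per-frame rigid
#' rotation about the centroid, `t` the per-frame translation, and the noise
#' is iid Gaussian per coordinate with the SD of the atom's residue.  Frame
#' 1 therefore fluctuates about the unmoved reference.  Fully seeded and
#' deterministic.
#'
#' @param reference a [structure_model()].
#' @param spec a [fluctuation_spec()]; `per_residue_sigma` must have one
#'   entry per residue of the reference.
#' @return a [trajectory()].
#' @export
generate_trajectory <- function(reference, spec) {
  stopifnot(inherits(reference, "structure_model"),
            inherits(spec, "fluctuation_spec"))
  resids <- unique(reference$atoms$resid)
  if (length(spec$per_residue_sigma) != length(resids))
    stop(sprintf("per_residue_sigma has length %d but reference has %d residues",
                 length(spec$per_residue_sigma), length(resids)), call. = FALSE)
  set.seed(spec$seed, kind = "Mersenne-Twister")
  sigma_atom <- spec$per_residue_sigma[match(reference$atoms$resid, resids)]
  n_at <- nrow(reference$atoms)
  coords <- array(NA_real_, c(n_at, 3, spec$n_frames))
  centroid <- colMeans(reference$xyz)
  R <- rotation_matrix(spec$rotation_axis, spec$rigid_rotation_per_frame)
  base <- reference$xyz
  for (f in seq_len(spec$n_frames)) {
    if (f > 1) {
      base <- sweep(sweep(base, 2, centroid) %*% t(R), 2, centroid, "+")
      base <- sweep(base, 2, spec$rigid_translation_per_frame, "+")
    }
    noise <- matrix(stats::rnorm(n_at * 3, 0, rep(sigma_atom, 3)), n_at, 3)
    coords[, , f] <- base + noise
  }
  trajectory(reference, coords)
}
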