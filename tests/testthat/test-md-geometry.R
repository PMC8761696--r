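test_that("superposition recovers rigid transforms and matches a brute-force oracle", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  R <- fismd:::rotation_matrix(c(1, -1, 2), 63)
  mob <- ref %*% t(R) + rep(c(4, -7, 2), each = 10)
  expect_lt(superpose(mob, ref)$rmsd, 1e-6)
  # two 4-atom toys with a known optimal rmsd from the rotation-grid oracle
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(rnorm(12, sd = 2), 4, 3)
    b <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(superpose(a, b)$rmsd, brute_superpose_rmsd(a, b),
                 tolerance = 1e-3)
  }
  expect_error(superpose(ref[1:2, ], ref[1:2, ], fit_selection = 1:2), "3 atoms")
  line <- cbind(1:5, 0, 0) * 1.0
  expect_error(superpose(line, line + 1), "collinear|degenerate")
})

test_that("rmsd_series handles static, translated and fitted trajectories", {
  ref <- generate_reference_structure(12)
  tj <- static_traj(ref, 4)
  expect_equal(rmsd_series(tj, ref), rep(0, 4), tolerance = 1e-12)
  # pure translation of (1,2,2): |d| = 3 without fitting, 0 with
  shifted <- tj
  shifted$coords <- tj$coords + rep(c(1, 2, 2), each = 12)
  expect_equal(rmsd_series(shifted, ref, fit = FALSE), rep(3, 4))
  expect_equal(rmsd_series(shifted, ref, fit = TRUE), rep(0, 4),
               tolerance = 1e-9)
  expect_error(rmsd_series(tj, ref, selection = list(names = "XX")), "no atoms")
})

test_that("fitting never increases per-frame RMSD and removes global motion", {
  ref <- generate_reference_structure(20)
  tr <- generate_trajectory(ref, fluctuation_spec(
    25, rep(0.4, 20), rigid_translation_per_frame = c(0.3, 0, 0.1),
    rigid_rotation_per_frame = 2, seed = 31L))
  fit <- rmsd_series(tr, ref, fit = TRUE)
  nofit <- rmsd_series(tr, ref, fit = FALSE)
  expect_true(all(fit <= nofit + 1e-12))
  # with fitting the drift is removed: late-frame RMSD stays near noise level
  expect_lt(max(fit), 3 * 0.4 * sqrt(3))
  expect_gt(nofit[25], fit[25])
})

test_that("geometry is invariant under a global rigid motion of all frames", {
  ref <- generate_reference_structure(15)
  tr <- generate_trajectory(ref, fluctuation_spec(10, rep(0.3, 15), seed = 17L))
  R <- fismd:::rotation_matrix(c(2, 1, 1), 41)
  moved <- tr
  for (f in 1:10)
    moved$coords[, , f] <- tr$coords[, , f] %*% t(R) + rep(c(3, -1, 5), each = 15)
  expect_equal(rmsd_series(moved, ref), rmsd_series(tr, ref), tolerance = 1e-9)
  expect_equal(rmsf(moved, ref)$value, rmsf(tr, ref)$value, tolerance = 1e-9)
})

test_that("residue_rmsd isolates a displaced residue and obeys the rms identity", {
  ref <- generate_reference_structure(10)
  co <- array(rep(ref$xyz, 5), c(10, 3, 5))
  co[4, 3, ] <- co[4, 3, ] + 2
  tj <- trajectory(ref, co)
  prof <- residue_rmsd(tj, ref,
                       fit_selection = list(resid = setdiff(1:10, 4), names = "CA"))
  expect_equal(prof$value[4], 2, tolerance = 0.15)
  expect_true(all(prof$value[-4] < 0.2))
  # static trajectory: all zeros
  expect_equal(residue_rmsd(static_traj(ref), ref)$value, rep(0, 10),
               tolerance = 1e-12)
  # rms over residues of the profile equals the quadratic mean of the
  # global rmsd series under the same fit (algebraic identity)
  tr <- generate_trajectory(ref, fluctuation_spec(20, runif(10, 0.1, 0.6),
                                                  seed = 23L))
  p <- residue_rmsd(tr, ref)
  g <- rmsd_series(tr, ref)
  expect_equal(sqrt(mean(p$value^2)), sqrt(mean(g^2)), tolerance = 1e-9)
  expect_error(residue_rmsd(tr, ref, window = 50:60), "window")
})

test_that("rmsf recovers the programmed sigma*sqrt(3) and separates its two modes", {
  ref <- generate_reference_structure(10)
  expect_equal(rmsf(static_traj(ref), ref)$value, rep(0, 10))
  expect_equal(rmsf(static_traj(ref), ref, mode = "mean")$value, rep(0, 10))
  # constant 1 A offset, fit disabled: reference-mode 1, mean-mode 0
  off <- static_traj(ref, 4)
  off$coords <- off$coords + rep(c(1, 0, 0), each = 10)
  expect_equal(rmsf(off, ref, fit = FALSE)$value, rep(1, 10))
  expect_equal(rmsf(off, ref, fit = FALSE, mode = "mean")$value, rep(0, 10),
               tolerance = 1e-12)
  # parameter recovery at 20k frames: sigma = 0.5 per coordinate
  refb <- generate_reference_structure(10)
  tr <- generate_trajectory(refb, fluctuation_spec(20000, rep(0.5, 10), seed = 2L))
  for (mode in c("reference", "mean")) {
    v <- rmsf(tr, refb, fit = FALSE, mode = mode)$value
    expect_equal(v, rep(0.5 * sqrt(3), 10), tolerance = 0.02)
  }
  expect_error(rmsf(static_traj(ref), ref, mode = "nope"))
})

test_that("min_distance_series equals brute force and validates selections", {
  # two fixed atoms 3.5 A apart
  at <- data.frame(serial = 1:2, name = "CA", resname = "ALA", resid = 1:2,
                   chain = "A", element = "C")
  m <- structure_model(at, rbind(c(0, 0, 0), c(3.5, 0, 0)))
  tj <- static_traj(m, 3)
  ds <- min_distance_series(tj, 1L, 2L)
  expect_equal(ds$distances, rep(3.5, 3))
  expect_equal(ds$mean, 3.5)
  expect_equal(ds$sd, 0)
  # random 20x15 selections over 50 frames match the O(n*m) oracle exactly
  ref <- generate_reference_structure(35)
  tr <- generate_trajectory(ref, fluctuation_spec(50, rep(1.0, 35), seed = 77L))
  ia <- 1:20; ib <- 21:35
  ds2 <- min_distance_series(tr, ia, ib)
  for (f in c(1, 17, 50))
    expect_equal(ds2$distances[f],
                 brute_min_dist(tr$coords[ia, , f], tr$coords[ib, , f]),
                 tolerance = 1e-12)
  # trailing summary window
  ds3 <- min_distance_series(tr, ia, ib, summary_window = 10)
  expect_equal(ds3$mean, mean(ds2$distances[41:50]))
  expect_error(min_distance_series(tr, 1:5, 5:10), "disjoint")
})

test_that("salt-bridge contact fraction uses a strict 4 A cutoff", {
  ref <- generate_reference_structure(2, sidechains = TRUE)
  mk <- function(dists) {
    co <- array(rep(ref$xyz, length(dists)), c(4, 3, length(dists)))
    for (f in seq_along(dists)) {
      co[4, , f] <- co[2, , f] + c(dists[f], 0, 0)
    }
    trajectory(ref, co)
  }
  # alternating 3.5 / 4.5 A -> fraction 0.5
  expect_equal(saltbridge_contact_fraction(mk(rep(c(3.5, 4.5), 5)), 1, 2)$fraction, 0.5)
  # exactly 4.0 A never counts (strict inequality)
  expect_equal(saltbridge_contact_fraction(mk(rep(4.0, 6)), 1, 2)$fraction, 0)
  expect_equal(saltbridge_contact_fraction(mk(rep(3.0, 6)), 1, 2)$fraction, 1)
  # missing side-chain atoms is a selection error
  bare <- generate_reference_structure(2)
  expect_error(saltbridge_contact_fraction(static_traj(bare), 1, 2), "side-chain")
})

test_that("min C-alpha distance between a residue and a span", {
  ref <- generate_reference_structure(12, spacing = 5, first_resid = 30L)
  # span containing the residue itself -> 0
  expect_equal(min_calpha_distance(ref, 33, c(30, 41)), 0)
  # nearest CA of a distant span: zigzag chain, consecutive spacing 5
  d <- min_calpha_distance(ref, 30, c(31, 41))
  expect_equal(d, 5)
  expect_error(min_calpha_distance(ref, 99, c(30, 41)), "no atoms")
})

test_that("selection mini-language resolves chains, ranges and atom names", {
  m <- generate_reference_structure(20, first_resid = 630L, sidechains = TRUE)
  idx <- select_atoms(m, "chain A and resid 630-639 and name CA")
  expect_length(idx, 10)
  expect_true(all(m$atoms$name[idx] == "CA"))
  expect_length(select_atoms(m, resid = "630-631,  633", names = "CA"), 3)
  expect_error(select_atoms(m, "chain B"), "no atoms")
  expect_error(select_atoms(m, "protein all"), "keyword")
})
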