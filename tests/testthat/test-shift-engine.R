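make_line_residue <- function() {
  # N, CA, C, O along x at 0,1,2,3 angstrom — COM x hand-computable
  topo <- backbone_topology(
    data.frame(serial = 1L, label = "GLY1", chain = "A", orig_resno = 1L),
    data.frame(serial = 1L, name = c("N", "CA", "C", "O"), index = 1:4,
               mass = c(14.007, 12.011, 12.011, 15.999)))
  coords <- array(0, dim = c(2, 4, 3))
  coords[, , 1] <- matrix(rep(0:3, each = 2), 2, 4)
  list(topology = topo, ensemble = traj_ensemble(coords))
}

test_that("backbone COM is the mass-weighted mean of the backbone atoms", {
  lr <- make_line_residue()
  expected_x <- (0 * 14.007 + 1 * 12.011 + 2 * 12.011 + 3 * 15.999) /
    (14.007 + 12.011 + 12.011 + 15.999)
  com <- residue_backbone_com(lr$topology, lr$ensemble, 1, 1)
  expect_equal(com, c(expected_x, 0, 0), tolerance = 1e-12)
  expect_equal(com, oracle_com(lr$topology, lr$ensemble, 1, 1),
               tolerance = 1e-12)

  # coincident atoms collapse to the shared point
  co <- lr$ensemble$coords
  co[, , ] <- rep(c(1, 2, 3), each = 8)
  ens <- traj_ensemble(co)
  expect_equal(residue_backbone_com(lr$topology, ens, 1, 2), c(1, 2, 3))
})

test_that("a single-atom residue's COM is that atom's position", {
  topo <- backbone_topology(
    data.frame(serial = 1L, label = "GLY1", chain = "A", orig_resno = 1L),
    data.frame(serial = 1L, name = "CA", index = 1L, mass = 12.011))
  coords <- array(c(4, 4, -1, -1, 7, 7), dim = c(2, 1, 3))
  ens <- traj_ensemble(coords)
  expect_equal(residue_backbone_com(topo, ens, 1, 1), c(4, -1, 7))
})

test_that("ca_only uses the CA position as the shift point", {
  lr <- make_line_residue()
  expect_equal(residue_backbone_com(lr$topology, lr$ensemble, 1, 1,
                                    point = "ca_only"), c(1, 0, 0))
  re <- random_ensemble(4, 6, seed = 11)
  has_ca <- all(seq_len(4) %in%
                  re$topology$atoms$serial[re$topology$atoms$name == "CA"])
  if (has_ca) {
    m <- compute_shift_matrix(re$topology, re$ensemble, point = "ca_only")
    expect_equal(m$values,
                 oracle_shift_matrix(re$topology, re$ensemble, point = "ca_only"),
                 tolerance = 1e-9)
  }
})

test_that("a static trajectory yields an all-zero map in both modes", {
  coords <- array(rep(stats::runif(8 * 3), each = 4), dim = c(4, 8, 3))
  topo <- random_ensemble(2, 2, seed = 3)$topology
  topo$atoms$index <- seq_len(nrow(topo$atoms))
  ens <- traj_ensemble(array(rep(coords[1, seq_len(nrow(topo$atoms)), ],
                                 each = 4), c(4, nrow(topo$atoms), 3)))
  for (ref in c("fixed", "previous"))
    expect_equal(compute_shift_matrix(topo, ens, reference = ref)$values,
                 matrix(0, 2, 4))
})

test_that("a rigid (3,4,0) translation from frame 2 onward shifts every residue by 5", {
  re <- random_ensemble(5, 2, seed = 7)
  co <- array(NA_real_, dim = c(6, dim(re$ensemble$coords)[2], 3))
  for (f in 1:6) co[f, , ] <- re$ensemble$coords[1, , ]
  co[2:6, , 1] <- co[2:6, , 1] + 3
  co[2:6, , 2] <- co[2:6, , 2] + 4
  m <- compute_shift_matrix(re$topology, traj_ensemble(co))
  expect_equal(m$values[, 1], rep(0, 5))
  expect_equal(m$values[, 2:6], matrix(5, 5, 5), tolerance = 1e-12)
  # previous-step map sees the jump only once
  mp <- compute_shift_matrix(re$topology, traj_ensemble(co), reference = "previous")
  expect_equal(mp$values[, 2], rep(5, 5), tolerance = 1e-12)
  expect_equal(mp$values[, c(1, 3:6)], matrix(0, 5, 5))
})

test_that("shift matrices agree with the brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    re <- random_ensemble(sample(2:10, 1), sample(3:20, 1), seed = seed)
    for (ref in c("fixed", "previous")) {
      m <- compute_shift_matrix(re$topology, re$ensemble, reference = ref)
      expect_lt(max(abs(m$values -
                          oracle_shift_matrix(re$topology, re$ensemble, ref))),
                1e-9)
    }
    # non-default fixed reference frame
    rf <- sample(re$ensemble$n_frames, 1)
    m <- compute_shift_matrix(re$topology, re$ensemble, ref_frame = rf)
    expect_lt(max(abs(m$values -
                        oracle_shift_matrix(re$topology, re$ensemble, "fixed", rf))),
              1e-9)
    expect_equal(m$values[, rf], rep(0, nrow(m$values)))
  }
})

test_that("shifts are non-negative and the fixed reference column is zero", {
  for (seed in 4:8) {
    re <- random_ensemble(4, 8, seed = seed)
    m <- compute_shift_matrix(re$topology, re$ensemble)
    expect_true(all(m$values >= 0))
    expect_equal(m$values[, 1], rep(0, 4))
    expect_identical(m$kind, "shift")
    expect_identical(unname(m$meta["reference_mode"]), "fixed_frame")
  }
})

test_that("reordering atoms within a residue leaves shifts unchanged", {
  re <- random_ensemble(4, 6, seed = 21)
  m1 <- compute_shift_matrix(re$topology, re$ensemble)
  topo2 <- re$topology
  perm <- order(stats::runif(nrow(topo2$atoms)))
  topo2$atoms <- topo2$atoms[perm, ]
  m2 <- compute_shift_matrix(topo2, re$ensemble)
  expect_equal(m2$values, m1$values, tolerance = 1e-12)
})

test_that("translating one frame of a previously static ensemble shows |v| exactly", {
  fx <- generate_fixture(fixture_config(n_residues = 3, n_frames = 5,
                                        base_jitter_sigma = 0, seed = 1))
  co <- fx$ensemble$coords
  v <- c(1, -2, 2)  # |v| = 3
  co[4, , ] <- sweep(co[4, , ], 2, v, `+`)
  m <- compute_shift_matrix(fx$topology, traj_ensemble(co))
  expect_equal(m$values[, 4], rep(3, 3), tolerance = 1e-12)
  expect_equal(m$values[, -4], matrix(0, 3, 4))
})

test_that("RMSD series is zero at its reference and matches the oracle", {
  fx <- generate_fixture(fixture_config(n_residues = 4, n_frames = 8,
                                        base_jitter_sigma = 0.4, seed = 5))
  r <- rmsd_series(fx$topology, fx$ensemble, reference_index = 3)
  expect_equal(r$values[3], 0)
  expect_true(all(r$values >= 0))
  expect_equal(r$values, oracle_rmsd(fx$topology, fx$ensemble, 3),
               tolerance = 1e-9)

  # rigid translation by (0,0,2) at one frame -> RMSD exactly 2
  co <- generate_fixture(fixture_config(n_residues = 3, n_frames = 4,
                                        base_jitter_sigma = 0, seed = 1))
  co$ensemble$coords[2, , 3] <- co$ensemble$coords[2, , 3] + 2
  r2 <- rmsd_series(co$topology, traj_ensemble(co$ensemble$coords))
  expect_equal(r2$values, c(0, 2, 0, 0), tolerance = 1e-12)
})

test_that("out-of-range and empty selections raise the stated errors", {
  lr <- make_line_residue()
  expect_error(residue_backbone_com(lr$topology, lr$ensemble, 2, 1), "out of range")
  expect_error(residue_backbone_com(lr$topology, lr$ensemble, 1, 9), "out of range")
  expect_error(compute_shift_matrix(lr$topology, lr$ensemble, ref_frame = 0),
               "out of range")
  topo_no_ca <- backbone_topology(
    data.frame(serial = 1L, label = "GLY1", chain = "A", orig_resno = 1L),
    data.frame(serial = 1L, name = "N", index = 1L, mass = 14.007))
  ens <- traj_ensemble(array(0, c(2, 1, 3)))
  expect_error(rmsd_series(topo_no_ca, ens), "no CA")
  expect_error(compute_shift_matrix(topo_no_ca, ens, point = "ca_only"), "CA")
})
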