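# Independent scalar-arithmetic oracles. These deliberately use explicit
# loops and no shared code with the package internals, so they can serve
# as brute-force references for the vectorized implementations.

oracle_com <- function(topology, ensemble, residue, frame,
                       point = "backbone_com") {
  atoms <- topology$atoms
  out <- c(0, 0, 0)
  msum <- 0
  for (i in seq_len(nrow(atoms))) {
    if (atoms$serial[i] != residue) next
    if (point == "ca_only" && atoms$name[i] != "CA") next
    for (k in 1:3)
      out[k] <- out[k] + atoms$mass[i] * ensemble$coords[frame, atoms$index[i], k]
    msum <- msum + atoms$mass[i]
  }
  out / msum
}

oracle_shift_matrix <- function(topology, ensemble, reference = "fixed",
                                ref_frame = 1L, point = "backbone_com") {
  R <- nrow(topology$residues)
  F_ <- ensemble$n_frames
  vals <- matrix(0, R, F_)
  for (r in seq_len(R)) {
    for (f in seq_len(F_)) {
      if (reference == "fixed") {
        a <- oracle_com(topology, ensemble, r, f, point)
        b <- oracle_com(topology, ensemble, r, ref_frame, point)
      } else {
        if (f == 1L) next
        a <- oracle_com(topology, ensemble, r, f, point)
        b <- oracle_com(topology, ensemble, r, f - 1L, point)
      }
      s <- 0
      for (k in 1:3) s <- s + (a[k] - b[k])^2
      vals[r, f] <- sqrt(s)
    }
  }
  vals
}

oracle_rmsd <- function(topology, ensemble, ref = 1L) {
  ca <- topology$atoms$index[topology$atoms$name == "CA"]
  F_ <- ensemble$n_frames
  out <- numeric(F_)
  for (f in seq_len(F_)) {
    acc <- 0
    for (a in ca)
      for (k in 1:3)
        acc <- acc + (ensemble$coords[f, a, k] - ensemble$coords[ref, a, k])^2
    out[f] <- sqrt(acc / length(ca))
  }
  out
}

# random topology + ensemble with variable backbone composition per residue
random_ensemble <- function(n_res, n_frames, seed) {
  set.seed(seed)
  names_pool <- c("N", "CA", "C", "O")
  atoms <- NULL
  idx <- 0L
  for (r in seq_len(n_res)) {
    nm <- sort(sample(4L, sample(4L, 1)))
    atoms <- rbind(atoms,
                   data.frame(serial = r, name = names_pool[nm],
                              index = idx + seq_along(nm),
                              mass = c(N = 14.007, CA = 12.011, C = 12.011,
                                       O = 15.999)[names_pool[nm]]))
    idx <- idx + length(nm)
  }
  rownames(atoms) <- NULL
  topo <- backbone_topology(
    data.frame(serial = seq_len(n_res),
               label = paste0("GLY", seq_len(n_res)),
               chain = "A", orig_resno = seq_len(n_res),
               stringsAsFactors = FALSE),
    atoms)
  coords <- array(stats::rnorm(n_frames * idx * 3, sd = 5),
                  dim = c(n_frames, idx, 3))
  list(topology = topo, ensemble = traj_ensemble(coords))
}

random_shift_matrix <- function(n_res, n_frames, seed, kind = "shift") {
  set.seed(seed)
  v <- matrix(stats::runif(n_res * n_frames, 0, 8), n_res, n_frames)
  if (kind == "difference") v <- v - 4
  shift_matrix(v, kind = kind)
}

# noise-free toy trajectory with a held step on a region
toy_step_fixture <- function(n_res = 6, n_frames = 12, region = "2-4",
                             onset = 7, disp = c(3, 4, 0), sigma = 0,
                             seed = 1) {
  generate_fixture(fixture_config(
    n_residues = n_res, n_frames = n_frames, base_jitter_sigma = sigma,
    events = list(event_step(region, onset, disp)), seed = seed))
}
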