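tmpl <- default_atom_template()
ref_xyz <- template_xyz(tmpl)

test_that("Kabsch superposition removes rigid motion exactly", {
  k <- kabsch_superpose(ref_xyz, ref_xyz)
  expect_equal(k$rmsd, 0, tolerance = 1e-12)
  expect_equal(k$rotation, diag(3), tolerance = 1e-8)

  R <- rotation_matrix(c(0, 0, 1), pi / 2)
  moved <- sweep(ref_xyz %*% t(R), 2, c(4, -2, 7), "+")
  k2 <- kabsch_superpose(moved, ref_xyz)
  expect_lt(k2$rmsd, 1e-8)
  expect_equal(k2$transform(moved), ref_xyz, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("fitted RMSD agrees with a brute-force rotation-space search", {
  A <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  B <- A
  B[4, ] <- B[4, ] + c(0.7, -0.4, 0.5)  # one displaced atom
  k <- kabsch_superpose(A, B)
  expect_equal(k$rmsd, oracle_fitted_rmsd(A, B), tolerance = 1e-4)
})

test_that("degenerate fit selections are refused", {
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(ref_xyz, ref_xyz, fit = 1:2), "at least 3")
})

test_that("RMSD series is zero for the reference frame and rigid-only motion", {
  g <- gen_trajectory(traj_sim_spec(n_frames = 8, atom_template = tmpl,
                                    fluct_sd = 0.3, seed = 3))
  rs <- rmsd_series(g$trajectory)  # reference defaults to frame 1
  expect_equal(rs[1], 0, tolerance = 1e-10)

  g2 <- gen_trajectory(traj_sim_spec(
    n_frames = 10, atom_template = tmpl, fluct_sd = 0,
    translation = matrix(rep(seq(0, 9), 3), ncol = 3),
    rot_angles = seq(0, pi / 3, length.out = 10), seed = 1))
  rs2 <- rmsd_series(g2$trajectory, reference = ref_xyz)
  expect_equal(rs2, rep(0, 10), tolerance = 1e-8)
})

test_that("RMSD series cross-checks against the bio3d superposition oracle", {
  g <- gen_trajectory(traj_sim_spec(n_frames = 6, atom_template = tmpl,
                                    fluct_sd = 0.4, seed = 5))
  tr <- g$trajectory
  sel <- select_atoms(tr, "protein and backbone")
  rs <- rmsd_series(tr, reference = ref_xyz,
                    fit_selection = "protein and backbone")
  xyz_ind <- as.numeric(vapply(sel, function(i) (3 * i - 2):(3 * i),
                               numeric(3)))
  ref_flat <- as.numeric(t(ref_xyz))
  oracle <- vapply(seq_len(6), function(t) {
    mob <- as.numeric(t(frame_coords(tr, t)))
    fitted <- bio3d::fit.xyz(ref_flat, mob, fixed.inds = xyz_ind,
                             mobile.inds = xyz_ind)
    bio3d::rmsd(ref_flat[xyz_ind], fitted[xyz_ind])
  }, numeric(1))
  # bio3d::rmsd rounds to 3 decimals; compare at that precision
  expect_equal(rs, oracle, tolerance = 2e-3)
})

test_that("measuring over a different selection than the fit works", {
  g <- gen_trajectory(traj_sim_spec(n_frames = 5, atom_template = tmpl,
                                    fluct_sd = 0.2, seed = 7))
  lig <- rmsd_series(g$trajectory, reference = ref_xyz,
                     fit_selection = "protein and backbone",
                     measure_selection = "ligand")
  expect_length(lig, 5)
  expect_true(all(lig >= 0))
})

test_that("radius of gyration matches analytic and hand-computed values", {
  # two unit masses 2 Angstrom apart: Rg = 1 exactly
  at2 <- data.frame(residue_index = 1:2, residue_name = "X",
                    atom_name = c("A1", "A2"), element = "C",
                    backbone = FALSE, mass = 1, chain = "protein",
                    x = c(0, 2), y = 0, z = 0)
  tr2 <- trajectory(array(template_xyz(at2), dim = c(1, 2, 3)), at2[, 1:7])
  expect_equal(radius_of_gyration(tr2, mass_weighted = FALSE), 1)
  expect_equal(radius_of_gyration(tr2, mass_weighted = TRUE), 1)

  # translation invariance
  g <- gen_trajectory(traj_sim_spec(
    n_frames = 6, atom_template = tmpl, fluct_sd = 0,
    translation = matrix(rnorm(18), 6, 3), seed = 2))
  rg <- radius_of_gyration(g$trajectory)
  expect_equal(rg, rep(rg[1], 6), tolerance = 1e-10)

  # 5-atom hand computation, mass-weighted
  at5 <- data.frame(residue_index = 1, residue_name = "X",
                    atom_name = paste0("A", 1:5), element = "C",
                    backbone = FALSE, mass = c(12, 16, 1, 14, 32),
                    chain = "protein",
                    x = c(0, 1, 2, -1, 0.5), y = c(0, 1, 0, 2, -1),
                    z = c(1, 0, -1, 0, 2))
  xyz <- template_xyz(at5)
  tr5 <- trajectory(array(xyz, dim = c(1, 5, 3)), at5[, 1:7])
  w <- at5$mass
  ctr <- colSums(xyz * w) / sum(w)
  hand <- sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
  expect_equal(radius_of_gyration(tr5), hand, tolerance = 1e-10)
})

test_that("RMSF recovers the isotropic fluctuation magnitude", {
  g <- gen_trajectory(traj_sim_spec(n_frames = 2000, atom_template = tmpl,
                                    fluct_sd = 0.5, seed = 4))
  # no rigid motion present, so measure without superposition
  out <- rmsf(g$trajectory, selection = "all", fit = FALSE)
  expect_true(all(abs(out$atom$rmsf - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.05))
  # static trajectory: all zeros
  g0 <- gen_trajectory(traj_sim_spec(n_frames = 5, atom_template = tmpl,
                                     fluct_sd = 0, seed = 1))
  out0 <- rmsf(g0$trajectory, selection = "all", fit = FALSE)
  expect_equal(out0$atom$rmsf, rep(0, nrow(out0$atom)))
  expect_error(rmsf(trajectory(array(0, c(1, 3, 3)),
                               g0$trajectory$atoms[1:3, ])), "2 frames")
})

test_that("superposition makes RMSF insensitive to global rotation", {
  base <- gen_trajectory(traj_sim_spec(n_frames = 800, atom_template = tmpl,
                                       fluct_sd = 0.3, seed = 6))
  rot <- gen_trajectory(traj_sim_spec(
    n_frames = 800, atom_template = tmpl, fluct_sd = 0.3,
    rot_angles = seq(0, 2 * pi, length.out = 800), seed = 6))
  a <- rmsf(base$trajectory, selection = "all", fit = TRUE)$atom$rmsf
  b <- rmsf(rot$trajectory, selection = "all", fit = TRUE)$atom$rmsf
  expect_true(all(abs(a - b) / a < 0.02))
})

test_that("per-residue RMSF aggregates over each residue's atoms", {
  g <- gen_trajectory(traj_sim_spec(n_frames = 50, atom_template = tmpl,
                                    fluct_sd = 0.3, seed = 8))
  out <- rmsf(g$trajectory, selection = "protein and backbone", fit = FALSE)
  agg <- tapply(out$atom$rmsf, out$atom$residue_index, mean)
  expect_equal(out$residue$rmsf,
               as.numeric(agg[as.character(out$residue$residue_index)]),
               tolerance = 1e-12)
})

test_that("hydrogen-bond detection honours schedule, cutoffs and boundaries", {
  g <- gen_trajectory(traj_sim_spec(
    n_frames = 100, atom_template = tmpl, fluct_sd = 0.1,
    hbond_schedule = list(
      list(donor = "LN1", hydrogen = "LH1", acceptor = "LO1", fraction = 0.6),
      list(donor = "N1", hydrogen = "HN1", acceptor = "O2", fraction = 0.15)),
    seed = 9))
  hb <- hbond_stats(g$trajectory,
                    data.frame(donor = c("LN1", "N1"),
                               hydrogen = c("LH1", "HN1"),
                               acceptor = c("LO1", "O2")))
  expect_equal(hb$all$occupancy, c(60, 15))
  # 20% occupancy cutoff keeps only the scheduled 60% bond in the headline
  expect_equal(nrow(hb$table), 1)
  expect_equal(hb$table$donor, "LN1")
  expect_equal(hb$table$avg_distance, 2.7, tolerance = 1e-9)
  # per-frame counts equal the sum of per-bond indicators
  expect_equal(sum(hb$per_frame_counts), 60 + 15)
  expect_true(all(hb$all$occupancy >= 0 & hb$all$occupancy <= 100))
})

test_that("geometry exactly at the cutoffs counts as satisfied", {
  # donor at origin, H on x; acceptor placed at exactly 3.0 A and 135 deg
  ang <- 135 * pi / 180
  # D-H...A angle has its vertex at H: position A so that the angle between
  # H->D and H->A is exactly 135 degrees
  H <- c(1, 0, 0)
  hd <- c(-1, 0, 0)                       # H -> D
  # direction making exactly 135 degrees with H -> D
  ha <- c(cos(pi - ang), sin(pi - ang), 0)
  # scale |HA| so that |DA| is exactly 3.0
  f <- function(s) sqrt(sum((H + s * ha)^2)) - 3.0
  s <- uniroot(f, c(0.1, 10), tol = 1e-14)$root
  A <- H + s * ha
  at3 <- data.frame(residue_index = 1, residue_name = "X",
                    atom_name = c("D", "H", "A"),
                    element = c("N", "H", "O"), backbone = FALSE,
                    mass = c(14, 1, 16), chain = "protein",
                    x = c(0, H[1], A[1]), y = c(0, H[2], A[2]),
                    z = c(0, H[3], A[3]))
  coords <- array(NA_real_, c(2, 3, 3))
  coords[1, , ] <- template_xyz(at3)
  coords[2, , ] <- template_xyz(at3)
  tr <- trajectory(coords, at3[, 1:7])
  hb <- hbond_stats(tr, data.frame(donor = "D", hydrogen = "H",
                                   acceptor = "A"))
  expect_equal(hb$all$occupancy, 100)    # inclusive at both cutoffs
  # independent geometric recomputation
  expect_equal(sqrt(sum(A^2)), 3.0, tolerance = 1e-12)
  cosang <- sum(hd * (A - H)) / sqrt(sum((A - H)^2))
  expect_equal(acos(cosang) * 180 / pi, 135, tolerance = 1e-9)
})

test_that("a missing hydrogen skips the candidate with a warning", {
  g <- gen_trajectory(traj_sim_spec(n_frames = 5, atom_template = tmpl,
                                    fluct_sd = 0.1, seed = 2))
  expect_warning(
    hb <- hbond_stats(g$trajectory,
                      data.frame(donor = "LN1", hydrogen = "NOPE",
                                 acceptor = "LO1")),
    "skipped")
  expect_equal(nrow(hb$all), 0)
})

test_that("PCA conserves variance and recovers a planted collective mode", {
  set.seed(10)
  n_at <- nrow(tmpl)
  nf <- 400
  dirs <- matrix(rnorm(n_at * 3), n_at, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coeff <- sin(seq(0, 8 * pi, length.out = nf)) * 1.5
  coords <- array(NA_real_, c(nf, n_at, 3))
  for (t in seq_len(nf)) {
    coords[t, , ] <- ref_xyz + coeff[t] * dirs +
      matrix(rnorm(n_at * 3, 0, 0.05), n_at, 3)
  }
  tr <- trajectory(coords, tmpl[, setdiff(names(tmpl), c("x", "y", "z"))])
  p <- trajectory_pca(tr, selection = "all", fit = FALSE)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-8)
  expect_gte(p$variance_fraction[1], 0.9)
  expect_gte(abs(cor(p$projections[, 1], coeff)), 0.95)
  # projections centred, eigenvectors orthonormal
  expect_lt(max(abs(colMeans(p$projections))), 1e-10)
  expect_equal(crossprod(p$eigenvectors), diag(ncol(p$eigenvectors)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a static trajectory has all-zero eigenvalues", {
  coords <- array(rep(ref_xyz, each = 4), c(4, nrow(tmpl), 3))
  tr <- trajectory(coords, tmpl[, setdiff(names(tmpl), c("x", "y", "z"))])
  expect_warning(p <- trajectory_pca(tr, selection = "all", fit = FALSE),
                 "rank")
  expect_equal(max(p$eigenvalues), 0, tolerance = 1e-12)
})

test_that("the free-energy landscape follows Boltzmann inversion exactly", {
  # all frames in one bin
  f1 <- free_energy_landscape(rep(0.5, 20), rep(0.5, 20), bins = 4)
  expect_equal(min(f1$G[f1$occupied]), 0)
  expect_equal(sum(f1$occupied), 1)
  expect_true(all(f1$G[!f1$occupied] > max(f1$G[f1$occupied])))

  # uniform occupancy: all occupied bins at zero
  xs <- rep(seq(0.125, 0.875, 0.25), each = 4)
  ys <- rep(seq(0.125, 0.875, 0.25), times = 4)
  f2 <- free_energy_landscape(xs, ys, bins = 4)
  expect_equal(max(abs(f2$G[f2$occupied])), 0)

  # pairwise identity G1 - G2 = -kT ln(n1/n2)
  set.seed(13)
  pc1 <- rnorm(3000); pc2 <- rnorm(3000)
  f3 <- free_energy_landscape(pc1, pc2, bins = 8)
  counts <- matrix(0L, 8, 8)
  ix <- pmin(findInterval(pc1, f3$x_edges, rightmost.closed = TRUE), 8)
  iy <- pmin(findInterval(pc2, f3$y_edges, rightmost.closed = TRUE), 8)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  kT <- 0.0019872041 * 300
  occ <- which(counts > 0)
  g_pair <- -kT * log(counts[occ] / max(counts))
  expect_equal(f3$G[occ], g_pair, tolerance = 1e-12)
})

test_that("two bins at count ratio e differ by kT", {
  n2 <- 368  # closest integer to 1000 / e
  pc1 <- c(rep(0.1, 1000), rep(0.9, n2))
  f <- free_energy_landscape(pc1, rep(0.5, length(pc1)), bins = 2)
  dG <- max(f$G[f$occupied]) - min(f$G[f$occupied])
  kT <- 0.0019872041 * 300
  expect_equal(dG, kT * log(1000 / n2), tolerance = 1e-12)
  expect_equal(dG, 0.596, tolerance = 2e-3)
})

test_that("binding-site selection applies an inclusive heavy-atom cutoff", {
  # three protein residues at 4.9 / 5.0 / 5.1 A from a one-atom ligand
  mk <- function(d, i) data.frame(residue_index = i, residue_name = "ALA",
                                  atom_name = paste0("CA", i), element = "C",
                                  backbone = TRUE, mass = 12,
                                  chain = "protein", x = d, y = 0, z = 0)
  at <- rbind(mk(4.9, 1), mk(5.0, 2), mk(5.1, 3),
              data.frame(residue_index = 4, residue_name = "LIG",
                         atom_name = "L1", element = "C", backbone = FALSE,
                         mass = 12, chain = "ligand", x = 0, y = 0, z = 0))
  tr <- trajectory(array(template_xyz(at), c(1, 4, 3)), at[, 1:7])
  sel <- binding_site_selection(tr, cutoff = 5.0)
  expect_equal(sort(unique(tr$atoms$residue_index[sel])), c(1, 2))

  # ligand beyond the cutoff from everything: empty with a warning
  at$x[4] <- 100
  tr2 <- trajectory(array(template_xyz(at), c(1, 4, 3)), at[, 1:7])
  expect_warning(sel2 <- binding_site_selection(tr2, cutoff = 5.0),
                 "empty")
  expect_length(sel2, 0)
})

test_that("stability metrics are invariant under a global rigid transform", {
  g <- gen_trajectory(traj_sim_spec(n_frames = 30, atom_template = tmpl,
                                    fluct_sd = 0.3, seed = 11))
  tr <- g$trajectory
  R <- rotation_matrix(c(1, 1, 0), 0.8)
  shift <- c(10, -5, 3)
  coords2 <- tr$coords
  for (t in seq_len(n_frames(tr))) {
    coords2[t, , ] <- sweep(frame_coords(tr, t) %*% t(R), 2, shift, "+")
  }
  tr2 <- trajectory(coords2, tr$atoms)
  ref2 <- sweep(ref_xyz %*% t(R), 2, shift, "+")
  expect_equal(rmsd_series(tr, reference = ref_xyz),
               rmsd_series(tr2, reference = ref2), tolerance = 1e-8)
  expect_equal(radius_of_gyration(tr), radius_of_gyration(tr2),
               tolerance = 1e-10)
  expect_equal(rmsf(tr, "all")$atom$rmsf, rmsf(tr2, "all")$atom$rmsf,
               tolerance = 1e-6)
})

test_that("the selection grammar intersects clauses correctly", {
  sel <- select_atoms(tmpl, "protein and backbone")
  expect_true(all(tmpl$chain[sel] == "protein" & tmpl$backbone[sel]))
  expect_equal(select_atoms(tmpl, "ligand and heavy"),
               which(tmpl$chain == "ligand" & tmpl$element != "H"))
  expect_equal(select_atoms(tmpl, "resid 2"),
               which(tmpl$residue_index == 2))
  expect_equal(select_atoms(tmpl, "resid 1-2"),
               which(tmpl$residue_index <= 2))
  expect_equal(select_atoms(tmpl, "name CA1 CA2"),
               which(tmpl$atom_name %in% c("CA1", "CA2")))
  expect_error(select_atoms(tmpl, "bogus"), "unknown selection")
})
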