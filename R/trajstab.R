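# Trajectory stability analytics: Kabsch superposition, RMSD series,
# radius of gyration, RMSF, hydrogen-bond statistics, PCA of atomic
# fluctuations and the free-energy landscape over the leading components.

#' Kabsch least-squares superposition
#'
#' Optimal rigid transform (proper rotation + translation) minimising the
#' RMSD of `mobile` onto `reference` over the fit selection, via SVD of the
#' cross-covariance with a determinant correction that excludes
#' reflections.
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @param fit integer indices of the atoms used for fitting (default all);
#'   at least 3 non-collinear points.
#' @return A list: `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (over the fit selection after transform) and `transform`, a function
#'   mapping any M x 3 matrix through the fitted rigid motion.
#' @export
kabsch_superpose <- function(mobile, reference, fit = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) .err("coordinate dims differ")
  if (is.null(fit)) fit <- seq_len(nrow(mobile))
  if (length(fit) < 3L) .err("fit selection needs at least 3 atoms")
  A <- mobile[fit, , drop = FALSE]
  B <- reference[fit, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  if (qr(Bc)$rank < 2L || qr(Ac)$rank < 2L) {
    .err("degenerate (collinear) fit selection")
  }
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transform <- function(x) {
    sweep(sweep(as.matrix(x), 2, ca) %*% t(R), 2, cb, "+")
  }
  fitted <- transform(A)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = cb - as.numeric(R %*% ca),
       rmsd = rmsd, transform = transform)
}

.sel_idx <- function(traj, sel, default) {
  if (is.null(sel)) sel <- default
  select_atoms(traj, sel)
}

#' Per-frame RMSD relative to a reference structure
#'
#' Each frame is superposed onto the reference over `fit_selection`
#' (default: protein backbone) and the RMSD is then measured over
#' `measure_selection`. Measuring over the backbone, the ligand, or a
#' binding-site selection reproduces the three standard stability panels.
#'
#' @param traj a [trajectory()].
#' @param reference N x 3 reference coordinates; default frame 1.
#' @param fit_selection selection (string or indices) used for fitting.
#' @param measure_selection selection the RMSD is reported over; default
#'   the fit selection.
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL,
                        fit_selection = "protein and backbone",
                        measure_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  reference <- as.matrix(reference)
  if (nrow(reference) != dim(traj$coords)[2]) {
    .err("reference must cover all trajectory atoms")
  }
  fit <- .sel_idx(traj, fit_selection, "all")
  meas <- if (is.null(measure_selection)) fit else
    select_atoms(traj, measure_selection)
  if (length(meas) == 0L) .err("empty measure selection")
  vapply(seq_len(n_frames(traj)), function(t) {
    x <- frame_coords(traj, t)
    k <- kabsch_superpose(x, reference, fit)
    d <- k$transform(x[meas, , drop = FALSE]) - reference[meas, , drop = FALSE]
    sqrt(mean(rowSums(d * d)))
  }, numeric(1))
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt(sum w_i |r_i - rbar|^2 / sum w_i)` with weights equal to the
#' atom masses (default) or unity.
#'
#' @param traj a [trajectory()].
#' @param selection atom selection (default all atoms).
#' @param mass_weighted use masses as weights (default `TRUE`).
#' @return Numeric vector of per-frame Rg values (Angstrom).
#' @export
radius_of_gyration <- function(traj, selection = "all",
                               mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- select_atoms(traj, selection)
  if (length(sel) == 0L) .err("empty selection")
  w <- if (mass_weighted) traj$atoms$mass[sel] else rep(1, length(sel))
  if (sum(w) <= 0) .err("zero total weight")
  vapply(seq_len(n_frames(traj)), function(t) {
    x <- frame_coords(traj, t)[sel, , drop = FALSE]
    ctr <- colSums(x * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(x, 2, ctr)^2)) / sum(w))
  }, numeric(1))
}

# superpose every frame of a trajectory onto the iterated mean structure
# over `sel`; returns frames x atoms x 3 array restricted to sel
.fit_to_mean <- function(traj, sel, passes = 2L) {
  nf <- n_frames(traj)
  sub <- traj$coords[, sel, , drop = FALSE]
  ref <- matrix(sub[1, , ], ncol = 3)
  for (p in seq_len(passes)) {
    for (t in seq_len(nf)) {
      x <- matrix(sub[t, , ], ncol = 3)
      sub[t, , ] <- kabsch_superpose(x, ref, seq_len(nrow(x)))$transform(x)
    }
    ref <- apply(sub, c(2, 3), mean)
  }
  sub
}

#' Root-mean-square fluctuation per atom (and per residue)
#'
#' After optional superposition of every frame onto the iterated mean
#' structure (two passes; removes global rotation and translation), the
#' per-atom fluctuation is
#' `RMSF_i = sqrt(mean_t |r_i(t) - rbar_i|^2)`. The per-residue value is
#' the mean over each residue's selected atoms.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom selection (default protein backbone).
#' @param fit superpose frames before measuring (default `TRUE`).
#' @return A list: `atom` (data frame: atom index, residue index, rmsf) and
#'   `residue` (data frame: residue index, rmsf).
#' @export
rmsf <- function(traj, selection = "protein and backbone", fit = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) .err("RMSF needs at least 2 frames")
  sel <- select_atoms(traj, selection)
  if (length(sel) == 0L) .err("empty selection")
  sub <- if (fit) .fit_to_mean(traj, sel) else
    traj$coords[, sel, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mu)^2
  per_atom <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and xyz, x3
  resi <- traj$atoms$residue_index[sel]
  atom_df <- data.frame(atom_index = sel, residue_index = resi,
                        rmsf = per_atom)
  res_df <- stats::aggregate(rmsf ~ residue_index, atom_df, mean)
  list(atom = atom_df, residue = res_df)
}

#' Hydrogen-bond geometric criteria
#'
#' @param distance_cutoff donor-heavy-atom to acceptor distance cutoff in
#'   Angstrom (default 3.0); comparisons are inclusive.
#' @param angle_cutoff donor-H-acceptor angle cutoff in degrees (default
#'   135); inclusive.
#' @param occupancy_cutoff fraction of frames below which a bond is left
#'   out of the headline table (default 0.20).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(distance_cutoff = 3.0, angle_cutoff = 135,
                           occupancy_cutoff = 0.20) {
  if (distance_cutoff <= 0) .err("distance_cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180) {
    .err("angle_cutoff must be in (0, 180]")
  }
  if (occupancy_cutoff < 0 || occupancy_cutoff > 1) {
    .err("occupancy_cutoff must be in [0, 1]")
  }
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff,
                 occupancy_cutoff = occupancy_cutoff),
            class = "hbond_criteria")
}

#' Hydrogen-bond occupancy statistics over a trajectory
#'
#' A candidate bond is satisfied in a frame when the donor-heavy-atom to
#' acceptor distance is at most `distance_cutoff` and the donor-H-acceptor
#' angle (vertex at the hydrogen) is at least `angle_cutoff`; both
#' comparisons inclusive. Occupancy is the percentage of satisfying
#' frames; the average distance is taken over satisfying frames only.
#' Bonds below the occupancy cutoff are excluded from the headline table
#' but retained in the full listing.
#'
#' @param traj a [trajectory()] with explicit hydrogens.
#' @param roster data frame with columns `donor`, `hydrogen`, `acceptor`
#'   giving atom names (or indices) of each candidate triple. A missing or
#'   unknown hydrogen skips the candidate with a warning.
#' @param criteria an [hbond_criteria()].
#' @return A list of class `hbond_result`: `table` (headline data frame:
#'   donor, acceptor, avg_distance, occupancy), `all` (every candidate),
#'   and `per_frame_counts` (satisfied bonds per frame).
#' @export
hbond_stats <- function(traj, roster, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "trajectory"), inherits(criteria, "hbond_criteria"))
  roster <- as.data.frame(roster)
  nf <- n_frames(traj)
  resolve <- function(ref) {
    if (is.numeric(ref)) return(as.integer(ref))
    i <- match(ref, traj$atoms$atom_name)
    i
  }
  rows <- list()
  counts <- integer(nf)
  for (i in seq_len(nrow(roster))) {
    d <- resolve(roster$donor[i])
    h <- resolve(roster$hydrogen[i])
    a <- resolve(roster$acceptor[i])
    if (is.na(h) || is.na(d) || is.na(a)) {
      warning(sprintf("candidate %d: atom not found (missing hydrogen?); skipped", i))
      next
    }
    D <- traj$coords[, d, , drop = FALSE]
    Hc <- traj$coords[, h, , drop = FALSE]
    A <- traj$coords[, a, , drop = FALSE]
    dv <- matrix(D - A, ncol = 3)
    dist_da <- sqrt(rowSums(dv * dv))
    v1 <- matrix(D - Hc, ncol = 3)
    v2 <- matrix(A - Hc, ncol = 3)
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    sat <- dist_da <= criteria$distance_cutoff & ang >= criteria$angle_cutoff
    counts <- counts + sat
    rows[[length(rows) + 1L]] <- data.frame(
      donor = as.character(roster$donor[i]),
      hydrogen = as.character(roster$hydrogen[i]),
      acceptor = as.character(roster$acceptor[i]),
      avg_distance = if (any(sat)) mean(dist_da[sat]) else NA_real_,
      occupancy = 100 * sum(sat) / nf,
      stringsAsFactors = FALSE
    )
  }
  all_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = character(0), hydrogen = character(0),
               acceptor = character(0), avg_distance = numeric(0),
               occupancy = numeric(0))
  headline <- all_df[all_df$occupancy > 100 * criteria$occupancy_cutoff, ,
                     drop = FALSE]
  structure(list(table = headline, all = all_df,
                 per_frame_counts = counts),
            class = "hbond_result")
}

#' Principal component analysis of atomic fluctuations
#'
#' Frames are superposed onto the iterated mean structure (two passes,
#' removing global rotation and translation), the covariance matrix of the
#' 3N-dimensional coordinate vector about its mean is diagonalised, and
#' per-frame projections onto the components are returned. Eigenvalues are
#' clamped at zero against numerical round-off.
#'
#' @param traj a [trajectory()].
#' @param selection atom selection (default protein backbone). Cartesian
#'   (unweighted) covariance.
#' @param fit superpose before analysis (default `TRUE`).
#' @return An object of class `pca_result`: `eigenvalues` (descending,
#'   A^2), `eigenvectors` (3N x 3N), `projections` (frames x components),
#'   `variance_fraction`, `trace`.
#' @export
trajectory_pca <- function(traj, selection = "protein and backbone",
                           fit = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- select_atoms(traj, selection)
  if (length(sel) == 0L) .err("empty selection")
  nf <- n_frames(traj)
  if (nf <= 3L * length(sel)) {
    warning("fewer frames than 3 x selected atoms; covariance is rank-deficient")
  }
  sub <- if (fit) .fit_to_mean(traj, sel) else
    traj$coords[, sel, , drop = FALSE]
  X <- matrix(sub, nrow = nf)  # frames x 3N (atom-major per axis blocks)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / (nf - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  proj <- Xc %*% e$vectors
  structure(list(
    eigenvalues = ev, eigenvectors = e$vectors,
    projections = proj,
    variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
    trace = sum(diag(C))
  ), class = "pca_result")
}

#' Free-energy landscape over two collective coordinates
#'
#' Boltzmann inversion of the frame density over a 2-D grid:
#' `G_bin = -kB T ln(n_bin / n_max)` so the most populated bin sits at
#' zero. Empty bins are assigned the maximum finite G plus `empty_offset`
#' and flagged. Basins are counted as local minima (8-neighbourhood) with
#' G below `basin_depth`.
#'
#' @param pc1,pc2 per-frame projections on the two coordinates.
#' @param bins number of bins per axis (default 32).
#' @param temperature simulation temperature in Kelvin (default 300).
#' @param unit `"kcal"` (default) or `"kJ"` per mol.
#' @param empty_offset energy added above the finite maximum for empty
#'   bins (default 1).
#' @param basin_depth depth threshold for basin counting (default 1).
#' @return An object of class `free_energy_surface`: `G` (bins x bins
#'   matrix), `x_edges`, `y_edges`, `occupied` (logical matrix),
#'   `temperature`, `unit`, `n_basins`.
#' @export
free_energy_landscape <- function(pc1, pc2, bins = 32L, temperature = 300,
                                  unit = c("kcal", "kJ"),
                                  empty_offset = 1, basin_depth = 1) {
  unit <- match.arg(unit)
  if (length(pc1) != length(pc2) || length(pc1) == 0L) {
    .err("pc1 and pc2 must be non-empty and equal length")
  }
  kB <- if (unit == "kcal") 0.0019872041 else 0.0083144626
  kT <- kB * temperature
  x_edges <- seq(min(pc1), max(pc1), length.out = bins + 1L)
  y_edges <- seq(min(pc2), max(pc2), length.out = bins + 1L)
  ix <- pmin(findInterval(pc1, x_edges, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(pc2, y_edges, rightmost.closed = TRUE), bins)
  counts <- matrix(0L, bins, bins)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  occupied <- counts > 0L
  G <- matrix(NA_real_, bins, bins)
  G[occupied] <- -kT * log(counts[occupied] / max(counts))
  gmax <- max(G, na.rm = TRUE)
  G[!occupied] <- gmax + empty_offset
  # basin count: occupied local minima below the depth threshold
  n_basins <- 0L
  for (i in which(occupied)) {
    r <- (i - 1L) %% bins + 1L
    c_ <- (i - 1L) %/% bins + 1L
    nb <- expand.grid(r = r + (-1:1), c = c_ + (-1:1))
    nb <- nb[!(nb$r == r & nb$c == c_) & nb$r >= 1 & nb$r <= bins &
               nb$c >= 1 & nb$c <= bins, ]
    if (G[r, c_] <= basin_depth &&
        all(G[r, c_] <= G[cbind(nb$r, nb$c)])) {
      n_basins <- n_basins + 1L
    }
  }
  structure(list(G = G, x_edges = x_edges, y_edges = y_edges,
                 occupied = occupied, temperature = temperature,
                 unit = unit, n_basins = n_basins),
            class = "free_energy_surface")
}

#' Binding-site selection by heavy-atom contact
#'
#' Protein residues with any heavy atom within `cutoff` (inclusive) of any
#' ligand heavy atom in the stated frame; the returned selection is those
#' residues' backbone atoms by default.
#'
#' @param traj a [trajectory()].
#' @param ligand_selection selection for the ligand (default `"ligand"`).
#' @param cutoff contact distance in Angstrom (default 5.0).
#' @param frame frame used for the contact test (default 1).
#' @param backbone_only return only backbone atoms of contact residues
#'   (default `TRUE`).
#' @return Integer atom indices (possibly empty, with a warning).
#' @export
binding_site_selection <- function(traj, ligand_selection = "ligand",
                                   cutoff = 5.0, frame = 1L,
                                   backbone_only = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  lig <- intersect(select_atoms(traj, ligand_selection),
                   select_atoms(traj, "heavy"))
  if (length(lig) == 0L) .err("empty ligand selection")
  prot <- intersect(select_atoms(traj, "protein"),
                    select_atoms(traj, "heavy"))
  x <- frame_coords(traj, frame)
  d2 <- outer(rowSums(x[prot, , drop = FALSE]^2),
              rowSums(x[lig, , drop = FALSE]^2), "+") -
    2 * x[prot, , drop = FALSE] %*% t(x[lig, , drop = FALSE])
  near <- prot[apply(d2 <= cutoff^2 + 1e-9, 1, any)]
  resids <- unique(traj$atoms$residue_index[near])
  if (length(resids) == 0L) {
    warning("no protein residue within the cutoff; empty selection")
    return(integer(0))
  }
  keep <- traj$atoms$residue_index %in% resids &
    traj$atoms$chain == "protein"
  if (backbone_only) keep <- keep & traj$atoms$backbone
  which(keep)
}
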