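# Synthetic-data generators: fingerprint/activity datasets with planted
# signal, two-class score tables for enrichment validation, and trajectories
# with controlled fluctuation, rigid-body motion and scheduled hydrogen bonds.

#' Specification for a synthetic fingerprint/activity dataset
#'
#' Describes a binary fingerprint matrix with a planted linear
#' bit-to-activity signal. Uninformative bits are Bernoulli with a
#' prevalence drawn once per bit from `bit_prob_range`, mimicking the
#' sparsity profile of real structural fingerprints. The noiseless signal is
#' affinely rescaled to span `activity_range`, so `noise_sd` keeps its pIC50
#' units.
#'
#' @param n_compounds number of rows (compounds).
#' @param n_bits fingerprint length.
#' @param n_informative number of bits carrying signal (must not exceed
#'   `n_bits`).
#' @param effect_weights per-informative-bit activity increments (pIC50 per
#'   set bit) before rescaling; recycled to length `n_informative`.
#' @param noise_sd Gaussian noise standard deviation in pIC50 units.
#' @param activity_range numeric \[low, high\] the noiseless signal spans.
#' @param bit_prob_range range for the per-bit Bernoulli prevalence.
#' @param seed integer RNG seed.
#' @return A `qsar_spec` list.
#' @export
qsar_spec <- function(n_compounds = 103L, n_bits = 1024L,
                      n_informative = 10L,
                      effect_weights = rep(1, n_informative),
                      noise_sd = 0.3,
                      activity_range = c(4.398, 7.721),
                      bit_prob_range = c(0.05, 0.5),
                      seed = 1L) {
  n_compounds <- .check_count(n_compounds, "n_compounds", 2L)
  n_bits <- .check_count(n_bits, "n_bits", 1L)
  n_informative <- .check_count(n_informative, "n_informative", 0L)
  if (n_informative > n_bits) .err("n_informative exceeds n_bits")
  if (noise_sd < 0) .err("noise_sd must be non-negative")
  if (length(activity_range) != 2L || activity_range[1] >= activity_range[2]) {
    .err("activity_range must be [low, high] with low < high")
  }
  effect_weights <- rep_len(as.numeric(effect_weights), n_informative)
  structure(list(
    n_compounds = n_compounds, n_bits = n_bits,
    n_informative = n_informative, effect_weights = effect_weights,
    noise_sd = noise_sd, activity_range = as.numeric(activity_range),
    bit_prob_range = as.numeric(bit_prob_range), seed = as.integer(seed)
  ), class = "qsar_spec")
}

#' Generate a synthetic fingerprint dataset with planted signal
#'
#' Draws the bit matrix, picks `n_informative` planted columns, forms the
#' linear signal, rescales it so the noiseless signal spans
#' `activity_range`, and adds Gaussian noise. The planted column indices and
#' the post-rescaling effect weights are recorded in the dataset metadata so
#' that recovery by feature selection or regression can be scored.
#'
#' @param spec a [qsar_spec()].
#' @return A [fingerprint_dataset()]; `metadata` carries `informative_bits`,
#'   `effect_weights` (raw), `scaled_weights`, `intercept`, `noise_sd` and
#'   `seed`.
#' @export
gen_qsar_dataset <- function(spec) {
  stopifnot(inherits(spec, "qsar_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  m <- spec$n_bits
  p <- stats::runif(m, spec$bit_prob_range[1], spec$bit_prob_range[2])
  bits <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), nrow = n)
  colnames(bits) <- sprintf("bit_%04d", seq_len(m))
  informative <- sort(sample.int(m, spec$n_informative))
  raw <- if (spec$n_informative > 0) {
    as.numeric(bits[, informative, drop = FALSE] %*% spec$effect_weights)
  } else {
    rep(0, n)
  }
  lo <- spec$activity_range[1]
  hi <- spec$activity_range[2]
  if (max(raw) > min(raw)) {
    a <- (hi - lo) / (max(raw) - min(raw))
    b <- lo - a * min(raw)
  } else {
    # degenerate constant signal: park it at the range midpoint
    a <- 1
    b <- (lo + hi) / 2 - raw[1]
  }
  activity <- a * raw + b + stats::rnorm(n, 0, spec$noise_sd)
  fingerprint_dataset(
    ids = sprintf("CMP%05d", seq_len(n)),
    bits = bits, activity = activity,
    fingerprint_name = "synthetic",
    metadata = list(
      informative_bits = informative,
      effect_weights = spec$effect_weights,
      scaled_weights = a * spec$effect_weights,
      intercept = b, rescale_slope = a,
      noise_sd = spec$noise_sd, seed = spec$seed
    )
  )
}

#' Specification for a two-class synthetic score table
#'
#' Gaussian score distributions for an active and an inactive class, used to
#' validate ranking statistics (ROC AUC, enrichment factors) against their
#' closed forms.
#'
#' @param n_active,n_inactive class sizes.
#' @param mean_active,mean_inactive,sd_active,sd_inactive Gaussian
#'   parameters in score units.
#' @param direction `"lower_better"` (docking-energy convention) or
#'   `"higher_better"`.
#' @param seed integer RNG seed.
#' @return A `score_sim_spec` list.
#' @export
score_sim_spec <- function(n_active, n_inactive,
                           mean_active = -9, mean_inactive = -7,
                           sd_active = 1, sd_inactive = 1,
                           direction = c("lower_better", "higher_better"),
                           seed = 1L) {
  direction <- match.arg(direction)
  n_active <- .check_count(n_active, "n_active")
  n_inactive <- .check_count(n_inactive, "n_inactive")
  if (sd_active <= 0 || sd_inactive <= 0) .err("score sds must be positive")
  structure(list(
    n_active = n_active, n_inactive = n_inactive,
    mean_active = mean_active, mean_inactive = mean_inactive,
    sd_active = sd_active, sd_inactive = sd_inactive,
    direction = direction, seed = as.integer(seed)
  ), class = "score_sim_spec")
}

#' Generate a labelled synthetic score table
#'
#' @param spec a [score_sim_spec()].
#' @param protocol name for the single simulated scoring protocol.
#' @return A [score_table()] with one protocol, the stated direction and a
#'   logical active-label vector.
#' @export
gen_score_set <- function(spec, protocol = "sim") {
  stopifnot(inherits(spec, "score_sim_spec"))
  set.seed(spec$seed)
  s_act <- stats::rnorm(spec$n_active, spec$mean_active, spec$sd_active)
  s_ina <- stats::rnorm(spec$n_inactive, spec$mean_inactive, spec$sd_inactive)
  n <- spec$n_active + spec$n_inactive
  scores <- matrix(c(s_act, s_ina), ncol = 1,
                   dimnames = list(NULL, protocol))
  score_table(
    compound_ids = sprintf("CMP%05d", seq_len(n)),
    scores = scores,
    directions = stats::setNames(spec$direction, protocol),
    labels = c(rep(TRUE, spec$n_active), rep(FALSE, spec$n_inactive))
  )
}

#' Specification for a synthetic trajectory
#'
#' Frames are built as `rigid_motion_t applied to (reference + Gaussian
#' fluctuation)`. The rigid rotation is taken about the template centroid so
#' the radius of gyration is invariant by construction. Scheduled hydrogen
#' bonds override the acceptor position relative to the (fluctuated) donor:
#' conforming frames place the acceptor 2.7 A from the donor heavy atom
#' along the donor-hydrogen direction (donor-H-acceptor angle 180 degrees),
#' non-conforming frames at 5.0 A, so a geometry-based detector sees the
#' bond in exactly the scheduled fraction of frames (rounded to the nearest
#' frame count).
#'
#' @param n_frames number of frames (at least 2).
#' @param atom_template data frame with columns `residue_index`,
#'   `residue_name`, `atom_name`, `element`, `backbone` (logical), `mass`,
#'   `chain` (`"protein"`, `"ligand"` or `"solvent"`) and reference
#'   coordinates `x`, `y`, `z` in Angstrom. Hydrogens are explicit.
#' @param fluct_sd per-atom fluctuation standard deviation (A); scalar or
#'   one value per atom.
#' @param translation optional `n_frames` x 3 matrix of per-frame rigid
#'   translations (A).
#' @param rot_angles optional per-frame rotation angles (radians) about
#'   `rot_axis` through the template centroid.
#' @param rot_axis rotation axis, default z.
#' @param hbond_schedule list of entries `list(donor=, hydrogen=, acceptor=,
#'   fraction=)` naming atoms by `atom_name` (or giving indices).
#' @param time_per_frame frame spacing in ps.
#' @param seed integer RNG seed.
#' @return A `traj_sim_spec` list.
#' @export
traj_sim_spec <- function(n_frames, atom_template = default_atom_template(),
                          fluct_sd = 0.3,
                          translation = NULL, rot_angles = NULL,
                          rot_axis = c(0, 0, 1),
                          hbond_schedule = list(),
                          time_per_frame = 2,
                          seed = 1L) {
  n_frames <- .check_count(n_frames, "n_frames", 2L)
  atom_template <- .check_atom_template(atom_template)
  if (any(fluct_sd < 0)) .err("fluct_sd must be non-negative")
  fluct_sd <- rep_len(as.numeric(fluct_sd), nrow(atom_template))
  if (!is.null(translation)) {
    translation <- as.matrix(translation)
    if (nrow(translation) != n_frames || ncol(translation) != 3L) {
      .err("translation must be an n_frames x 3 matrix")
    }
  }
  if (!is.null(rot_angles)) rot_angles <- rep_len(as.numeric(rot_angles), n_frames)
  for (hb in hbond_schedule) {
    if (is.null(hb$donor) || is.null(hb$hydrogen) || is.null(hb$acceptor) ||
        is.null(hb$fraction)) {
      .err("each hbond_schedule entry needs donor, hydrogen, acceptor, fraction")
    }
    if (hb$fraction < 0 || hb$fraction > 1) .err("hbond fraction must be in [0, 1]")
  }
  structure(list(
    n_frames = n_frames, atom_template = atom_template,
    fluct_sd = fluct_sd, translation = translation,
    rot_angles = rot_angles, rot_axis = as.numeric(rot_axis),
    hbond_schedule = hbond_schedule,
    time_per_frame = time_per_frame, seed = as.integer(seed)
  ), class = "traj_sim_spec")
}

.check_atom_template <- function(at) {
  at <- as.data.frame(at)
  need <- c("residue_index", "residue_name", "atom_name", "element",
            "backbone", "mass", "chain", "x", "y", "z")
  missing <- setdiff(need, names(at))
  if (length(missing)) {
    .err("atom_template lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (nrow(at) < 1L) .err("atom_template is empty")
  at
}

# resolve an hbond-schedule atom reference (index or atom_name) to an index
.resolve_atom <- function(ref, template) {
  if (is.numeric(ref)) {
    idx <- as.integer(ref)
    if (idx < 1L || idx > nrow(template)) .err("atom index %d out of range", idx)
    return(idx)
  }
  idx <- which(template$atom_name == ref)
  if (length(idx) == 0L) .err("unknown atom '%s' in hbond schedule", ref)
  idx[1]
}

#' Generate a synthetic trajectory and its reference structure
#'
#' @param spec a [traj_sim_spec()].
#' @return A list with elements `trajectory` (a [trajectory()]) and
#'   `reference` (the template data frame, i.e. the frame-0 topology plus
#'   reference coordinates).
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_sim_spec"))
  set.seed(spec$seed)
  at <- spec$atom_template
  n_atoms <- nrow(at)
  nf <- spec$n_frames
  ref <- as.matrix(at[, c("x", "y", "z")])
  centroid <- colMeans(ref)

  # resolve schedules up front (errors before any simulation work)
  sched <- lapply(spec$hbond_schedule, function(hb) {
    list(d = .resolve_atom(hb$donor, at),
         h = .resolve_atom(hb$hydrogen, at),
         a = .resolve_atom(hb$acceptor, at),
         fraction = hb$fraction)
  })
  sched_frames <- lapply(sched, function(s) {
    k <- round(s$fraction * nf)
    if (k > 0) sort(sample.int(nf, k)) else integer(0)
  })

  coords <- array(NA_real_, dim = c(nf, n_atoms, 3))
  for (t in seq_len(nf)) {
    x <- ref + matrix(stats::rnorm(n_atoms * 3, 0, spec$fluct_sd),
                      ncol = 3)
    # scheduled hydrogen bonds: exact geometry relative to the noisy donor
    for (j in seq_along(sched)) {
      s <- sched[[j]]
      u <- ref[s$h, ] - ref[s$d, ]
      u <- u / sqrt(sum(u^2))
      d_aa <- if (t %in% sched_frames[[j]]) 2.7 else 5.0
      x[s$h, ] <- x[s$d, ] + 1.0 * u
      x[s$a, ] <- x[s$d, ] + d_aa * u
    }
    if (!is.null(spec$rot_angles)) {
      R <- rotation_matrix(spec$rot_axis, spec$rot_angles[t])
      x <- sweep(sweep(x, 2, centroid) %*% t(R), 2, centroid, "+")
    }
    if (!is.null(spec$translation)) {
      x <- sweep(x, 2, spec$translation[t, ], "+")
    }
    coords[t, , ] <- x
  }
  traj <- trajectory(coords, atoms = at[, setdiff(names(at), c("x", "y", "z"))],
                     time_per_frame = spec$time_per_frame)
  list(trajectory = traj, reference = at)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis vector (normalised internally).
#' @param angle rotation angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               nrow = 3, byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

#' Small built-in atom template for trajectory simulation
#'
#' A compact pseudo-system: a three-residue protein stretch (backbone N, CA,
#' C, O plus an amide hydrogen per residue) and a four-atom ligand carrying
#' a donor-hydrogen pair and an acceptor, laid out on a simple lattice.
#' Intended for tests and examples; it makes no claim to stereochemical
#' realism.
#'
#' @param n_residues number of protein residues (default 3).
#' @return An atom-template data frame as required by [traj_sim_spec()].
#' @export
default_atom_template <- function(n_residues = 3L) {
  rows <- list()
  for (i in seq_len(n_residues)) {
    x0 <- 3.8 * (i - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      residue_index = i, residue_name = "ALA",
      atom_name = c(paste0("N", i), paste0("CA", i), paste0("C", i),
                    paste0("O", i), paste0("HN", i)),
      element = c("N", "C", "C", "O", "H"),
      backbone = c(TRUE, TRUE, TRUE, TRUE, FALSE),
      mass = c(14.007, 12.011, 12.011, 15.999, 1.008),
      chain = "protein",
      x = x0 + c(0, 1.4, 2.5, 2.9, -0.5),
      y = c(0, 0.8, 0, 0.9, -0.8),
      z = c(0, 0, 0.5, 1.2, 0.4)
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    residue_index = n_residues + 1L, residue_name = "LIG",
    atom_name = c("LN1", "LH1", "LO1", "LC1"),
    element = c("N", "H", "O", "C"),
    backbone = FALSE,
    mass = c(14.007, 1.008, 15.999, 12.011),
    chain = "ligand",
    x = c(1.5, 1.5, 3.0, 0.5),
    y = c(4.0, 5.0, 4.5, 3.2),
    z = c(1.0, 1.0, 1.5, 0.5)
  )
  do.call(rbind, rows)
}
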