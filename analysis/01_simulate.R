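#!/usr/bin/env Rscript
# Stage 1 — synthetic substrates for the whole funnel.
#
# Builds the three inputs every later stage consumes: a 103-compound
# fingerprint/activity dataset with ten planted informative bits (activity
# spanning pIC50 4.398-7.721), a labelled docking-score table with a
# lower-is-better convention, and a 2000-frame trajectory with a scheduled
# ligand-protein hydrogen bond. Everything is seeded, so downstream stages
# are reproducible.

suppressMessages(library(funnelscreen))
dir.create("results", showWarnings = FALSE)
seed <- 20260101L

ds <- gen_qsar_dataset(qsar_spec(n_compounds = 103, n_bits = 1024,
                                 n_informative = 10, noise_sd = 0.3,
                                 seed = seed))
write_fingerprint_csv(ds, "results/qsar_dataset.csv",
                      "results/qsar_dataset_meta.json")
cat(sprintf("dataset: %d compounds x %d bits, pIC50 %.3f..%.3f\n",
            nrow(ds$bits), ncol(ds$bits), min(ds$activity),
            max(ds$activity)))
cat("planted bits:", ds$metadata$informative_bits, "\n")

st <- gen_score_set(score_sim_spec(
  n_active = 500, n_inactive = 4500, mean_active = -9.5, mean_inactive = -8,
  sd_active = 1, sd_inactive = 1, direction = "lower_better",
  seed = seed + 1L), protocol = "dock")
write.csv(data.frame(compound_id = st$compound_ids,
                     dock = st$scores[, "dock"], active = st$labels),
          "results/score_set.csv", row.names = FALSE)
cat(sprintf("score set: %d compounds, %d actives, scores %.2f..%.2f\n",
            length(st$compound_ids), sum(st$labels),
            min(st$scores), max(st$scores)))

g <- gen_trajectory(traj_sim_spec(
  n_frames = 2000, atom_template = default_atom_template(4),
  fluct_sd = 0.5, rot_angles = seq(0, 4 * pi, length.out = 2000),
  hbond_schedule = list(list(donor = "LN1", hydrogen = "LH1",
                             acceptor = "LO1", fraction = 0.6)),
  seed = seed + 2L))
write_structure_pdb(g$reference, "results/reference.pdb")
write_trajectory_pdb(g$trajectory, "results/trajectory.pdb")
cat(sprintf("trajectory: %d frames x %d atoms written\n",
            n_frames(g$trajectory), nrow(g$trajectory$atoms)))
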