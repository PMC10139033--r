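#!/usr/bin/env Rscript
# Stage 5 — trajectory stability analytics.
#
# Reads the stage-1 reference and multi-model trajectory and produces the
# standard stability panels: backbone / ligand / binding-site RMSD series,
# radius of gyration, per-residue RMSF, hydrogen-bond occupancy at the
# 3.0 A / 135 degree / 20% criteria, PCA of backbone fluctuations, and the
# free-energy landscape over PC1/PC2 at 300 K.

suppressMessages(library(funnelscreen))

traj <- read_trajectory_pdb("results/trajectory.pdb")
ref <- frame_coords(read_trajectory_pdb("results/reference.pdb"), 1)
cat(sprintf("loaded %d frames x %d atoms\n", n_frames(traj),
            nrow(traj$atoms)))

bb <- rmsd_series(traj, reference = ref,
                  fit_selection = "protein and backbone")
lig <- rmsd_series(traj, reference = ref,
                   fit_selection = "protein and backbone",
                   measure_selection = "ligand and heavy")
site <- binding_site_selection(traj, cutoff = 5.0)
bs <- rmsd_series(traj, reference = ref,
                  fit_selection = "protein and backbone",
                  measure_selection = site)
rg <- radius_of_gyration(traj, "protein")
cat(sprintf("mean RMSD: backbone %.3f, ligand %.3f, binding site %.3f A\n",
            mean(bb), mean(lig), mean(bs)))
cat(sprintf("mean Rg: %.3f A\n", mean(rg)))
write.csv(data.frame(frame = seq_along(bb), time_ps = (seq_along(bb) - 1) *
                       traj$time_per_frame, rmsd_backbone = bb,
                     rmsd_ligand = lig, rmsd_binding_site = bs, rg = rg),
          "results/rmsd_series.csv", row.names = FALSE)

rf <- rmsf(traj, selection = "protein and backbone")
cat(sprintf("RMSF: %d residues, mean %.3f A\n", nrow(rf$residue),
            mean(rf$residue$rmsf)))
write.csv(rf$residue, "results/rmsf_per_residue.csv", row.names = FALSE)

hb <- hbond_stats(traj, data.frame(donor = "LN1", hydrogen = "LH1",
                                   acceptor = "LO1"))
cat("hydrogen bonds above the 20% occupancy cutoff:\n")
print(hb$table)
write.csv(hb$all, "results/hbonds.csv", row.names = FALSE)

pca <- trajectory_pca(traj, selection = "protein and backbone")
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]))
fel <- free_energy_landscape(pca$projections[, 1], pca$projections[, 2],
                             bins = 24)
cat(sprintf("FEL: max occupied G %.3f kcal/mol, %d basins\n",
            max(fel$G[fel$occupied]), fel$n_basins))
g_df <- expand.grid(i = seq_len(nrow(fel$G)), j = seq_len(ncol(fel$G)))
g_df$G <- fel$G[cbind(g_df$i, g_df$j)]
g_df$occupied <- fel$occupied[cbind(g_df$i, g_df$j)]
write.csv(g_df, "results/fel_grid.csv", row.names = FALSE)
jsonlite::write_json(list(temperature = fel$temperature, unit = fel$unit,
                          x_edges = fel$x_edges, y_edges = fel$y_edges,
                          n_basins = fel$n_basins),
                     "results/fel_meta.json", auto_unbox = TRUE)
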