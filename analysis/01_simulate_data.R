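#!/usr/bin/env Rscript
# Stage 1: generate every synthetic dataset with known ground truth.
#
# Emulates the full experimental design: a 4-group x 3-replicate LFQ
# proximity-labelling experiment (Cav1 bait under NT / HYPO / REC plus the
# NES cytoplasmic reference) with planted interactor classes and
# detection-limit missingness; polarised-cell and PLA images; and
# persistent-random-walk migration tracks at the observed ~0.4 um/min scale.

suppressMessages(library(caviprox))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_proteome_config(n_proteins = 2000, seed = seed)
sim <- simulate_lfq_experiment(cfg)
write_protein_table(sim$table, "results/data/proteinGroups_synthetic.tsv")
write.csv(as.data.frame(sim$table$design), "results/data/sample_design.csv",
          row.names = FALSE)
write.csv(sim$truth, "results/data/planted_truth.csv", row.names = FALSE)
cat(sprintf("LFQ table: %d proteins x %d samples, %.1f%% missing; classes: %s\n",
            nrow(sim$table$intensity), ncol(sim$table$intensity),
            100 * mean(is.na(sim$table$intensity)),
            paste(names(table(sim$truth$class)), table(sim$truth$class),
                  sep = "=", collapse = ", ")))

pol <- simulate_polarized_cell_image(rear_fold = 8, noise = "poisson",
                                     seed = seed)
write_image_tiff(pol$image, "results/data/polarized_cell.tiff",
                 scale = max(pol$image))
write_image_tiff(pol$mask, "results/data/polarized_cell_mask.tiff", scale = 1)
pla <- simulate_pla_image(n_dots = 12, min_separation = 20, seed = seed)
write_image_tiff(pla$image, "results/data/pla.tiff", scale = max(pla$image))
write_image_tiff(pla$mask, "results/data/pla_mask.tiff", scale = 1)
cat(sprintf("images: planted rear fold %.0f; %d PLA dots\n",
            pol$truth$rear_fold, pla$truth$dot_count))

tracks <- simulate_tracks(200, speed = 0.4, persistence = 10,
                          frame_interval = 5, n_frames = 73, seed = seed + 1L)
write_tracks(tracks, "results/data/tracks.csv")
cat(sprintf("tracks: %d persistent random walks (S = 0.4 um/min, P = 10 min)\n",
            length(unique(tracks$track_id))))
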