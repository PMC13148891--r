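#!/usr/bin/env Rscript
# Step 1: simulate every input the pipeline consumes, with known ground
# truth, under the study conditions: a 7-point 10-fold standard dilution
# series in triplicate (Ct noise SD 0.15 cycles), three eVLP preps at
# titers around 6e6 copies/uL with no-RT controls 20-26-fold lower,
# live-cell luminescence time courses (1 and 5 uL doses, a 4-fold
# endosomal-acidification inhibitor arm, and a PBS-like baseline-only
# control), and a plasmid sequence with a HiBiT-like motif planted in a
# reverse reading frame.

suppressMessages(library(evlptiter))

seed <- 20260919
outdir <- "results/simulated"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

params <- workflow_params()        # 69-bp amplicon, 100-fold cDNA dilution
curve <- true_curve(efficiency = 0.95, b = 1.5)

std <- gen_standard_series(curve, n_points = 7, ct_sd = 0.15, seed = seed)
preps <- gen_prep_samples(c(6.2e6, 3.1e6, 8.9e6), curve, params,
                          n_preps = 3, ct_sd = 0.15, seed = seed + 1)
plate <- rbind(std$plate, preps$plate)
write.csv(plate, file.path(outdir, "qpcr_plate.csv"), row.names = FALSE)
write.csv(std$series, file.path(outdir, "dilution_series.csv"),
          row.names = FALSE)
write.csv(preps$truth, file.path(outdir, "prep_truth.csv"), row.names = FALSE)

conds <- data.frame(condition = c("eVLP_1ul", "eVLP_5ul", "eVLP_1ul_BafA1"),
                    dose_ul = c(1, 5, 1), lum_factor = c(1, 1, 4))
tcs <- gen_timecourses(conds, rlu_cv = 0.1, seed = seed + 2)
write.csv(tcs$wells, file.path(outdir, "timecourses.csv"), row.names = FALSE)
write.csv(tcs$truth, file.path(outdir, "timecourse_truth.csv"),
          row.names = FALSE)

plasmid <- gen_plasmid_with_motif(frame = -2L, offset = 40L,
                                  length_nt = 1500, n_mutations = 1L,
                                  id = "synthetic_plasmid", seed = seed + 3)
write_fasta(setNames(plasmid$seq, plasmid$id),
            file.path(outdir, "synthetic_plasmid.fasta"))
write.csv(as.data.frame(plasmid$annotation),
          file.path(outdir, "plasmid_truth.csv"), row.names = FALSE)

cat("Simulated inputs written to", outdir, "\n")
cat(sprintf("  qPCR plate: %d rows (%d standards, %d test/no-RT)\n",
            nrow(plate), nrow(std$plate), nrow(preps$plate)))
cat(sprintf("  true prep titers: %s copies/uL\n",
            paste(format(preps$truth$copies_per_ul_prep, big.mark = ","),
                  collapse = ", ")))
cat(sprintf("  time courses: %d wells x %d time points\n",
            length(unique(tcs$wells$well)),
            length(unique(tcs$wells$time_h))))
cat(sprintf("  plasmid: %d nt, motif planted in frame %d at 1 mismatch\n",
            nchar(plasmid$seq), plasmid$annotation$frame))
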