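#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analyses consume, with
# ground-truth sidecars, under data/simulated/. All generators are seeded,
# so re-running reproduces the files bit for bit.

suppressPackageStartupMessages(library(splicescreen))

out <- "data/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260923L

# Reporter images: one drug-treated group (planted ratio 2.0) and one vehicle
# group (planted ratio 1.4), 12 worms each, 10% sensor noise.
trt_truth <- reporter_truth(100, 50, 10, 5, c(128L, 128L), 0.25)
veh_truth <- reporter_truth(70, 50, 10, 5, c(128L, 128L), 0.25)
write_truth_yaml(trt_truth, file.path(out, "reporter_treated_truth.yaml"))
write_truth_yaml(veh_truth, file.path(out, "reporter_vehicle_truth.yaml"))
if (requireNamespace("tiff", quietly = TRUE)) {
  for (grp in c("treated", "vehicle")) {
    tr <- if (grp == "treated") trt_truth else veh_truth
    pairs <- gen_reporter_images(tr, 12, seed = seed + match(grp, c("treated", "vehicle")))
    dir.create(file.path(out, paste0("images_", grp)), showWarnings = FALSE)
    for (p in pairs) write_reporter_tiffs(p, file.path(out, paste0("images_", grp)))
  }
  cat("wrote 24 reporter image pairs (TIFF)\n")
}

# Junction dataset: 20 cassette-exon genes, PSI 0.5, 10% unannotated
# junction reads, 5% intronic bases, 50k junction reads.
jt <- junction_truth(0.5, 0.10, 0.05, 100L, 50000L)
jd <- gen_junction_dataset(jt, 20, seed = seed)
write_junction_tsv(jd$junctions, file.path(out, "junctions.tsv"))
write.csv(jd$events, file.path(out, "splice_events.csv"), row.names = FALSE)
write.csv(jd$reads, file.path(out, "read_placements.csv"), row.names = FALSE)
write_truth_yaml(jt, file.path(out, "junctions_truth.yaml"))
if (requireNamespace("rtracklayer", quietly = TRUE))
  write_annotation_gtf(jd$annotation, file.path(out, "annotation.gtf"))
cat("wrote junction dataset:", nrow(jd$junctions), "junction records\n")

# Lifespan cohorts: control vs drug at +30%, plus per-strain cohorts for the
# microbe screen (WT full effect, single KO half, double KO none, rescue
# near-full).
st <- survival_truth(20, 0.30, 0.1, 120, "weibull")
write_survival_csv(gen_survival(st, seed = seed),
                   file.path(out, "lifespan_drug.csv"))
write_truth_yaml(st, file.path(out, "lifespan_drug_truth.yaml"))
strain_effects <- c(WT = 0.30, single_ko = 0.15, double_ko = 0.00,
                    rescue = 0.27)
for (s in names(strain_effects)) {
  tr <- survival_truth(20, strain_effects[[s]], 0.1, 150, "weibull")
  write_survival_csv(gen_survival(tr, seed = seed + 10L + match(s, names(strain_effects))),
                     file.path(out, sprintf("lifespan_strain_%s.csv", s)))
}
cat("wrote lifespan cohorts for", length(strain_effects), "strains\n")

# Growth curves: control vs growth-inhibited (rate halved).
write.csv(gen_growth_curve(1.2, 0.5, 2, 24, 0.01, seed = seed),
          file.path(out, "growth_control.csv"), row.names = FALSE)
write.csv(gen_growth_curve(1.2, 0.25, 2, 24, 0.01, seed = seed + 1L),
          file.path(out, "growth_inhibited.csv"), row.names = FALSE)

# Omics matrix with a planted regulon.
ot <- omics_truth(500, 6, 25, 2, 0.5, 10)
om <- gen_omics(ot, seed = seed)
write_omics_tsv(om$matrix, om$samples, file.path(out, "omics_matrix.tsv"),
                file.path(out, "omics_samples.csv"))
write_regulon_tsv(om$regulon, file.path(out, "regulon.tsv"))
write_truth_yaml(ot, file.path(out, "omics_truth.yaml"))
writeLines(om$planted_set, file.path(out, "omics_planted_set.txt"))
cat("wrote omics matrix:", nrow(om$matrix), "features x",
    ncol(om$matrix), "samples\n")
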