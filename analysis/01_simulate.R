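#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the data layers the discovery pipeline consumes: a mouse
# structure-by-age atlas with a planted 13-gene VZ module, a human prenatal
# structure panel and a human developmental time series whose planted
# modules overlap (carrying the seven-gene mouse/human core), a five-channel
# association compendium around the mouse module, and flat annotations
# enriched in the human planted genes. Everything is deterministic given the
# config seed.

suppressMessages(library(vznet))

cfg <- pipeline_config(seed = 1L)
out <- file.path("results", "inputs")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

inputs <- simulate_inputs(cfg)

write_expression_matrix(inputs$mouse_atlas,
                        file.path(out, "mouse_atlas.tsv"),
                        file.path(out, "mouse_atlas_samples.tsv"))
write_expression_matrix(inputs$human_spatial,
                        file.path(out, "human_spatial.tsv"),
                        file.path(out, "human_spatial_samples.tsv"))
write_expression_matrix(inputs$human_temporal,
                        file.path(out, "human_temporal.tsv"),
                        file.path(out, "human_temporal_samples.tsv"))
for (nm in names(inputs$networks)) {
  write_network(inputs$networks[[nm]],
                file.path(out, paste0("evidence_", nm, ".graphml")), "graphml")
}
write_gene_sets(inputs$annotations, file.path(out, "annotations.gmt"))
write_config(cfg, file.path(out, "config.yaml"))
jsonlite::write_json(
  list(mouse_planted = inputs$truth$mouse$planted$members,
       spatial_planted = inputs$truth$spatial$planted$members,
       temporal_planted = inputs$truth$temporal$planted$members,
       associated_tier = inputs$truth$associated,
       enriched_sets = inputs$truth$enriched_sets),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)

cat("Simulated inputs written to", out, "\n")
cat("  mouse atlas:", nrow(inputs$mouse_atlas$values), "genes x",
    ncol(inputs$mouse_atlas$values), "samples;",
    length(inputs$truth$mouse$planted$members), "planted VZ genes\n")
cat("  human spatial:", nrow(inputs$human_spatial$values), "genes;",
    length(inputs$truth$spatial$planted$members), "planted zone genes\n")
cat("  human temporal:", nrow(inputs$human_temporal$values), "genes;",
    length(inputs$truth$temporal$planted$members), "planted early genes\n")
cat("  association compendium:", length(inputs$networks), "evidence channels\n")
cat("  annotations:", length(inputs$annotations), "gene sets (",
    length(inputs$truth$enriched_sets), "planted-enriched)\n")
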