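#!/usr/bin/env Rscript
# Stage 4: cross-species integration.
#
# The two human screen hit lists are intersected into the candidate list;
# the mouse VZ network is ortholog-mapped to human symbols (case-restyle
# fallback when the table has no entry) and intersected with the candidates
# to give the cross-species core. A pairwise overlap report covers all
# lists.

suppressMessages(library(vznet))

cfg <- pipeline_config(seed = 1L)
inputs <- simulate_inputs(cfg)
dir.create("results", showWarnings = FALSE)

mask <- zone_mask(inputs$mouse_atlas, age = "E15.5")
net <- build_vz_network(inputs$mouse_atlas, mask, cfg)
mouse_list <- gene_list(net$nodes, name = "mouse_vz_network", species = "mouse")

spatial_hits <- screen_hits(
  run_screen(inputs$human_spatial, zone_contrast(inputs$human_spatial), cfg),
  name = "human_spatial_hits", species = "human")
temporal_hits <- screen_hits(
  run_screen(inputs$human_temporal,
             stage_contrast(inputs$human_temporal, "8-9pcw"), cfg),
  name = "human_temporal_hits", species = "human")

candidates <- intersect_lists(spatial_hits, temporal_hits,
                              name = "human_candidates")
mapped <- map_orthologs(mouse_list, inputs$orthologs, "mouse_to_human")
core <- intersect_lists(mapped, candidates, name = "cross_species_core")

cat("Spatial hits:", length(spatial_hits$members),
    "| temporal hits:", length(temporal_hits$members),
    "| candidates (intersection):", length(candidates$members), "\n")
cat("Cross-species core (", length(core$members), " genes): ",
    paste(core$members, collapse = ", "), "\n", sep = "")

write_gene_list(candidates, "results/human_candidates.txt")
write_gene_list(core, "results/cross_species_core.txt")
rep <- overlap_report(
  list(mouse_network = mouse_list, spatial = spatial_hits,
       temporal = temporal_hits, candidates = candidates),
  path = "results/list_membership.tsv")
cat("Pairwise overlap counts:\n")
print(rep$counts)
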