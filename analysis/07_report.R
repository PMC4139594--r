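#!/usr/bin/env Rscript
# Stage 7: the full pipeline in one call, with the aggregated run report.

suppressMessages(library(vznet))

cfg <- pipeline_config(seed = 1L)
inputs <- simulate_inputs(cfg)
run <- run_pipeline(inputs, cfg, out_dir = file.path("results", "run"))
print(run)
cat("\nAll artifacts written to results/run\n")
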