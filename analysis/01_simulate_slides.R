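#!/usr/bin/env Rscript
# Step 1: simulate the study's slide material.
#
# Generates two default synthetic slides (multichannel DAPI/CK/CD45/
# brightfield, ~1500 px square at 0.5 um/px) with planted WBCs, epi./im.
# CTCs, LEVs, debris and tumor-immune pairs in the three relationships
# (pic / overlap / gap). Images go to scratch/ (they are bulky and fully
# reproducible from the seed); the ground-truth tables go to results/.

suppressMessages(library(picscore))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/slides", recursive = TRUE, showWarnings = FALSE)

seeds <- c(101, 102)
for (s in seeds) {
  cfg <- sim_config(seed = s)
  sim <- generate_slide(cfg)
  write_slide(sim, "scratch/slides", prefix = sprintf("slide%d", s))
  write.csv(sim$truth, sprintf("results/truth_slide%d.csv", s),
            row.names = FALSE)
  cat(sprintf("slide %d: %d planted objects (%s)\n", s, nrow(sim$truth),
              paste(sprintf("%s=%d", names(table(sim$truth$class)),
                            table(sim$truth$class)), collapse = ", ")))
}
cat("Slides written to scratch/slides, ground truth to results/.\n")
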