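#!/usr/bin/env Rscript
# Per-condition stability analysis: delta-Ct, BestKeeper, geNorm (with V
# series and optimal gene number), NormFinder and the RefFinder aggregate
# for each simulated condition from 01_simulate.R. One report bundle per
# condition under results/<condition>/.

suppressPackageStartupMessages(library(refstab))

conditions <- c("n10_stages", "s24_stages", "mixed_populations")

for (cond in conditions) {
  path <- file.path("results/synthetic", paste0(cond, ".csv"))
  if (!file.exists(path)) stop("run analysis/01_simulate.R first: ", path)
  bundle <- run_analysis(path, out_dir = file.path("results", cond),
                         quiet = TRUE)
  top <- names(which.min(bundle$reffinder$stability))
  cat(sprintf("%-18s RefFinder best: %-10s geNorm optimal n: %d%s\n",
              cond, top, bundle$genorm$optimal$n,
              if (bundle$genorm$optimal$decided) "" else " (no V < cutoff)"))
}
cat("per-condition bundles written under results/\n")
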