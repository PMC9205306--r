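#!/usr/bin/env Rscript
# Step 1: simulate the two study communities with known ground truth.
#
# Two synthetic species-mean trait tables mirror the two study designs:
# a moist-forest community (43 species, all 10 traits measured) and a
# dry-forest community (52 species, root traits measured for only 28).
# Both plant two trait modules; the module map is written alongside so the
# later network stage can be scored against it.

suppressPackageStartupMessages(library(traitnet))
seed <- 1
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sites <- list(moist = spec_moist_forest(), dry = spec_dry_forest())
for (s in names(sites)) {
  tree <- simulate_tree(sites[[s]]$n_species, seed = sub_seed(seed, paste0(s, "_tree")))
  tab <- simulate_traits(tree, sites[[s]], seed = sub_seed(seed, s), site = s)
  write_trait_table(tab, file.path(out, paste0(s, "_traits.csv")))
  ape::write.tree(tree, file.path(out, paste0(s, "_tree.nwk")))
  gt <- attr(tab, "ground_truth")$modules
  write.csv(data.frame(trait = names(gt), module = unname(gt)),
            file.path(out, paste0(s, "_truth.csv")), row.names = FALSE)
  cat(sprintf("%s: %d species x %d traits, %d missing cells, %d planted modules\n",
              s, nrow(tab$values), ncol(tab$values), sum(is.na(tab$values)),
              length(unique(gt))))
}
cat("wrote", out, "\n")
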