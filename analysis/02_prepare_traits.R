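#!/usr/bin/env Rscript
# Stage 2: curate the raw observations -- outlier trimming, genotype-year
# upright means, chimera shape descriptors from the categorical scores, and
# the trait correlation/cluster report.

library(cranmetaqtl)
source("analysis/00_config.R")

phen <- read.csv(file.path(DATA_DIR, "phenotypes.csv"),
                 colClasses = c(year = "character"))
scores <- read.csv(file.path(DATA_DIR, "shape_scores.csv"),
                   colClasses = c(year = "character"))

trimmed <- trim_outliers(phen)
cat(sprintf("outlier trimming removed %d of %d observations\n",
            nrow(trimmed$log), nrow(phen)))
write.csv(trimmed$log, file.path(RESULTS, "removal_log.csv"),
          row.names = FALSE)

means <- upright_means(trimmed$data)

# chimera descriptors per genotype-year from the categorical shape scores
templates <- shape_templates(CFG$shape$template_size, CFG$shape$template_area)
desc <- chimera_descriptors(scores, templates)
write.csv(desc, file.path(RESULTS, "chimera_descriptors.csv"),
          row.names = FALSE)

# fold the digital shape traits into the means table
desc_long <- do.call(rbind, lapply(
  c("UKEC", "UKLvW", "UKTO", "UKSO", "UKUX", "UKUY"), function(tr)
    data.frame(genotype = desc$genotype, year = desc$year, trait = tr,
               mean_value = desc[[tr]], n_uprights = CFG$traits$uprights)))
means <- rbind(means, desc_long)
write.csv(means, file.path(RESULTS, "upright_means.csv"), row.names = FALSE)

cc <- correlation_cliques(means)
write.csv(round(cc$r, 4), file.path(RESULTS, "trait_correlations.csv"))
clust <- data.frame(trait = names(cc$clusters), cluster = cc$clusters)
write.csv(clust, file.path(RESULTS, "trait_clusters.csv"), row.names = FALSE)

cat("non-singleton correlation clusters:\n")
for (k in unique(cc$clusters))
  cat(sprintf("  cluster %d: %s\n", k,
              paste(names(cc$clusters)[cc$clusters == k], collapse = ", ")))
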