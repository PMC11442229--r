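#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- linkage map, four-way cross,
# field layout, two quantitative traits with known architecture, and
# categorical berry-shape scores whose class distribution is driven by a
# shape locus (so the digital shape descriptors should map back to it).

library(cranmetaqtl)
source("analysis/00_config.R")

map <- simulate_map(CFG$map$n_lg, CFG$map$markers_per_lg, CFG$map$length_cm,
                    seed = MASTER_SEED)
geno <- simulate_cross(map, CFG$cross$n_progeny, seed = MASTER_SEED + 1)
layout <- simulate_layout(rownames(geno), seed = MASTER_SEED + 2)
A <- compute_A(fourway_dosage(geno))

# trait "MASS": one strong maternal QTL on LG1 plus a paternal QTL on LG4,
# polygenic background drawn with covariance A, GxY, spatial trend
arch_mass <- trait_architecture(
  qtl = data.frame(linkage_group = c(1, 4), position = c(40, 20),
                   maternal = c(1.0, 0), paternal = c(0, 0.8),
                   interaction = c(0, 0)),
  polygenic_variance = 0.5, residual_variance = 1, gxy_variance = 0.2,
  spatial_amplitude = 0.5, mu = 10,
  year_effects = c("2011" = 0, "2012" = 0.5, "2013" = -0.3))
sim_mass <- simulate_traits(geno, map, arch_mass, layout, CFG$traits$years,
                            CFG$traits$uprights, seed = MASTER_SEED + 3,
                            trait = "MASS", polygenic_K = A)

# trait "TY": purely polygenic, for a heritability contrast
arch_ty <- trait_architecture(
  polygenic_variance = 2, residual_variance = 2, gxy_variance = 0.5, mu = 300,
  year_effects = c("2011" = 0, "2012" = 20, "2013" = -10))
sim_ty <- simulate_traits(geno, map, arch_ty, layout, CFG$traits$years,
                          CFG$traits$uprights, seed = MASTER_SEED + 4,
                          trait = "TY", polygenic_K = A)

# berry-shape scores: the shape locus on LG3 shifts class odds from round
# toward oblong/spindle for maternal-B carriers
shape_mk <- map$marker_id[map$linkage_group == 3][6]
is_A <- substr(geno[, shape_mk], 1, 1) == "A"
bias <- matrix(rep(c(0.45, 0.30, 0.15, 0.05, 0.05), each = nrow(geno)),
               nrow(geno), 5)
bias[!is_A, ] <- matrix(rep(c(0.05, 0.10, 0.35, 0.15, 0.35),
                            each = sum(!is_A)), sum(!is_A), 5)
scores <- simulate_shape_scores(nrow(geno), CFG$traits$uprights, bias,
                                years = CFG$traits$years,
                                seed = MASTER_SEED + 5)

phen <- rbind(sim_mass$phenotypes, sim_ty$phenotypes)
write.csv(map, file.path(DATA_DIR, "map.csv"), row.names = FALSE)
write.csv(data.frame(progeny = rownames(geno), geno, check.names = FALSE),
          file.path(DATA_DIR, "genotypes.csv"), row.names = FALSE)
write.csv(layout, file.path(DATA_DIR, "layout.csv"), row.names = FALSE)
write.csv(phen, file.path(DATA_DIR, "phenotypes.csv"), row.names = FALSE)
write.csv(rbind(cbind(trait = "MASS", sim_mass$truth$components),
                cbind(trait = "TY", sim_ty$truth$components)),
          file.path(DATA_DIR, "truth_components.csv"), row.names = FALSE)
write.csv(scores, file.path(DATA_DIR, "shape_scores.csv"), row.names = FALSE)

cat(sprintf("map: %d markers on %d linkage groups\n", nrow(map),
            length(unique(map$linkage_group))))
cat(sprintf("cross: %d progeny, %d phenotype records, shape locus at %s\n",
            nrow(geno), nrow(phen), shape_mk))
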