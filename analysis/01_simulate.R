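#!/usr/bin/env Rscript
# Build the synthetic full-sib mapping population used by the downstream
# analyses: 200 F1 individuals, 20 linkage groups x 30 markers (~17%
# intercross), and a correlated leaf-trait pair (LL, LW) carrying two
# planted pleiotropic QTLs -- a testcross QTL on lg16 and an additive
# intercross QTL on lg18.  Phenotypes are rescaled to realistic leaf
# dimensions (cm); the LR scan is affine invariant, so this is cosmetic.

library(covqtl)

out_dir <- "results/simdata"
seed <- 20260924

cfg <- sim_config(
  n_individuals = 200L,
  groups = data.frame(n_markers = rep(30L, 20L), length_cM = rep(157.6, 20L)),
  rho = 0.5,
  qtls = list(
    list(lg = 16, pos_cM = 75, effects = rbind(c(0, 0), c(0.8, 0.8))),
    list(lg = 18, pos_cM = 49,
         effects = rbind(c(0, 0), c(0.4, 0.4), c(0.8, 0.8)))),
  trait_names = c("LL", "LW"))
sim <- simulate_population(cfg, seed = seed)

# cosmetic rescale to leaf length/width in cm
sim$phen$LL <- 17.84 + 2.8 * sim$phen$LL
sim$phen$LW <- 13.43 + 2.2 * sim$phen$LW

dd <- dedup_markers(sim$map)
sim$map <- dd
seg <- segregation_check(sim$map)

write_simulation(sim, out_dir)
write.table(seg, file.path(out_dir, "segregation_check.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("Simulated %d individuals, %d markers on %d linkage groups (%d duplicate markers dropped).",
                n_individuals(sim$map), n_markers(sim$map),
                length(unique(sim$map$markers$lg)), dd$n_dropped))
message(sprintf("Seg types: %s.",
                paste(names(table(sim$map$markers$seg_type)),
                      table(sim$map$markers$seg_type),
                      sep = "=", collapse = ", ")))
message(sprintf("Markers with segregation-distortion p < 0.01: %d of %d.",
                sum(seg$p_value < 0.01), nrow(seg)))
for (q in sim$truth$qtls) {
  message(sprintf("Planted QTL at %s (%s, %.1f cM, %s).",
                  q$marker, q$lg, q$pos_cM, q$seg_type))
}
message("Wrote ", out_dir, "/{genotypes.tsv,phenotypes.csv,truth.tsv,segregation_check.tsv}")
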