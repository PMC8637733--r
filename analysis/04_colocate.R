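#!/usr/bin/env Rscript
# Scan the remaining leaf trait pairs (LL-L_W, LW-L_W) and collate
# significant covQTLs across pairs.  Both planted QTLs shift LL and LW
# jointly, so their markers should co-locate across several pairs --
# the signature of pleiotropic control of trait covariation.

library(covqtl)

in_dir <- "results/simdata"
seed <- 20260924 + 3

map <- read_genotype_map(file.path(in_dir, "genotypes.tsv"))
phen <- read_phenotypes(file.path(in_dir, "phenotypes_derived.csv"), map = map)

pairs <- list(c("LL", "LW"), c("LL", "L_W"), c("LW", "L_W"))
calls <- lapply(seq_along(pairs), function(i) {
  p <- pairs[[i]]
  sc <- scan_pair(map, phen, p)
  thr <- permutation_threshold(map, phen, p, n_perm = 1000L,
                               alpha = 0.05, seed = seed + i)
  out <- call_significant(set_threshold(sc, thr, alpha = 0.05,
                                        n_perm = 1000L, seed = seed + i))
  message(sprintf("%s-%s: threshold %.2f, %d covQTLs",
                  p[1], p[2], thr, nrow(out)))
  out
})

co <- colocate(calls, min_pairs = 2L)
write.table(co, "results/colocation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("Total covQTL calls %d; unique markers %d; markers in >= 2 pairs: %d.",
                attr(co, "n_total"), attr(co, "n_unique"), attr(co, "n_ge_k")))
shared <- co[co$n_pairs >= 2, ]
for (i in seq_len(nrow(shared))) {
  message(sprintf("  %s (%s, %.1f cM) significant for: %s",
                  shared$marker[i], shared$lg[i], shared$pos_cM[i],
                  shared$pairs[i]))
}
message("Wrote results/colocation.tsv")
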