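#!/usr/bin/env Rscript
# Append derived traits to the simulated phenotypes.  Stem measurements
# (DBH in mm, H in m, WD in g/cm^3) are synthetic draws emulating a young
# full-sib trial -- DBH around 17.6 mm, height around 2.9 m, wood density
# around 0.36 g/cm^3, with height and diameter positively correlated --
# and are marked as such; they exist to exercise the derived-trait chain:
# V = 0.785 * DBH^2 * H (DBH converted to m, so V is in m^3),
# SB = V * WD (WD converted to kg/m^3, so SB is in kg), L_W = LL / LW.

library(covqtl)

in_dir <- "results/simdata"
map <- read_genotype_map(file.path(in_dir, "genotypes.tsv"))
phen <- read_phenotypes(file.path(in_dir, "phenotypes.csv"), map = map)

set.seed(20260924 + 1)
n <- nrow(phen)
z <- rnorm(n)
phen$DBH <- pmax(17.63 + 3.0 * z + rnorm(n, sd = 1.0), 5)       # mm
phen$H <- pmax(2.90 + 0.45 * (0.6 * z + 0.8 * rnorm(n)), 0.5)   # m
phen$WD <- pmax(0.36 + 0.04 * rnorm(n), 0.15)                   # g/cm^3

phen <- derive_traits(phen, dbh_unit = "mm")
write_phenotypes(phen, file.path(in_dir, "phenotypes_derived.csv"))

message(sprintf("Derived traits for %d individuals.", n))
message(sprintf("Mean DBH %.2f mm, H %.2f m, WD %.3f g/cm^3.",
                mean(phen$DBH), mean(phen$H), mean(phen$WD)))
message(sprintf("Mean stemwood volume V = %.5f m^3, biomass SB = %.3f kg, L/W = %.3f.",
                mean(phen$V), mean(phen$SB), mean(phen$L_W)))
message("Wrote ", in_dir, "/phenotypes_derived.csv with columns V, SB, L_W appended.")
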