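#!/usr/bin/env Rscript
# Generate the synthetic breeding population: 147 phenotyped queens over
# two seasons (70 + 77) from 10 + 7 maternal sister lines that share
# grand-dams, each line's dam mated at an isolated station to 12 drones
# from the year's 12 drone-producing colonies.  Trait marginals and
# genetic parameters are calibrated to the study population; spermatheca
# volume is derived per queen from three replicate diameter measurements
# by the sphere formula.  Writes the pedigree, sire-group and phenotype
# tables under results/sim/.

suppressPackageStartupMessages(library(apisqg))

seed <- 2026L
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

design <- breeding_design()
model <- default_trait_model()

ped <- generate_pedigree(design, seed = seed)
A <- compute_kinship(ped)
pheno <- simulate_phenotypes(ped, A, model, design, seed = seed + 1L)
pheno <- inject_defect_flags(pheno, default_defect_rates(), seed = seed + 2L)

write_pedigree(ped, file.path(out_dir, "pedigree.csv"),
               file.path(out_dir, "sire_groups.csv"))
write_phenotypes(pheno, file.path(out_dir, "phenotypes.csv"))

ids <- phenotyped_ids(ped)
yr <- ped$queens$year[match(ids, ped$queens$id)]
cat("Simulated population\n")
cat("  queens in pedigree:  ", nrow(ped$queens), "\n")
cat("  phenotyped queens:   ", length(ids), "(",
    paste(table(yr), collapse = " + "), ")\n")
cat("  maternal lines:      ",
    length(unique(ped$queens$dam_id[match(ids, ped$queens$id)])), "\n")
cat("  sire groups:         ", nrow(ped$groups), "\n")
cat("  traits recorded:     ",
    paste(setdiff(names(pheno)[!startsWith(names(pheno), "defect_")],
                  c("queen_id", "year", "week")), collapse = " "), "\n")
cat("  sperm-count records: ", sum(!is.na(pheno$sp)), "of", length(ids), "\n")
cat("Files written to", out_dir, "\n")
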