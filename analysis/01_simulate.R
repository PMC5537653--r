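#!/usr/bin/env Rscript

# Stage 1: simulate a synthetic sinorhizobial-style virome.
#
# Ten temperate phages share protein families planted at three identity
# levels (90% for strongly conserved proteins such as holins/endolysins,
# 75% for typical shared modules, 60% for weakly related ones); marker
# families (terminase large subunit, major capsid protein, integrase) are
# laid out so that TerL and MCP cluster congruently while integrases are
# fragmented. Unlabeled proteins default to ~70% "hypothetical protein".
# Two host replicons carry planted prophages flanked by 17 bp and 57 bp
# direct repeats overlapping tRNA genes, with MTase genes adjacent to the
# replication module.

suppressPackageStartupMessages(library(viromenet))

out_dir <- "results/data"
phages <- sprintf("P%02d", 1:10)
set.seed(1021)  # governs the random choices in the specs below

families <- c(
  # congruent markers: TerL and MCP split the phages the same way
  list(
    family_spec("TERL_A", phages[1:5], 420, 75, "terminase large subunit"),
    family_spec("TERL_B", phages[6:10], 430, 75, "terminase large subunit"),
    family_spec("MCP_A", phages[1:5], 330, 75, "major capsid protein"),
    family_spec("MCP_B", phages[6:10], 340, 75, "major capsid protein"),
    # integrases: fragmented into small, weakly related groups
    family_spec("INT_A", phages[1:2], 360, 60, "integrase"),
    family_spec("INT_B", phages[3:4], 360, 60, "integrase"),
    family_spec("INT_C", phages[5:6], 365, 60, "integrase"),
    # conserved lysis proteins
    family_spec("HOL_A", phages[1:8], 110, 90, "holin"),
    family_spec("LYS_A", phages[1:8], 250, 90, "endolysin"),
    # MTases carrying the amino-MTase catalytic motif
    family_spec("MTA_A", phages[c(1, 3, 5, 7)], 300, 75,
                "adenine DNA methyltransferase", plant_motif = "NPPW"),
    family_spec("MTA_B", phages[c(2, 4)], 280, 75,
                "adenine DNA methyltransferase", plant_motif = "NPPY")),
  # unlabeled shared families at the three identity levels
  lapply(1:12, function(k) {
    ident <- c(60, 75, 90)[1 + (k %% 3)]
    size <- 2 + (k %% 5)
    family_spec(sprintf("FAM%02d", k), sample(phages, size),
                sample(150:350, 1), ident)
  })
)

config <- synth_config(1021, families = families, n_singletons = 120)

prophages <- list(
  prophage_spec(prophage_length = 40000, att_repeat_length = 17,
                trna_isotype = "tRNA-Phe(GAA)"),
  prophage_spec(prophage_length = 40000, att_repeat_length = 57,
                trna_isotype = "tRNA-Pro(CGG)"))

paths <- run_simulate(config, out_dir, prophages = prophages)
cat("wrote:\n")
print(paths)
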