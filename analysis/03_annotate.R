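#!/usr/bin/env Rscript

# Stage 3: cluster-based annotation transfer, marker congruence and MTase
# motif scanning. Hypothetical proteins inherit the majority product of
# annotated proteins sharing their component; TerL-vs-MCP and TerL-vs-
# integrase clustering agreement is quantified by the adjusted Rand index;
# proteins are scanned for the amino-MTase catalytic motif NPP(Y/W/F) and
# MTase genes are placed relative to the replication module.

suppressPackageStartupMessages(library(viromenet))

res <- run_annotate("results/data/proteins.fasta",
                    "results/network/components.tsv",
                    "results/annotation",
                    features_gff3 = "results/data/features.gff3")

proteins <- read_protein_fasta("results/data/proteins.fasta")
partition <- read.delim("results/network/components.tsv",
                        stringsAsFactors = FALSE)

cat(sprintf("\n%d hypothetical proteins received a suggested function\n",
            nrow(res$suggestions)))
if (nrow(res$suggestions) > 0)
  print(utils::head(res$suggestions))

# marker congruence over phages carrying both markers; the marker protein
# sets come from the generator truth so that background singletons that
# happen to draw a marker-like label do not enter the marker panels
truth <- read.delim("results/data/truth.tsv", stringsAsFactors = FALSE)
marker_partition <- function(prefix) {
  ids <- truth$protein_id[grepl(prefix, truth$family_id)]
  partition[partition$protein_id %in% ids, c("protein_id", "component_id")]
}
p2p <- proteins[, c("protein_id", "phage_id")]
terl <- marker_partition("^TERL_")
mcp <- marker_partition("^MCP_")
int <- marker_partition("^INT_")

cong <- list(
  marker_congruence(terl, mcp, p2p, "TerL", "MCP"),
  marker_congruence(terl, int, p2p, "TerL", "integrase"))
for (cg in cong)
  cat(sprintf("congruence %s vs %s over %d shared phages: ARI = %s\n",
              cg$marker_a, cg$marker_b, cg$n_shared_phages,
              format(cg$adjusted_rand, digits = 3)))
jsonlite::write_json(cong, "results/annotation/congruence.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

calls <- res$mtase_calls
cat(sprintf("\n%d NPP(Y/W/F) motif calls in %d proteins\n",
            nrow(calls), length(unique(calls$protein_id))))
mtase_products <- proteins$product[match(calls$protein_id,
                                         proteins$protein_id)]
cat(sprintf("of which %d are in annotated MTases\n",
            sum(grepl("methyltransferase", mtase_products), na.rm = TRUE)))
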