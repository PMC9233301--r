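#!/usr/bin/env Rscript
# Step 3 — relationships between clusters: copying vectors, nnls sharing
# profiles, total variation distance and Hudson's Fst.
#
# Uses the chunklength matrix and cluster assignment from 02_paint_cluster.R
# at the tier matching the simulated subpopulations, and the phased panel
# for allele-frequency statistics.

suppressMessages(library(hapsharing))
data_dir <- "results/data"
paint_dir <- "results/paint"
out <- "results/profiles"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

chunklengths <- as.matrix(read.table(file.path(paint_dir, "chunklengths.tsv"),
                                     header = TRUE, row.names = 1L, check.names = FALSE))
cl_tab <- read.table(file.path(paint_dir, "clusters.tsv"), header = TRUE,
                     colClasses = "character")
# first-tier assignment: the subpopulation level
tier1 <- vapply(strsplit(cl_tab$cluster, ".", fixed = TRUE), `[[`, "", 1L)
assignment <- setNames(tier1, cl_tab$id)

cv <- copying_vectors(chunklengths, assignment)
message("copying vectors (rows = clusters):")
print(round(cv, 3))

beta <- nnls_profiles(chunklengths, assignment)
tvd_m <- tvd_matrix(cv)
panel <- read_phased_vcf(file.path(data_dir, "structured.vcf"),
                         file.path(data_dir, "structured.map"))
fst_m <- fst_matrix(panel, assignment)
write_profiles(beta, tvd_m, fst_m, out)

message("pairwise TVD:")
print(round(tvd_m, 3))
message("pairwise Hudson Fst:")
print(round(fst_m, 4))
message("nnls sharing profiles (rows = targets):")
print(round(beta, 3))
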