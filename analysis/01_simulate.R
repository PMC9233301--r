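#!/usr/bin/env Rscript
# Step 1 — simulate the study panels.
#
# Three desk-scale cohorts drive the downstream analyses:
#   structured : four subpopulations exchanging 0.1% of couples per
#                generation, the substrate for painting, clustering and
#                profile analyses;
#   constant   : one population of constant diploid size 500, the substrate
#                for IBD detection benchmarking and Ne estimation;
#   regimes    : random-mating, consanguineous (30% first-cousin unions) and
#                bottlenecked cohorts for the inbreeding contrasts.
# Each panel is written as phased VCF + PLINK map + labels, together with
# ground-truth IBD segments for the constant-size cohort.

suppressMessages(library(hapsharing))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

message("structured panel: 4 x 60 diploids, 30 generations, 2 x 50 cM")
mig <- matrix(0.001, 4L, 4L); diag(mig) <- 1 - 3 * 0.001
cfg_s <- sim_config(4L, 60L, 30L, migration = mig,
                    chromosomes = data.frame(length_cM = c(50, 50),
                                             n_sites = c(1500L, 1500L)),
                    seed = derive_seed(seed, 1L))
sim_s <- simulate_panel(cfg_s)
write_phased_vcf(sim_s$panel, file.path(out, "structured.vcf"))
write_plink_map(sim_s$panel, file.path(out, "structured.map"))
write_labels(sim_s$labels, file.path(out, "structured_labels.tsv"))

message("constant-size panel: 500 diploids (200 sampled), 50 generations, 2 x 100 cM")
cfg_c <- sim_config(1L, 500L, 50L,
                    chromosomes = data.frame(length_cM = c(100, 100),
                                             n_sites = c(5000L, 5000L)),
                    seed = derive_seed(seed, 2L))
mos_c <- transmit_haplotypes(simulate_pedigree(cfg_c), cfg_c)
set.seed(derive_seed(seed, 3L))
mos_c <- subset_individuals(mos_c, sort(sample.int(500L, 200L)))
panel_c <- genotype_panel(mos_c, cfg_c)
write_phased_vcf(panel_c, file.path(out, "constant.vcf"))
write_plink_map(panel_c, file.path(out, "constant.map"))
truth_c <- truth_ibd(mos_c, min_cM = 2)
write_truth_ibd(truth_c, file.path(out, "constant_truth_ibd.tsv"))
message(sprintf("  %d truth segments >= 2 cM", nrow(truth_c)))

message("inbreeding regime panels (3 x 100 cM genomes)")
for (rg in list(list(name = "random", n = 200L, G = 25L, cousin = 0),
                list(name = "consanguineous", n = 200L, G = 25L, cousin = 0.3),
                list(name = "bottleneck", n = 100L, G = 50L, cousin = 0))) {
  cfg_r <- sim_config(1L, rg$n, rg$G, cousin_mating_rate = rg$cousin,
                      chromosomes = data.frame(length_cM = rep(100, 3L),
                                               n_sites = rep(4000L, 3L)),
                      seed = derive_seed(seed, 4L))
  sim_r <- simulate_panel(cfg_r)
  write_phased_vcf(sim_r$panel, file.path(out, paste0(rg$name, ".vcf")))
  write_plink_map(sim_r$panel, file.path(out, paste0(rg$name, ".map")))
  message(sprintf("  %-14s %d diploids, %d generations", rg$name, rg$n, rg$G))
}
message("done: panels in ", out)
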