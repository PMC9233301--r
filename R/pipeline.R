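#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Input is either a
#' simulation ([sim_config()]) or a phased VCF with genetic map and label
#' table. All randomized stages derive their seeds from `seed`
#' (see [derive_seed()]).
#'
#' @param sim a [sim_config()], or `NULL` to read files.
#' @param vcf,map,labels input paths when `sim` is `NULL`; `labels` is a
#'   two-column TSV (id, label).
#' @param out_dir output directory.
#' @param paint a [paint_config()].
#' @param edge_low,edge_high strict chunkcount edge filter bounds.
#' @param leiden_depth,min_community,leiden_resolution Leiden recursion
#'   settings.
#' @param ibd_min_cm detection threshold (cM).
#' @param merge_gap_cm,merge_max_discordant gap-merge rule.
#' @param ne_min_cm segment selection threshold for Ne fitting.
#' @param ne_generations,bootstrap Ne fit settings.
#' @param roh a [roh_params()].
#' @param qc a [qc_params()].
#' @param cluster_groups optional named vector mapping leaf clusters to the
#'   coarser groups used for F_SNP frequencies (default: leaf clusters).
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, vcf = NULL, map = NULL, labels = NULL,
                            out_dir = "hapsharing_out",
                            paint = paint_config(),
                            edge_low = 2, edge_high = 25,
                            leiden_depth = 4L, min_community = 100L,
                            leiden_resolution = 1,
                            ibd_min_cm = 1, merge_gap_cm = 0.6,
                            merge_max_discordant = 1L,
                            ne_min_cm = 4, ne_generations = 50L,
                            bootstrap = 100L,
                            roh = roh_params(), qc = qc_params(),
                            cluster_groups = NULL, seed = 1L) {
  if (is.null(sim)) {
    for (p in c(vcf, map, labels))
      if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s", p)
    if (is.null(vcf)) stopf("either a simulation config or a VCF is required")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full haplotype-sharing pipeline
#'
#' Simulate (or load) a phased panel, then: QC report, PBWT painting,
#' coancestry PCA, edge-filtered network, recursive Leiden clustering, nnls
#' sharing profiles with TVD and Fst, IBD detection and gap merging,
#' within-cluster sharing summaries, Ne fitting, ROH scan and inbreeding
#' coefficients. Every stage's tables are written under `out_dir` together
#' with a machine-readable manifest; stage progress is logged via
#' `message()`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(fmt, ...) message(sprintf(paste0("[hapsharing] ", fmt), ...))

  if (!is.null(config$sim)) {
    log("simulating panel (seed %d)", config$sim$seed)
    sim <- simulate_panel(config$sim)
    panel <- sim$panel
    labels <- sim$labels
    truth <- NULL
    write_phased_vcf(panel, file.path(config$out_dir, "panel.vcf"))
    write_plink_map(panel, file.path(config$out_dir, "panel.map"))
    write_labels(labels, file.path(config$out_dir, "labels.tsv"))
  } else {
    log("reading %s", config$vcf)
    panel <- read_phased_vcf(config$vcf, config$map)
    labels <- NULL
    if (!is.null(config$labels)) {
      lt <- read.table(config$labels, header = TRUE, sep = "\t")
      labels <- setNames(as.character(lt[[2L]]), as.character(lt[[1L]]))
    }
  }
  log("panel: %d individuals, %d sites", length(panel$indiv), nrow(panel$sites))

  gt <- panel_genotypes(panel)
  qc <- qc_filter(gt$geno, gt$sites, config$qc)
  log("QC removals: %s", paste(names(qc$report), qc$report, sep = "=", collapse = ", "))
  write.table(data.frame(reason = names(qc$report), n = as.integer(qc$report)),
              file.path(config$out_dir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log("painting (%d haplotypes)", ncol(panel$alleles))
  pc <- config$paint
  pc$seed <- derive_seed(config$seed, 11L)
  coan <- paint_panel(panel, pc)
  write_coancestry(coan, config$out_dir)
  pca <- coancestry_pca(coan, k = min(4L, length(panel$indiv)))
  write.table(data.frame(id = rownames(pca), pca),
              file.path(config$out_dir, "coancestry_pca.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log("network + Leiden clustering")
  g <- build_graph(coan, config$edge_low, config$edge_high)
  tree <- leiden_recursive(g, max_depth = config$leiden_depth,
                           min_size = config$min_community,
                           resolution = config$leiden_resolution,
                           seed = derive_seed(config$seed, 13L))
  write_clusters(tree, config$out_dir)
  log("%d leaf clusters", length(tree$leaves))

  assignment <- tree$assignment
  profiles <- NULL
  if (length(tree$leaves) >= 2L) {
    log("sharing profiles (nnls, TVD, Fst)")
    cv <- copying_vectors(coan, assignment)
    beta <- nnls_profiles(coan, assignment)
    write_profiles(beta, tvd_matrix(cv), fst_matrix(panel, assignment),
                   config$out_dir)
    profiles <- list(copying = cv, beta = beta)
  } else log("single cluster; profiles skipped")

  log("IBD detection (min %.2f cM)", config$ibd_min_cm)
  segs <- detect_ibd(panel, config$ibd_min_cm)
  segs <- merge_ibd(segs, panel, config$merge_gap_cm, config$merge_max_discordant)
  write_ibd(segs, file.path(config$out_dir, "ibd_segments.tsv"))
  shares <- sharing_summary(segs, assignment)
  write.table(shares, file.path(config$out_dir, "ibd_sharing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log("%d IBD segments", nrow(segs))

  log("Ne fitting (segments > %.1f cM, %d bootstraps)",
      config$ne_min_cm, config$bootstrap)
  chrom_len <- tapply(panel$sites$cM, panel$sites$chrom,
                      function(v) max(v) - min(v))
  ne_fits <- list()
  for (cl in names(tree$leaves)) {
    members <- tree$leaves[[cl]]
    within <- segs[segs$id_a %in% members & segs$id_b %in% members &
                     segs$length_cM > config$ne_min_cm, , drop = FALSE]
    if (nrow(within) < 10L) next
    sp <- segment_spectrum(within, members, chrom_lengths_cM = as.numeric(chrom_len))
    ne_fits[[cl]] <- fit_ne(sp, G = config$ne_generations,
                            n_bootstrap = config$bootstrap,
                            seed = derive_seed(config$seed, 17L))
    write_ne(ne_fits[[cl]],
             file.path(config$out_dir, sprintf("ne_cluster_%s.tsv", cl)),
             file.path(config$out_dir, sprintf("ne_cluster_%s_summary.tsv", cl)))
  }

  log("ROH scan + inbreeding coefficients")
  roh <- detect_roh(gt, params = config$roh)
  genome_bp <- sum(tapply(panel$sites$bp, panel$sites$chrom,
                          function(v) max(v) - min(v)))
  froh <- f_roh(roh, genome_bp = genome_bp, ids = panel$indiv)
  groups <- assignment
  if (!is.null(config$cluster_groups))
    groups <- setNames(config$cluster_groups[assignment], names(assignment))
  fsnp <- f_snp(gt, groups)
  inb <- cbind(fsnp[, c("id", "group")], F_ROH = froh[fsnp$id],
               fsnp[, c("F_SNP", "O_HOM", "E_HOM", "N")])
  write_inbreeding(roh, inb, config$out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hapsharing")),
    seed = config$seed,
    n_individuals = length(panel$indiv),
    n_sites = nrow(panel$sites),
    n_clusters = length(tree$leaves),
    n_ibd_segments = nrow(segs),
    parameters = list(edge_low = config$edge_low, edge_high = config$edge_high,
                      leiden_depth = config$leiden_depth,
                      min_community = config$min_community,
                      ibd_min_cm = config$ibd_min_cm,
                      merge_gap_cm = config$merge_gap_cm,
                      ne_min_cm = config$ne_min_cm,
                      bootstrap = config$bootstrap))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(manifest, file.path(config$out_dir, "manifest.R"))
  }
  log("done: outputs in %s", config$out_dir)
  invisible(list(panel = panel, coancestry = coan, graph = g, tree = tree,
                 profiles = profiles, segments = segs, sharing = shares,
                 ne = ne_fits, roh = roh, inbreeding = inb, qc = qc))
}
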