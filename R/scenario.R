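#' Generate the default synthetic study and its pipeline configuration
#'
#' Builds a complete, self-consistent synthetic input set at desk scale:
#' a KGML pathway collection with heavy-tailed degree structure over a gene
#' sub-universe, an NB count matrix over a larger gene universe with DE
#' planted on a chosen number of network hub genes (the planted markers)
#' plus background genes chosen outside the hub set, a GMT file of the
#' pathway memberships, and the label/id-map sidecar files. The returned
#' truth manifest records the planted DE genes, hub genes, and their
#' intersection — the marker set an end-to-end pipeline run should recover.
#'
#' @param out_dir directory for all generated files.
#' @param seed integer master seed; sub-stage seeds are derived from it.
#' @param n_genes total genes in the count matrix.
#' @param n_tumor,n_normal group sizes.
#' @param n_pathway_genes size of the pathway gene sub-universe.
#' @param n_pathways number of KGML files.
#' @param n_marker_hubs how many hub genes get DE planted on them (capped at
#'   the number of hubs the pathway generator produced).
#' @param frac_de overall fraction of DE genes.
#' @param lfc_magnitude,dispersion passed to [simulate_counts()].
#' @param attachment_param passed to [simulate_kgml()].
#' @return List: `config` (a `RunConfig` ready for [run_pipeline()]),
#'   `truth` (`SimTruth` with `de_genes`, `hub_genes` and `marker_genes`),
#'   and `paths` of the generated files.
#' @export
synthetic_scenario <- function(out_dir = tempfile("scenario"), seed = 1,
                               n_genes = 2000, n_tumor = 150, n_normal = 100,
                               n_pathway_genes = 300, n_pathways = 12,
                               n_marker_hubs = 12, frac_de = 0.1,
                               lfc_magnitude = 2, dispersion = 0.3,
                               attachment_param = 5.75) {
  stopifnot(n_pathway_genes <= n_genes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pathway_genes <- sprintf("PWG%04d", seq_len(n_pathway_genes))
  filler_genes <- sprintf("BKG%04d", seq_len(n_genes - n_pathway_genes))
  universe <- c(pathway_genes, filler_genes)

  kg <- simulate_kgml(n_pathways, pathway_genes,
                      attachment_param = attachment_param,
                      seed = seed, out_dir = file.path(out_dir, "kgml"))

  # plant DE on a subset of hubs (the intended markers) and fill the rest of
  # the DE quota from non-hub genes, so DE-intersect-hub == planted markers
  n_de <- round(frac_de * n_genes)
  marker_genes <- with_seed(seed + 1L, {
    sort(sample(kg$truth$hub_genes,
                min(n_marker_hubs, length(kg$truth$hub_genes))))
  })
  non_hub <- setdiff(universe, kg$truth$hub_genes)
  other_de <- with_seed(seed + 2L, {
    sort(sample(non_hub, max(0L, n_de - length(marker_genes))))
  })
  de_genes <- sort(c(marker_genes, other_de))

  sim <- simulate_counts(n_genes, n_tumor, n_normal,
                         lfc_magnitude = lfc_magnitude,
                         dispersion = dispersion, seed = seed + 3L,
                         gene_ids = universe, de_genes = de_genes)

  counts_path <- file.path(out_dir, "counts.tsv")
  labels_path <- file.path(out_dir, "labels.tsv")
  write_count_matrix(sim$counts, counts_path, labels_path)
  gmt_path <- file.path(out_dir, "pathways.gmt")
  write_gmt(kg$pathway_genes, gmt_path)

  truth <- structure(
    list(de_genes = de_genes, lfc = sim$truth$lfc,
         dispersion = sim$truth$dispersion,
         hub_genes = kg$truth$hub_genes,
         marker_genes = marker_genes,
         seed = as.integer(seed)),
    class = "SimTruth"
  )

  config <- pipeline_config(
    counts = counts_path, labels = labels_path,
    kgml_dir = file.path(out_dir, "kgml"),
    id_map = file.path(out_dir, "kgml", "id_map.tsv"),
    gmt = gmt_path,
    out_dir = file.path(out_dir, "run"),
    seed = seed
  )
  list(config = config, truth = truth,
       paths = list(counts = counts_path, labels = labels_path,
                    kgml = kg$paths, gmt = gmt_path,
                    id_map = config$id_map))
}
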