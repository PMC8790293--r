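#' Reference tables from the breast-cancer study
#'
#' Plain-text transcriptions of the study's published results ship with the
#' package: the 28 significantly enriched KEGG pathways (term, DEG overlap
#' count, enrichment p-value), the 23 candidate diagnostic marker genes
#' (symbol, network degree, differential-expression p-value, and whether the
#' gene had prior literature support), and the 12-gene literature-confirmed
#' list. These serve as worked-example inputs and test fixtures; they are
#' reference values, not recomputed results.
#'
#' @return `reference_pathways()` and `reference_markers()` return
#'   data.frames; `reference_literature_genes()` a character vector.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
reference_pathways <- function() {
  read.delim(system.file("extdata", "table1_pathways.tsv",
                         package = "pathmarker"),
             stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_markers <- function() {
  read.delim(system.file("extdata", "table2_markers.tsv",
                         package = "pathmarker"),
             stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_literature_genes <- function() {
  readLines(system.file("extdata", "literature_genes.txt",
                        package = "pathmarker"))
}

#' Copy the reference fixtures into a directory
#'
#' Writes the three reference tables ([reference_tables]) as TSV/text files
#' plus a JSON manifest describing them.
#'
#' @param out_dir target directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pathways = file.path(out_dir, "enriched_pathways.tsv"),
    markers = file.path(out_dir, "candidate_markers.tsv"),
    literature = file.path(out_dir, "literature_genes.txt")
  )
  write.table(reference_pathways(), paths$pathways, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(reference_markers(), paths$markers, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(reference_literature_genes(), paths$literature)
  manifest <- list(
    files = lapply(paths, normalizePath),
    n_pathways = nrow(reference_pathways()),
    n_markers = nrow(reference_markers()),
    n_literature_genes = length(reference_literature_genes())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
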