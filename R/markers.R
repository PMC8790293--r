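#' Intersect DEGs with network hub genes to form candidate markers
#'
#' A candidate diagnostic marker is a gene that is both differentially
#' expressed and a hub in the pathway interaction network. Symbols are
#' matched case-insensitively after whitespace stripping; mixed id
#' namespaces (KEGG ids vs symbols) must be resolved upstream via the id
#' map.
#'
#' @param degs a `DEGTable` (or any data.frame with `gene` and `PValue`
#'   columns, optionally `direction`).
#' @param hubs character vector of hub gene symbols.
#' @param degrees a `DegreeTable` supplying each marker's network degree.
#' @return data.frame of class `MarkerSet`, sorted alphabetically, with
#'   columns `gene`, `degree`, `p_value`, `direction`. An empty intersection
#'   returns an empty `MarkerSet` with a warning.
#' @export
intersect_markers <- function(degs, hubs, degrees) {
  stopifnot(is.data.frame(degs), all(c("gene", "PValue") %in% names(degs)),
            is.data.frame(degrees))
  norm <- function(x) toupper(trimws(x))
  deg_key <- norm(degs$gene)
  hub_key <- unique(norm(hubs))
  keep <- !duplicated(deg_key)
  degs <- degs[keep, , drop = FALSE]
  deg_key <- deg_key[keep]

  hit <- deg_key %in% hub_key
  if (!any(hit)) {
    warning("DEG list and hub set share no genes; marker set is empty")
  }
  sel <- degs[hit, , drop = FALSE]
  deg_lookup <- setNames(degrees$degree, norm(degrees$gene))
  out <- data.frame(
    gene = sel$gene,
    degree = as.integer(deg_lookup[norm(sel$gene)]),
    p_value = sel$PValue,
    direction = if ("direction" %in% names(sel)) sel$direction else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MarkerSet", "data.frame")
  out
}

#' Flag markers confirmed by a literature gene list
#'
#' Adds a logical `literature_confirmed` column: `TRUE` for markers whose
#' symbol appears in `confirmed` (case-insensitive, whitespace-stripped).
#'
#' @param markers a `MarkerSet` (or data.frame with a `gene` column).
#' @param confirmed character vector of confirmed gene symbols.
#' @return The input with a `literature_confirmed` column appended.
#' @export
annotate_literature <- function(markers, confirmed) {
  stopifnot(is.data.frame(markers), "gene" %in% names(markers))
  norm <- function(x) toupper(trimws(x))
  markers$literature_confirmed <- norm(markers$gene) %in% norm(confirmed)
  markers
}

#' Write a marker table to TSV
#'
#' Columns mirror the candidate-marker table shape: `gene`, `degree`,
#' `p_value`, plus `direction` and `literature_confirmed` when present.
#'
#' @param markers a `MarkerSet`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
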