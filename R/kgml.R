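#' Parse a KGML pathway document
#'
#' Reads a KGML (KEGG Markup Language) XML file into a structured pathway
#' model: the `entry` elements (pathway nodes), `relation` elements
#' (typed interactions: ECrel, PPrel, GErel, PCrel, maplink) and `group`
#' entries (complexes, with `component` children referencing other entries).
#'
#' Multi-id `name` attributes (e.g. `"hsa:1571 hsa:1572"`) are split on
#' whitespace. Unknown attributes are ignored. A relation endpoint that does
#' not resolve to an entry id, or a group without components, is a parse
#' error naming the offending element.
#'
#' @param x path to a KGML file, or a single string of KGML XML.
#' @return An object of class `PathwayDoc`: a list with `pathway_id`,
#'   `title`, `entries` (data.frame: `id`, `type`, `label`, list-column
#'   `names`), `relations` (data.frame: `entry1`, `entry2`, `type`,
#'   list-column `subtypes`) and `groups` (data.frame: `id`, list-column
#'   `components`).
#' @export
parse_kgml <- function(x) {
  doc <- xml2::read_xml(x)
  root <- xml2::xml_name(doc)
  if (root != "pathway") {
    stop("not a KGML document: root element is <", root, ">, expected <pathway>")
  }

  entry_nodes <- xml2::xml_find_all(doc, "./entry")
  entries <- data.frame(
    id = xml2::xml_attr(entry_nodes, "id"),
    type = xml2::xml_attr(entry_nodes, "type"),
    label = vapply(entry_nodes, function(e) {
      g <- xml2::xml_find_first(e, "./graphics")
      if (inherits(g, "xml_missing")) NA_character_ else xml2::xml_attr(g, "name")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  entries$names <- lapply(entry_nodes, function(e) {
    nm <- xml2::xml_attr(e, "name")
    if (is.na(nm) || !nzchar(nm)) character(0) else strsplit(trimws(nm), "\\s+")[[1]]
  })
  if (anyDuplicated(entries$id)) {
    stop("duplicate entry id(s): ",
         paste(unique(entries$id[duplicated(entries$id)]), collapse = ", "))
  }

  rel_nodes <- xml2::xml_find_all(doc, "./relation")
  relations <- data.frame(
    entry1 = xml2::xml_attr(rel_nodes, "entry1"),
    entry2 = xml2::xml_attr(rel_nodes, "entry2"),
    type = xml2::xml_attr(rel_nodes, "type"),
    stringsAsFactors = FALSE
  )
  relations$subtypes <- lapply(rel_nodes, function(r) {
    st <- xml2::xml_find_all(r, "./subtype")
    data.frame(name = xml2::xml_attr(st, "name"),
               value = xml2::xml_attr(st, "value"),
               stringsAsFactors = FALSE)
  })
  known <- c("ECrel", "PPrel", "GErel", "PCrel", "maplink")
  bad <- setdiff(unique(relations$type), known)
  if (length(bad)) {
    stop("unknown relation type(s): ", paste(bad, collapse = ", "))
  }
  dangling <- setdiff(unique(c(relations$entry1, relations$entry2)), entries$id)
  if (length(dangling)) {
    stop("relation endpoint(s) reference missing entry id(s): ",
         paste(dangling, collapse = ", "))
  }

  grp_idx <- which(entries$type == "group")
  groups <- data.frame(id = entries$id[grp_idx], stringsAsFactors = FALSE)
  groups$components <- lapply(entry_nodes[grp_idx], function(e) {
    xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id")
  })
  for (i in seq_along(grp_idx)) {
    comp <- groups$components[[i]]
    if (!length(comp)) {
      stop("group entry '", groups$id[i], "' has no components")
    }
    missing <- setdiff(comp, entries$id)
    if (length(missing)) {
      stop("group entry '", groups$id[i],
           "' references missing component id(s): ",
           paste(missing, collapse = ", "))
    }
  }

  structure(
    list(
      pathway_id = xml2::xml_attr(doc, "name"),
      title = xml2::xml_attr(doc, "title"),
      entries = entries,
      relations = relations,
      groups = groups
    ),
    class = "PathwayDoc"
  )
}

#' @export
print.PathwayDoc <- function(x, ...) {
  cat(sprintf("PathwayDoc %s (%s): %d entries, %d relations, %d groups\n",
              x$pathway_id, x$title, nrow(x$entries), nrow(x$relations),
              nrow(x$groups)))
  invisible(x)
}

#' Serialize a pathway model back to KGML XML
#'
#' Inverse of [parse_kgml()] for the fields the model captures; a
#' parse-write-parse round trip is lossless on entries, relations and groups.
#'
#' @param doc a `PathwayDoc`.
#' @param path output file path; if `NULL`, the XML is returned as a string.
#' @return `path` invisibly, or the XML string when `path` is `NULL`.
#' @export
write_kgml <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "PathwayDoc"))
  xml <- xml2::xml_new_root(
    "pathway",
    name = doc$pathway_id,
    title = if (is.na(doc$title)) NULL else doc$title
  )
  comp_of <- setNames(doc$groups$components, doc$groups$id)
  for (i in seq_len(nrow(doc$entries))) {
    e <- xml2::xml_add_child(xml, "entry",
                             id = doc$entries$id[i],
                             name = paste(doc$entries$names[[i]], collapse = " "),
                             type = doc$entries$type[i])
    if (!is.na(doc$entries$label[i])) {
      xml2::xml_add_child(e, "graphics", name = doc$entries$label[i])
    }
    if (doc$entries$type[i] == "group") {
      for (cid in comp_of[[doc$entries$id[i]]]) {
        xml2::xml_add_child(e, "component", id = cid)
      }
    }
  }
  for (i in seq_len(nrow(doc$relations))) {
    r <- xml2::xml_add_child(xml, "relation",
                             entry1 = doc$relations$entry1[i],
                             entry2 = doc$relations$entry2[i],
                             type = doc$relations$type[i])
    st <- doc$relations$subtypes[[i]]
    for (j in seq_len(NROW(st))) {
      xml2::xml_add_child(r, "subtype", name = st$name[j], value = st$value[j])
    }
  }
  if (is.null(path)) {
    return(as.character(xml))
  }
  xml2::write_xml(xml, path)
  invisible(path)
}

# Gene symbols represented by one entry: gene entries map their KEGG ids
# through id_map (ids absent from the map keep the KEGG id as label); group
# entries expand to the union of their components' genes; every other entry
# type (compound, map, ...) contributes nothing.
entry_gene_sets <- function(doc, id_map = NULL) {
  map_ids <- function(ids) {
    if (is.null(id_map)) return(ids)
    mapped <- id_map[ids]
    ifelse(is.na(mapped), ids, mapped)
  }
  sets <- setNames(vector("list", nrow(doc$entries)), doc$entries$id)
  for (i in seq_len(nrow(doc$entries))) {
    sets[[i]] <- if (doc$entries$type[i] == "gene") {
      unique(map_ids(doc$entries$names[[i]]))
    } else {
      character(0)
    }
  }
  for (i in seq_len(nrow(doc$groups))) {
    sets[[doc$groups$id[i]]] <-
      unique(unlist(sets[doc$groups$components[[i]]], use.names = FALSE))
  }
  sets
}

#' Convert a pathway document into undirected gene-gene edges
#'
#' Each relation of type `ECrel`, `PPrel`, `GErel` or `PCrel` whose two
#' endpoints resolve (after group expansion) to non-empty gene sets A and B
#' emits all pairs A x B, excluding self-pairs. `maplink` relations never
#' emit edges (their target is a map, not a gene product), and relations with
#' a non-gene endpoint (compound, map) are skipped; the number of skipped
#' relations is reported via an attribute.
#'
#' @param doc a `PathwayDoc` from [parse_kgml()].
#' @param id_map optional named character vector mapping KEGG ids (e.g.
#'   `"hsa:1571"`) to gene symbols; unmapped ids keep the KEGG id as label.
#' @param include_group_internal also emit co-membership edges inside each
#'   group (complex); off by default, so edges are purely relation-derived.
#' @return data.frame with columns `gene_a`, `gene_b` (sorted within row),
#'   `relation_type` and `pathway_id`; attribute `n_skipped` counts relations
#'   that produced no edge.
#' @export
pathway_edges <- function(doc, id_map = NULL, include_group_internal = FALSE) {
  stopifnot(inherits(doc, "PathwayDoc"))
  sets <- entry_gene_sets(doc, id_map)
  edge_types <- c("ECrel", "PPrel", "GErel", "PCrel")

  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(doc$relations))) {
    type <- doc$relations$type[i]
    if (!type %in% edge_types) {
      n_skipped <- n_skipped + 1L
      next
    }
    a <- sets[[doc$relations$entry1[i]]]
    b <- sets[[doc$relations$entry2[i]]]
    if (!length(a) || !length(b)) {
      n_skipped <- n_skipped + 1L
      next
    }
    pairs <- expand.grid(gene_a = a, gene_b = b,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    if (nrow(pairs)) {
      pairs$relation_type <- type
      out[[length(out) + 1L]] <- pairs
    }
  }
  if (include_group_internal) {
    for (i in seq_len(nrow(doc$groups))) {
      g <- sets[[doc$groups$id[i]]]
      if (length(g) >= 2) {
        pairs <- t(utils::combn(g, 2))
        out[[length(out) + 1L]] <- data.frame(
          gene_a = pairs[, 1], gene_b = pairs[, 2],
          relation_type = "group", stringsAsFactors = FALSE
        )
      }
    }
  }

  edges <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               relation_type = character(0), stringsAsFactors = FALSE)
  }
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges$pathway_id <- rep(doc$pathway_id, nrow(edges))
  rownames(edges) <- NULL
  attr(edges, "n_skipped") <- n_skipped
  edges
}

#' Read a KEGG-id-to-symbol map from a two-column TSV
#'
#' @param path TSV with columns `kegg_id` and `symbol` (header required).
#' @return Named character vector, KEGG id -> symbol.
#' @export
read_id_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("kegg_id", "symbol") %in% names(df))) {
    stop("id map must have columns 'kegg_id' and 'symbol'")
  }
  setNames(df$symbol, df$kegg_id)
}
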