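#' Simulate KGML pathway files with known hub structure
#'
#' Grows one preferential-attachment (Barabasi-Albert style) gene interaction
#' graph over the supplied gene universe, so that the merged degree
#' distribution is heavy-tailed, then partitions its edges into `n_pathways`
#' schema-valid KGML documents. Each document contains gene `entry` elements
#' (KEGG ids, symbol labels), `relation` elements with types drawn uniformly
#' from ECrel/PPrel/GErel/PCrel, a configurable fraction of `maplink`
#' relations to map entries (which carry no gene edge, exercising the edge
#' filter), and occasional `group` entries whose expansion reproduces graph
#' edges. A fraction of edges is emitted in two pathways to exercise
#' provenance merging.
#'
#' @param n_pathways number of KGML files to generate (>= 1).
#' @param gene_universe character vector of gene symbols (non-empty).
#' @param attachment_param mean number of edges each newly attached node
#'   brings; the merged graph has ~`attachment_param * length(gene_universe)`
#'   edges. Default 5.75 matches the edge density of the pathway network the
#'   pipeline is modelled on (1277 nodes, 7345 edges).
#' @param maplink_frac fraction of extra maplink relations per pathway,
#'   relative to its gene-edge relation count.
#' @param group_frac fraction of pathways in which one wedge (two edges
#'   sharing a node) is encoded through a group entry instead of two plain
#'   relations.
#' @param dup_frac fraction of edges assigned to a second pathway.
#' @param seed integer seed; the same seed reproduces byte-identical files.
#' @param out_dir directory to write into (created if needed).
#' @return A list: `paths` (KGML file per pathway), `id_map` (data.frame
#'   `kegg_id`, `symbol`, also written to `id_map.tsv`), `pathway_genes`
#'   (list of member symbols per pathway id), `edges` (merged unique
#'   symbol-pair edges of the underlying graph), and `truth` (`SimTruth`
#'   whose `hub_genes` are all nodes with merged degree > 30).
#' @export
simulate_kgml <- function(n_pathways, gene_universe, attachment_param = 5.75,
                          maplink_frac = 0.15, group_frac = 0.5,
                          dup_frac = 0.1, seed = 1, out_dir = tempfile("kgml")) {
  if (!is.numeric(n_pathways) || n_pathways < 1 || n_pathways != round(n_pathways)) {
    stop("'n_pathways' must be a positive integer")
  }
  gene_universe <- as.character(gene_universe)
  if (!length(gene_universe)) stop("'gene_universe' must be non-empty")
  if (anyDuplicated(gene_universe)) stop("'gene_universe' has duplicates")
  if (attachment_param < 1) stop("'attachment_param' must be >= 1")
  n <- length(gene_universe)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  with_seed(seed, {
    kegg_ids <- paste0("hsa:", 1000L + seq_len(n))
    id_map <- data.frame(kegg_id = kegg_ids, symbol = gene_universe,
                         stringsAsFactors = FALSE)

    ## --- preferential-attachment growth over a random arrival order ---
    arrival <- sample.int(n)                      # arrival[t] = node index
    m0 <- min(n, ceiling(attachment_param) + 1L)
    deg <- integer(n)
    ea <- integer(0); eb <- integer(0)            # edge endpoints (node idx)
    add_edge <- function(u, v) {
      ea[[length(ea) + 1L]] <<- u
      eb[[length(eb) + 1L]] <<- v
      deg[u] <<- deg[u] + 1L
      deg[v] <<- deg[v] + 1L
    }
    for (t in seq_len(m0 - 1L)) add_edge(arrival[t], arrival[t + 1L])
    base_m <- floor(attachment_param)
    extra_p <- attachment_param - base_m
    if (n > m0) {
      for (t in (m0 + 1L):n) {
        node <- arrival[t]
        m <- min(t - 1L, base_m + (runif(1) < extra_p))
        existing <- arrival[seq_len(t - 1L)]
        targets <- sample(existing, m, prob = deg[existing] + 1)
        for (v in targets) add_edge(node, v)
      }
    }
    n_edges <- length(ea)
    hub_genes <- sort(gene_universe[deg > 30])

    ## --- partition edges into pathways (some duplicated across two) ---
    primary <- sample.int(n_pathways, n_edges, replace = TRUE)
    assign <- lapply(seq_len(n_edges), function(i) primary[i])
    if (n_pathways >= 2 && dup_frac > 0) {
      dup <- which(runif(n_edges) < dup_frac)
      for (i in dup) {
        other <- sample(setdiff(seq_len(n_pathways), primary[i]), 1)
        assign[[i]] <- c(assign[[i]], other)
      }
    }

    pathway_ids <- sprintf("synp%05d", seq_len(n_pathways))
    rel_types <- c("ECrel", "PPrel", "GErel", "PCrel")
    paths <- character(n_pathways)
    pathway_genes <- setNames(vector("list", n_pathways), pathway_ids)

    for (p in seq_len(n_pathways)) {
      in_p <- vapply(assign, function(a) p %in% a, logical(1))
      pe_a <- ea[in_p]; pe_b <- eb[in_p]
      genes <- sort(unique(c(pe_a, pe_b)))
      if (!length(genes)) genes <- sort(sample.int(n, min(2L, n)))
      pathway_genes[[p]] <- gene_universe[genes]

      entry_id <- setNames(as.character(seq_along(genes)), genes)
      next_id <- length(genes)

      rel <- data.frame(
        entry1 = entry_id[as.character(pe_a)],
        entry2 = entry_id[as.character(pe_b)],
        type = sample(rel_types, length(pe_a), replace = TRUE),
        stringsAsFactors = FALSE
      )

      ## encode one wedge through a group entry
      group_comp <- NULL; group_id <- NULL
      if (nrow(rel) >= 2 && runif(1) < group_frac) {
        cnt <- table(c(rel$entry1, rel$entry2))
        center <- names(cnt)[cnt >= 2][1]
        if (!is.na(center)) {
          hit <- which(rel$entry1 == center | rel$entry2 == center)[1:2]
          others <- ifelse(rel$entry1[hit] == center,
                           rel$entry2[hit], rel$entry1[hit])
          if (!anyDuplicated(others)) {
            next_id <- next_id + 1L
            group_id <- as.character(next_id)
            group_comp <- others
            rel <- rel[-hit, , drop = FALSE]
            rel <- rbind(rel, data.frame(entry1 = group_id, entry2 = center,
                                         type = "PPrel",
                                         stringsAsFactors = FALSE))
          }
        }
      }

      ## maplink relations to map entries (no gene edge)
      n_map <- round(maplink_frac * nrow(rel))
      map_ids <- character(0)
      if (n_map > 0) {
        map_ids <- as.character(next_id + seq_len(n_map))
        next_id <- next_id + n_map
        rel <- rbind(rel, data.frame(
          entry1 = entry_id[as.character(sample(genes, n_map, replace = TRUE))],
          entry2 = map_ids,
          type = "maplink",
          stringsAsFactors = FALSE
        ))
      }

      ## assemble the XML document
      xml <- xml2::xml_new_root("pathway", name = pathway_ids[p], org = "hsa",
                                title = sprintf("Synthetic pathway %d", p))
      for (g in genes) {
        e <- xml2::xml_add_child(xml, "entry", id = entry_id[as.character(g)],
                                 name = kegg_ids[g], type = "gene")
        xml2::xml_add_child(e, "graphics", name = gene_universe[g])
      }
      if (!is.null(group_id)) {
        e <- xml2::xml_add_child(xml, "entry", id = group_id,
                                 name = "undefined", type = "group")
        for (cid in group_comp) xml2::xml_add_child(e, "component", id = cid)
      }
      for (k in seq_along(map_ids)) {
        xml2::xml_add_child(xml, "entry", id = map_ids[k],
                            name = sprintf("path:map%05d", k), type = "map")
      }
      for (i in seq_len(nrow(rel))) {
        r <- xml2::xml_add_child(xml, "relation", entry1 = rel$entry1[i],
                                 entry2 = rel$entry2[i], type = rel$type[i])
        if (rel$type[i] != "maplink") {
          xml2::xml_add_child(r, "subtype", name = "binding/association",
                              value = "---")
        }
      }
      paths[p] <- file.path(out_dir, paste0(pathway_ids[p], ".xml"))
      xml2::write_xml(xml, paths[p])
    }

    write.table(id_map, file.path(out_dir, "id_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    key_a <- pmin(gene_universe[ea], gene_universe[eb])
    key_b <- pmax(gene_universe[ea], gene_universe[eb])
    ord <- order(key_a, key_b)
    edges <- data.frame(gene_a = key_a[ord], gene_b = key_b[ord],
                        stringsAsFactors = FALSE)

    truth <- structure(
      list(de_genes = character(0),
           lfc = setNames(numeric(0), character(0)),
           dispersion = numeric(0),
           hub_genes = hub_genes,
           seed = as.integer(seed)),
      class = "SimTruth"
    )
    list(paths = paths, id_map = id_map, pathway_genes = pathway_genes,
         edges = edges, truth = truth)
  })
}
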