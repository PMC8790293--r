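#' Merge per-pathway edge lists into one gene interaction network
#'
#' Collapses duplicate gene pairs (within and across pathways) into single
#' undirected edges, unioning the contributing pathway ids as per-edge
#' provenance. Self-loops are dropped. The node set is the union of edge
#' endpoints, so isolated nodes cannot occur.
#'
#' @param edge_lists a single data.frame from [pathway_edges()] or a list of
#'   them (columns `gene_a`, `gene_b`, `pathway_id`; extra columns ignored).
#' @return Object of class `GeneNetwork`: list with `edges` (data.frame
#'   `gene_a`, `gene_b`, `pathways` list-column of sorted pathway ids) and
#'   `nodes` (sorted character vector).
#' @export
merge_networks <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  if (inherits(edge_lists, "GeneNetwork")) {
    edge_lists <- list(as_edge_frame(edge_lists))
  }
  edge_lists <- lapply(edge_lists, function(el) {
    if (inherits(el, "GeneNetwork")) as_edge_frame(el) else el
  })
  all <- do.call(rbind, lapply(edge_lists, function(el) {
    el[, c("gene_a", "gene_b", "pathway_id"), drop = FALSE]
  }))
  all <- all[all$gene_a != all$gene_b, , drop = FALSE]
  if (!NROW(all)) stop("no edges to merge")
  a <- pmin(all$gene_a, all$gene_b)
  b <- pmax(all$gene_a, all$gene_b)
  key <- paste(a, b, sep = "\r")
  prov <- split(all$pathway_id, key)
  keys <- sort(names(prov))
  pair <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  edges <- data.frame(gene_a = pair[, 1], gene_b = pair[, 2],
                      stringsAsFactors = FALSE)
  edges$pathways <- lapply(prov[keys], function(p) sort(unique(p)))
  rownames(edges) <- NULL
  structure(
    list(edges = edges, nodes = sort(unique(c(edges$gene_a, edges$gene_b)))),
    class = "GeneNetwork"
  )
}

# flatten a GeneNetwork back into a pathway-expanded edge frame
as_edge_frame <- function(net) {
  reps <- lengths(net$edges$pathways)
  data.frame(
    gene_a = rep(net$edges$gene_a, reps),
    gene_b = rep(net$edges$gene_b, reps),
    pathway_id = unlist(net$edges$pathways, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a gene network
#'
#' Degree is the number of distinct neighbors; the handshake identity
#' `sum(degree) == 2 * n_edges` holds exactly.
#'
#' @param net a `GeneNetwork`.
#' @return data.frame of class `DegreeTable` with columns `gene`, `degree`,
#'   sorted by decreasing degree then symbol.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "GeneNetwork"))
  if (!length(net$nodes)) stop("empty network")
  tab <- table(c(net$edges$gene_a, net$edges$gene_b))
  out <- data.frame(gene = names(tab), degree = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("DegreeTable", "data.frame")
  out
}

#' Power-law diagnostic for a degree distribution
#'
#' Bins degrees logarithmically (default 20 bins), computes the empirical
#' probability density per bin (bin count / n / linear bin width), and fits
#' ordinary least squares of log density on log bin midpoint over non-empty
#' bins. The exponent is minus the slope; R-squared measures how well a
#' straight line on the log-log scale describes the distribution. A
#' degenerate distribution (fewer than 10 distinct degrees, or fewer than 3
#' usable bins) yields `applicable = FALSE` rather than an error.
#'
#' @param degrees a `DegreeTable` or an integer vector of degrees (>= 1).
#' @param n_bins number of logarithmic bins.
#' @return List: `applicable`, `exponent`, `r_squared`, and `fit` (data.frame
#'   of bin midpoints and densities used).
#' @export
powerlaw_diagnostic <- function(degrees, n_bins = 20) {
  d <- if (is.data.frame(degrees)) degrees$degree else degrees
  d <- as.numeric(d)
  if (any(d < 1)) stop("degrees must be >= 1")
  na_result <- list(applicable = FALSE, exponent = NA_real_,
                    r_squared = NA_real_, fit = NULL)
  if (length(unique(d)) < 10) return(na_result)
  breaks <- exp(seq(log(min(d)), log(max(d) + 1), length.out = n_bins + 1))
  breaks <- unique(breaks)
  if (length(breaks) < 4) return(na_result)
  idx <- findInterval(d, breaks, rightmost.closed = TRUE)
  idx[idx == length(breaks)] <- length(breaks) - 1L
  cnt <- tabulate(idx, nbins = length(breaks) - 1L)
  width <- diff(breaks)
  mid <- sqrt(breaks[-length(breaks)] * breaks[-1])
  keep <- cnt > 0
  if (sum(keep) < 3) return(na_result)
  dens <- cnt[keep] / (length(d) * width[keep])
  fit <- lm(log(dens) ~ log(mid[keep]))
  list(applicable = TRUE,
       exponent = -unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       fit = data.frame(degree = mid[keep], density = dens))
}

#' Extract hub genes by degree threshold
#'
#' The default rule keeps nodes whose degree is strictly greater than
#' `min_degree` (30). Alternatively, `mode = "top_fraction"` keeps the top
#' `fraction` of nodes by degree, with all ties at the cutoff degree
#' included.
#'
#' @param degrees a `DegreeTable`.
#' @param min_degree strict lower threshold (`degree > min_degree`).
#' @param mode `"threshold"` (default) or `"top_fraction"`.
#' @param fraction top fraction of nodes kept in `top_fraction` mode.
#' @return Sorted character vector of hub gene symbols.
#' @export
hub_genes <- function(degrees, min_degree = 30,
                      mode = c("threshold", "top_fraction"), fraction = 0.1) {
  stopifnot(is.data.frame(degrees), nrow(degrees) > 0)
  mode <- match.arg(mode)
  if (mode == "threshold") {
    return(sort(degrees$gene[degrees$degree > min_degree]))
  }
  k <- max(1L, floor(fraction * nrow(degrees)))
  cutoff <- sort(degrees$degree, decreasing = TRUE)[k]
  sort(degrees$gene[degrees$degree >= cutoff])
}

#' Write a network as an edge-list TSV
#'
#' Columns: `gene_a`, `gene_b`, `pathways` (semicolon-joined provenance).
#'
#' @param net a `GeneNetwork`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "GeneNetwork"))
  df <- data.frame(
    gene_a = net$edges$gene_a, gene_b = net$edges$gene_b,
    pathways = vapply(net$edges$pathways, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML (Cytoscape-importable)
#'
#' Node degree is attached as a vertex attribute and the provenance as an
#' edge attribute.
#'
#' @param net a `GeneNetwork`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "GeneNetwork"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$gene_a, to = net$edges$gene_b,
               pathways = vapply(net$edges$pathways, paste, character(1),
                                 collapse = ";"),
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
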