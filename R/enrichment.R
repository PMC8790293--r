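#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set id, description, then member gene symbols.
#'
#' @param path GMT file path.
#' @return A `GeneSetCollection`: named list of character vectors (members,
#'   de-duplicated), with a `descriptions` attribute. Set ids must be unique.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate gene-set ids in GMT")
  sets <- setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, character(1), 2), ids)
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (member symbols).
#' @param path output path.
#' @param descriptions optional named descriptions; defaults to the set ids.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing an overlap of at least `k` genes between a query
#' of size `n` and a set of size `m`, drawn from a universe of size `N`
#' without replacement. With `ease = TRUE` the observed overlap is decremented
#' by one (the conservative EASE-score variant used by DAVID).
#'
#' @param k overlap count; `m` set size; `n` query size; `N` universe size.
#' @param ease use the EASE variant (k replaced by k - 1).
#' @return p-value in `(0, 1]`; `k = 0` (and `k <= 1` under EASE) gives 1.
#' @export
hypergeom_test <- function(k, m, n, N, ease = FALSE) {
  if (any(c(k, m, n, N) < 0) || m > N || n > N || k > min(m, n)) {
    stop("inconsistent margins: need k <= min(m, n) and m, n <= N")
  }
  k_eff <- if (ease) k - 1 else k
  if (k_eff <= 0) return(1)
  phyper(k_eff - 1, m, N - m, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list against gene sets
#'
#' For each set, counts the overlap with the query inside the universe and
#' computes the upper-tail hypergeometric p-value ([hypergeom_test()]).
#' Query genes outside the universe are dropped with a warning; set members
#' outside the universe do not count toward the set size.
#'
#' @param query character vector of gene symbols (non-empty after universe
#'   filtering).
#' @param sets a `GeneSetCollection` (named list of member vectors).
#' @param universe character vector of background gene symbols.
#' @param alpha significance cutoff on the raw p-value.
#' @param ease passed to [hypergeom_test()].
#' @return data.frame sorted by p-value with columns `set_id`, `name`,
#'   `overlap` (k), `set_size` (m), `query_size` (n), `universe_size` (N),
#'   `p_value`, `fdr` (BH, informational) and `significant` (`p < alpha`).
#' @export
enrich <- function(query, sets, universe, alpha = 0.05, ease = FALSE) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe filtering")
  descr <- attr(sets, "descriptions")
  n <- length(query); N <- length(universe)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    m <- length(members)
    k <- length(intersect(query, members))
    data.frame(set_id = id,
               name = if (!is.null(descr)) descr[[id]] else id,
               overlap = k, set_size = m, query_size = n, universe_size = N,
               p_value = hypergeom_test(k, m, n, N, ease = ease),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
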