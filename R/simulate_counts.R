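#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Draws negative-binomial counts for a two-group (tumor vs normal) design.
#' Per-gene baseline means are log-normal; a fraction `frac_de` of genes is
#' planted as differentially expressed by multiplying the tumor-group mean by
#' `2^lfc_magnitude` for half of them (up-regulated) and by
#' `2^-lfc_magnitude` for the other half (down-regulated). The NB
#' parameterization is mean `mu`, variance `mu + dispersion * mu^2`;
#' `dispersion = 0` is the Poisson limit.
#'
#' @param n_genes,n_tumor,n_normal positive integer sizes.
#' @param frac_de fraction of genes planted as DE, in `[0, 1]`.
#' @param lfc_magnitude absolute log2 fold change planted on DE genes.
#' @param dispersion NB dispersion phi (>= 0), shared across genes.
#' @param seed integer seed; identical seeds give identical output.
#' @param gene_ids optional character vector of `n_genes` gene ids; default
#'   `g00001, g00002, ...`.
#' @param de_genes optional character vector naming the genes to plant as DE
#'   (must be a subset of `gene_ids`); by default `round(frac_de * n_genes)`
#'   genes are sampled. When supplied, `frac_de` is ignored.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for per-gene
#'   baseline means (defaults give a median mean of ~50 counts).
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (class `SimTruth`: `de_genes`, signed per-gene `lfc`, `dispersion`,
#'   `hub_genes` — empty here — and `seed`).
#' @export
simulate_counts <- function(n_genes, n_tumor, n_normal, frac_de = 0.1,
                            lfc_magnitude = 2, dispersion = 0.1, seed = 1,
                            gene_ids = NULL, de_genes = NULL,
                            baseline_meanlog = log(50), baseline_sdlog = 1) {
  for (nm in c("n_genes", "n_tumor", "n_normal")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
      stop("'", nm, "' must be a positive integer")
    }
  }
  if (frac_de < 0 || frac_de > 1) stop("'frac_de' must be in [0, 1]")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
  } else if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    stop("'gene_ids' must be ", n_genes, " unique ids")
  }

  with_seed(seed, {
    mu0 <- rlnorm(n_genes, meanlog = baseline_meanlog, sdlog = baseline_sdlog)
    names(mu0) <- gene_ids

    if (is.null(de_genes)) {
      n_de <- round(frac_de * n_genes)
      de_genes <- if (n_de > 0) sort(sample(gene_ids, n_de)) else character(0)
    } else {
      if (!all(de_genes %in% gene_ids)) {
        stop("'de_genes' must be a subset of 'gene_ids'")
      }
      de_genes <- sort(unique(de_genes))
    }

    lfc <- setNames(numeric(n_genes), gene_ids)
    if (length(de_genes)) {
      n_up <- ceiling(length(de_genes) / 2)
      up <- sample(de_genes, n_up)
      lfc[up] <- lfc_magnitude
      lfc[setdiff(de_genes, up)] <- -lfc_magnitude
    }

    mu_tumor <- mu0 * 2^lfc
    draw <- function(mu_vec, n_samp) {
      m <- matrix(rep(mu_vec, n_samp), nrow = n_genes)
      if (dispersion == 0) {
        matrix(rpois(n_genes * n_samp, lambda = m), nrow = n_genes)
      } else {
        matrix(rnbinom(n_genes * n_samp, mu = m, size = 1 / dispersion),
               nrow = n_genes)
      }
    }
    counts <- cbind(draw(mu_tumor, n_tumor), draw(mu0, n_normal))
    rownames(counts) <- gene_ids
    colnames(counts) <- c(sprintf("T%04d", seq_len(n_tumor)),
                          sprintf("N%04d", seq_len(n_normal)))
    storage.mode(counts) <- "integer"

    cm <- count_matrix(counts, rep(c("tumor", "normal"), c(n_tumor, n_normal)))
    truth <- structure(
      list(de_genes = de_genes, lfc = lfc,
           dispersion = setNames(rep(dispersion, n_genes), gene_ids),
           hub_genes = character(0), seed = as.integer(seed)),
      class = "SimTruth"
    )
    list(counts = cm, truth = truth)
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d planted DE genes, %d planted hub genes (seed %d)\n",
              length(x$de_genes), length(x$hub_genes), x$seed))
  invisible(x)
}
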