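#' Compute per-sample normalization size factors
#'
#' `libsize` factors are proportional to column sums, rescaled so their
#' geometric mean is 1. `tmm` factors additionally correct for composition
#' bias by the trimmed mean of M-values: per sample, gene-wise log2 ratios
#' (M) against a reference sample are trimmed (30% of M, 5% of A, two-sided)
#' and their mean taken; the reference is the sample whose upper-quartile
#' expression is closest to the across-sample mean. TMM factors are likewise
#' centered to geometric mean 1 and multiply the library sizes.
#'
#' @param counts a [count_matrix()].
#' @param method `"libsize"` or `"tmm"`.
#' @param trim_m,trim_a two-sided trim fractions for M and A values (TMM).
#' @return Named numeric vector of size factors, one per sample; dividing a
#'   sample's counts by `factor * 1` puts all samples on a common scale
#'   (effective library size = `library_size * attr(,"norm_factor")` for TMM).
#' @export
normalize_factors <- function(counts, method = c("libsize", "tmm"),
                              trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(counts, "CountMatrix"))
  method <- match.arg(method)
  lib <- counts$library_sizes
  if (all(lib == 0)) stop("all-zero count matrix")
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(names(lib)[lib == 0], collapse = ", "))

  if (method == "libsize") {
    f <- lib / geometric_mean(lib)
    return(setNames(as.numeric(f), colnames(counts$counts)))
  }

  x <- counts$counts
  uq <- apply(sweep(x, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  nf <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair_factor(x[, j], x[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  nf <- nf / geometric_mean(nf)
  f <- lib * nf
  f <- f / geometric_mean(f)
  structure(setNames(as.numeric(f), colnames(x)), norm_factor = nf)
}

# Trimmed mean of M values of sample `obs` against `ref` (2^result is the
# TMM normalization factor). Genes zero in either sample are dropped; then
# genes outside the central (1 - 2*trim_m) of M and (1 - 2*trim_a) of A are
# trimmed before averaging M.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m = 0.3, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  p_obs <- obs[keep] / n_obs
  p_ref <- ref[keep] / n_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  lo_m <- quantile(m, trim_m); hi_m <- quantile(m, 1 - trim_m)
  lo_a <- quantile(a, trim_a); hi_a <- quantile(a, 1 - trim_a)
  kept <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(kept)) return(1)
  2^mean(m[kept])
}

#' Estimate negative-binomial dispersion
#'
#' Method-of-moments estimation on size-factor-normalized counts under the
#' mean/variance convention `var = mu + phi * mu^2`. Per-gene raw estimates
#' `(s2 - m) / m^2` are pooled within each label group (weighted by degrees
#' of freedom), the common dispersion is their 10%-trimmed mean clamped at 0,
#' and per-gene values are shrunk toward the common value:
#' `phi_g = (1 - prior_weight) * max(raw_g, 0) + prior_weight * common`.
#'
#' @param counts a [count_matrix()]; needs >= 2 samples in at least one group.
#' @param size_factors optional factors from [normalize_factors()]; computed
#'   with `libsize` by default.
#' @param prior_weight shrinkage weight toward the common dispersion in
#'   `[0, 1]`; 1 returns the common value for every gene.
#' @return List with `common` (scalar) and `tagwise` (named per-gene vector).
#' @export
estimate_dispersion <- function(counts, size_factors = NULL, prior_weight = 0.3) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (is.null(size_factors)) size_factors <- normalize_factors(counts)
  z <- sweep(counts$counts, 2, size_factors, "/")
  groups <- split(seq_along(counts$labels), counts$labels)
  sizes <- lengths(groups)
  usable <- sizes >= 2
  if (!any(usable)) stop("need at least one group with >= 2 samples")
  if (!all(usable)) {
    warning("group(s) with a single sample excluded from dispersion ",
            "estimation: ", paste(names(sizes)[!usable], collapse = ", "))
  }

  num <- 0; den <- 0
  for (g in names(groups)[usable]) {
    zi <- z[, groups[[g]], drop = FALSE]
    m <- rowMeans(zi)
    s2 <- apply(zi, 1, var)
    w <- sizes[[g]] - 1
    raw <- ifelse(m > 0, (s2 - m) / m^2, 0)
    num <- num + w * raw
    den <- den + w
  }
  raw <- num / den
  common <- max(0, mean(raw, trim = 0.1))
  tagwise <- (1 - prior_weight) * pmax(raw, 0) + prior_weight * common
  # constant genes (zero variance in every group) pin to the floor
  list(common = common,
       tagwise = setNames(as.numeric(tagwise), rownames(counts$counts)))
}

#' Negative-binomial conditional exact test for two groups of counts
#'
#' Tests whether two groups of NB-distributed counts share a common mean.
#' Counts are assumed to be on a common library scale (see [de_table()],
#' which rescales all samples to the geometric-mean library size first).
#' Group sums are NB with size `n_g / phi`; conditioning on the overall
#' total `t`, the two-sided p-value is the sum of conditional probabilities
#' of all splits of `t` that are no more probable than the observed one.
#' With `phi = 0` the conditional law is Binomial(t, nA / (nA + nB)).
#'
#' @param counts_a,counts_b non-negative integer count vectors (one entry per
#'   sample) for the two groups.
#' @param dispersion NB dispersion phi (>= 0).
#' @return p-value in `(0, 1]`; both groups all zero gives 1.
#' @export
exact_test <- function(counts_a, counts_b, dispersion = 0) {
  if (any(counts_a < 0) || any(counts_b < 0)) stop("counts must be >= 0")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  ya <- round(sum(counts_a)); yb <- round(sum(counts_b))
  t <- ya + yb
  if (t == 0) return(1)
  na <- length(counts_a); nb <- length(counts_b)
  a <- 0:t
  if (dispersion == 0) {
    logp <- dbinom(a, size = t, prob = na / (na + nb), log = TRUE)
  } else {
    ra <- na / dispersion; rb <- nb / dispersion
    mu <- t / (na + nb)
    logp <- dnbinom(a, size = ra, mu = ra * mu, log = TRUE) +
      dnbinom(t - a, size = rb, mu = rb * mu, log = TRUE)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))   # normalize the conditional law
  }
  obs <- logp[ya + 1L]
  keep <- logp <= obs + 1e-12
  p <- sum(exp(logp[keep]))
  min(1, max(p, .Machine$double.xmin))
}

#' Differential expression table for a tumor/normal count matrix
#'
#' Normalizes, rescales every sample to the geometric-mean effective library
#' size (pseudo-counts), runs the NB conditional [exact_test()] per gene with
#' the shrunk tagwise dispersion, and reports group CPM means, fold change
#' (tumor / normal, with a CPM pseudocount to avoid division by zero),
#' log2 fold change, p-value, BH-adjusted FDR (informational), direction and
#' the combined filter flag `passes_filter`, true iff
#' `p < p_thresh` and (`FC > fc_up` or `FC < fc_down`), both strict.
#'
#' @param counts a [count_matrix()].
#' @param method normalization method, see [normalize_factors()].
#' @param dispersion optional fixed dispersion (scalar or per-gene vector);
#'   estimated via [estimate_dispersion()] when `NULL`.
#' @param pseudo_cpm pseudocount added to group CPM means before the ratio.
#' @param p_thresh,fc_up,fc_down filter thresholds.
#' @param prior_weight passed to [estimate_dispersion()].
#' @return data.frame of class `DEGTable` with columns `gene`, `cpm_tumor`,
#'   `cpm_normal`, `FC`, `logFC`, `PValue`, `FDR`, `direction`
#'   (`up`/`down`/`ns`), `passes_filter`.
#' @export
de_table <- function(counts, method = "libsize", dispersion = NULL,
                     pseudo_cpm = 0.5, p_thresh = 0.05, fc_up = 2,
                     fc_down = 0.5, prior_weight = 0.3) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (length(unique(counts$labels)) < 2) {
    stop("both tumor and normal samples are required")
  }
  sf <- normalize_factors(counts, method)
  nf <- attr(sf, "norm_factor")
  eff_lib <- counts$library_sizes * (if (is.null(nf)) 1 else nf)

  genes <- rownames(counts$counts)
  if (is.null(dispersion)) {
    phi <- estimate_dispersion(counts, size_factors = sf,
                               prior_weight = prior_weight)$tagwise
  } else if (length(dispersion) == 1) {
    phi <- setNames(rep(dispersion, length(genes)), genes)
  } else {
    phi <- dispersion[genes]
  }

  # pseudo-counts: every sample rescaled to the common (geometric mean)
  # effective library size, so group sums are exchangeable under the null
  common_lib <- geometric_mean(eff_lib)
  pseudo <- round(sweep(counts$counts, 2, common_lib / eff_lib, "*"))

  tum <- counts$labels == "tumor"
  p <- vapply(seq_along(genes), function(i) {
    exact_test(pseudo[i, tum], pseudo[i, !tum], phi[[i]])
  }, numeric(1))

  cpm <- sweep(counts$counts, 2, eff_lib / 1e6, "/")
  cpm_t <- rowMeans(cpm[, tum, drop = FALSE])
  cpm_n <- rowMeans(cpm[, !tum, drop = FALSE])
  fc <- (cpm_t + pseudo_cpm) / (cpm_n + pseudo_cpm)

  passes <- (p < p_thresh) & (fc > fc_up | fc < fc_down)
  direction <- ifelse(!passes, "ns", ifelse(fc > 1, "up", "down"))

  out <- data.frame(
    gene = genes, cpm_tumor = cpm_t, cpm_normal = cpm_n,
    FC = fc, logFC = log2(fc), PValue = p,
    FDR = p.adjust(p, "BH"), direction = direction,
    passes_filter = passes,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("DEGTable", "data.frame")
  out
}

#' Filter a DEG table to the significant genes
#'
#' Re-applies the fold-change / p-value filter with the supplied thresholds
#' (both fold-change bounds strict, as is the p cutoff) and returns only the
#' passing genes plus the up/down tally.
#'
#' @param table a `DEGTable` from [de_table()].
#' @param p_thresh,fc_up,fc_down thresholds; a gene passes iff
#'   `PValue < p_thresh` and (`FC > fc_up` or `FC < fc_down`).
#' @return List with `degs` (the filtered table, `direction` recomputed),
#'   `n_up` and `n_down`.
#' @export
call_degs <- function(table, p_thresh = 0.05, fc_up = 2, fc_down = 0.5) {
  stopifnot(is.data.frame(table),
            all(c("gene", "FC", "PValue") %in% names(table)))
  keep <- table$PValue < p_thresh & (table$FC > fc_up | table$FC < fc_down)
  degs <- table[keep, , drop = FALSE]
  degs$direction <- ifelse(degs$FC > 1, "up", "down")
  degs$passes_filter <- TRUE
  rownames(degs) <- NULL
  list(degs = degs, n_up = sum(degs$direction == "up"),
       n_down = sum(degs$direction == "down"))
}
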