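test_that("simulate_counts respects group structure, labels and determinism", {
  sim <- simulate_counts(200, 30, 20, frac_de = 0, dispersion = 0.2, seed = 11)
  expect_length(sim$truth$de_genes, 0)
  expect_identical(dim(sim$counts$counts), c(200L, 50L))
  expect_true(all(sim$counts$counts >= 0))
  expect_identical(as.vector(table(sim$counts$labels)[c("tumor", "normal")]),
                   c(30L, 20L))
  expect_identical(sim$counts$library_sizes, colSums(sim$counts$counts))

  sim2 <- simulate_counts(200, 30, 20, frac_de = 0, dispersion = 0.2, seed = 11)
  expect_identical(sim$counts$counts, sim2$counts$counts)
  sim3 <- simulate_counts(200, 30, 20, frac_de = 0, dispersion = 0.2, seed = 12)
  expect_false(identical(sim$counts$counts, sim3$counts$counts))

  expect_error(simulate_counts(0, 5, 5), "positive integer")
  expect_error(simulate_counts(10, 2.5, 5), "positive integer")
  expect_error(simulate_counts(10, 5, 5, dispersion = -1), ">= 0")
})

test_that("null genes have equal group means and planted DE splits up/down", {
  sim <- simulate_counts(400, 250, 250, frac_de = 0.2, lfc_magnitude = 2,
                         dispersion = 0.1, seed = 5)
  tum <- sim$counts$labels == "tumor"
  null_genes <- setdiff(rownames(sim$counts$counts), sim$truth$de_genes)
  m_t <- rowMeans(sim$counts$counts[null_genes, tum])
  m_n <- rowMeans(sim$counts$counts[null_genes, !tum])
  # per-gene group means agree within 3 standard errors for nearly all genes
  se <- sqrt((m_t + 0.1 * m_t^2) / 250 + (m_n + 0.1 * m_n^2) / 250)
  frac_within <- mean(abs(m_t - m_n) <= 3 * se)
  expect_gt(frac_within, 0.99)

  lfc <- sim$truth$lfc[sim$truth$de_genes]
  expect_identical(sum(lfc > 0), 40L)  # half of 80 planted genes up
  expect_identical(sum(lfc < 0), 40L)
  expect_true(all(abs(lfc) == 2))
})

test_that("dispersion 0 gives the Poisson limit (variance ~ mean)", {
  sim <- simulate_counts(1000, 100, 100, frac_de = 0, dispersion = 0,
                         seed = 3, baseline_meanlog = log(40),
                         baseline_sdlog = 0.5)
  x <- sim$counts$counts
  ratio <- apply(x, 1, var) / rowMeans(x)
  # index of dispersion concentrates at 1; MC error at n = 200 samples
  expect_lt(abs(mean(ratio) - 1), 0.02)
  expect_gt(mean(abs(ratio - 1) < 0.5), 0.99)
})

test_that("the full study data shape can be simulated", {
  sim <- simulate_counts(20530, 1104, 114, frac_de = 0, dispersion = 0,
                         seed = 1, baseline_meanlog = log(5),
                         baseline_sdlog = 0.5)
  expect_identical(dim(sim$counts$counts), c(20530L, 1218L))
  expect_identical(sum(sim$counts$labels == "tumor"), 1104L)
  expect_identical(sum(sim$counts$labels == "normal"), 114L)
})

test_that("simulate_kgml minimal case yields exactly one recoverable edge", {
  out <- simulate_kgml(1, c("AAA", "BBB"), attachment_param = 1, seed = 2,
                       out_dir = withr::local_tempdir())
  doc <- parse_kgml(out$paths[1])
  edges <- pathway_edges(doc, id_map = setNames(out$id_map$symbol,
                                                out$id_map$kegg_id))
  expect_identical(nrow(edges), 1L)
  expect_setequal(c(edges$gene_a, edges$gene_b), c("AAA", "BBB"))
})

test_that("simulate_kgml is byte-deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g <- sprintf("G%03d", 1:60)
  o1 <- simulate_kgml(4, g, seed = 9, out_dir = d1)
  o2 <- simulate_kgml(4, g, seed = 9, out_dir = d2)
  for (i in seq_along(o1$paths)) {
    expect_identical(readLines(o1$paths[i]), readLines(o2$paths[i]))
  }
  o3 <- simulate_kgml(4, g, seed = 10, out_dir = withr::local_tempdir())
  expect_false(identical(readLines(o1$paths[1]), readLines(o3$paths[1])))
})

test_that("attachment model reaches the reference network scale", {
  # 1277 nodes at the default attachment density targets ~7345 edges
  out <- simulate_kgml(20, sprintf("N%04d", 1:1277), seed = 4,
                       out_dir = withr::local_tempdir())
  expect_lt(abs(nrow(out$edges) - 7345) / 7345, 0.05)
  # generated files round-trip through the parser without losing edges
  net <- merge_networks(lapply(lapply(out$paths, parse_kgml), pathway_edges,
                               id_map = setNames(out$id_map$symbol,
                                                 out$id_map$kegg_id)))
  expect_identical(nrow(net$edges), nrow(out$edges))
})

test_that("write_fixtures emits the reference tables with documented shapes", {
  dir <- withr::local_tempdir()
  manifest <- write_fixtures(dir)
  expect_identical(manifest$n_pathways, 28L)
  expect_identical(manifest$n_markers, 23L)
  expect_identical(manifest$n_literature_genes, 12L)

  markers <- read.delim(file.path(dir, "candidate_markers.tsv"))
  expect_identical(anyDuplicated(markers$gene), 0L)
  expect_identical(nrow(markers), 23L)
  lit <- readLines(file.path(dir, "literature_genes.txt"))
  expect_identical(lit[1], "ADH1A")
  expect_length(lit, 12)
  paths <- read.delim(file.path(dir, "enriched_pathways.tsv"))
  expect_identical(nrow(paths), 28L)
  expect_identical(paths$term[1], "hsa04080")
})
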