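# Independent oracles and shared fixtures for the test suite.

# Conditional law of the group-A sum given the overall total, derived from
# the negative-binomial pmf written with lgamma (not dnbinom): for group
# sizes rA = nA/phi, rB = nB/phi the conditional pmf at a | total t is
#   C(a + rA - 1, a) * C(t - a + rB - 1, t - a) / C(t + rA + rB - 1, t),
# a beta-binomial-type form in which the NB mean cancels. phi = 0 falls back
# to Binomial(t, nA / (nA + nB)).
oracle_conditional_pmf <- function(t, n_a, n_b, phi) {
  a <- 0:t
  if (phi == 0) return(dbinom(a, t, n_a / (n_a + n_b)))
  r_a <- n_a / phi; r_b <- n_b / phi
  lognum <- lgamma(a + r_a) - lgamma(r_a) - lfactorial(a) +
    lgamma(t - a + r_b) - lgamma(r_b) - lfactorial(t - a)
  logden <- lgamma(t + r_a + r_b) - lgamma(r_a + r_b) - lfactorial(t)
  exp(lognum - logden)
}

# Two-sided exact p by brute force: sum the conditional probabilities of all
# splits no more probable than the observed one.
oracle_exact_p <- function(y_a, y_b, n_a, n_b, phi) {
  t <- y_a + y_b
  if (t == 0) return(1)
  pmf <- oracle_conditional_pmf(t, n_a, n_b, phi)
  pmf <- pmf / sum(pmf)
  sum(pmf[pmf <= pmf[y_a + 1] * (1 + 1e-12)])
}

# AUC as the raw fraction of positive-negative score pairs correctly
# ordered, ties counted half.
oracle_pairwise_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# Minimal KGML document builders -------------------------------------------

kgml_minimal <- function() {
  paste0(
    '<pathway name="path:test01" title="Toy pathway">',
    '<entry id="1" name="hsa:10" type="gene"><graphics name="GENEA"/></entry>',
    '<entry id="2" name="hsa:20" type="gene"><graphics name="GENEB"/></entry>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>',
    '</pathway>'
  )
}

kgml_with_group <- function() {
  paste0(
    '<pathway name="path:test02" title="Group pathway">',
    '<entry id="1" name="hsa:10" type="gene"/>',
    '<entry id="2" name="hsa:20" type="gene"/>',
    '<entry id="3" name="hsa:30" type="gene"/>',
    '<entry id="4" name="undefined" type="group">',
    '<component id="1"/><component id="2"/></entry>',
    '<relation entry1="4" entry2="3" type="GErel"/>',
    '</pathway>'
  )
}

kgml_rich <- function() {
  paste0(
    '<pathway name="path:test03" title="Mixed pathway">',
    '<entry id="1" name="hsa:1571 hsa:1572" type="gene"/>',
    '<entry id="2" name="hsa:20 hsa:21 hsa:22" type="gene"/>',
    '<entry id="3" name="cpd:C00031" type="compound"/>',
    '<entry id="4" name="path:hsa00010" type="map"/>',
    '<entry id="5" name="hsa:50" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>',
    '<relation entry1="5" entry2="3" type="PCrel"/>',
    '<relation entry1="5" entry2="4" type="maplink"/>',
    '</pathway>'
  )
}

# Shared seeded synthetic scenario run, computed once per test session ------

.scenario_cache <- new.env(parent = emptyenv())

get_scenario_run <- function() {
  if (is.null(.scenario_cache$run)) {
    sc <- synthetic_scenario(out_dir = file.path(tempdir(), "pm_scenario"),
                             seed = 1)
    rep <- suppressMessages(run_pipeline(sc$config))
    .scenario_cache$run <- list(scenario = sc, report = rep)
  }
  .scenario_cache$run
}
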