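# exhaustive-enumeration oracle for the hypergeometric upper tail
hyper_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

test_that("hypergeometric upper-tail p handles the edge cases", {
  expect_equal(hypergeom_p(20, 5, 7, 0), 1.0)
  expect_equal(hypergeom_p(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_p(8, 8, 3, 3), 1.0)  # pathway is the whole universe
  expect_error(hypergeom_p(10, 11, 5, 2), "inconsistent")
  expect_error(hypergeom_p(10, 5, 5, 6), "inconsistent")
})

test_that("hypergeometric p equals exhaustive enumeration for all N <= 12", {
  for (N in 2:12) for (K in 0:N) for (n in 0:N) {
    for (k in 0:min(K, n)) {
      expect_equal(hypergeom_p(N, K, n, k), hyper_oracle(N, K, n, k),
                   tolerance = 1e-12,
                   info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("Holm adjustment reproduces the hand-applied step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  # ordered case worked by hand: m=4, sorted (0.005, 0.01, 0.03, 0.04)
  # -> cummax(4*0.005, 3*0.01, 2*0.03, 1*0.04) = (0.02, 0.03, 0.06, 0.06)
  expect_equal(holm_adjust(c(0.03, 0.005, 0.04, 0.01)),
               c(0.06, 0.02, 0.06, 0.03))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm adjustment dominates raw p and preserves order", {
  set.seed(55)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))  # monotone in p
  }
})

test_that("relative betweenness matches the analytic toy graphs", {
  toys <- generate_toy_pathways()
  star <- relative_betweenness(toys$star)
  expect_equal(unname(star["hub"]), 1.0)
  expect_equal(unname(star[paste0("leaf", 1:4)]), rep(0, 4))

  p3 <- relative_betweenness(toys$path3)
  expect_equal(unname(p3), c(0, 1, 0))

  k4 <- relative_betweenness(toys$complete4)
  expect_equal(unname(k4), rep(0, 4))

  # 8-node tree against the hand-computed frozen table
  frozen <- read.csv(system.file("extdata", "toy_tree8_centralities.csv",
                                 package = "amniolipids"), comment.char = "#")
  got <- relative_betweenness(toys$tree8)
  expect_equal(unname(got[frozen$compound]), frozen$relative_betweenness,
               tolerance = 1e-12)
})

test_that("pathway impact is the matched share of centrality mass", {
  toys <- generate_toy_pathways()
  expect_equal(pathway_impact(toys$star, "hub"), 1.0)
  expect_equal(pathway_impact(toys$star, "leaf1"), 0.0)
  expect_equal(pathway_impact(toys$path3, c("pa", "pb")), 1.0)
  expect_equal(pathway_impact(toys$complete4, paste0("k", 1:4)), 0)  # no mass
  expect_equal(pathway_impact(toys$tree8, character(0)), 0)
  expect_error(pathway_impact(toys$star, "nope"), "nope")
})

test_that("impact is monotone under matched-set inclusion", {
  toys <- generate_toy_pathways()
  set.seed(31)
  for (i in 1:20) {
    nodes <- sample(toys$tree8$compounds)
    impacts <- vapply(seq_along(nodes), function(k)
      pathway_impact(toys$tree8, nodes[seq_len(k)]), numeric(1))
    expect_true(all(diff(impacts) >= -1e-15))
    expect_equal(impacts[length(nodes)], 1.0)  # all matched -> full mass
  }
})

test_that("pathway construction rejects malformed graphs", {
  expect_error(pathway("bad", c("a", "b"), rbind(c("a", "z"))), "z")
  expect_error(pathway("loop", c("a", "b"), rbind(c("a", "a"))), "self-loop")
  expect_error(pathway("dup", c("a", "a")), "duplicate")
  iso <- pathway("iso", c("a", "b", "c"))  # edgeless is fine
  expect_equal(unname(relative_betweenness(iso)), rep(0, 3))
})

test_that("enrichment ranks pathways and respects the contracts", {
  toys <- generate_toy_pathways()
  background <- unique(unlist(lapply(toys, `[[`, "compounds")))

  # no evidence: p = 1 everywhere, impact 0
  none <- enrich(toys, character(0), background)
  expect_equal(none$raw_p, rep(1, 4))
  expect_equal(none$impact, rep(0, 4))
  expect_equal(nrow(none), length(toys))

  # hits covering all of the star and nothing else rank it first
  res <- enrich(toys, toys$star$compounds, background)
  expect_equal(res$pathway[1], "star")
  expect_equal(res$impact[res$pathway == "star"], 1.0)
  expect_true(all(res$holm_p >= res$raw_p))
  expect_true(all(res$impact >= 0 & res$impact <= 1))
  expect_equal(res$neg_log_p, -log(res$raw_p))

  # base-10 option
  res10 <- enrich(toys, toys$star$compounds, background, log_base = "10")
  expect_equal(res10$neg_log_p[1], -log10(res10$raw_p[1]))

  expect_error(enrich(toys, "hub", character(0)), "empty")
  expect_error(enrich(toys, "martian", background), "martian")
})
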