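test_that("network construction enforces bipartiteness and collapses duplicates", {
  net <- cpi_network(c("c1", "c2"), c("p1", "p2"),
                     expand.grid(compound = c("c1", "c2"),
                                 protein = c("p1", "p2"),
                                 stringsAsFactors = FALSE))
  expect_s3_class(net, "cpi_network")
  expect_equal(nrow(net$edges), 4)
  expect_equal(density_summary(net)$density, 1)

  # duplicate edge keeps the channel maximum
  net2 <- cpi_network("c1", "p1",
                      data.frame(compound = c("c1", "c1"),
                                 protein = c("p1", "p1"),
                                 experimental = c(0.3, 0.7)))
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$experimental, 0.7)

  # random edge table: distinct-pair count by brute force
  set.seed(42)
  tab <- data.frame(compound = sprintf("c%d", sample(10, 50, TRUE)),
                    protein = sprintf("p%d", sample(10, 50, TRUE)),
                    experimental = runif(50))
  k <- length(unique(paste(tab$compound, tab$protein)))
  net3 <- cpi_network(sprintf("c%d", 1:10), sprintf("p%d", 1:10), tab)
  expect_equal(nrow(net3$edges), k)
  expect_silent(validate_cpi_network(net3))

  # rejections
  expect_error(cpi_network("c1", "p1",
                           data.frame(compound = "cX", protein = "p1",
                                      experimental = 1)),
               "unknown compound")
  expect_error(cpi_network(c("n1"), c("n1"),
                           data.frame(compound = "n1", protein = "n1",
                                      experimental = 1)),
               "collision")
  expect_error(cpi_network("c1", "p1",
                           data.frame(compound = "c1", protein = "p1",
                                      experimental = 1.2)),
               "outside")
})

test_that("confidence filtering is inclusive at the boundary and monotone", {
  net <- cpi_network(c("c1", "c2", "c3"), "p1",
                     data.frame(compound = c("c1", "c2", "c3"),
                                protein = "p1",
                                experimental = c(0.39, 0.40, 0.41)))
  expect_equal(nrow(filter_by_confidence(net, "experimental", 0.4)$edges), 2)
  expect_equal(filter_by_confidence(net, "experimental", 0)$edges, net$edges)
  expect_error(filter_by_confidence(net, "nope", 0.4), "unknown score channel")

  set.seed(7)
  scores <- runif(100)
  net2 <- cpi_network(sprintf("c%d", 1:100), "p1",
                      data.frame(compound = sprintf("c%d", 1:100),
                                 protein = "p1", experimental = scores))
  expect_equal(nrow(filter_by_confidence(net2, "experimental", 0.6)$edges),
               sum(scores >= 0.6))
  # monotone: higher threshold keeps a subset
  for (thr in c(0.2, 0.5, 0.8)) {
    lo <- filter_by_confidence(net2, "experimental", thr)$edges$compound
    hi <- filter_by_confidence(net2, "experimental", thr + 0.1)$edges$compound
    expect_true(all(hi %in% lo))
  }
})

test_that("heavy-atom counts match molecular formulas and tolerate bad SMILES", {
  expect_equal(heavy_atom_count("O"), 1)              # water
  expect_equal(heavy_atom_count("C1CCCCC1"), 6)        # cyclohexane
  expect_equal(heavy_atom_count("CC(=O)Oc1ccccc1C(=O)O"), 13)  # aspirin C9+O4
  expect_warning(res <- heavy_atom_count("not_a_smiles"), "parsed")
  expect_true(is.na(res))
})

test_that("cleanup removes small, flagged and non-C-number compounds and is idempotent", {
  cmp <- data.frame(
    id = c("small", "ok_size", "anti", "drug_only", "drug_and_c", "no_kegg"),
    heavy_atoms = c(4L, 5L, 10L, 10L, 10L, 10L),
    kegg_c = c("C1", "C2", "C3", "", "C4", ""),
    kegg_d = c("", "", "", "D1", "D2", ""),
    flags = c("", "", "antibiotic", "", "", ""))
  edges <- data.frame(compound = rep(cmp$id, each = 2),
                      protein = rep(c("pA", "pB"), 6), experimental = 1)
  net <- cpi_network(cmp, c("pA", "pB"), edges)
  out <- cleanup_network(net)
  expect_setequal(out$compounds$id, c("ok_size", "drug_and_c"))
  # idempotent
  out2 <- cleanup_network(out)
  expect_equal(out2$edges, out$edges)
  # no-op when nothing is filterable
  clean <- cpi_network(data.frame(id = c("a", "b"), heavy_atoms = c(9L, 9L),
                                  kegg_c = c("C8", "C9")),
                       c("pA", "pB"),
                       data.frame(compound = c("a", "a", "b", "b"),
                                  protein = c("pA", "pB", "pA", "pB"),
                                  experimental = 1))
  expect_equal(cleanup_network(clean)$edges, clean$edges)
})

test_that("degree-one pruning removes nodes simultaneously and fixpoint cascades", {
  # path c1-p1-c2: both compounds have degree 1, p1 becomes isolated
  path <- net_from_edges(c("c1", "c2"), c("p1", "p1"))
  pruned <- prune_degree_one(path, "single_pass")
  expect_equal(nrow(pruned$edges), 0)

  # complete 3x3 unchanged under either mode
  full <- net_from_matrix(matrix(TRUE, 3, 3))
  expect_equal(nrow(prune_degree_one(full, "single_pass")$edges), 9)
  expect_equal(nrow(prune_degree_one(full, "fixpoint")$edges), 9)

  # star: five degree-1 proteins fall, compound follows as isolated
  star <- net_from_edges(rep("hub", 5), sprintf("p%d", 1:5))
  expect_equal(nrow(prune_degree_one(star, "single_pass")$edges), 0)

  # chain that cascades only under fixpoint:
  # c1:{p1,p2}, c2:{p2,p3}, c3:{p3,p4}, p1 and p4 degree 1
  chain <- net_from_edges(c("c1", "c1", "c2", "c2", "c3", "c3"),
                          c("p1", "p2", "p2", "p3", "p3", "p4"))
  one <- prune_degree_one(chain, "single_pass")
  expect_gt(nrow(one$edges), 0)
  fx <- prune_degree_one(chain, "fixpoint")
  deg_ok <- function(net) {
    all(table(net$edges$compound) >= 2) && all(table(net$edges$protein) >= 2)
  }
  expect_true(nrow(fx$edges) == 0 || deg_ok(fx))
  expect_equal(prune_degree_one(chain, "off")$edges, chain$edges)
})

test_that("density and degree distributions follow their definitions", {
  expect_equal(density_summary(net_from_matrix(matrix(TRUE, 2, 2)))$density, 1)
  rnd0 <- random_net(9, 7, 0.35, seed = 5)
  d0 <- density_summary(rnd0)
  expect_equal(d0$density,
               d0$n_interactions / (d0$n_compounds * d0$n_proteins))
  expect_true((d0$density == 1) ==
                (d0$n_interactions == d0$n_compounds * d0$n_proteins))
  empty <- suppressWarnings(net_from_edges(character(), character()))
  expect_equal(density_summary(empty)$density, 0)

  full32 <- net_from_matrix(matrix(TRUE, 3, 2))
  dc <- degree_distribution(full32, "compound")
  expect_equal(dc, data.frame(degree = 2L, frequency = 3L))
  dp <- degree_distribution(full32, "protein")
  expect_equal(dp, data.frame(degree = 3L, frequency = 2L))

  rnd <- random_net(10, 8, 0.4, seed = 11)
  expect_equal(sum(degree_distribution(rnd, "compound")$frequency),
               nrow(rnd$compounds))
  expect_equal(sum(degree_distribution(rnd, "protein")$frequency),
               nrow(rnd$proteins))
})

test_that("cleanup and pruning preserve network invariants on random inputs", {
  for (s in 1:10) {
    net <- random_net(12, 9, 0.3, seed = 100 + s)
    expect_silent(validate_cpi_network(prune_degree_one(net, "single_pass")))
    fx <- prune_degree_one(net, "fixpoint")
    expect_silent(validate_cpi_network(fx))
    if (nrow(fx$edges) > 0) {
      expect_true(all(table(fx$edges$compound) >= 2))
      expect_true(all(table(fx$edges$protein) >= 2))
    }
    d <- density_summary(net)$density
    expect_gte(d, 0); expect_lte(d, 1)
  }
})
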