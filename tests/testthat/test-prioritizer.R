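cmp_row <- function(top = "t", mid = "m", target = "g",
                    src = c("StrongActivity", "WeakActivity", "StrongActivity"),
                    end = c("Poised", "WeakActivity", "WeakActivity"),
                    group = "edge_loss") {
  data.frame(top = top, mid = mid, target = target, group = group,
             n_edges_src = 3L, n_edges_end = 2L,
             top_src = src[1], mid_src = src[2], target_src = src[3],
             top_end = end[1], mid_end = end[2], target_end = end[3],
             state_missing = FALSE, stringsAsFactors = FALSE)
}

test_that("the scoring matrix carries the published defaults", {
  m <- state_change_scores()
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(isSymmetric(m))
  expect_equal(m["StrongActivity", "Poised"], 10)
  expect_equal(m["WeakActivity", "Repressed"], 10)
  expect_equal(m["Poised", "Repressed"], 5)
  expect_equal(m["StrongActivity", "WeakActivity"], 3)
})

test_that("instance scores follow the matrix plus the structural flat score", {
  # top Strong->Poised (10), mid Weak->Weak (0), target Strong->Weak (3),
  # one edge lost (+5)
  expect_equal(score_instance(cmp_row()), 18)
  expect_equal(score_instance(cmp_row(group = "no_change",
                                      end = c("StrongActivity",
                                              "WeakActivity",
                                              "StrongActivity"))), 0)
  expect_equal(score_instance(cmp_row(src = rep("Poised", 3),
                                      end = rep("Repressed", 3),
                                      group = "no_change")), 15)
})

test_that("instance scoring equals an exhaustive lookup oracle", {
  states <- broad_states()
  oracle_pair <- function(a, b) {
    if (a == b) return(0)
    act <- c("StrongActivity", "WeakActivity")
    rep_ <- c("Poised", "Repressed")
    if ((a %in% act) != (b %in% act)) return(10)
    if (all(c(a, b) %in% rep_)) return(5)
    3
  }
  grid <- expand.grid(src = states, end = states, changed = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    row <- cmp_row(src = c(g$src, "StrongActivity", "StrongActivity"),
                   end = c(g$end, "StrongActivity", "StrongActivity"),
                   group = if (g$changed) "edge_gain" else "no_change")
    expect_equal(score_instance(row),
                 oracle_pair(g$src, g$end) + 5 * g$changed)
  }
  # all three positions at once, exhaustive over 4x4 pairs per position in
  # a random sample of full configurations
  set.seed(14)
  for (i in 1:100) {
    src <- sample(states, 3, replace = TRUE)
    end <- sample(states, 3, replace = TRUE)
    changed <- sample(c(TRUE, FALSE), 1)
    row <- cmp_row(src = src, end = end,
                   group = if (changed) "edge_loss" else "no_change")
    want <- sum(mapply(oracle_pair, src, end)) + 5 * changed
    expect_equal(score_instance(row), want)
  }
})

test_that("summary scores add over instances and ties rank deterministically", {
  cmp <- rbind(cmp_row(top = "t1", mid = "m1", target = "shared"),
               cmp_row(top = "t2", mid = "m2", target = "shared",
                       src = rep("Poised", 3), end = rep("Repressed", 3),
                       group = "no_change"))
  res <- rank_genes(cmp)
  expect_equal(res$summary_score[res$gene == "shared"], 18 + 15)
  expect_equal(res$rank[res$gene == "shared"], 1L)
  # t1 and m1 tie at 18: same rank, gene-id order in the output
  sub <- res[res$gene %in% c("t1", "m1"), ]
  expect_equal(unique(sub$rank), 2L)
  expect_equal(sub$gene, c("m1", "t1"))
})

test_that("duplicate triples are counted once and scaling preserves ranks", {
  cmp <- rbind(cmp_row(), cmp_row())  # same unordered triple twice
  res <- rank_genes(cmp)
  expect_equal(res$n_instances, rep(1L, 3))
  expect_equal(res$summary_score, rep(18, 3))

  spec <- sim_spec(n_tfs = 15L, n_genes = 100L, seed = 83L)
  pair <- simulate_pair(spec)
  net_a <- annotate_network(regulatory_network(pair$A$edges), pair$A$states)
  net_b <- annotate_network(regulatory_network(pair$B$edges), pair$B$states)
  cmp2 <- compare_ffls(net_a, net_b, pair$A$states, pair$B$states)
  r1 <- rank_genes(cmp2)
  r2 <- rank_genes(cmp2, mat = 2 * state_change_scores(),
                   structural_change_score = 10)
  expect_equal(r2$summary_score, 2 * r1$summary_score)
  expect_equal(r2$rank, r1$rank)
  expect_equal(r2$gene, r1$gene)
  # order of instances does not matter
  r3 <- rank_genes(cmp2[rev(seq_len(nrow(cmp2))), ])
  expect_equal(r3, r1)
})

test_that("planted driver genes are enriched in the top 1%", {
  spec <- sim_spec(
    n_tfs = 20L, n_genes = 150L,
    planted_motifs = list(
      list(structure = "ffl",
           states = c("StrongActivity", "StrongActivity", "WeakActivity"),
           copies = 400L),                       # neutral copies
      list(structure = "ffl",
           states = c("Poised", "StrongActivity", "StrongActivity"),
           copies = 15L)                          # drivers
    ),
    transition_spec = data.frame(position = "top", from = "Poised",
                                 to = "StrongActivity", rate = 1.0,
                                 stringsAsFactors = FALSE),
    background_flip_rate = 0, edge_loss_rate = 0, seed = 101L
  )
  pair <- simulate_pair(spec)
  net_a <- annotate_network(regulatory_network(pair$A$edges), pair$A$states)
  net_b <- annotate_network(regulatory_network(pair$B$edges), pair$B$states)
  cmp <- compare_ffls(net_a, net_b, pair$A$states, pair$B$states)
  res <- rank_genes(cmp)
  m <- pair$A$truth$motifs
  drivers <- unlist(m[m$entry == 2, c("top", "mid", "target")])
  enr <- top_fraction_enrichment(res, drivers, fraction = 0.01)
  expect_lt(enr$p, 0.01)
  expect_true(all(enr$top_genes %in% drivers))
})

test_that("top-fraction enrichment validates inputs and degenerate sets", {
  res <- rank_genes(rbind(cmp_row()))
  expect_error(top_fraction_enrichment(res, "t", fraction = 1))
  expect_warning(enr <- top_fraction_enrichment(res, "absent"), "intersect")
  expect_equal(enr$p, 1)
})
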