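mk_labeled <- function(edges, states) {
  annotate_network(regulatory_network(edges), states)
}

test_that("identical networks are 100% no_change with zero transitions", {
  edges <- data.frame(tf = c("A", "A", "B"), target = c("B", "C", "C"))
  st <- c(A = "StrongActivity", B = "StrongActivity", C = "Poised")
  net <- mk_labeled(edges, st)
  cmp <- compare_ffls(net, net)
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$group, "no_change")
  expect_equal(cmp$n_edges_end, 3L)
  expect_equal(cmp$top_src, cmp$top_end)
})

test_that("a deleted edge classifies the instance as edge_loss", {
  edges <- data.frame(tf = c("A", "A", "B"), target = c("B", "C", "C"))
  st <- c(A = "StrongActivity", B = "StrongActivity", C = "Poised")
  net_a <- mk_labeled(edges, st)
  net_b <- mk_labeled(edges[-3, ], st)  # drop B -> C (mid -> target)
  cmp <- compare_ffls(net_a, net_b)
  expect_equal(cmp$group, "edge_loss")
  expect_equal(cmp$n_edges_end, 2L)
  # the reverse comparison records the instance as edge_gain
  cmp_rev <- compare_ffls(net_b, net_a)
  expect_equal(cmp_rev$group, "edge_gain")
  expect_equal(cmp_rev$n_edges_src, 2L)
})

test_that("planted edge losses appear at the planted rate", {
  spec <- sim_spec(seed = 29L)
  pair <- simulate_pair(spec)
  net_a <- annotate_network(regulatory_network(pair$A$edges),
                            pair$A$truth$states)
  net_b <- annotate_network(regulatory_network(pair$B$edges),
                            pair$B$truth$states)
  cmp <- compare_ffls(net_a, net_b, pair$A$states, pair$B$states)
  lost_copies <- unique(pair$truth_changes$edge_losses$copy)
  planted <- cmp[grepl("^P", cmp$top), ]
  expect_equal(sum(planted$group == "edge_loss"), length(lost_copies))
  # 20% planted loss rate, binomial tolerance
  n_copies <- nrow(pair$A$truth$motifs)
  frac <- length(lost_copies) / n_copies
  expect_lt(abs(frac - spec$edge_loss_rate),
            3 * sqrt(0.2 * 0.8 / n_copies))
})

test_that("planted top-position transitions dominate the background", {
  spec <- sim_spec(seed = 47L)
  pair <- simulate_pair(spec)
  net_a <- annotate_network(regulatory_network(pair$A$edges),
                            pair$A$truth$states)
  net_b <- annotate_network(regulatory_network(pair$B$edges),
                            pair$B$truth$states)
  cmp <- compare_ffls(net_a, net_b, pair$A$states, pair$B$states)
  set.seed(2)
  trans <- transition_test(cmp, net_a, net_b, pair$A$states, pair$B$states,
                           n_perm = 200L)
  cell <- trans[trans$group == "no_change" & trans$position == "top" &
                  trans$from == "Poised" & trans$to == "StrongActivity", ]
  # planted flips hit 30% of Poised-top FFLs vs ~2% background flips;
  # at 200 permutations the p-value sits at (or within one draw of) the
  # resolution floor
  expect_gt(cell$count, 0)
  expect_lte(cell$p, 2 / 200)
  # cross-state transitions that never occur keep p = 1
  absent <- trans[trans$count == 0 & trans$from != trans$to, ]
  expect_true(all(absent$p == 1))
  expect_true(all(absent$frequency == 0))
})

test_that("every source instance falls in exactly one change group", {
  spec <- sim_spec(n_tfs = 15L, n_genes = 100L, seed = 61L,
                   edge_gain_rate = 0.1)
  pair <- simulate_pair(spec)
  net_a <- annotate_network(regulatory_network(pair$A$edges),
                            pair$A$truth$states)
  net_b <- annotate_network(regulatory_network(pair$B$edges),
                            pair$B$truth$states)
  cmp <- compare_ffls(net_a, net_b)
  src <- ffl_instances(net_a)
  expect_equal(sum(cmp$group %in% c("no_change", "edge_loss")), nrow(src))
  gains <- cmp[cmp$group == "edge_gain", ]
  expect_true(all(gains$n_edges_src < 3))
  expect_gt(nrow(gains), 0)
  # gains recorded in the truth table are recovered
  gained_copies <- pair$truth_changes$edge_gains$copy
  expect_true(all(sub("_.*", "", gains$top[grepl("^P", gains$top)]) %in%
                    gained_copies | !grepl("^P", gains$top)))
})

test_that("transition p-values are super-uniform under a label-shuffled null", {
  set.seed(303)
  spec <- sim_spec(n_tfs = 20L, n_genes = 120L,
                   planted_motifs = list(list(structure = "ffl",
                                              states = c("StrongActivity",
                                                         "StrongActivity",
                                                         "Poised"),
                                              copies = 30L)),
                   transition_spec = data.frame(position = character(),
                                                from = character(),
                                                to = character(),
                                                rate = numeric()),
                   background_flip_rate = 0.05,
                   edge_loss_rate = 0, seed = 71L)
  pair <- simulate_pair(spec)
  states_a <- pair$A$states
  st_end <- pair$B$states
  st_end$state <- sample(st_end$state)  # break any real coupling
  net_a <- annotate_network(regulatory_network(pair$A$edges), states_a)
  tf_pool <- unique(net_a$edges$tf)
  tgt_pool <- unique(net_a$edges$target)
  src <- setNames(states_a$state, states_a$gene)
  end <- setNames(st_end$state, st_end$gene)
  # the "real" group is itself a pool draw, so the artificial-instance test
  # is exactly calibrated for it
  pvals <- c()
  for (r in 1:25) {
    k <- 40L
    top <- sample(tf_pool, k, replace = TRUE)
    mid <- sample(tf_pool, k, replace = TRUE)
    tgt <- sample(tgt_pool, k, replace = TRUE)
    ok <- top != mid & top != tgt & mid != tgt
    cmp <- data.frame(
      top = top[ok], mid = mid[ok], target = tgt[ok], group = "no_change",
      n_edges_src = 3L, n_edges_end = 3L,
      top_src = src[top[ok]], mid_src = src[mid[ok]],
      target_src = src[tgt[ok]],
      top_end = end[top[ok]], mid_end = end[mid[ok]],
      target_end = end[tgt[ok]],
      state_missing = FALSE, stringsAsFactors = FALSE
    )
    tr <- transition_test(cmp, net_a, NULL, states_a, st_end, n_perm = 49L)
    pvals <- c(pvals, tr$p)
  }
  # valid permutation p: P(p <= t) <= t (+ discreteness slack)
  for (t in c(0.05, 0.1, 0.25)) {
    slack <- 1 / 49 + 3 * sqrt(t * (1 - t) / length(pvals))
    expect_lt(mean(pvals <= t), t + slack)
  }
})
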