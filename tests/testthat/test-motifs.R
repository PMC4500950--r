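test_that("exactly 13 connected triad structures exist, matching igraph", {
  codes <- triad_structures()
  expect_length(codes, 13L)
  skip_if_not_installed("igraph")
  # independent check: igraph isomorphism classes of all 64 digraphs
  iso <- integer(0)
  for (ac in 0:63) {
    bits <- as.integer(intToBits(ac))[6:1]
    adj <- matrix(0L, 3, 3)
    adj[rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))] <- bits
    und <- (adj + t(adj)) > 0
    if (und[1, 2] + und[1, 3] + und[2, 3] < 2) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    iso <- c(iso, igraph::isomorphism_class(g))
  }
  expect_length(unique(iso), 13L)
})

test_that("canonical colored codes respect automorphisms and asymmetry", {
  # mutual dyad plus common regulator: swapping the symmetric pair's labels
  # gives the same class
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE   # mutual pair 1<->2
  adj[3, 1] <- adj[3, 2] <- TRUE   # 3 regulates both
  c1 <- canonical_colored_code(adj, c("Poised", "Repressed", "StrongActivity"))
  c2 <- canonical_colored_code(adj, c("Repressed", "Poised", "StrongActivity"))
  expect_equal(c1$code, c2$code)

  # the FFL has no nontrivial automorphism: permuting distinct states
  # across positions changes the class
  ffl <- matrix(FALSE, 3, 3)
  ffl[1, 2] <- ffl[1, 3] <- ffl[2, 3] <- TRUE
  a <- canonical_colored_code(ffl, c("StrongActivity", "Poised", "WeakActivity"))
  b <- canonical_colored_code(ffl, c("Poised", "StrongActivity", "WeakActivity"))
  expect_false(a$code == b$code)
  expect_equal(a$structure, ffl_structure_code())
  expect_error(canonical_colored_code(diag(3) > 1, rep("Poised", 3)),
               "not weakly connected")
})

test_that("colored class count matches the Burnside orbit count", {
  # Burnside: orbits of 4^3 colorings under each structure's automorphisms
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  n_cycles <- function(p) {
    seen <- rep(FALSE, 3); n <- 0L
    for (s in 1:3) {
      if (seen[s]) next
      n <- n + 1L; j <- s
      while (!seen[j]) { seen[j] <- TRUE; j <- p[j] }
    }
    n
  }
  expected <- 0
  for (code in triad_structures()) {
    bits <- as.integer(intToBits(code))[6:1]
    adj <- matrix(FALSE, 3, 3)
    adj[rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))] <- bits == 1
    aut <- which(vapply(1:6, function(p) {
      identical(adj[perms[p, ], perms[p, ]], adj)
    }, TRUE))
    expected <- expected +
      sum(vapply(aut, function(p) 4^n_cycles(perms[p, ]), 0)) / length(aut)
  }

  # distinct canonical colored codes over every structure x coloring
  states <- broad_states()
  seen <- new.env()
  for (code in 0:63) {
    bits <- as.integer(intToBits(code))[6:1]
    adj <- matrix(FALSE, 3, 3)
    adj[rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))] <- bits == 1
    und <- adj | t(adj)
    if (und[1, 2] + und[1, 3] + und[2, 3] < 2) next
    for (cc in 0:63) {
      cols <- states[c(cc %/% 16, (cc %/% 4) %% 4, cc %% 4) + 1]
      key <- as.character(canonical_colored_code(adj, cols)$code)
      assign(key, TRUE, envir = seen)
    }
  }
  expect_equal(length(ls(seen)), expected)
})

test_that("the census equals a brute-force colored census on random digraphs", {
  set.seed(202)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    net <- random_labeled_net(n, p_edge = 0.12)
    got <- census_as_vector(net)
    edges <- data.frame(from = match(net$edges$tf, net$nodes$gene),
                        to = match(net$edges$target, net$nodes$gene))
    want <- oracle_colored_census(n, edges,
                                  chromotif:::state_to_int(net$nodes$state))
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("renaming nodes leaves class keys unchanged", {
  set.seed(5)
  net <- random_labeled_net(15, 0.15)
  perm <- sample(nrow(net$nodes))
  map <- setNames(sprintf("z%02d", seq_along(perm)), net$nodes$gene[perm])
  net2 <- regulatory_network(
    data.frame(tf = unname(map[net$edges$tf]),
               target = unname(map[net$edges$target]),
               stringsAsFactors = FALSE),
    nodes = data.frame(gene = unname(map[net$nodes$gene]), is_tf = TRUE,
                       state = net$nodes$state, stringsAsFactors = FALSE)
  )
  c1 <- census_as_vector(net)
  c2 <- census_as_vector(net2)
  expect_equal(c1[order(names(c1))], c2[order(names(c2))])
})

test_that("randomization preserves degrees, target-state vectors and dyads", {
  set.seed(31)
  spec <- sim_spec(n_tfs = 40L, n_genes = 200L, n_background_edges = 600L,
                   seed = 13L)
  b <- simulate_condition(spec)
  net <- annotate_network(regulatory_network(b$edges), b$truth$states)
  deg0 <- degrees_of(net)
  tab0 <- tf_state_table(net)
  dy0 <- chromotif:::mutual_dyad_count(net)
  for (r in 1:10) {
    rnet <- randomize_network(net)
    expect_gt(attr(rnet, "accepted"), 0)
    deg <- degrees_of(rnet)
    expect_equal(deg$out, deg0$out)
    expect_equal(deg$inn, deg0$inn)
    expect_equal(tf_state_table(rnet), tab0)
    expect_equal(chromotif:::mutual_dyad_count(rnet), dy0)
    expect_false(any(rnet$edges$tf == rnet$edges$target))
    expect_equal(anyDuplicated(paste(rnet$edges$tf, rnet$edges$target)), 0L)
  }
})

test_that("networks with no legal swap come back unchanged", {
  # two edges whose targets have different states: every swap is rejected
  net <- regulatory_network(data.frame(tf = c("A", "B"),
                                       target = c("C", "D")))
  net <- annotate_network(net, c(A = "StrongActivity", B = "StrongActivity",
                                 C = "Poised", D = "Repressed"))
  rnet <- randomize_network(net, n_swaps = 100L)
  expect_equal(rnet$edges, net$edges)
  expect_equal(attr(rnet, "accepted"), 0L)
  # same-state targets: swaps toggle between exactly the two legal
  # configurations, and both are visited
  net2 <- annotate_network(
    regulatory_network(data.frame(tf = c("A", "B"), target = c("C", "D"))),
    c(A = "StrongActivity", B = "StrongActivity", C = "Poised", D = "Poised"))
  set.seed(8)
  seen <- unique(vapply(1:20, function(i) {
    r <- randomize_network(net2, n_swaps = 7L)
    paste(sort(paste(r$edges$tf, r$edges$target)), collapse = ";")
  }, ""))
  expect_true(all(seen %in% c("A C;B D", "A D;B C")))
  expect_length(seen, 2L)
})

test_that("planted colored FFLs are called significant, ties are not", {
  spec <- sim_spec(seed = 17L)
  b <- simulate_condition(spec)
  net <- annotate_network(regulatory_network(b$edges), b$truth$states)
  set.seed(1)
  res <- find_significant_motifs(net, n_random = 100L)
  planted <- ffl_class_code("StrongActivity", "StrongActivity", "Poised")
  row <- res[res$code == planted, ]
  expect_equal(nrow(row), 1L)
  expect_gte(row$n_real, 50L)
  expect_true(row$significant)
  expect_true(attr(res, "dyad_preserved"))

  # constant replicate counts equal to the real count are never significant
  fake <- data.frame(n_real = 10, n_rand = I(list(rep(10, 30))))
  p <- mean(fake$n_rand[[1]] >= fake$n_real)
  expect_equal(p, 1)
})

test_that("under random labels the significant fraction stays near alpha", {
  set.seed(77)
  net <- random_labeled_net(45, 0.10)
  res <- find_significant_motifs(net, n_random = 60L)
  expect_gt(nrow(res), 50)
  frac <- mean(res$p_emp < 0.05)
  # empirical P is super-uniform for discrete counts, so the fraction may
  # fall below alpha but should not exceed it by more than binomial noise
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("colored counts sum to the uncolored triad census (igraph)", {
  skip_if_not_installed("igraph")
  set.seed(12)
  net <- random_labeled_net(30, 0.12)
  cen <- enumerate_triads(net)
  g <- igraph::graph_from_data_frame(net$edges, vertices = net$nodes$gene)
  tc <- igraph::triad_census(g)
  # igraph classes 1-3 (003, 012, 102) are not weakly connected
  expect_equal(sum(cen$count), sum(tc[-(1:3)]))
  # per-structure marginal: locate each structure's igraph class via a
  # one-triad graph
  per_structure <- tapply(cen$count, cen$structure, sum)
  for (sc in names(per_structure)) {
    bits <- as.integer(intToBits(as.integer(sc)))[6:1]
    adj <- matrix(0L, 3, 3)
    adj[rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))] <- bits
    g1 <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    idx <- which(igraph::triad_census(g1) == 1)
    idx <- setdiff(idx, 1:3)
    expect_equal(unname(per_structure[[sc]]), tc[idx])
  }
})
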