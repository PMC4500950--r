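# Independent oracles used across the suite. These deliberately use
# different algorithms from the package paths they check: exhaustive
# enumeration over all triples / draws, vectorized base-R arithmetic.

ORACLE_PERMS <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
ORACLE_PAIRS <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))

# Exhaustive colored triad census over all C(n,3) triples of a directed
# graph. edges: data.frame(from, to) of 1-based node indices; colors:
# integer vector in 0..3. Returns a named count vector keyed by class code.
oracle_colored_census <- function(n, edges, colors) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) A[cbind(edges$from, edges$to)] <- TRUE
  diag(A) <- FALSE
  trip <- t(combn(n, 3))
  codes <- rep(Inf, nrow(trip))
  for (p in 1:6) {
    pt <- trip[, ORACLE_PERMS[p, ], drop = FALSE]
    adjcode <- 0
    for (k in 1:6) {
      adjcode <- adjcode * 2 +
        A[cbind(pt[, ORACLE_PAIRS[k, 1]], pt[, ORACLE_PAIRS[k, 2]])]
    }
    colcode <- colors[pt[, 1]] * 16 + colors[pt[, 2]] * 4 + colors[pt[, 3]]
    codes <- pmin(codes, adjcode * 64 + colcode)
  }
  U <- A | t(A)
  npairs <- U[cbind(trip[, 1], trip[, 2])] +
    U[cbind(trip[, 1], trip[, 3])] + U[cbind(trip[, 2], trip[, 3])]
  tab <- table(codes[npairs >= 2])
  setNames(as.integer(tab), names(tab))
}

# Random directed graph as a labeled regnet (every node flagged TF so the
# swap null can act on all edges).
random_labeled_net <- function(n, p_edge) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- pairs[runif(nrow(pairs)) < p_edge, ]
  genes <- sprintf("n%02d", seq_len(n))
  net <- regulatory_network(
    data.frame(tf = genes[keep$from], target = genes[keep$to],
               stringsAsFactors = FALSE),
    nodes = data.frame(gene = genes, is_tf = TRUE, stringsAsFactors = FALSE)
  )
  annotate_network(net, setNames(sample(broad_states(), n, replace = TRUE),
                                 genes))
}

# Census of a regnet keyed like the oracle (named count vector).
census_as_vector <- function(net) {
  cen <- enumerate_triads(net)
  setNames(cen$count, cen$code)
}

# Exhaustive hypergeometric upper tail by enumerating all draws of size M
# from N with the first n elements "marked".
oracle_hypergeom <- function(N, n, M, k) {
  draws <- combn(N, M)
  hits <- colSums(draws <= n)
  mean(hits >= k)
}

# Per-TF target-state count table of a labeled regnet.
tf_state_table <- function(net) {
  st <- setNames(net$nodes$state, net$nodes$gene)
  tab <- table(net$edges$tf, st[net$edges$target])
  tab[order(rownames(tab)), , drop = FALSE]
}

degrees_of <- function(net) {
  genes <- net$nodes$gene
  list(out = table(factor(net$edges$tf, genes)),
       inn = table(factor(net$edges$target, genes)))
}
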