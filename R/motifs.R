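# Colored triad census and the state-preserving randomization null.
#
# Class encoding (shared with the compiled census): a colored triad class is
# code = adjcode * 64 + colorcode, adjcode packing the six off-diagonal
# adjacency bits in pair order (1,2),(1,3),(2,1),(2,3),(3,1),(3,2) and
# colorcode = c1*16 + c2*4 + c3 with state integers 0..3
# (StrongActivity, WeakActivity, Poised, Repressed). The canonical code is
# the minimum over the six node permutations, so it is invariant under node
# relabeling and identifies colorings only up to structure automorphisms.

triad_perms <- function() {
  rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
}

triad_pairs <- function() {
  rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
}

adjcode_of <- function(adj, perm) {
  pr <- triad_pairs()
  a <- 0L
  for (k in 1:6) a <- a * 2L + as.integer(adj[perm[pr[k, 1]], perm[pr[k, 2]]])
  a
}

adj_from_code <- function(adjcode) {
  pr <- triad_pairs()
  bits <- as.integer(intToBits(adjcode))[6:1]
  adj <- matrix(FALSE, 3, 3)
  adj[pr] <- bits == 1L
  adj
}

#' Canonical colored code of a three-node subgraph
#'
#' Computes the isomorphism-invariant identity of one connected directed
#' 3-node graph together with a chromatin-state assignment to its nodes.
#' Two node relabelings of the same colored subgraph receive the same code;
#' for structures with nontrivial automorphisms, equivalent colorings
#' collapse to one class.
#'
#' @param adjacency 3x3 logical matrix (diagonal ignored, must be
#'   effectively FALSE).
#' @param colors Character vector of 3 broad states (see [broad_states()]).
#' @return List with `code` (integer), `structure` (canonical structure
#'   code) and `coloring` (the 3 states in canonical position order).
#' @export
canonical_colored_code <- function(adjacency, colors) {
  adjacency <- adjacency & !diag(TRUE, 3)
  und <- adjacency | t(adjacency)
  npairs <- und[1, 2] + und[1, 3] + und[2, 3]
  if (npairs < 2) stop("triad is not weakly connected")
  ci <- state_to_int(colors)
  perms <- triad_perms()
  best <- Inf
  for (p in 1:6) {
    perm <- perms[p, ]
    code <- adjcode_of(adjacency, perm) * 64 +
      ci[perm[1]] * 16 + ci[perm[2]] * 4 + ci[perm[3]]
    if (code < best) best <- code
  }
  best <- as.integer(best)
  list(code = best, structure = best %/% 64L,
       coloring = decode_coloring(best))
}

decode_coloring <- function(code) {
  cc <- code %% 64L
  int_to_state(c(cc %/% 16L, (cc %/% 4L) %% 4L, cc %% 4L))
}

coloring_string <- function(code) {
  vapply(code, function(x) paste(decode_coloring(x), collapse = "/"), "")
}

#' The 13 weakly connected three-node structures
#'
#' Brute-force enumeration over all 64 directed edge configurations on three
#' labeled nodes, grouped by isomorphism; exactly the 13 weakly connected
#' classes remain.
#'
#' @return Sorted integer vector of the 13 canonical structure codes.
#' @export
triad_structures <- function() {
  perms <- triad_perms()
  codes <- integer(0)
  for (ac in 0:63) {
    adj <- adj_from_code(ac)
    und <- adj | t(adj)
    if (und[1, 2] + und[1, 3] + und[2, 3] < 2) next
    codes <- c(codes, min(vapply(1:6, function(p) adjcode_of(adj, perms[p, ]), 0L)))
  }
  sort(unique(codes))
}

#' Canonical structure code of the feedforward loop
#'
#' Top regulates intermediate and target; intermediate regulates target.
#'
#' @return Integer structure code.
#' @export
ffl_structure_code <- function() {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[1, 3] <- adj[2, 3] <- TRUE
  perms <- triad_perms()
  min(vapply(1:6, function(p) adjcode_of(adj, perms[p, ]), 0L))
}

net_state_ints <- function(net) {
  if (anyNA(net$nodes$state)) {
    stop("network nodes lack states; run annotate_network() first")
  }
  state_to_int(net$nodes$state)
}

#' Census of state-colored connected triads
#'
#' Counts every weakly connected induced 3-node subgraph of the network
#' exactly once, keyed by canonical colored class. Self-loops are excluded
#' from enumeration.
#'
#' @param net A labeled `regnet` (states set on all nodes).
#' @param keep_instances Also return the instance list (genes in canonical
#'   position order) as attribute `"instances"`.
#' @return Data frame `code`, `structure`, `coloring`, `count`.
#' @export
enumerate_triads <- function(net, keep_instances = FALSE) {
  nodes <- net$nodes$gene
  e <- net$edges[net$edges$tf != net$edges$target, , drop = FALSE]
  res <- triad_census_colored_cpp(
    length(nodes),
    match(e$tf, nodes) - 1L, match(e$target, nodes) - 1L,
    net_state_ints(net), keep_instances
  )
  out <- data.frame(code = res$code,
                    structure = res$code %/% 64L,
                    coloring = coloring_string(res$code),
                    count = res$count,
                    stringsAsFactors = FALSE)
  if (keep_instances) {
    attr(out, "instances") <- data.frame(
      code = res$inst_code,
      n1 = nodes[res$inst_n1 + 1L],
      n2 = nodes[res$inst_n2 + 1L],
      n3 = nodes[res$inst_n3 + 1L],
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Randomize a labeled network under the state-preserving null
#'
#' Iterative constrained double edge swaps that preserve (exactly) the in-
#' and out-degree of every node, the per-TF count of targets in each broad
#' state, and the count of every two-node subgraph (single edges and mutual
#' dyads are swapped within their own class). Swaps that would create
#' self-loops, duplicate edges, or turn a single edge into a mutual pair are
#' rejected. Node states are untouched. Uses the current R RNG stream.
#'
#' @param net A labeled `regnet`.
#' @param n_swaps Number of attempted swaps; default `10 * n_edges`.
#' @return A `regnet` with shuffled edges (attribute `"accepted"` records
#'   accepted swaps).
#' @export
randomize_network <- function(net, n_swaps = NULL) {
  m <- nrow(net$edges)
  if (m < 2) {
    warning("fewer than 2 edges; nothing to randomize")
    return(net)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  nodes <- net$nodes$gene
  res <- swap_randomize_cpp(
    length(nodes),
    match(net$edges$tf, nodes) - 1L, match(net$edges$target, nodes) - 1L,
    net_state_ints(net), as.integer(n_swaps)
  )
  edges <- data.frame(tf = nodes[res$from + 1L], target = nodes[res$to + 1L],
                      stringsAsFactors = FALSE)
  out <- regulatory_network(edges, net$nodes)
  attr(out, "accepted") <- res$accepted
  out
}

mutual_dyad_count <- function(net) {
  key <- paste(net$edges$tf, net$edges$target)
  rev <- paste(net$edges$target, net$edges$tf)
  sum(key %in% rev & net$edges$tf < net$edges$target)
}

#' Significant state-modified motifs against randomized networks
#'
#' Counts colored triad classes in the real network and in `n_random`
#' randomized replicates (each generated from the real network by
#' [randomize_network()]). A class observed in the real network is
#' significant when its empirical P (fraction of replicates with a count at
#' least as large) is below `alpha` and the real count exceeds the
#' randomized mean by more than 5%: `n_real - n_rand_mean > 0.05 *
#' n_rand_mean`. Only classes observed in the real network are tested.
#'
#' @param net A labeled `regnet`.
#' @param n_random Number of randomized networks; default 500.
#' @param alpha Significance level; default 0.05.
#' @param swap_factor Attempted swaps per replicate as a multiple of the
#'   edge count; default 10.
#' @param keep_instances Attach the real network's instance list.
#' @return Data frame `code`, `structure`, `coloring`, `n_real`,
#'   `n_rand_mean`, `n_rand_sd`, `p_emp`, `significant`; the replicate count
#'   matrix is attached as attribute `"n_rand"`, and the two-node-subgraph
#'   preservation check as attribute `"dyad_preserved"`.
#' @export
find_significant_motifs <- function(net, n_random = 500L, alpha = 0.05,
                                    swap_factor = 10L, keep_instances = FALSE) {
  if (n_random < 20) warning("n_random < 20: empirical P resolution is coarse")
  real <- enumerate_triads(net, keep_instances = keep_instances)
  nr <- matrix(0L, nrow = nrow(real), ncol = n_random,
               dimnames = list(real$code, NULL))
  dy <- mutual_dyad_count(net)
  dyad_ok <- TRUE
  n_swaps <- as.integer(swap_factor) * nrow(net$edges)
  for (r in seq_len(n_random)) {
    rnet <- randomize_network(net, n_swaps = n_swaps)
    if (mutual_dyad_count(rnet) != dy) dyad_ok <- FALSE
    cen <- enumerate_triads(rnet)
    idx <- match(cen$code, real$code)
    keep <- !is.na(idx)
    nr[idx[keep], r] <- cen$count[keep]
  }
  n_real <- real$count
  p_emp <- rowMeans(nr >= n_real)
  mean_rand <- rowMeans(nr)
  out <- data.frame(
    code = real$code, structure = real$structure, coloring = real$coloring,
    n_real = n_real,
    n_rand_mean = mean_rand,
    n_rand_sd = apply(nr, 1, sd),
    p_emp = p_emp,
    significant = p_emp < alpha & (n_real - mean_rand) > 0.05 * mean_rand,
    stringsAsFactors = FALSE
  )
  attr(out, "n_rand") <- nr
  attr(out, "dyad_preserved") <- dyad_ok
  if (keep_instances) attr(out, "instances") <- attr(real, "instances")
  out
}

#' Colored class code of an FFL with given position states
#'
#' Maps a (top, intermediate, target) state assignment of a feedforward
#' loop to its canonical colored class code, the key used by
#' [enumerate_triads()] and [find_significant_motifs()]. Vectorized.
#'
#' @param top_state,mid_state,target_state Broad states per position.
#' @return Integer class code(s).
#' @export
ffl_class_code <- function(top_state, mid_state, target_state) {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[1, 3] <- adj[2, 3] <- TRUE
  vapply(seq_along(top_state), function(i) {
    canonical_colored_code(
      adj, c(top_state[i], mid_state[i], target_state[i]))$code
  }, 0L)
}
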