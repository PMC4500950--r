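# Between-condition FFL comparison: structural change classification and
# the state-transition permutation test.

#' Compare FFL instances between two cell conditions
#'
#' Every FFL instance of the source network is classified by how many of
#' its three edges persist in the end network (3: `no_change`; fewer:
#' `edge_loss`); every FFL instance of the end network whose edges are not
#' all present in the source is recorded as `edge_gain`. Per-condition
#' states are looked up in the networks or in explicit gene-state tables
#' (states are promoter properties, so genes absent from one network can
#' still carry a state there); instances with a gene lacking a state in
#' either condition are flagged via `state_missing` and excluded from
#' transition counting.
#'
#' @param net_src,net_end Labeled `regnet`s sharing a gene namespace.
#' @param states_src,states_end Optional gene-state tables (`gene`,
#'   `state`) overriding the node states.
#' @return Data frame with the instance triple, `group`, `n_edges_src`,
#'   `n_edges_end`, per-position source/end states and `state_missing`.
#' @export
compare_ffls <- function(net_src, net_end, states_src = NULL,
                         states_end = NULL) {
  st_src <- condition_states(net_src, states_src)
  st_end <- condition_states(net_end, states_end)
  f_src <- ffl_instances(net_src)
  f_end <- ffl_instances(net_end)
  ekey_src <- paste(net_src$edges$tf, net_src$edges$target)
  ekey_end <- paste(net_end$edges$tf, net_end$edges$target)

  count_edges <- function(f, ekey) {
    if (nrow(f) == 0) return(integer(0))
    (paste(f$top, f$mid) %in% ekey) +
      (paste(f$top, f$target) %in% ekey) +
      (paste(f$mid, f$target) %in% ekey)
  }

  rows <- list()
  if (nrow(f_src) > 0) {
    in_end <- count_edges(f_src, ekey_end)
    rows$src <- data.frame(
      top = f_src$top, mid = f_src$mid, target = f_src$target,
      group = ifelse(in_end == 3L, "no_change", "edge_loss"),
      n_edges_src = 3L, n_edges_end = in_end,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(f_end) > 0) {
    in_src <- count_edges(f_end, ekey_src)
    gain <- in_src < 3L
    if (any(gain)) {
      rows$end <- data.frame(
        top = f_end$top[gain], mid = f_end$mid[gain],
        target = f_end$target[gain],
        group = "edge_gain",
        n_edges_src = in_src[gain], n_edges_end = 3L,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(top = character(), mid = character(), target = character(),
               group = character(), n_edges_src = integer(),
               n_edges_end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (pos in c("top", "mid", "target")) {
    out[[paste0(pos, "_src")]] <- unname(st_src[out[[pos]]])
    out[[paste0(pos, "_end")]] <- unname(st_end[out[[pos]]])
  }
  out$state_missing <- is.na(out$top_src) | is.na(out$mid_src) |
    is.na(out$target_src) | is.na(out$top_end) | is.na(out$mid_end) |
    is.na(out$target_end)
  if (any(out$state_missing)) {
    message(sum(out$state_missing),
            " instance(s) with missing states flagged; excluded from transitions")
  }
  out
}

condition_states <- function(net, states) {
  st <- setNames(net$nodes$state, net$nodes$gene)
  if (!is.null(states)) {
    if (is.data.frame(states)) states <- setNames(states$state, states$gene)
    st[names(states)] <- states
    extra <- setdiff(names(states), names(st))
    st <- c(st[setdiff(names(st), extra)], states[extra])
  }
  st
}

#' Permutation test for per-position state transitions
#'
#' Within each structural change group, the frequency of every (from ->
#' to) state pair at every FFL position (including within-state pairs) is
#' compared with artificial FFL instance sets: each of the `n_perm` sets
#' draws as many triples as the real group, sampling top and intermediate
#' positions from the source network's TF pool and the bottom position from
#' its target pool, uniformly and without regard to edges, with the three
#' genes of a triple distinct. The P-value is the fraction of artificial
#' sets whose transition frequency is greater than or equal to the real
#' one (ties count against significance).
#'
#' @param comparisons Output of [compare_ffls()].
#' @param net_src Source-condition `regnet` providing the sampling pools.
#' @param net_end End-condition `regnet` (for end states); optional when
#'   `states_end` is given.
#' @param states_src,states_end Optional gene-state tables for the pools.
#' @param n_perm Number of artificial sets; default 1000.
#' @return Data frame `group`, `position`, `from`, `to`, `count`,
#'   `frequency`, `p`.
#' @export
transition_test <- function(comparisons, net_src, net_end = NULL,
                            states_src = NULL, states_end = NULL,
                            n_perm = 1000L) {
  if (is.null(net_end) && is.null(states_end)) {
    stop("provide net_end and/or states_end for end-condition states")
  }
  st_src <- condition_states(net_src, states_src)
  st_end <- condition_states(net_end %||% net_src, states_end)
  cmp <- comparisons[!comparisons$state_missing, , drop = FALSE]
  if (nrow(cmp) == 0) stop("no instances with complete states")

  tf_pool <- unique(net_src$edges$tf)
  tgt_pool <- unique(net_src$edges$target)
  pool_ok <- function(pool) {
    ok <- !is.na(st_src[pool]) & !is.na(st_end[pool])
    if (!all(ok)) warning(sum(!ok), " pool gene(s) without both states dropped")
    pool[ok]
  }
  tf_pool <- pool_ok(tf_pool)
  tgt_pool <- pool_ok(tgt_pool)
  if (length(tf_pool) < 2 || length(tgt_pool) < 1) {
    stop("TF or target pool too small for artificial instances")
  }
  # transition id (1..16) per pool gene
  tid <- function(genes) {
    4L * (state_to_int(st_src[genes])) + state_to_int(st_end[genes]) + 1L
  }
  tf_tid <- tid(tf_pool)
  tgt_tid <- tid(tgt_pool)

  states <- state_levels()
  grid <- expand.grid(to = states, from = states, stringsAsFactors = FALSE)
  grid <- grid[, c("from", "to")]
  pos_names <- c(top = "top", mid = "intermediate", target = "bottom")

  out <- list()
  for (g in unique(cmp$group)) {
    sub <- cmp[cmp$group == g, , drop = FALSE]
    k <- nrow(sub)
    # artificial sets: k triples per set, distinct genes within a triple
    perm_counts <- vector("list", 3)
    names(perm_counts) <- c("top", "mid", "target")
    for (p in names(perm_counts)) {
      perm_counts[[p]] <- matrix(0L, nrow = n_perm, ncol = 16L)
    }
    for (r in seq_len(n_perm)) {
      top_i <- sample.int(length(tf_pool), k, replace = TRUE)
      mid_i <- sample.int(length(tf_pool), k, replace = TRUE)
      tgt_i <- sample.int(length(tgt_pool), k, replace = TRUE)
      bad <- which(tf_pool[top_i] == tf_pool[mid_i] |
                     tf_pool[top_i] == tgt_pool[tgt_i] |
                     tf_pool[mid_i] == tgt_pool[tgt_i])
      guard <- 0L
      while (length(bad)) {
        mid_i[bad] <- sample.int(length(tf_pool), length(bad), replace = TRUE)
        tgt_i[bad] <- sample.int(length(tgt_pool), length(bad), replace = TRUE)
        bad <- bad[tf_pool[top_i[bad]] == tf_pool[mid_i[bad]] |
                     tf_pool[top_i[bad]] == tgt_pool[tgt_i[bad]] |
                     tf_pool[mid_i[bad]] == tgt_pool[tgt_i[bad]]]
        guard <- guard + 1L
        if (guard > 1000L) stop("cannot draw distinct artificial triples")
      }
      perm_counts$top[r, ] <- tabulate(tf_tid[top_i], 16L)
      perm_counts$mid[r, ] <- tabulate(tf_tid[mid_i], 16L)
      perm_counts$target[r, ] <- tabulate(tgt_tid[tgt_i], 16L)
    }
    for (p in c("top", "mid", "target")) {
      real_tid <- 4L * state_to_int(sub[[paste0(p, "_src")]]) +
        state_to_int(sub[[paste0(p, "_end")]]) + 1L
      real_counts <- tabulate(real_tid, 16L)
      pv <- vapply(1:16, function(t) {
        mean(perm_counts[[p]][, t] >= real_counts[t])
      }, 0)
      out[[length(out) + 1L]] <- data.frame(
        group = g, position = pos_names[[p]],
        from = grid$from, to = grid$to,
        count = real_counts,
        frequency = real_counts / k,
        p = pv,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
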