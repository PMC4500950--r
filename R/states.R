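#' Promoter fold enrichment of a chromatin state
#'
#' `(a/b) / (c/d)` where `a` is the number of promoter bases in the state,
#' `b` the promoter length, `c` the genome-wide bases in the state and `d`
#' the total state-marked bases. Returns 0 when `a = 0`. Vectorized.
#'
#' @param a Promoter bases in the state.
#' @param b Promoter length in bases.
#' @param c_s Genome-wide bases in the state.
#' @param d Total genome-wide state-marked bases.
#' @return The fold enrichment (scale-invariant in both ratios).
#' @export
fold_enrichment <- function(a, b, c_s, d) {
  stopifnot(all(b > 0), all(c_s > 0), all(d > 0))
  fe <- (a / b) / (c_s / d)
  fe[a == 0] <- 0
  fe
}

#' Genome-wide base totals per broad state
#'
#' @param segments Segmentation data frame from [read_segmentation()].
#' @return Named numeric vector over the four broad states (absent states
#'   get 0).
#' @export
genome_state_totals <- function(segments) {
  tot <- tapply(segments$end - segments$start, segments$broad, sum)
  out <- setNames(numeric(4), broad_states())
  out[names(tot)] <- tot
  out
}

#' Assign broad chromatin states to gene promoters
#'
#' For every gene, promoter bases covered by each broad state are counted
#' and the state with maximal fold enrichment against its genome-wide
#' abundance is chosen. Ties are broken by the fixed priority
#' StrongActivity > Poised > WeakActivity > Repressed. A state with zero
#' genome-wide bases is skipped (enrichment undefined). Promoters that
#' overlap no segment are labeled Repressed (low signal) with a warning.
#'
#' @param genes Gene annotation data frame.
#' @param segments Segmentation data frame with a `broad` column.
#' @param up,down Promoter flanks in bases.
#' @param genome_totals Per-state genome-wide base totals; computed from
#'   `segments` when omitted.
#' @return Data frame `gene`, `state` and one `fe_<state>` column per broad
#'   state.
#' @export
gene_states <- function(genes, segments, up = 500L, down = 500L,
                        genome_totals = NULL) {
  states <- broad_states()
  if (is.null(genome_totals)) genome_totals <- genome_state_totals(segments)
  genome_totals <- genome_totals[states]
  d <- sum(genome_totals)
  if (d <= 0) stop("segmentation covers zero bases")
  skipped <- states[genome_totals == 0]
  if (length(skipped)) {
    message("state(s) absent genome-wide, skipped: ", paste(skipped, collapse = ", "))
  }

  prom <- promoter_of(genes$tss, genes$strand, up, down)
  prom$chrom <- genes$chrom
  pg <- df_to_gr(prom)
  sg <- df_to_gr(segments)
  hits <- GenomicRanges::findOverlaps(pg, sg)
  ov <- IRanges::width(IRanges::pintersect(
    pg[S4Vectors::queryHits(hits)], sg[S4Vectors::subjectHits(hits)]
  ))
  # promoter x state coverage matrix
  a <- matrix(0, nrow = nrow(genes), ncol = length(states),
              dimnames = list(genes$gene_id, states))
  if (length(hits)) {
    key <- paste(S4Vectors::queryHits(hits),
                 segments$broad[S4Vectors::subjectHits(hits)])
    agg <- rowsum(ov, key)
    parts <- strsplit(rownames(agg), " ")
    gi <- as.integer(vapply(parts, `[[`, "", 1))
    si <- match(vapply(parts, `[[`, "", 2), states)
    a[cbind(gi, si)] <- agg[, 1]
  }

  b <- prom$end - prom$start
  fe <- matrix(0, nrow = nrow(genes), ncol = length(states),
               dimnames = list(genes$gene_id, states))
  for (s in seq_along(states)) {
    if (genome_totals[s] == 0) next
    fe[, s] <- fold_enrichment(a[, s], b, genome_totals[s], d)
  }

  uncovered <- rowSums(a) == 0
  if (any(uncovered)) {
    warning(sum(uncovered), " promoter(s) overlap no segment; labeled Repressed")
  }
  # argmax with fixed priority order on ties
  prio <- match(states, broad_states())
  pick <- apply(fe, 1, function(row) {
    mx <- max(row)
    cand <- which(row == mx)
    cand[which.min(prio[cand])]
  })
  state <- states[pick]
  state[uncovered] <- "Repressed"

  out <- data.frame(gene = genes$gene_id, state = state,
                    stringsAsFactors = FALSE)
  colnames(fe) <- paste0("fe_", c("strong", "poised", "weak", "repressed"))
  cbind(out, as.data.frame(fe, row.names = seq_len(nrow(fe))))
}

#' Broad state of a single promoter
#'
#' Single-gene convenience wrapper around [gene_states()].
#'
#' @param promoter List or data frame row with `chrom`, `start`, `end`.
#' @param segments Segmentation data frame.
#' @param genome_totals Optional per-state genome totals.
#' @return The broad state (character scalar).
#' @export
assign_gene_state <- function(promoter, segments, genome_totals = NULL) {
  center <- (promoter$start + promoter$end) %/% 2L
  g <- data.frame(gene_id = "g", chrom = promoter$chrom,
                  tss = center, strand = "+", stringsAsFactors = FALSE)
  up <- center - promoter$start
  down <- promoter$end - center
  gene_states(g, segments, up = up, down = down,
              genome_totals = genome_totals)$state
}

#' Attach broad states to network nodes
#'
#' @param net A `regnet`.
#' @param states Data frame `gene`, `state` (from [gene_states()]) or a
#'   named character vector.
#' @param missing Policy for nodes without a state: `"error"` (default)
#'   or `"drop"` (remove the node and its incident edges, with a message).
#' @return The labeled `regnet`.
#' @export
annotate_network <- function(net, states, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  if (is.data.frame(states)) states <- setNames(states$state, states$gene)
  st <- unname(states[net$nodes$gene])
  absent <- net$nodes$gene[is.na(st)]
  if (length(absent)) {
    if (missing == "error") {
      stop("no state for node(s): ", paste(head(absent, 10), collapse = ", "),
           if (length(absent) > 10) " ...")
    }
    message("dropping ", length(absent), " node(s) without a state")
    keep_edges <- !(net$edges$tf %in% absent | net$edges$target %in% absent)
    nodes <- net$nodes[!is.na(st), , drop = FALSE]
    nodes$state <- st[!is.na(st)]
    return(regulatory_network(net$edges[keep_edges, , drop = FALSE], nodes))
  }
  bad <- setdiff(unique(st), broad_states())
  if (length(bad)) stop("invalid state label(s): ", paste(bad, collapse = ", "))
  net$nodes$state <- st
  net
}
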