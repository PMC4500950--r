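# Candidate-gene prioritization from chromatin-state and structure changes
# of FFL instances between two cell conditions.

#' State-change scoring matrix
#'
#' Symmetric 4x4 matrix over broad states with zero diagonal. Changes
#' crossing the activation/repression divide (strong or weak activity vs
#' poised or repressed) carry the highest score; poised <-> repressed the
#' intermediate score; strong <-> weak activity the lowest.
#'
#' @param cross Activation <-> repression score; default 10.
#' @param poised_repressed Poised <-> repressed score; default 5.
#' @param strong_weak Strong <-> weak activity score; default 3.
#' @return Named 4x4 numeric matrix.
#' @export
state_change_scores <- function(cross = 10, poised_repressed = 5,
                                strong_weak = 3) {
  s <- state_levels()
  m <- matrix(cross, 4, 4, dimnames = list(s, s))
  diag(m) <- 0
  m["StrongActivity", "WeakActivity"] <- strong_weak
  m["WeakActivity", "StrongActivity"] <- strong_weak
  m["Poised", "Repressed"] <- poised_repressed
  m["Repressed", "Poised"] <- poised_repressed
  m
}

#' Score one FFL comparison instance
#'
#' Sum over the three positions of the state-change score between the
#' source and end condition, plus a flat structural-change score when the
#' instance gained or lost edges. Instances with a missing state score NA
#' (callers skip them).
#'
#' @param cmp One row of [compare_ffls()] output (or a vectorized data
#'   frame of rows).
#' @param mat Scoring matrix from [state_change_scores()].
#' @param structural_change_score Flat score for any structural change;
#'   default 5.
#' @return Numeric score(s).
#' @export
score_instance <- function(cmp, mat = state_change_scores(),
                           structural_change_score = 5) {
  s <- rep(NA_real_, nrow(cmp))
  ok <- !(cmp$state_missing %||% rep(FALSE, nrow(cmp)))
  if (any(ok)) {
    s[ok] <- mat[cbind(cmp$top_src[ok], cmp$top_end[ok])] +
      mat[cbind(cmp$mid_src[ok], cmp$mid_end[ok])] +
      mat[cbind(cmp$target_src[ok], cmp$target_end[ok])] +
      structural_change_score * (cmp$group[ok] != "no_change")
  }
  s
}

#' Rank candidate genes by summary score
#'
#' Candidates are all genes appearing in at least one FFL instance in
#' either condition. Instances are deduplicated by their unordered gene
#' triple, instances with missing states are skipped (with a message), and
#' each gene's summary score is the sum of its instances' scores over every
#' position it occupies. Ranks are descending with ties sharing the
#' minimum rank; output rows are ordered by rank then gene id.
#'
#' @param comparisons Output of [compare_ffls()].
#' @param mat Scoring matrix.
#' @param structural_change_score Flat structural-change score; default 5.
#' @param source_nodes Optional character vector of "source node" genes
#'   (TFs with ChIP-seq in the conditions) carried through as a flag.
#' @return Data frame `gene`, `n_instances`, `summary_score`, `rank`,
#'   `percentile`, `is_source_node`.
#' @export
rank_genes <- function(comparisons, mat = state_change_scores(),
                       structural_change_score = 5, source_nodes = NULL) {
  if (nrow(comparisons) == 0) {
    return(data.frame(gene = character(), n_instances = integer(),
                      summary_score = numeric(), rank = integer(),
                      percentile = numeric(), is_source_node = logical(),
                      stringsAsFactors = FALSE))
  }
  key <- vapply(seq_len(nrow(comparisons)), function(i) {
    paste(sort(c(comparisons$top[i], comparisons$mid[i],
                 comparisons$target[i])), collapse = "|")
  }, "")
  cmp <- comparisons[!duplicated(key), , drop = FALSE]
  skip <- cmp$state_missing
  if (any(skip)) message(sum(skip), " instance(s) skipped for missing states")
  candidates <- sort(unique(c(cmp$top, cmp$mid, cmp$target)))
  cmp <- cmp[!skip, , drop = FALSE]
  score <- score_instance(cmp, mat, structural_change_score)
  gene <- c(cmp$top, cmp$mid, cmp$target)
  per_gene <- rowsum(rep(score, 3), gene)
  n_inst <- table(gene)
  out <- data.frame(
    gene = candidates,
    n_instances = as.integer(n_inst[candidates]),
    summary_score = per_gene[candidates, 1],
    stringsAsFactors = FALSE
  )
  out$n_instances[is.na(out$n_instances)] <- 0L
  out$summary_score[is.na(out$summary_score)] <- 0
  out$rank <- rank(-out$summary_score, ties.method = "min")
  out$percentile <- 100 * out$rank / nrow(out)
  out$is_source_node <- out$gene %in% (source_nodes %||% character(0))
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of a gene set in the top-ranked fraction
#'
#' Takes the top `ceiling(fraction * n)` candidates by rank (ties broken
#' by gene id) and tests their overlap with `gene_set` against the
#' candidate universe by the upper-tail hypergeometric test.
#'
#' @param records Output of [rank_genes()].
#' @param gene_set Character vector of genes of interest.
#' @param fraction Top fraction in (0, 1); default 0.01.
#' @return List `N`, `n`, `M`, `k`, `p`, `top_genes`.
#' @export
top_fraction_enrichment <- function(records, gene_set, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 1)
  n_cand <- nrow(records)
  m_top <- ceiling(fraction * n_cand)
  top_genes <- records$gene[seq_len(m_top)]
  term <- intersect(unique(gene_set), records$gene)
  if (length(term) == 0) {
    warning("gene set does not intersect the candidate universe")
    return(list(N = n_cand, n = 0L, M = m_top, k = 0L, p = 1,
                top_genes = top_genes))
  }
  k <- length(intersect(top_genes, term))
  list(N = n_cand, n = length(term), M = m_top, k = k,
       p = hypergeom_enrichment(n_cand, length(term), m_top, k),
       top_genes = top_genes)
}
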