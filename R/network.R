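#' Construct a regulatory network object
#'
#' A directed TF -> target graph. Nodes carry a TF flag and (after
#' [annotate_network()]) a broad chromatin state. Duplicate edges are
#' collapsed; every edge source is marked as a TF.
#'
#' @param edges Data frame with character columns `tf` and `target`.
#' @param nodes Optional data frame with columns `gene`, `is_tf` and
#'   optionally `state`; derived from the edges when omitted.
#' @return An object of class `regnet`.
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("tf", "target") %in% names(edges)))
  edges <- unique(data.frame(tf = as.character(edges$tf),
                             target = as.character(edges$target),
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    gene <- sort(unique(c(edges$tf, edges$target)))
    nodes <- data.frame(gene = gene, is_tf = gene %in% edges$tf,
                        state = NA_character_, stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene") %in% names(nodes)))
    gene <- as.character(nodes$gene)
    nodes <- data.frame(gene = gene,
                        is_tf = if (is.null(nodes$is_tf))
                          rep(FALSE, length(gene)) else as.logical(nodes$is_tf),
                        state = if (is.null(nodes$state))
                          rep(NA_character_, length(gene)) else as.character(nodes$state),
                        stringsAsFactors = FALSE)
    extra <- setdiff(unique(c(edges$tf, edges$target)), nodes$gene)
    if (length(extra)) {
      nodes <- rbind(nodes, data.frame(gene = extra, is_tf = extra %in% edges$tf,
                                       state = NA_character_, stringsAsFactors = FALSE))
    }
    nodes$is_tf <- nodes$is_tf | nodes$gene %in% edges$tf
    nodes <- nodes[order(nodes$gene), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf("regnet: %d nodes (%d TFs), %d edges; states %s\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges),
              if (all(is.na(x$nodes$state))) "unset" else "set"))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

#' TF binding sites from peak summits
#'
#' Each peak contributes one binding-site window of `width` bases centered
#' on its summit, clipped at position 0.
#'
#' @param peaks Peak data frame from [read_peaks()].
#' @param width Window width in bases (even, >= 2); default 40.
#' @return Data frame `chrom`, `start`, `end`, `tf_name`.
#' @export
peaks_to_tfbs <- function(peaks, width = 40L) {
  stopifnot(width >= 2, width %% 2 == 0)
  summit <- peaks$start + peaks$summit_offset
  data.frame(
    chrom = peaks$chrom,
    start = pmax(0L, summit - width %/% 2L),
    end = summit + width %/% 2L,
    tf_name = peaks$tf_name,
    stringsAsFactors = FALSE
  )
}

#' Keep binding sites that fall into DNase I hypersensitive sites
#'
#' A binding site is retained when it overlaps a DHS interval by at least
#' one base (default) or lies fully within one (`containment = TRUE`).
#' Input order is preserved.
#'
#' @param tfbs Data frame of binding-site intervals.
#' @param dhs Data frame of DHS intervals.
#' @param containment Require full containment instead of 1-bp overlap.
#' @return The retained subset of `tfbs`.
#' @export
filter_by_dhs <- function(tfbs, dhs, containment = FALSE) {
  if (nrow(tfbs) == 0 || nrow(dhs) == 0) return(tfbs[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(
    df_to_gr(tfbs), df_to_gr(dhs),
    type = if (containment) "within" else "any"
  )
  tfbs[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Promoter window around a TSS
#'
#' On the '+' strand the promoter is `[tss - up, tss + down)`; on the '-'
#' strand the roles of up and down are swapped. Starts are clipped at 0.
#' Vectorized over genes.
#'
#' @param tss Integer TSS positions (0-based).
#' @param strand Character vector of strands ('+' or '-').
#' @param up,down Bases upstream / downstream of the TSS; defaults 500/500.
#' @return Data frame `start`, `end`.
#' @export
promoter_of <- function(tss, strand, up = 500L, down = 500L) {
  minus <- strand == "-"
  start <- ifelse(minus, tss - down, tss - up)
  end <- ifelse(minus, tss + up, tss + down)
  data.frame(start = pmax(0L, as.integer(start)), end = as.integer(end))
}

#' Build the TF -> target network from DHS-filtered binding sites
#'
#' A gene is a target of a TF when at least one binding site of the TF
#' overlaps the gene's promoter by >= 1 bp (or is fully contained with
#' `containment = TRUE`). Edges are deduplicated; the node set is the TFs
#' with at least one edge plus all targets.
#'
#' @param tfbs Data frame of (already DHS-filtered) binding sites with a
#'   `tf_name` column.
#' @param genes Gene annotation data frame (see [read_gene_annotation()]).
#' @param up,down Promoter flanks in bases.
#' @param containment Require binding sites fully inside the promoter.
#' @return A `regnet` object.
#' @export
build_network <- function(tfbs, genes, up = 500L, down = 500L,
                          containment = FALSE) {
  unknown_tf <- setdiff(unique(tfbs$tf_name), genes$gene_id)
  if (length(unknown_tf)) {
    warning("TF(s) absent from annotation: ", paste(unknown_tf, collapse = ", "))
  }
  prom <- promoter_of(genes$tss, genes$strand, up, down)
  prom$chrom <- genes$chrom
  edges <- data.frame(tf = character(), target = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tfbs) > 0) {
    hits <- GenomicRanges::findOverlaps(
      df_to_gr(tfbs), df_to_gr(prom),
      type = if (containment) "within" else "any"
    )
    edges <- unique(data.frame(
      tf = tfbs$tf_name[S4Vectors::queryHits(hits)],
      target = genes$gene_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    ))
  }
  keep <- unique(c(edges$tf, edges$target))
  nodes <- genes[genes$gene_id %in% keep, c("gene_id", "is_tf"), drop = FALSE]
  names(nodes) <- c("gene", "is_tf")
  if (length(unknown_tf)) {
    nodes <- rbind(nodes, data.frame(gene = intersect(unknown_tf, keep),
                                     is_tf = TRUE, stringsAsFactors = FALSE))
  }
  regulatory_network(edges, nodes)
}
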