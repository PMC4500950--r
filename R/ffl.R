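#' Feedforward-loop instances of a network
#'
#' Ordered triples (top, intermediate, target) with the three edges
#' top->intermediate, top->target and intermediate->target all present and
#' all three genes distinct. Extraction is non-induced: extra edges among
#' the triple (e.g. mutual regulation) do not disqualify an instance. When
#' the network is labeled, per-position states are attached.
#'
#' @param net A `regnet`.
#' @return Data frame `top`, `mid`, `target` (+ `top_state`, `mid_state`,
#'   `target_state` when states are set).
#' @export
ffl_instances <- function(net) {
  e <- net$edges[net$edges$tf != net$edges$target, , drop = FALSE]
  empty <- data.frame(top = character(), mid = character(),
                      target = character(), stringsAsFactors = FALSE)
  if (nrow(e) < 3) return(empty)
  two <- merge(e, e, by.x = "target", by.y = "tf")
  # columns: target (= mid), tf (= top), target.y (= final target)
  names(two) <- c("mid", "top", "target")
  two <- two[two$top != two$target & two$top != two$mid &
               two$mid != two$target, , drop = FALSE]
  key <- paste(two$top, two$target)
  direct <- paste(e$tf, e$target)
  out <- two[key %in% direct, c("top", "mid", "target"), drop = FALSE]
  out <- out[order(out$top, out$mid, out$target), , drop = FALSE]
  rownames(out) <- NULL
  if (!all(is.na(net$nodes$state))) {
    st <- setNames(net$nodes$state, net$nodes$gene)
    out$top_state <- unname(st[out$top])
    out$mid_state <- unname(st[out$mid])
    out$target_state <- unname(st[out$target])
  }
  out
}
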