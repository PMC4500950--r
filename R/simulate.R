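# Synthetic condition bundles with the statistical structure the analysis
# assumes: a heavy-tailed directed TF->target background, promoter-localized
# peaks inside DHSs, a segmentation that covers each promoter with its
# planted broad state, planted colored FFL copies on dedicated nodes, state
# transitions and edge changes between two conditions, and expression
# stratified by state.

#' Specification for a synthetic condition (or condition pair)
#'
#' The defaults are the study conditions the pipeline is exercised under:
#' 50 planted feedforward loops colored (StrongActivity, StrongActivity,
#' Poised) and 100 colored (Poised, StrongActivity, StrongActivity) over a
#' scale-free background large enough that planted nodes remain a minority
#' of the regulatory gene pool; between the two conditions, 30% of the
#' planted FFLs with a Poised top flip it to StrongActivity, 2% of
#' background genes flip to a random other state, and 20% of planted FFLs
#' lose one edge.
#'
#' @param n_tfs,n_genes Background TFs and non-TF genes.
#' @param n_background_edges Exact background edge count (sources drawn
#'   proportionally to a power-law degree sequence); `NULL` draws a
#'   power-law out-degree per TF instead.
#' @param degree_exponent Power-law exponent for out-degrees; default 2.
#' @param max_out_degree Cap for the per-TF degree draw; default 50.
#' @param state_frequencies Named 4-vector of broad-state frequencies
#'   summing to 1.
#' @param planted_motifs List of `list(structure = "ffl", states =
#'   <3 broad states>, copies = <int>)`; dedicated nodes per copy.
#' @param transition_spec Data frame `position` (`top`/`mid`/`target`),
#'   `from`, `to`, `rate` describing planted state flips for condition B.
#' @param background_flip_rate Per-gene probability of a random state flip
#'   in condition B for non-planted genes; default 0.02.
#' @param edge_loss_rate Fraction of planted FFLs losing one random edge
#'   in condition B; default 0.2.
#' @param edge_gain_rate Fraction of planted FFLs present only in
#'   condition B (one edge withheld from A); default 0.
#' @param expression_log2_mean Named per-state mean of log2 expression.
#' @param expression_log2_sd Dispersion of log2 expression; default 1.
#' @param tile_bp Genome bases reserved per gene (promoters are disjoint
#'   within tiles); default 2000.
#' @param genome_length Optional total genome length; must fit all tiles.
#' @param seed RNG seed driving every draw.
#' @return A validated `sim_spec` list.
#' @export
sim_spec <- function(n_tfs = 150L, n_genes = 700L,
                     n_background_edges = NULL,
                     degree_exponent = 2,
                     max_out_degree = 50L,
                     state_frequencies = c(StrongActivity = 0.30,
                                           WeakActivity = 0.25,
                                           Poised = 0.15,
                                           Repressed = 0.30),
                     planted_motifs = list(
                       list(structure = "ffl",
                            states = c("StrongActivity", "StrongActivity", "Poised"),
                            copies = 50L),
                       list(structure = "ffl",
                            states = c("Poised", "StrongActivity", "StrongActivity"),
                            copies = 100L)
                     ),
                     transition_spec = data.frame(
                       position = "top", from = "Poised",
                       to = "StrongActivity", rate = 0.3,
                       stringsAsFactors = FALSE
                     ),
                     background_flip_rate = 0.02,
                     edge_loss_rate = 0.2,
                     edge_gain_rate = 0,
                     expression_log2_mean = c(StrongActivity = 8,
                                              WeakActivity = 5,
                                              Poised = 3,
                                              Repressed = 1),
                     expression_log2_sd = 1,
                     tile_bp = 2000L,
                     genome_length = NULL,
                     seed = 1L) {
  spec <- as.list(environment())
  if (abs(sum(state_frequencies) - 1) > 1e-9) {
    stop("state_frequencies must sum to 1")
  }
  if (!setequal(names(state_frequencies), broad_states())) {
    stop("state_frequencies must be named by the four broad states")
  }
  spec$planted_motifs <- lapply(planted_motifs, function(m) {
    m$states <- as.character(unlist(m$states))
    stopifnot(identical(m$structure, "ffl"), length(m$states) == 3,
              m$copies >= 0)
    state_to_int(m$states)
    m$copies <- as.integer(m$copies)
    m
  })
  rates <- c(transition_spec$rate, background_flip_rate,
             edge_loss_rate, edge_gain_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  class(spec) <- "sim_spec"
  spec
}

# --- layout: genes, states, edges, planted truth ----------------------------

sim_layout <- function(spec) {
  bg_tfs <- sprintf("TF%03d", seq_len(spec$n_tfs))
  bg_genes <- sprintf("G%04d", seq_len(spec$n_genes))

  planted <- list()
  for (e in seq_along(spec$planted_motifs)) {
    m <- spec$planted_motifs[[e]]
    if (m$copies == 0) next
    for (cp in seq_len(m$copies)) {
      id <- sprintf("P%dC%03d", e, cp)
      planted[[length(planted) + 1L]] <- data.frame(
        entry = e, copy = cp,
        top = paste0(id, "_top"), mid = paste0(id, "_mid"),
        target = paste0(id, "_tgt"),
        top_state = m$states[1], mid_state = m$states[2],
        target_state = m$states[3],
        stringsAsFactors = FALSE
      )
    }
  }
  motifs <- if (length(planted)) do.call(rbind, planted) else
    data.frame(entry = integer(), copy = integer(), top = character(),
               mid = character(), target = character(),
               top_state = character(), mid_state = character(),
               target_state = character(), stringsAsFactors = FALSE)

  planted_nodes <- c(rbind(motifs$top, motifs$mid, motifs$target))
  all_genes <- c(bg_tfs, bg_genes, planted_nodes)
  is_tf <- c(rep(TRUE, length(bg_tfs)), rep(FALSE, length(bg_genes)),
             rep(c(TRUE, TRUE, FALSE), nrow(motifs)))

  need <- length(all_genes) * spec$tile_bp
  if (!is.null(spec$genome_length) && spec$genome_length < need) {
    stop("genome too short to place promoters disjointly: need ", need,
         " bases, have ", spec$genome_length)
  }

  # states: planted fixed, background sampled
  states <- setNames(rep(NA_character_, length(all_genes)), all_genes)
  states[motifs$top] <- motifs$top_state
  states[motifs$mid] <- motifs$mid_state
  states[motifs$target] <- motifs$target_state
  bg <- c(bg_tfs, bg_genes)
  states[bg] <- sample(names(spec$state_frequencies), length(bg),
                       replace = TRUE, prob = spec$state_frequencies)

  # background edges: heavy-tailed out-degrees, TF -> (TF or gene)
  pool <- c(bg_tfs, bg_genes)
  edges <- data.frame(tf = character(), target = character(),
                      stringsAsFactors = FALSE)
  if (spec$n_tfs > 0) {
    kmax <- min(spec$max_out_degree, length(pool) - 1L)
    pk <- (seq_len(kmax))^(-spec$degree_exponent)
    if (is.null(spec$n_background_edges)) {
      rows <- lapply(bg_tfs, function(tf) {
        k <- sample.int(kmax, 1, prob = pk)
        data.frame(tf = tf, target = sample(setdiff(pool, tf), k),
                   stringsAsFactors = FALSE)
      })
      edges <- do.call(rbind, rows)
    } else {
      wt <- sample(seq_len(kmax), spec$n_tfs, replace = TRUE, prob = pk)
      got <- data.frame(tf = character(), target = character(),
                        stringsAsFactors = FALSE)
      tries <- 0L
      while (nrow(got) < spec$n_background_edges && tries < 50L) {
        need_n <- spec$n_background_edges - nrow(got)
        src <- sample(bg_tfs, need_n, replace = TRUE, prob = wt)
        tgt <- sample(pool, need_n, replace = TRUE)
        cand <- data.frame(tf = src, target = tgt, stringsAsFactors = FALSE)
        cand <- cand[cand$tf != cand$target, , drop = FALSE]
        got <- unique(rbind(got, cand))
        tries <- tries + 1L
      }
      edges <- got[seq_len(min(nrow(got), spec$n_background_edges)), ,
                   drop = FALSE]
    }
  }
  if (nrow(motifs)) {
    edges <- rbind(edges,
                   data.frame(tf = motifs$top, target = motifs$mid,
                              stringsAsFactors = FALSE),
                   data.frame(tf = motifs$top, target = motifs$target,
                              stringsAsFactors = FALSE),
                   data.frame(tf = motifs$mid, target = motifs$target,
                              stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  rownames(edges) <- NULL

  tf_ids <- all_genes[is_tf]
  tf_effects <- data.frame(
    gene = tf_ids,
    effect = sample(c("activator", "repressor"), length(tf_ids),
                    replace = TRUE),
    stringsAsFactors = FALSE
  )

  annotation <- data.frame(
    gene_id = all_genes,
    chrom = "chr1",
    tss = (seq_along(all_genes) - 1L) * spec$tile_bp + spec$tile_bp %/% 2L,
    strand = rep(c("+", "-"), length.out = length(all_genes)),
    is_tf = is_tf,
    tf_effect = "unknown",
    stringsAsFactors = FALSE
  )
  annotation$tf_effect[match(tf_effects$gene, annotation$gene_id)] <-
    tf_effects$effect

  list(annotation = annotation, states = states, edges = edges,
       motifs = motifs, tf_effects = tf_effects)
}

# --- materialization: peaks, DHS, segmentation, expression ------------------

sim_materialize <- function(spec, layout, states, edges, label, seed) {
  set.seed(seed)
  ann <- layout$annotation
  tile <- spec$tile_bp
  up <- 500L
  idx <- match(ann$gene_id, ann$gene_id)
  prom_start <- ann$tss - up
  prom_end <- ann$tss + up

  # peaks: one per edge, 40-bp summit window inside the target promoter
  tgt_i <- match(edges$target, ann$gene_id)
  summit <- ann$tss[tgt_i] + sample(seq(-up + 20L, up - 21L), nrow(edges),
                                    replace = TRUE)
  pk_start <- pmax(0L, summit - 100L)
  peaks <- data.frame(
    chrom = rep("chr1", nrow(edges)), start = pk_start,
    end = summit + 100L,
    summit_offset = summit - pk_start, tf_name = edges$tf,
    stringsAsFactors = FALSE
  )
  peaks <- peaks[order(peaks$tf_name, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL

  dhs <- data.frame(chrom = "chr1", start = prom_start, end = prom_end,
                    stringsAsFactors = FALSE)

  # segmentation: promoters carry the gene's state; inter-promoter gaps
  # cycle through the four states so every state has genome-wide mass
  states_vec <- unname(states[ann$gene_id])
  n <- nrow(ann)
  filler <- broad_states()[(seq_len(2L * n) - 1L) %% 4L + 1L]
  seg <- rbind(
    data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * tile,
               end = prom_start, label = filler[seq_len(n)],
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", start = prom_start, end = prom_end,
               label = states_vec, stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", start = prom_end, end = seq_len(n) * tile,
               label = filler[n + seq_len(n)], stringsAsFactors = FALSE)
  )
  seg <- seg[order(seg$start), , drop = FALSE]
  seg$broad <- seg$label
  rownames(seg) <- NULL

  expr_log2 <- rnorm(n, mean = spec$expression_log2_mean[states_vec],
                     sd = spec$expression_log2_sd)
  expression <- data.frame(gene = ann$gene_id,
                           value = round(2^expr_log2, 4),
                           stringsAsFactors = FALSE)
  names(expression)[2] <- label

  list(
    label = label,
    annotation = ann,
    states = data.frame(gene = ann$gene_id, state = states_vec,
                        stringsAsFactors = FALSE),
    edges = edges,
    peaks = peaks,
    dhs = dhs,
    segments = seg,
    expression = expression,
    truth = list(edges = edges,
                 states = data.frame(gene = ann$gene_id, state = states_vec,
                                     stringsAsFactors = FALSE),
                 motifs = layout$motifs,
                 tf_effects = layout$tf_effects)
  )
}

#' Simulate one cell condition
#'
#' Generates the full input bundle for one condition: gene annotation,
#' per-TF peaks (one peak per planted edge, 40-bp summit window inside the
#' target's promoter and inside a DHS), DHS intervals, a broad-state
#' segmentation whose promoter segments carry each gene's planted state,
#' an expression table stratified by state, and truth tables.
#'
#' @param spec A [sim_spec()].
#' @param label Condition label used for the expression column; default
#'   "A".
#' @return A bundle list; see [sim_spec()] for the planted structure.
#' @export
simulate_condition <- function(spec, label = "A") {
  set.seed(child_seed(spec$seed, 1L))
  layout <- sim_layout(spec)
  sim_materialize(spec, layout, layout$states, layout$edges, label,
                  child_seed(spec$seed, 3L))
}

#' Simulate a pair of cell conditions with planted changes
#'
#' Condition B differs from condition A by (i) the planted per-position
#' state flips of `transition_spec`, applied to the specified fraction of
#' eligible planted FFLs, (ii) random background state flips at
#' `background_flip_rate`, (iii) loss of one random edge for
#' `edge_loss_rate` of the planted FFLs, and (iv) `edge_gain_rate` of the
#' planted FFLs being present only in B (one edge withheld from A). A
#' truth table records every change.
#'
#' @param spec A [sim_spec()].
#' @return List with bundles `A` and `B` and `truth_changes` (`flips`,
#'   `edge_losses`, `edge_gains`).
#' @export
simulate_pair <- function(spec) {
  set.seed(child_seed(spec$seed, 1L))
  layout <- sim_layout(spec)
  motifs <- layout$motifs

  set.seed(child_seed(spec$seed, 2L))
  states_B <- layout$states

  pos_col <- c(top = "top", mid = "mid", intermediate = "mid",
               target = "target", bottom = "target")
  flips <- list()
  if (nrow(spec$transition_spec) && nrow(motifs)) {
    for (i in seq_len(nrow(spec$transition_spec))) {
      tr <- spec$transition_spec[i, ]
      col <- pos_col[[tr$position]]
      eligible <- which(motifs[[paste0(col, "_state")]] == tr$from)
      sel <- eligible[runif(length(eligible)) < tr$rate]
      if (length(sel)) {
        genes <- motifs[[col]][sel]
        states_B[genes] <- tr$to
        flips[[length(flips) + 1L]] <- data.frame(
          gene = genes, position = col, from = tr$from, to = tr$to,
          copy = paste0("P", motifs$entry[sel], "C",
                        sprintf("%03d", motifs$copy[sel])),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  flips <- if (length(flips)) do.call(rbind, flips) else
    data.frame(gene = character(), position = character(),
               from = character(), to = character(), copy = character(),
               stringsAsFactors = FALSE)

  planted_nodes <- unique(c(motifs$top, motifs$mid, motifs$target))
  bg <- setdiff(names(states_B), planted_nodes)
  flip_bg <- bg[runif(length(bg)) < spec$background_flip_rate]
  for (g in flip_bg) {
    states_B[g] <- sample(setdiff(broad_states(), states_B[g]), 1)
  }

  # structural changes on planted copies
  edge_of <- function(m, j) {
    switch(j,
           data.frame(tf = m$top, target = m$mid, stringsAsFactors = FALSE),
           data.frame(tf = m$top, target = m$target, stringsAsFactors = FALSE),
           data.frame(tf = m$mid, target = m$target, stringsAsFactors = FALSE))
  }
  losses <- gains <- data.frame(tf = character(), target = character(),
                                copy = character(), stringsAsFactors = FALSE)
  drop_A <- drop_B <- character(0)
  if (nrow(motifs)) {
    lose <- which(runif(nrow(motifs)) < spec$edge_loss_rate)
    remaining <- setdiff(seq_len(nrow(motifs)), lose)
    gain <- remaining[runif(length(remaining)) < spec$edge_gain_rate]
    for (i in lose) {
      e <- edge_of(motifs[i, ], sample.int(3L, 1))
      drop_B <- c(drop_B, paste(e$tf, e$target))
      losses <- rbind(losses, data.frame(
        tf = e$tf, target = e$target,
        copy = paste0("P", motifs$entry[i], "C", sprintf("%03d", motifs$copy[i])),
        stringsAsFactors = FALSE))
    }
    for (i in gain) {
      e <- edge_of(motifs[i, ], sample.int(3L, 1))
      drop_A <- c(drop_A, paste(e$tf, e$target))
      gains <- rbind(gains, data.frame(
        tf = e$tf, target = e$target,
        copy = paste0("P", motifs$entry[i], "C", sprintf("%03d", motifs$copy[i])),
        stringsAsFactors = FALSE))
    }
  }
  ekey <- paste(layout$edges$tf, layout$edges$target)
  edges_A <- layout$edges[!ekey %in% drop_A, , drop = FALSE]
  edges_B <- layout$edges[!ekey %in% drop_B, , drop = FALSE]

  A <- sim_materialize(spec, layout, layout$states, edges_A, "A",
                       child_seed(spec$seed, 3L))
  B <- sim_materialize(spec, layout, states_B, edges_B, "B",
                       child_seed(spec$seed, 4L))
  list(A = A, B = B,
       truth_changes = list(flips = flips, edge_losses = losses,
                            edge_gains = gains))
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' Peaks go to one narrowPeak file per TF (column 10 carries the summit
#' offset), DHSs and the segmentation to BED, annotation and expression to
#' TSV; truth tables are written under `truth_*` names.
#'
#' @param bundle Output of [simulate_condition()] (or one condition of
#'   [simulate_pair()]).
#' @param dir Output directory (created if needed).
#' @return A manifest-style list of the written paths (fields `peaks`,
#'   `dhs`, `segmentation`, `annotation`, `expression`).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  peak_paths <- character(0)
  for (tf in unique(bundle$peaks$tf_name)) {
    p <- bundle$peaks[bundle$peaks$tf_name == tf, , drop = FALSE]
    path <- file.path(dir, paste0("peaks_", tf, ".narrowPeak"))
    np <- data.frame(p$chrom, p$start, p$end, paste0(tf, "_peak", seq_len(nrow(p))),
                     0L, ".", 0, -1, -1, p$summit_offset)
    write.table(np, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    peak_paths[tf] <- path
  }
  dhs_path <- file.path(dir, "dhs.bed")
  write.table(bundle$dhs, dhs_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  seg_path <- file.path(dir, "segmentation.bed")
  write.table(bundle$segments[, c("chrom", "start", "end", "label")],
              seg_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ann_path <- file.path(dir, "annotation.tsv")
  write_tsv(bundle$annotation, ann_path)
  expr_path <- file.path(dir, "expression.tsv")
  write_tsv(bundle$expression, expr_path)
  write_tsv(bundle$truth$edges, file.path(dir, "truth_edges.tsv"))
  write_tsv(bundle$truth$states, file.path(dir, "truth_states.tsv"))
  write_tsv(bundle$truth$motifs, file.path(dir, "truth_motifs.tsv"))
  write_tsv(bundle$truth$tf_effects, file.path(dir, "truth_tf_effects.tsv"))
  list(peaks = peak_paths, dhs = dhs_path, segmentation = seg_path,
       annotation = ann_path, expression = expr_path)
}
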