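# End-to-end driver chaining the pipeline stages over a manifest of input
# files, one entry per cell condition.

read_bed3 <- function(path) {
  fields <- read_bed_fields(path, min_cols = 3)
  if (length(fields) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1),
                   start = bed_int(fields, 2, path),
                   end = bed_int(fields, 3, path),
                   stringsAsFactors = FALSE)
  assert_intervals(df, paste0(path, " line"))
  df
}

#' Run the full analysis pipeline over a manifest
#'
#' The manifest is a list with a `conditions` element: a named list where
#' each condition supplies `peaks` (named character vector, TF name ->
#' path), `dhs`, `segmentation`, `annotation` and optionally `expression`
#' paths. All inputs are checked before any computation starts. Per
#' condition the pipeline builds the network, annotates broad states, runs
#' the motif census against randomized networks and the exclusivity test;
#' with two conditions it additionally runs the FFL comparison, the
#' transition test and the gene prioritization (a single condition skips
#' those stages with a logged notice). Stage outputs are written as
#' tab-delimited tables under `outdir`; a log records the seed, parameter
#' values and per-stage record counts. Reruns with the same seed and
#' inputs are byte-identical.
#'
#' @param manifest Manifest list (see above); [write_bundle()] returns a
#'   single condition's entry.
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with `status` (0 on success), per-condition
#'   results and, when applicable, `comparisons`, `transitions` and
#'   `gene_scores`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), outdir) {
  conds <- manifest$conditions
  if (is.null(conds) || length(conds) < 1) stop("manifest lists no conditions")
  for (nm in names(conds)) {
    cd <- conds[[nm]]
    paths <- c(cd$peaks, cd$dhs, cd$segmentation, cd$annotation, cd$expression)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("missing input(s) for condition ", nm, ": ",
           paste(missing, collapse = ", "))
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("seed\t%d", config$rng_seed),
           sprintf("n_random_networks\t%d", config$n_random_networks),
           sprintf("n_excl_perms\t%d", config$n_excl_perms),
           sprintf("n_transition_perms\t%d", config$n_transition_perms),
           sprintf("promoter\t-%d/+%d", config$promoter_up_bp,
                   config$promoter_down_bp),
           sprintf("tfbs_width\t%d", config$tfbs_width_bp))

  results <- list()
  stream <- 10L
  for (nm in names(conds)) {
    cd <- conds[[nm]]
    tf_names <- names(cd$peaks)
    if (is.null(tf_names) || any(!nzchar(tf_names))) {
      # fall back to the peaks_<TF>.<ext> file naming convention
      tf_names <- sub("^peaks_", "",
                      sub("\\.(bed|narrowPeak)$", "", basename(cd$peaks)))
    }
    peaks <- do.call(rbind, Map(read_peaks, cd$peaks, tf_names))
    tfbs <- peaks_to_tfbs(peaks, config$tfbs_width_bp)
    dhs <- read_bed3(cd$dhs)
    tfbs <- filter_by_dhs(tfbs, dhs, containment = config$containment)
    genes <- read_gene_annotation(cd$annotation)
    net <- build_network(tfbs, genes, config$promoter_up_bp,
                         config$promoter_down_bp,
                         containment = config$containment)
    seg <- read_segmentation(cd$segmentation, config$state_map)
    st <- gene_states(genes, seg, config$promoter_up_bp,
                      config$promoter_down_bp)
    net <- annotate_network(net, st, missing = "drop")
    set.seed(child_seed(config$rng_seed, stream))
    motifs <- find_significant_motifs(net, config$n_random_networks,
                                      config$significance_alpha,
                                      config$swap_factor)
    M <- exclusivity_matrix(motifs)
    excl <- NULL
    if (nrow(M) >= 1 && ncol(M) >= 1) {
      set.seed(child_seed(config$rng_seed, stream + 1L))
      excl <- exclusivity_test(M, config$n_excl_perms)
    } else {
      log <- c(log, sprintf("[%s] no significant motifs; exclusivity skipped", nm))
    }
    write_tsv(net$edges, file.path(outdir, paste0(nm, "_edges.tsv")))
    write_tsv(st, file.path(outdir, paste0(nm, "_gene_states.tsv")))
    write_tsv(motifs, file.path(outdir, paste0(nm, "_motif_stats.tsv")))
    if (!is.null(excl)) {
      write_tsv(data.frame(S_M = excl$S_M, p = excl$p),
                file.path(outdir, paste0(nm, "_exclusivity.tsv")))
    }
    log <- c(log, sprintf("[%s] edges\t%d", nm, nrow(net$edges)),
             sprintf("[%s] genes_with_state\t%d", nm, nrow(st)),
             sprintf("[%s] motif_classes\t%d", nm, nrow(motifs)),
             sprintf("[%s] significant_motifs\t%d", nm, sum(motifs$significant)))
    results[[nm]] <- list(net = net, states = st, motifs = motifs,
                          exclusivity = excl)
    stream <- stream + 2L
  }

  if (length(conds) >= 2) {
    nms <- names(conds)[1:2]
    a <- results[[nms[1]]]; b <- results[[nms[2]]]
    cmp <- compare_ffls(a$net, b$net, a$states, b$states)
    set.seed(child_seed(config$rng_seed, 100L))
    trans <- transition_test(cmp, a$net, b$net, a$states, b$states,
                             n_perm = config$n_transition_perms)
    scores <- rank_genes(cmp, source_nodes = unique(c(a$net$edges$tf,
                                                      b$net$edges$tf)))
    write_tsv(cmp, file.path(outdir, "ffl_comparisons.tsv"))
    write_tsv(trans, file.path(outdir, "state_transitions.tsv"))
    write_tsv(scores, file.path(outdir, "gene_scores.tsv"))
    log <- c(log, sprintf("ffl_comparisons\t%d", nrow(cmp)),
             sprintf("transition_rows\t%d", nrow(trans)),
             sprintf("candidate_genes\t%d", nrow(scores)))
    results$comparisons <- cmp
    results$transitions <- trans
    results$gene_scores <- scores
  } else {
    log <- c(log, "single condition: comparative and prioritization skipped")
    message("single condition: comparative and prioritization skipped")
  }
  writeLines(log, file.path(outdir, "pipeline.log"))
  results$status <- 0L
  invisible(results)
}
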