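# Cross-cutting statistics: mutual exclusivity permutation test,
# composition-wise expression comparisons, hypergeometric enrichment with
# BH correction, and the cell-type specificity score.

#' Mutual exclusivity score of a binary matrix
#'
#' Rows are chromatin-state compositions, columns are motif structures (or
#' cell types). `S_i = 1` when row i carries exactly one 1; the score is
#' the mean of `S_i` over all rows.
#'
#' @param M Binary matrix.
#' @return The exclusivity score in `[0, 1]`.
#' @export
exclusivity_score <- function(M) {
  M <- as.matrix(M)
  mean(rowSums(M) == 1)
}

#' Permutation test for mutual exclusivity
#'
#' Entries are shuffled independently within every column (column sums are
#' preserved exactly); the P-value is the fraction of permutations whose
#' score is greater than or equal to the observed score. Rows that become
#' all-zero after permutation contribute `S_i = 0`.
#'
#' @param M Binary matrix; every row must have at least one 1.
#' @param n_perm Number of permutations; default 10000.
#' @return List with `S_M`, `p` and the permutation scores (`perm`).
#' @export
exclusivity_test <- function(M, n_perm = 10000L) {
  M <- as.matrix(M)
  if (all(M == 0)) stop("all-zero matrix")
  if (any(rowSums(M) == 0)) stop("every row must have at least one 1")
  obs <- exclusivity_score(M)
  n <- nrow(M)
  perm <- vapply(seq_len(n_perm), function(i) {
    Mp <- apply(M, 2, function(col) col[sample.int(n)])
    if (is.null(dim(Mp))) Mp <- matrix(Mp, nrow = n)
    mean(rowSums(Mp) == 1)
  }, 0)
  list(S_M = obs, p = mean(perm >= obs), perm = perm)
}

#' Exclusivity matrix from motif statistics
#'
#' Builds the binary compositions x structures matrix from a motif-stats
#' table: entry (i, j) is 1 when composition i is (significantly) coupled
#' with structure j. A composition is identified by its multiset of states,
#' so colorings of structures with different canonical position orders
#' align on one row.
#'
#' @param motif_stats Output of [find_significant_motifs()].
#' @param significant_only Keep only significant classes; default TRUE.
#' @return Binary matrix (rows: compositions; columns: structure codes).
#' @export
exclusivity_matrix <- function(motif_stats, significant_only = TRUE) {
  df <- motif_stats
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  if (nrow(df) == 0) return(matrix(0L, 0, 0))
  comp <- vapply(strsplit(df$coloring, "/", fixed = TRUE),
                 function(x) paste(sort(x), collapse = "/"), "")
  tab <- table(comp, df$structure)
  M <- matrix(as.integer(tab > 0), nrow = nrow(tab),
              dimnames = dimnames(tab))
  M
}

#' Upper-tail hypergeometric enrichment P-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, n, M)`: drawing `M` query genes
#' from a background of `N` containing `n` term genes.
#'
#' @param N Background size.
#' @param n Term (gene-set) size.
#' @param M Query-set size.
#' @param k Overlap between query and term.
#' @return The P-value.
#' @export
hypergeom_enrichment <- function(N, n, M, k) {
  stopifnot(n <= N, M <= N, k >= 0)
  if (k > min(n, M)) stop("k exceeds min(n, M)")
  phyper(k - 1, n, N - n, M, lower.tail = FALSE)
}

#' Gene-set enrichment over flat sets with BH correction
#'
#' @param query Character vector of query genes.
#' @param sets Named list of gene sets (character vectors).
#' @param universe Background gene universe.
#' @return Data frame `set_id`, `N`, `n`, `M`, `k`, `p`, `p_adj` (BH).
#' @export
enrich_gene_sets <- function(query, sets, universe) {
  query <- intersect(unique(query), universe)
  rows <- lapply(names(sets), function(id) {
    term <- intersect(unique(sets[[id]]), universe)
    k <- length(intersect(query, term))
    data.frame(set_id = id, N = length(universe), n = length(term),
               M = length(query), k = k,
               p = hypergeom_enrichment(length(universe), length(term),
                                        length(query), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Cell-type specificity scores
#'
#' For each gene the expression in each cell line is divided by its total
#' across cell lines; a gene is specific to a cell line when its score
#' there exceeds 0.85. All-zero genes are skipped with a warning.
#'
#' @param expr Numeric matrix or data frame (genes x cell lines,
#'   non-negative).
#' @param threshold Specificity cutoff; default 0.85.
#' @return List with `scores` (matrix, NA rows for all-zero genes) and
#'   `specific` (data frame `gene`, `cell`).
#' @export
cell_specificity <- function(expr, threshold = 0.85) {
  expr <- as.matrix(expr)
  stopifnot(all(expr >= 0, na.rm = TRUE))
  tot <- rowSums(expr)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero total expression skipped")
  }
  scores <- expr / tot
  scores[zero, ] <- NA_real_
  hit <- which(scores > threshold, arr.ind = TRUE)
  specific <- data.frame(
    gene = rownames(expr)[hit[, 1]] %||% as.character(hit[, 1]),
    cell = colnames(expr)[hit[, 2]] %||% as.character(hit[, 2]),
    stringsAsFactors = FALSE
  )
  list(scores = scores, specific = specific)
}

#' FFL type from TF regulatory effects
#'
#' Type I: top and intermediate TFs are repressors; type II: both
#' activators; type III: top activator, intermediate repressor; type IV:
#' top repressor, intermediate activator.
#'
#' @param top_effect,mid_effect Character vectors in
#'   `{activator, repressor, unknown}`.
#' @return Character vector of types (`I`..`IV`, or NA when an effect is
#'   unknown).
#' @export
ffl_type <- function(top_effect, mid_effect) {
  out <- rep(NA_character_, length(top_effect))
  out[top_effect == "repressor" & mid_effect == "repressor"] <- "I"
  out[top_effect == "activator" & mid_effect == "activator"] <- "II"
  out[top_effect == "activator" & mid_effect == "repressor"] <- "III"
  out[top_effect == "repressor" & mid_effect == "activator"] <- "IV"
  out
}

#' Expression comparisons between state compositions of one FFL type
#'
#' Within one FFL type (defined by the activator/repressor effects of the
#' top and intermediate TFs), target-gene expression is compared between
#' every pair of chromatin-state compositions by a two-sided Wilcoxon
#' rank-sum test. Targets shared by more than one composition are removed
#' first; pairs where either group has fewer than 3 targets are skipped.
#'
#' @param instances Labeled FFL instances (see [ffl_instances()]).
#' @param expr Named numeric vector of target expression.
#' @param effects Data frame `gene`, `effect` for TFs.
#' @param type FFL type to analyze (`"I"`..`"IV"`).
#' @param min_n Minimal group size; default 3.
#' @return Data frame `class1`, `class2`, `n1`, `n2`, `W`, `p`.
#' @export
composition_expression_test <- function(instances, expr, effects, type,
                                        min_n = 3L) {
  eff <- setNames(effects$effect, effects$gene)
  ty <- ffl_type(unname(eff[instances$top]), unname(eff[instances$mid]))
  ins <- instances[!is.na(ty) & ty == type, , drop = FALSE]
  empty <- data.frame(class1 = character(), class2 = character(),
                      n1 = integer(), n2 = integer(), W = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  if (nrow(ins) == 0) return(empty)
  cls <- paste(ins$top_state, ins$mid_state, ins$target_state, sep = "/")
  # drop targets appearing in more than one composition
  tc <- unique(data.frame(target = ins$target, cls = cls,
                          stringsAsFactors = FALSE))
  shared <- names(which(table(tc$target) > 1))
  ins <- ins[!ins$target %in% shared, , drop = FALSE]
  cls <- paste(ins$top_state, ins$mid_state, ins$target_state, sep = "/")
  groups <- split(ins$target, cls)
  groups <- lapply(groups, unique)
  ids <- names(groups)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      x <- expr[groups[[ids[i]]]]
      y <- expr[groups[[ids[j]]]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < min_n || length(y) < min_n) {
        message("skipping ", ids[j], " vs ", ids[i], ": group too small")
        next
      }
      wt <- suppressWarnings(wilcox.test(x, y))
      rows[[length(rows) + 1L]] <- data.frame(
        class1 = ids[j], class2 = ids[i],
        n1 = length(y), n2 = length(x),
        W = unname(wt$statistic), p = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
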