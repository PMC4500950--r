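#' Read a BED / narrowPeak file of ChIP-seq peaks
#'
#' Accepts plain BED (>= 3 columns) and the narrowPeak dialect. Coordinates
#' are kept in the BED-native 0-based half-open convention. The peak summit
#' is taken from narrowPeak column 10 (offset from the interval start) when
#' present and non-negative; otherwise the interval midpoint is used.
#'
#' @param path Path to the peak file.
#' @param tf_name Name of the TF whose peaks these are.
#' @return A data.frame with columns `chrom`, `start`, `end`,
#'   `summit_offset`, `tf_name`.
#' @export
read_peaks <- function(path, tf_name) {
  fields <- read_bed_fields(path, min_cols = 3)
  if (length(fields) == 0) {
    warning("no peak records in ", path)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      summit_offset = integer(), tf_name = character(),
                      stringsAsFactors = FALSE))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- bed_int(fields, 2, path)
  end <- bed_int(fields, 3, path)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  assert_intervals(df, paste0(path, " line"))
  summit <- rep(NA_integer_, nrow(df))
  has10 <- vapply(fields, length, 0L) >= 10
  if (any(has10)) {
    s10 <- suppressWarnings(as.integer(vapply(fields[has10], `[[`, "", 10)))
    summit[has10] <- s10
  }
  mid <- (end - start) %/% 2L
  summit[is.na(summit) | summit < 0] <- mid[is.na(summit) | summit < 0]
  bad <- which(summit >= end - start)
  if (length(bad)) {
    stop(path, ": summit offset outside peak on record ", bad[1])
  }
  df$summit_offset <- summit
  df$tf_name <- tf_name
  df
}

#' Read a genome chromatin-state segmentation (BED4)
#'
#' Column 4 carries the state label; labels are resolved to the four broad
#' states through `vocab_map` (see [default_state_map()]). Labels that are
#' already broad-state names pass through even when absent from the map.
#'
#' @param path Path to the BED4 segmentation.
#' @param vocab_map Named character vector mapping raw labels to broad
#'   states.
#' @return A data.frame with columns `chrom`, `start`, `end`, `label` (raw)
#'   and `broad`.
#' @export
read_segmentation <- function(path, vocab_map = default_state_map()) {
  # state labels may contain spaces, so segmentations split on tabs only;
  # fall back to whitespace for space-delimited files without tabs
  probe <- readLines(path, n = 5L, warn = FALSE)
  split <- if (any(grepl("\t", probe))) "\t" else "[ \t]+"
  fields <- read_bed_fields(path, min_cols = 4, split = split)
  if (length(fields) == 0) {
    warning("no segments in ", path)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), broad = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = bed_int(fields, 2, path),
    end = bed_int(fields, 3, path),
    label = vapply(fields, `[[`, "", 4),
    stringsAsFactors = FALSE
  )
  assert_intervals(df, paste0(path, " line"))
  broad <- unname(vocab_map[df$label])
  passthrough <- is.na(broad) & df$label %in% broad_states()
  broad[passthrough] <- df$label[passthrough]
  if (anyNA(broad)) {
    stop("unknown segmentation label(s): ",
         paste(unique(df$label[is.na(broad)]), collapse = ", "))
  }
  df$broad <- broad
  df
}

#' Read a gene / promoter annotation table
#'
#' Tab-delimited with header and columns `gene_id`, `chrom`, `tss`,
#' `strand`, `is_tf`, `tf_effect`. TSS positions are 0-based; pass
#' `one_based = TRUE` to shift a 1-based input by -1 exactly once. Genes
#' lacking a strand are treated as '+' with a warning.
#'
#' @param path Path to the TSV.
#' @param one_based Whether `tss` in the file is 1-based.
#' @return A data.frame of gene models.
#' @export
read_gene_annotation <- function(path, one_based = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) {
    stop(path, ": duplicated gene_id ", df$gene_id[duplicated(df$gene_id)][1])
  }
  if (one_based) df$tss <- df$tss - 1L
  nostrand <- !(df$strand %in% c("+", "-"))
  if (any(nostrand)) {
    warning(sum(nostrand), " gene(s) without strand treated as '+'")
    df$strand[nostrand] <- "+"
  }
  if (is.null(df$is_tf)) df$is_tf <- FALSE
  df$is_tf <- as.logical(df$is_tf)
  if (is.null(df$tf_effect)) df$tf_effect <- "unknown"
  df
}

#' Read an expression table (genes x conditions)
#'
#' @param path TSV with a `gene` column followed by one numeric column per
#'   cell condition.
#' @return A data.frame with rownames set to gene ids.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (!"gene" %in% names(df)) stop(path, ": missing 'gene' column")
  rownames(df) <- df$gene
  df
}

#' Write a tab-delimited table with header
#'
#' All pipeline outputs go through this writer so that write-then-read
#' round-trips reproduce records exactly.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration with the published default parameters
#'
#' Defaults: 500 bp promoter flanks on both sides of the TSS, 40 bp TF
#' binding-site windows centered on peak summits, 500 randomized networks
#' for motif significance, 10,000 exclusivity permutations, 1,000 transition
#' permutations, significance level 0.05.
#'
#' @param ... Overrides for any field.
#' @return A list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    promoter_up_bp = 500L,
    promoter_down_bp = 500L,
    tfbs_width_bp = 40L,
    n_random_networks = 500L,
    n_excl_perms = 10000L,
    n_transition_perms = 1000L,
    rng_seed = 1L,
    significance_alpha = 0.05,
    state_map = default_state_map(),
    swap_factor = 10L,
    containment = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# --- internal BED plumbing ---------------------------------------------------

read_bed_fields <- function(path, min_cols, split = "[ \t]+") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], split)
  nc <- vapply(fields, length, 0L)
  if (any(nc < min_cols)) {
    bad <- which(nc < min_cols)[1]
    stop(path, ": line ", lineno[bad], " has ", nc[bad],
         " field(s); expected >= ", min_cols)
  }
  attr(fields, "lineno") <- lineno
  fields
}

bed_int <- function(fields, col, path) {
  raw <- vapply(fields, `[[`, "", col)
  x <- suppressWarnings(as.integer(raw))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1]
    lineno <- attr(fields, "lineno")
    stop(path, ": line ", lineno[bad], ": non-integer coordinate '", raw[bad], "'")
  }
  x
}
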