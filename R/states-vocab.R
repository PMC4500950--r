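#' The four broad chromatin states
#'
#' Promoter chromatin is summarised into four broad classes: strong activity
#' (active promoter / strong enhancer marks), weak activity (the same marks at
#' moderate levels), poised (bivalent H3K4me3 + H3K27me3) and repressed
#' (Polycomb, heterochromatin / low signal and other non-active segments).
#' The vector order is also the deterministic tie-break priority used when
#' two states have equal promoter fold enrichment.
#'
#' @return Character vector of the four state names, in tie-break priority
#'   order: `StrongActivity`, `Poised`, `WeakActivity`, `Repressed`.
#' @export
broad_states <- function() c("StrongActivity", "Poised", "WeakActivity", "Repressed")

# fixed integer coding used by the compiled census (0..3)
state_levels <- function() c("StrongActivity", "WeakActivity", "Poised", "Repressed")

state_to_int <- function(x) {
  i <- match(x, state_levels())
  if (anyNA(i)) {
    stop("unknown broad state label(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i - 1L
}

int_to_state <- function(i) state_levels()[i + 1L]

#' Default mapping from 15 segmentation labels to 4 broad states
#'
#' Collapses a 15-state genome segmentation vocabulary to the four broad
#' classes: active promoter and strong enhancer labels become
#' `StrongActivity`; weak promoter and weak enhancer labels become
#' `WeakActivity`; the poised (bivalent) promoter label becomes `Poised`; all
#' remaining labels (transcription-associated, insulator, Polycomb repressed,
#' heterochromatin/low signal, repetitive) fall into `Repressed`. The map is
#' a plain named character vector so users can supply their own; segmentation
#' files that already carry broad labels pass through an identity mapping.
#'
#' @return Named character vector: names are segmentation labels, values are
#'   broad states.
#' @export
default_state_map <- function() {
  c(
    "Active Promoter"            = "StrongActivity",
    "Active promoter"            = "StrongActivity",
    "Strong Enhancer"            = "StrongActivity",
    "Strong enhancer"            = "StrongActivity",
    "Weak Promoter"              = "WeakActivity",
    "Weak promoter"              = "WeakActivity",
    "Weak Enhancer"              = "WeakActivity",
    "Weak enhancer"              = "WeakActivity",
    "Poised Promoter"            = "Poised",
    "Poised promoter"            = "Poised",
    "Insulator"                  = "Repressed",
    "Txn Transition"             = "Repressed",
    "Txn Elongation"             = "Repressed",
    "Weak Txn"                   = "Repressed",
    "Repressed"                  = "Repressed",
    "Polycomb repressed"         = "Repressed",
    "Heterochrom/lo"             = "Repressed",
    "Heterochromatin/low signal" = "Repressed",
    "Repetitive/CNV"             = "Repressed",
    "StrongActivity"             = "StrongActivity",
    "WeakActivity"               = "WeakActivity",
    "Poised"                     = "Poised"
  )
}
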