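# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seizure phase levels
#'
#' Ordered set of clinically delineated event labels used throughout the
#' package: the pre-ictal baseline, seizure onset, and up to three ictal
#' propagation phases.
#'
#' @return Character vector of valid phase labels.
#' @export
phase_levels <- function() {
  c("baseline", "onset", "ictal1", "ictal2", "ictal3")
}

#' Electrode name of a contact label
#'
#' SEEG contacts are labelled electrode-plus-index (e.g. `"LJ1"` is contact 1
#' of depth electrode LJ). The electrode name is the label with its trailing
#' contact index stripped; it is used to restrict pairwise statistics to
#' contacts on distinct electrodes.
#'
#' @param label Character vector of contact labels.
#' @return Character vector of electrode names.
#' @examples
#' contact_electrode(c("LJ1", "LK2", "RF3"))
#' @export
contact_electrode <- function(label) {
  sub("[0-9]+$", "", label)
}

# strict clamp to [0, 1], preserving dim attributes
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# off-diagonal values of a square matrix as a vector
offdiag <- function(m) {
  m[row(m) != col(m)]
}

stop_ictalnet <- function(msg, class) {
  abort(msg, class = c(class, "ictalnet_error"))
}
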