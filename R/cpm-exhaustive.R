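#' Exhaustive constant-Potts-model optimum (brute force)
#'
#' Enumerates every set partition of the features and returns the partition
#' with the maximal CPM objective. Only feasible for small feature counts
#' (n <= 14); serves as an independent reference for the Leiden optimizer.
#'
#' @param m symmetric similarity matrix (diagonal ignored).
#' @param gamma CPM resolution parameter.
#' @return list with `objective` and `membership` (integer labels in
#'   first-occurrence order).
#' @export
cpm_exhaustive <- function(m, gamma) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  .cpm_exhaustive_cpp(m, gamma)
}
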