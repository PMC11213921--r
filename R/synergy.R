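## Bliss-independence synergy scoring of odor-mixture responses.
## Components enter at half concentration in the mixture, so the
## independence expectation uses the halved responses.

#' Bliss interaction score
#'
#' \deqn{f_{expected} = (f_1/2 + f_2/2) - (f_1/2)(f_2/2)}
#' \deqn{score = 100 (f_3 - f_{expected})}
#' where \eqn{f_1, f_2} are the component responses (dF/F0 as
#' decimals), \eqn{f_3} the observed mixture response. Positive scores
#' indicate synergy, negative antagonism, ~0 additivity. Symmetric in
#' \eqn{f_1, f_2}; negative (inhibitory) responses pass through
#' unmodified.
#'
#' @param f1,f2 component response strengths (vectorized).
#' @param f3 observed mixture response strength.
#' @return Bliss score(s).
#' @examples
#' bliss_score(0.2, 0.2, 0.3) # 11: synergistic
#' bliss_score(0.4, 0.2, 0.28) # 0: additive
#' @export
bliss_score <- function(f1, f2, f3) {
  .check(all(is.finite(c(f1, f2, f3))), "responses must be finite")
  f_expected <- (f1 / 2 + f2 / 2) - (f1 / 2) * (f2 / 2)
  100 * (f3 - f_expected)
}

#' Frame-wise Bliss traces for units
#'
#' Computes the per-frame Bliss score for every unit from its
#' frame-aligned component traces (f1, f2) and mixture trace (f3),
#' plus a window-summary score (mean frame-wise score over the
#' analysis window). Units whose motif triplet is identical across
#' all three stimuli are computed but flagged for exclusion from
#' population pooling.
#'
#' @param f1,f2,f3 units x frames matrices of dF/F0 traces (f1, f2:
#'   components; f3: mixture), equal shapes.
#' @param onset_frame 1-based stimulus onset.
#' @param window analysis window length in frames (default 10).
#' @param triplets optional data.frame of per-unit motif ids with one
#'   column per stimulus (rows aligned with the trace matrices); used
#'   for the identical-motif exclusion flag.
#' @return data.frame (unit, score = window summary,
#'   excluded) of class \code{"bliss_traces"}; frame-wise score
#'   matrix in attribute \code{"traces"}, expected-response traces in
#'   attribute \code{"expected"}.
#' @export
bliss_traces <- function(f1, f2, f3, onset_frame, window = 10,
                         triplets = NULL) {
  f1 <- as.matrix(f1); f2 <- as.matrix(f2); f3 <- as.matrix(f3)
  .check(identical(dim(f1), dim(f2)) && identical(dim(f1), dim(f3)),
         "misaligned frame counts across the three stimuli")
  scores <- bliss_score(f1, f2, f3)
  expected <- f3 - scores / 100
  win <- onset_frame:min(onset_frame + window - 1, ncol(f1))
  summary_score <- rowMeans(scores[, win, drop = FALSE])
  excluded <- rep(FALSE, nrow(f1))
  if (!is.null(triplets)) {
    .check(nrow(triplets) == nrow(f1), "one triplet row per unit expected")
    m <- as.matrix(triplets)
    excluded <- apply(m, 1, function(r) length(unique(r)) == 1)
  }
  out <- data.frame(unit = seq_len(nrow(f1)), score = summary_score,
                    excluded = excluded)
  class(out) <- c("bliss_traces", "data.frame")
  attr(out, "traces") <- scores
  attr(out, "expected") <- expected
  out
}

#' Proportion of strongly synergistic units
#'
#' The threshold is one standard deviation of the pooled score
#' distribution; the fraction of units with score strictly greater is
#' returned. A zero-variance distribution yields 0 with a flag.
#'
#' @param scores per-unit window-summary Bliss scores (pooled; apply
#'   the identical-triplet exclusion before calling).
#' @return proportion, with attributes \code{threshold} and \code{n}.
#' @export
synergistic_fraction <- function(scores) {
  scores <- scores[is.finite(scores)]
  .check(length(scores) >= 2, "need at least 2 units")
  s <- stats::sd(scores)
  if (s == 0) {
    warning("zero-variance score distribution")
    return(structure(0, threshold = 0, n = length(scores)))
  }
  structure(mean(scores > s), threshold = s, n = length(scores))
}
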