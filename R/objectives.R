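#' Hedonic tuning parameters
#'
#' Optimal concentration (`theta`) and tuning width (`w`) per modality for
#' the Gaussian-product pleasantness score.  Defaults: NaCl optimum 100
#' (width 50), acidity optimum 0.1 (width 2), sweetness optimum 15000
#' (width 10000), bitterness optimum 1 (width 5).
#'
#' @param theta length-4 vector of optima (Na, H, sweet, bitter order).
#' @param w length-4 vector of strictly positive widths.
#' @return An object of class `hedonic_params`.
#' @export
hedonic_params <- function(theta = c(Na = 100, H = 0.1, sweet = 15000,
                                     bitter = 1),
                           w = c(Na = 50, H = 2, sweet = 10000, bitter = 5)) {
  stopifnot(length(theta) == 4, length(w) == 4, all(w > 0))
  structure(list(theta = theta, w = w), class = "hedonic_params")
}

#' Hedonic value of a stimulus
#'
#' Gaussian-product pleasantness score
#' `prod_i exp(-(S_i - theta_i)^2 / w_i^2)`, in (0, 1]; equals 1 exactly at
#' the hedonic optimum and decreases as any component departs from it.
#'
#' @param S a [tastant_stimulus()] (or numeric length 4).
#' @param p hedonic parameters.
#' @return Scalar in (0, 1].
#' @export
hedonic_value <- function(S, p = hedonic_params()) {
  s <- as.numeric(S)
  stopifnot(length(s) == 4)
  prod(exp(-(s - as.numeric(p$theta))^2 / as.numeric(p$w)^2))
}

#' Hedonic distance between two stimuli
#'
#' Signed difference of hedonic values, `hedonic_value(A) -
#' hedonic_value(B)`; the task losses use its absolute value.
#'
#' @param A,B stimuli.
#' @param p hedonic parameters.
#' @return Scalar in (-1, 1).
#' @export
hedonic_distance <- function(A, B, p = hedonic_params()) {
  hedonic_value(A, p) - hedonic_value(B, p)
}

#' Information distance between two output patterns
#'
#' Variation of information `H(X,Y) - MI(X;Y) = H(X|Y) + H(Y|X)` between the
#' empirical distributions of two binary spike patterns of the same shape.
#' The estimator pools the per-(bin, neuron) binary symbols of both patterns
#' into one empirical joint distribution over \{0,1\}^2 (plug-in estimate,
#' base-2 logarithms, `0 log 0 = 0`).  Nonnegative; exactly zero for a
#' pattern against itself.
#'
#' @param X,Y binary matrices of identical shape.
#' @param normalized if `TRUE`, divide by the joint entropy `H(X,Y)`,
#'   giving the normalized information distance in \[0, 1\] (0 when the
#'   joint entropy is zero): 1 for informative but independent patterns of
#'   any density, 0 for identical ones.  The default reports plain bits.
#' @return Distance in bits (at most 2 for binary symbols), or the
#'   dimensionless normalized distance.
#' @export
info_distance <- function(X, Y, normalized = FALSE) {
  if (!all(dim(X) == dim(Y)))
    stop("output patterns must have identical shape")
  x <- as.integer(X)
  y <- as.integer(Y)
  n <- length(x)
  pj <- c(sum(x == 0 & y == 0), sum(x == 0 & y == 1),
          sum(x == 1 & y == 0), sum(x == 1 & y == 1)) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hxy <- ent(pj)
  hx <- ent(c(pj[1] + pj[2], pj[3] + pj[4]))
  hy <- ent(c(pj[1] + pj[3], pj[2] + pj[4]))
  vi <- max(0, 2 * hxy - hx - hy)
  if (!normalized) return(vi)
  if (hxy <= 0) 0 else vi / hxy
}

#' Is a stimulus a pure taste?
#'
#' A stimulus is pure when exactly one modality component is nonzero.
#'
#' @param S a stimulus.
#' @return Logical.
#' @export
is_pure <- function(S) sum(as.numeric(S) > 0) == 1

#' Stimulus pair
#'
#' A pair of stimuli with purity labels, the unit of evaluation for the
#' task losses.  Labels default to the component count rule of [is_pure()].
#'
#' @param A,B stimuli.
#' @param pure_A,pure_B logical purity labels.
#' @return An object of class `stimulus_pair`.
#' @export
stimulus_pair <- function(A, B, pure_A = is_pure(A), pure_B = is_pure(B)) {
  structure(list(A = A, B = B, pure_A = pure_A, pure_B = pure_B),
            class = "stimulus_pair")
}

#' Input distance for the discrimination task
#'
#' `||A||_1 + ||B||_1` when both stimuli are labelled pure;
#' `0.5 * ||A - B||_2` otherwise.
#'
#' @param pair a [stimulus_pair()].
#' @return Nonnegative scalar.
#' @export
input_distance_task2 <- function(pair) {
  a <- as.numeric(pair$A)
  b <- as.numeric(pair$B)
  if (isTRUE(pair$pure_A) && isTRUE(pair$pure_B))
    sum(abs(a)) + sum(abs(b))
  else
    0.5 * sqrt(sum((a - b)^2))
}

#' Task loss over a batch of stimulus pairs
#'
#' Mean absolute mismatch between the normalized input-space distance and
#' the normalized output-pattern information distance, negated:
#' `-(1/n) * sum_i |Din_norm_i - Dres_norm_i|`.  For task 1 the input
#' distance is `|hedonic_distance|` (already in \[0, 1\)); for task 2 it is
#' [input_distance_task2()] normalized by the batch maximum (or `din_max`
#' when supplied).  The output distance is the information distance in
#' bits divided by the marginal support ceiling of the binary-symbol
#' estimator (1 bit = log2 of a single symbol's state count), so a
#' normalized output distance of 1 corresponds to a pair of independent
#' sparse patterns near 11% occupancy — the operating regime of a
#' fingerprint code — while silence and saturation both map to 0 and
#' over-dense codes overshoot past 1.  The genetic algorithm maximizes
#' this quantity, i.e. drives the mismatch to zero; 0 is the best
#' attainable value.  See the package vignette for the analysis behind
#' this normalization.
#'
#' @param pairs list of [stimulus_pair()] objects.
#' @param outputs list (same length) of `list(X, Y)` output-pattern pairs.
#' @param task 1 (hedonic encoding) or 2 (pure/mixed discrimination).
#' @param p hedonic parameters (task 1).
#' @param din_max optional fixed normalizer for task-2 input distances.
#' @return Nonpositive scalar loss.
#' @export
task_loss <- function(pairs, outputs, task = 1, p = hedonic_params(),
                      din_max = NULL) {
  if (length(pairs) == 0) stop("at least one stimulus pair is required")
  if (length(outputs) != length(pairs))
    stop("pairs and outputs must be aligned")
  task <- match.arg(as.character(task), c("1", "2"))
  din <- vapply(pairs, function(pr) {
    if (task == "1") abs(hedonic_distance(pr$A, pr$B, p))
    else input_distance_task2(pr)
  }, numeric(1))
  if (task == "2") {
    m <- if (is.null(din_max)) max(din) else din_max
    din <- if (m > 0) din / m else din * 0
  }
  dres <- vapply(outputs, function(o) info_distance(o[[1]], o[[2]]),
                 numeric(1))
  -mean(abs(din - dres))
}
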