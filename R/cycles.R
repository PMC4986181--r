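#' Classify a length-4 cycle by its sign pattern
#'
#' A length-4 cycle is two drugs (i, j) sharing two targets (A, B). Each
#' target carries an action pair that is coherent or incoherent; the cycle
#' is `coherent` when both targets are coherent, `incoherent` when both are
#' incoherent, `mixed` otherwise. Cycle parity is the sign of the product
#' of the four edge signs: coherent and incoherent cycles are positive
#' (even number of negative edges), mixed cycles negative.
#'
#' The canonical pattern label is invariant under swapping the drugs,
#' swapping the targets, or both: each target's unordered sign pair is
#' written `+,+` / `+,-` / `-,-` and the two are sorted, e.g. `"(+,+/-,-)"`.
#'
#' @param sign_i_A,sign_j_A,sign_i_B,sign_j_B Edge signs in `{-1, +1}`:
#'   drug i and j on target A, drug i and j on target B. Vectorized.
#' @return A data.frame with columns `coherence` in
#'   `{coherent, mixed, incoherent}`, `parity` in `{positive, negative}`,
#'   and `pattern` (canonical label).
#' @export
classify_4cycle <- function(sign_i_A, sign_j_A, sign_i_B, sign_j_B) {
  signs <- cbind(sign_i_A, sign_j_A, sign_i_B, sign_j_B)
  if (any(signs == 0L)) stop("unsigned edge (sign 0) in a cycle")
  stopifnot(all(signs %in% c(-1L, 1L)))
  coh_A <- sign_i_A == sign_j_A
  coh_B <- sign_i_B == sign_j_B
  coherence <- ifelse(coh_A & coh_B, "coherent",
                      ifelse(!coh_A & !coh_B, "incoherent", "mixed"))
  parity <- ifelse(sign_i_A * sign_j_A * sign_i_B * sign_j_B > 0,
                   "positive", "negative")
  lab <- function(a, b) {  # unordered sign pair label
    ifelse(a == 1L & b == 1L, "+,+",
           ifelse(a == -1L & b == -1L, "-,-", "+,-"))
  }
  lab_A <- lab(sign_i_A, sign_j_A)
  lab_B <- lab(sign_i_B, sign_j_B)
  pattern <- paste0("(", pmin(lab_A, lab_B), "/", pmax(lab_A, lab_B), ")")
  data.frame(coherence = coherence, parity = parity, pattern = pattern,
             stringsAsFactors = FALSE)
}

.cycle_patterns <- data.frame(
  pattern = c("(+,+/+,+)", "(+,+/-,-)", "(-,-/-,-)",
              "(+,+/+,-)", "(+,-/-,-)", "(+,-/+,-)"),
  coherence = c("coherent", "coherent", "coherent",
                "mixed", "mixed", "incoherent"),
  parity = c("positive", "positive", "positive",
             "negative", "negative", "positive"),
  stringsAsFactors = FALSE
)

#' Count length-4 cycles by sign-pattern class
#'
#' Each unordered (drug pair, target pair) with all four signed edges
#' present contributes exactly one cycle; a pair with k common signed
#' targets therefore contributes choose(k, 2) cycles. Counts are
#' accumulated over the six canonical sign patterns, which follow
#' combinatorially from each pair's (c_pp, c_mm, c_pm) split.
#'
#' @param net A [signed_dtn()]; unsigned edges are ignored.
#' @return A data.frame of class `cycle_counts` with one row per pattern:
#'   `pattern`, `coherence`, `parity`, `n`.
#' @export
enumerate_4cycles <- function(net) {
  stopifnot(inherits(net, "signed_dtn"))
  ov <- enumerate_shared_pairs(net)
  choose2 <- function(k) k * (k - 1) / 2
  out <- .cycle_patterns
  out$n <- c(
    sum(choose2(ov$c_pp)),         # (+,+/+,+)
    sum(ov$c_pp * ov$c_mm),        # (+,+/-,-)
    sum(choose2(ov$c_mm)),         # (-,-/-,-)
    sum(ov$c_pp * ov$c_pm),        # (+,+/+,-)
    sum(ov$c_mm * ov$c_pm),        # (+,-/-,-)
    sum(choose2(ov$c_pm))          # (+,-/+,-)
  )
  out$n <- as.numeric(out$n)
  class(out) <- c("cycle_counts", "data.frame")
  out
}

#' Build a cycle-count table from the six pattern counts
#'
#' Convenience constructor for working directly from published or external
#' count tables, in the canonical pattern order `(+,+/+,+)`, `(+,+/-,-)`,
#' `(-,-/-,-)`, `(+,+/+,-)`, `(+,-/-,-)`, `(+,-/+,-)`.
#'
#' @param n Numeric vector of six nonnegative counts.
#' @return A `cycle_counts` data.frame as in [enumerate_4cycles()].
#' @export
cycle_counts <- function(n) {
  stopifnot(length(n) == 6L, all(n >= 0))
  out <- .cycle_patterns
  out$n <- as.numeric(n)
  class(out) <- c("cycle_counts", "data.frame")
  out
}

#' Fractions of coherent, mixed, incoherent and positive length-4 cycles
#'
#' Exact arithmetic on the integer counts; positive cycles are the coherent
#' plus the incoherent ones (both have an even number of negative edges).
#'
#' @param counts A `cycle_counts` table ([enumerate_4cycles()] or
#'   [cycle_counts()]) with total >= 1.
#' @return A named list: `frac_coherent`, `frac_mixed`, `frac_incoherent`,
#'   `frac_positive`, `total`.
#' @export
cycle_fractions <- function(counts) {
  stopifnot(inherits(counts, "cycle_counts"))
  total <- sum(counts$n)
  if (total < 1) stop("no length-4 cycles to summarize")
  coh <- sum(counts$n[counts$coherence == "coherent"])
  mix <- sum(counts$n[counts$coherence == "mixed"])
  inc <- sum(counts$n[counts$coherence == "incoherent"])
  list(frac_coherent = coh / total,
       frac_mixed = mix / total,
       frac_incoherent = inc / total,
       frac_positive = (coh + inc) / total,
       total = total)
}
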