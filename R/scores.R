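#' Synergistic score coefficients of a drug pair
#'
#' For drugs i and j sharing signed pharmacological targets, the
#' synergistic score of drug i with respect to j is
#' `a_i(j) = (p_pp + p_mm - p_pm) / p_i`: coherent minus incoherent shared
#' pharmacological actions over drug i's signed pharmacological target
#' count. Positive scores mean mutual reinforcement on the principal
#' targets; since the numerator is shared, `a_i(j)` and `a_j(i)` always
#' agree in sign, while their magnitudes differ when the drugs have
#' different numbers of pharmacological targets. Scores lie in [-1, 1]; a
#' score of 1 means every pharmacological target of the drug is hit
#' coherently by the partner.
#'
#' @param overlaps A [enumerate_shared_pairs()] result (any subset of rows).
#' @return The input with numeric columns `a_ij`, `a_ji` appended;
#'   undefined coefficients (`p_i = 0` resp. `p_j = 0`) are `NA`, never 0.
#' @export
synergistic_score <- function(overlaps) {
  num <- overlaps$p_pp + overlaps$p_mm - overlaps$p_pm
  overlaps$a_ij <- ifelse(overlaps$p_i > 0L, num / overlaps$p_i, NA_real_)
  overlaps$a_ji <- ifelse(overlaps$p_j > 0L, num / overlaps$p_j, NA_real_)
  overlaps
}

#' Side-effect score coefficients of a drug pair
#'
#' For drugs i and j sharing off-targets, the side-effect score of drug i
#' under j is `b_i(j) = (s_pm - (s_pp + s_mm)) / s_i`: incoherent minus
#' coherent shared off-target actions (targets off-target for both drugs)
#' over drug i's signed off-target count. Positive
#' scores mean the partner drug opposes — and hence tends to mitigate —
#' drug i's off-target actions; `b_i(j) = 1` means every off-target of drug
#' i is hit by j with the opposite sign. `b_i(j)` and `b_j(i)` always agree
#' in sign.
#'
#' @param overlaps A [enumerate_shared_pairs()] result (any subset of rows).
#' @return The input with numeric columns `b_ij`, `b_ji` appended;
#'   undefined coefficients (`s_i = 0` resp. `s_j = 0`) are `NA`, never 0.
#' @export
side_effect_score <- function(overlaps) {
  num <- overlaps$s_pm - (overlaps$s_pp + overlaps$s_mm)
  overlaps$b_ij <- ifelse(overlaps$s_i > 0L, num / overlaps$s_i, NA_real_)
  overlaps$b_ji <- ifelse(overlaps$s_j > 0L, num / overlaps$s_j, NA_real_)
  overlaps
}

#' Screen drug pairs for pharmacological synergy
#'
#' Selects pairs whose overlap is purely pharmacological (`p_ij > 0` and
#' `s_ij = 0`), computes both synergistic scores, and buckets the pairs:
#' `mutual_high` (both scores >= `high`), `unilateral_high` (exactly one),
#' `positive` (both > 0, neither bucket above), `zero` (both exactly 0),
#' `negative` (both < 0), `undefined` (a score undefined because a drug has
#' no signed pharmacological target).
#'
#' @param net A [signed_dtn()].
#' @param high Threshold for a "high" score (default 0.5).
#' @return A list of class `screen_report`: `screen = "synergy"`, `high`,
#'   `pairs` (scored table with `synergy_class`), `bucket_sizes`.
#' @export
screen_synergy <- function(net, high = 0.5) {
  ov <- enumerate_shared_pairs(net)
  ov <- ov[ov$p_ij > 0L & ov$s_ij == 0L, , drop = FALSE]
  ov <- synergistic_score(ov)
  cls <- character(nrow(ov))
  if (nrow(ov)) {
    nd <- is.na(ov$a_ij) | is.na(ov$a_ji)
    hi_i <- !is.na(ov$a_ij) & ov$a_ij >= high
    hi_j <- !is.na(ov$a_ji) & ov$a_ji >= high
    cls[nd] <- "undefined"
    cls[!nd & hi_i & hi_j] <- "mutual_high"
    cls[!nd & xor(hi_i, hi_j)] <- "unilateral_high"
    rest <- !nd & !hi_i & !hi_j
    cls[rest & ov$a_ij > 0 & ov$a_ji > 0] <- "positive"
    cls[rest & ov$a_ij == 0 & ov$a_ji == 0] <- "zero"
    cls[rest & ov$a_ij < 0 & ov$a_ji < 0] <- "negative"
  }
  ov$synergy_class <- cls
  buckets <- c("mutual_high", "unilateral_high", "positive", "zero",
               "negative", "undefined")
  structure(list(
    screen = "synergy", high = high, pairs = ov,
    bucket_sizes = vapply(buckets, function(b) sum(cls == b), 0L)
  ), class = "screen_report")
}

#' Screen drug pairs for side-effect improvement
#'
#' Selects pairs sharing both pharmacological targets and off-targets
#' (`p_ij > 0`, `s_ij > 0`) whose pharmacological actions are predominantly
#' coherent (`p_pp + p_mm > p_pm`, i.e. positive synergistic score),
#' computes both side-effect scores, and buckets: `beneficial` (both > 0),
#' `neutral` (both = 0), `aggravating` (both < 0), `undefined`. Sub-flags
#' `mutual_high` (both >= `high`) and `unilateral_high` (exactly one) mark
#' strong mitigation.
#'
#' @inheritParams screen_synergy
#' @return A list of class `screen_report`: `screen = "side_effect"`,
#'   `high`, `pairs` (scored table with `side_effect_class` and
#'   `high_flag`), `bucket_sizes`.
#' @export
screen_side_effect <- function(net, high = 0.5) {
  ov <- enumerate_shared_pairs(net)
  ov <- ov[ov$p_ij > 0L & ov$s_ij > 0L &
             (ov$p_pp + ov$p_mm) > ov$p_pm, , drop = FALSE]
  ov <- side_effect_score(ov)
  cls <- character(nrow(ov))
  flag <- character(nrow(ov))
  if (nrow(ov)) {
    nd <- is.na(ov$b_ij) | is.na(ov$b_ji)
    cls[nd] <- "undefined"
    cls[!nd & ov$b_ij > 0 & ov$b_ji > 0] <- "beneficial"
    cls[!nd & ov$b_ij == 0 & ov$b_ji == 0] <- "neutral"
    cls[!nd & ov$b_ij < 0 & ov$b_ji < 0] <- "aggravating"
    hi_i <- !is.na(ov$b_ij) & ov$b_ij >= high
    hi_j <- !is.na(ov$b_ji) & ov$b_ji >= high
    flag[hi_i & hi_j] <- "mutual_high"
    flag[xor(hi_i, hi_j)] <- "unilateral_high"
    flag[!(hi_i | hi_j)] <- "none"
  }
  ov$side_effect_class <- cls
  ov$high_flag <- flag
  buckets <- c("beneficial", "neutral", "aggravating", "undefined")
  structure(list(
    screen = "side_effect", high = high, pairs = ov,
    bucket_sizes = vapply(buckets, function(b) sum(cls == b), 0L)
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("%s screen: %d pairs (high threshold %.2f)\n",
              x$screen, nrow(x$pairs), x$high))
  for (b in names(x$bucket_sizes)) {
    cat(sprintf("  %-16s %6d\n", b, x$bucket_sizes[[b]]))
  }
  invisible(x)
}
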