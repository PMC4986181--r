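#' Classify the joint action of two drugs on one target
#'
#' Two signed actions on a common target are coherent when they share a
#' sign — (+,+) or (-,-), the second drug reinforces the first — and
#' incoherent when the signs are opposite, (+,-), the drugs counteract each
#' other.
#'
#' @param sign_a,sign_b Integer vectors of signs in `{-1, +1}`. Unsigned
#'   edges (0) are an error and must be excluded upstream.
#' @return Character vector, `"coherent"` or `"incoherent"`.
#' @export
classify_action_pair <- function(sign_a, sign_b) {
  if (any(sign_a == 0L) || any(sign_b == 0L)) {
    stop("unsigned action (sign 0) cannot be classified; restrict to signed edges")
  }
  stopifnot(all(sign_a %in% c(-1L, 1L)), all(sign_b %in% c(-1L, 1L)))
  ifelse(sign_a == sign_b, "coherent", "incoherent")
}

# Long table of (pair, shared target) incidences on the signed restriction:
# one row per unordered drug pair and common signed target, with both signs
# and both pharmacological flags. Internal engine for the pair statistics.
pair_target_table <- function(net) {
  e <- net$edges[net$edges$sign != 0L, , drop = FALSE]
  m <- merge(e, e, by = "target", suffixes = c("_i", "_j"))
  m <- m[m$drug_i < m$drug_j, , drop = FALSE]
  m$pattern <- ifelse(m$sign_i == 1L & m$sign_j == 1L, "pp",
                      ifelse(m$sign_i == -1L & m$sign_j == -1L, "mm", "pm"))
  m$pharm_both <- m$pharmacological_i & m$pharmacological_j
  m$pharm_neither <- !m$pharmacological_i & !m$pharmacological_j
  rownames(m) <- NULL
  m
}

#' Enumerate drug pairs sharing signed targets
#'
#' For every unordered drug pair with at least one common signed target,
#' counts the shared targets by sign pattern — `c_pp` (+,+), `c_mm` (-,-)
#' and `c_pm` (+,-) — and splits them into pharmacological counts
#' (`p_pp`, `p_mm`, `p_pm`: targets whose edges are pharmacological for
#' BOTH drugs) and shared off-target action counts (`s_pp`, `s_mm`, `s_pm`:
#' targets non-pharmacological for both drugs, so that every such target is
#' an off-target of each drug and the side-effect scores stay in
#' \[-1, 1\]). Targets pharmacological for exactly one drug of the pair
#' count in `c_*` and in the derived `s_ij = c_ij - p_ij`, but in neither
#' split: they are the on-target action of one drug and a side effect of
#' the other, hence neither a shared pharmacological nor a shared
#' off-target action. Per-drug totals are
#' attached: `t_i` signed targets, `p_i` signed pharmacological targets,
#' `s_i = t_i - p_i` signed off-targets (and likewise for drug j).
#'
#' @param net A [signed_dtn()]; unsigned edges are ignored.
#' @return A data.frame of class `pair_overlap`, one row per pair
#'   (`drug_i < drug_j` lexicographically) with the count columns above
#'   plus the derived `c_ij`, `p_ij`, `s_ij`.
#' @export
enumerate_shared_pairs <- function(net) {
  stopifnot(inherits(net, "signed_dtn"))
  m <- pair_target_table(net)
  empty <- data.frame(
    drug_i = character(), drug_j = character(),
    c_pp = integer(), c_mm = integer(), c_pm = integer(), c_ij = integer(),
    p_pp = integer(), p_mm = integer(), p_pm = integer(), p_ij = integer(),
    s_pp = integer(), s_mm = integer(), s_pm = integer(), s_ij = integer(),
    t_i = integer(), p_i = integer(), s_i = integer(),
    t_j = integer(), p_j = integer(), s_j = integer()
  )
  if (!nrow(m)) {
    class(empty) <- c("pair_overlap", "data.frame")
    return(empty)
  }
  key <- paste(m$drug_i, m$drug_j, sep = "\r")
  grp <- factor(key, levels = unique(key))
  count_by <- function(cond) as.integer(tapply(cond, grp, sum, default = 0L))
  first <- !duplicated(key)
  out <- data.frame(
    drug_i = m$drug_i[first], drug_j = m$drug_j[first],
    c_pp = count_by(m$pattern == "pp"),
    c_mm = count_by(m$pattern == "mm"),
    c_pm = count_by(m$pattern == "pm"),
    p_pp = count_by(m$pattern == "pp" & m$pharm_both),
    p_mm = count_by(m$pattern == "mm" & m$pharm_both),
    p_pm = count_by(m$pattern == "pm" & m$pharm_both),
    s_pp = count_by(m$pattern == "pp" & m$pharm_neither),
    s_mm = count_by(m$pattern == "mm" & m$pharm_neither),
    s_pm = count_by(m$pattern == "pm" & m$pharm_neither),
    stringsAsFactors = FALSE
  )
  out$c_ij <- out$c_pp + out$c_mm + out$c_pm
  out$p_ij <- out$p_pp + out$p_mm + out$p_pm
  out$s_ij <- out$c_ij - out$p_ij

  e <- net$edges[net$edges$sign != 0L, , drop = FALSE]
  t_tot <- table(factor(e$drug, levels = net$drugs))
  p_tot <- table(factor(e$drug[e$pharmacological], levels = net$drugs))
  out$t_i <- as.integer(t_tot[out$drug_i])
  out$p_i <- as.integer(p_tot[out$drug_i])
  out$s_i <- out$t_i - out$p_i
  out$t_j <- as.integer(t_tot[out$drug_j])
  out$p_j <- as.integer(p_tot[out$drug_j])
  out$s_j <- out$t_j - out$p_j

  out <- out[order(out$drug_i, out$drug_j),
             c("drug_i", "drug_j", "c_pp", "c_mm", "c_pm", "c_ij",
               "p_pp", "p_mm", "p_pm", "p_ij",
               "s_pp", "s_mm", "s_pm", "s_ij",
               "t_i", "p_i", "s_i", "t_j", "p_j", "s_j")]
  rownames(out) <- NULL
  class(out) <- c("pair_overlap", "data.frame")
  out
}

#' Shared-target histograms of drug pairs by sign pattern
#'
#' For pattern `"any"`, a pair with `c_ij = k` common signed targets
#' increments bin `k`; for each signed pattern (`"++"`, `"--"`, `"+-"`), a
#' pair increments the bin equal to its count of that pattern (pairs with
#' zero of a pattern do not appear in that panel). The cumulative total per
#' pattern is the number of contributing pairs.
#'
#' @param overlaps A [enumerate_shared_pairs()] result.
#' @return A data.frame with columns `pattern`, `n_common_targets`,
#'   `n_pairs`, plus attribute `"totals"` (named cumulative pair counts per
#'   pattern).
#' @export
pair_sign_histograms <- function(overlaps) {
  cols <- c(any = "c_ij", `++` = "c_pp", `--` = "c_mm", `+-` = "c_pm")
  rows <- lapply(names(cols), function(p) {
    k <- overlaps[[cols[[p]]]]
    k <- k[k > 0L]
    if (!length(k)) return(NULL)
    tab <- table(k)
    data.frame(pattern = p, n_common_targets = as.integer(names(tab)),
               n_pairs = as.integer(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pattern = character(), n_common_targets = integer(),
                      n_pairs = integer())
  }
  rownames(out) <- NULL
  totals <- vapply(names(cols),
                   function(p) sum(out$n_pairs[out$pattern == p]), 0L)
  attr(out, "totals") <- totals
  out
}

#' Network-wide coherence probability
#'
#' The probability rho that a shared-target action pair is coherent:
#' the sum over pairs of coherent counts (`c_pp + c_mm`) divided by the sum
#' of all shared-target action counts (`c_ij`). This is the success
#' probability of the per-pair binomial enrichment test.
#'
#' @param overlaps A [enumerate_shared_pairs()] result with >= 1 pair.
#' @return A list of class `coherence_stats`: `total_coherent`,
#'   `total_incoherent`, `rho`, plus `n_pairs`, `n_pairs_coherent_ge1`,
#'   `pair_coherent_fraction` (the fraction of PAIRS whose actions are
#'   majority-classifiable; see Details).
#' @details Two related quantities are reported distinctly: `rho` is the
#'   fraction of pairwise ACTIONS that are coherent, while
#'   `pair_coherent_fraction` is the fraction of PAIRS with at least one
#'   coherent action among all pairs sharing a target. The two differ
#'   whenever pairs share several targets.
#' @export
coherence_probability <- function(overlaps) {
  if (!nrow(overlaps)) stop("no drug pairs share a signed target")
  total_coherent <- sum(overlaps$c_pp + overlaps$c_mm)
  total_incoherent <- sum(overlaps$c_pm)
  structure(list(
    total_coherent = total_coherent,
    total_incoherent = total_incoherent,
    rho = total_coherent / (total_coherent + total_incoherent),
    n_pairs = nrow(overlaps),
    n_pairs_coherent_ge1 = sum(overlaps$c_pp + overlaps$c_mm > 0L),
    n_pairs_incoherent_ge1 = sum(overlaps$c_pm > 0L),
    pair_coherent_fraction =
      sum(overlaps$c_pp + overlaps$c_mm > 0L) / nrow(overlaps)
  ), class = "coherence_stats")
}

#' @export
print.coherence_stats <- function(x, ...) {
  cat(sprintf("Coherence over %d drug pairs sharing signed targets\n",
              x$n_pairs))
  cat(sprintf("  actions: %d coherent, %d incoherent, rho = %.4f\n",
              x$total_coherent, x$total_incoherent, x$rho))
  cat(sprintf("  pairs with >=1 coherent action: %d (%.1f%% of pairs)\n",
              x$n_pairs_coherent_ge1, 100 * x$pair_coherent_fraction))
  invisible(x)
}

#' Per-pair binomial enrichment test for coherent or incoherent actions
#'
#' With xi coherent actions out of `c_ij` shared-target actions and
#' network-wide coherence probability rho, tests overabundance of coherent
#' actions with the one-sided upper binomial tail P(X >= xi),
#' X ~ Binomial(c_ij, rho), and symmetrically overabundance of incoherent
#' actions with P(Y >= c_pm), Y ~ Binomial(c_ij, 1 - rho). A pair is called
#' enriched when its smaller p-value is below `alpha`.
#'
#' `mode = "printed"` instead reproduces the algebra of the published
#' formula verbatim (its cumulative sum carries `1 - rho` on the running
#' index, with p-value one minus the sum), which is kept for comparability;
#' the default `"standard"` orientation is the test matching the stated
#' purpose of detecting coherent enrichment.
#'
#' @param overlaps A [enumerate_shared_pairs()] result (or any data.frame
#'   with columns `drug_i`, `drug_j`, `c_pp`, `c_mm`, `c_pm`, `c_ij`).
#' @param rho Coherence probability in (0, 1), typically
#'   `coherence_probability(overlaps)$rho`.
#' @param alpha Per-pair significance threshold.
#' @param mode `"standard"` (upper tails, default) or `"printed"`.
#' @param adjust `"none"` (per-pair threshold, default) or `"BH"` for
#'   Benjamini-Hochberg adjustment of each p-value family before calling.
#' @return A data.frame of class `pair_enrichment`: `drug_i`, `drug_j`,
#'   `xi` (coherent count), `n_incoherent`, `c_ij`, `p_coherent`,
#'   `p_incoherent`, `call` in `{coherent-enriched, incoherent-enriched,
#'   none}`, and attribute `"alpha"`.
#' @export
binomial_enrichment <- function(overlaps, rho, alpha = 0.05,
                                mode = c("standard", "printed"),
                                adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1) {
    stop("rho must be a single probability strictly inside (0, 1)")
  }
  xi <- overlaps$c_pp + overlaps$c_mm
  n_inc <- overlaps$c_pm
  n <- overlaps$c_ij
  stopifnot(all(n >= 1L))
  if (mode == "standard") {
    p_coh <- stats::pbinom(xi - 1L, n, rho, lower.tail = FALSE)
    p_inc <- stats::pbinom(n_inc - 1L, n, 1 - rho, lower.tail = FALSE)
  } else {
    # published algebra: p = 1 - sum_{l<=xi} C(n,l) (1-rho)^l rho^(n-l)
    p_coh <- 1 - stats::pbinom(xi, n, 1 - rho)
    p_inc <- 1 - stats::pbinom(n_inc, n, rho)
  }
  p_coh_cmp <- if (adjust == "BH") stats::p.adjust(p_coh, "BH") else p_coh
  p_inc_cmp <- if (adjust == "BH") stats::p.adjust(p_inc, "BH") else p_inc
  call <- rep("none", nrow(overlaps))
  sig_coh <- p_coh_cmp < alpha
  sig_inc <- p_inc_cmp < alpha
  call[sig_coh & (!sig_inc | p_coh_cmp <= p_inc_cmp)] <- "coherent-enriched"
  call[sig_inc & (!sig_coh | p_inc_cmp < p_coh_cmp)] <- "incoherent-enriched"
  out <- data.frame(
    drug_i = overlaps$drug_i, drug_j = overlaps$drug_j,
    xi = xi, n_incoherent = n_inc, c_ij = n,
    p_coherent = p_coh, p_incoherent = p_inc,
    call = call, stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "mode") <- mode
  attr(out, "adjust") <- adjust
  class(out) <- c("pair_enrichment", "data.frame")
  out
}

#' Two-dimensional coherence histogram of drug pairs
#'
#' Bins drug pairs by their (coherent, incoherent) shared-action counts and
#' flags each cell by the enrichment call of its pairs, producing the table
#' behind the two-tailed skew plot: a strongly organized network puts most
#' mass near the axes (pairs that are nearly all-coherent or
#' all-incoherent).
#'
#' @inheritParams binomial_enrichment
#' @return A data.frame with columns `n_coherent`, `n_incoherent`,
#'   `n_pairs`, `flag` in `{coherent, incoherent, none}`. Cell flags equal
#'   the per-pair enrichment calls, which are constant within a cell.
#' @export
coherence_histogram <- function(overlaps, rho, alpha = 0.05,
                                mode = c("standard", "printed")) {
  mode <- match.arg(mode)
  if (!nrow(overlaps)) {
    return(data.frame(n_coherent = integer(), n_incoherent = integer(),
                      n_pairs = integer(), flag = character()))
  }
  enr <- binomial_enrichment(overlaps, rho, alpha, mode)
  key <- paste(enr$xi, enr$n_incoherent)
  grp <- factor(key, levels = unique(key))
  first <- !duplicated(key)
  out <- data.frame(
    n_coherent = enr$xi[first],
    n_incoherent = enr$n_incoherent[first],
    n_pairs = as.integer(table(grp)),
    flag = sub("-enriched", "", enr$call[first]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$n_coherent, out$n_incoherent), ]
  rownames(out) <- NULL
  out
}
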