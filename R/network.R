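#' Construct a signed bipartite drug-target network
#'
#' The central container of the package. Edges join a drug to a target and
#' carry a sign (+1 activating-like, -1 inhibiting-like, 0 unclassifiable),
#' a logical `pharmacological` flag marking the intended on-target action,
#' and a logical `conflicting` flag set when several recorded actions for
#' the same drug-target pair disagreed in sign.
#'
#' Drug and target identifier spaces must be disjoint; a string used on both
#' sides is an error, since it would break bipartiteness.
#'
#' @param edges A data.frame with columns `drug`, `target`, `sign` (integer
#'   in `{-1, 0, 1}`), `pharmacological` (logical) and optionally
#'   `conflicting` (logical, default `FALSE`). At most one row per
#'   (drug, target) pair.
#' @param drugs,targets Optional character vectors of node identifiers; by
#'   default taken from the edges. Extra isolated nodes may be listed.
#' @return An object of class `signed_dtn`: a list with elements `edges`
#'   (the validated edge table), `drugs` and `targets`.
#' @seealso [load_edge_list()], [generate_network()], [generate_fixture()]
#' @export
signed_dtn <- function(edges, drugs = NULL, targets = NULL) {
  stopifnot(is.data.frame(edges))
  required <- c("drug", "target", "sign", "pharmacological")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"conflicting" %in% names(edges)) edges$conflicting <- logical(nrow(edges))
  edges <- edges[, c("drug", "target", "sign", "pharmacological", "conflicting")]
  edges$drug <- as.character(edges$drug)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  edges$pharmacological <- as.logical(edges$pharmacological)
  edges$conflicting <- as.logical(edges$conflicting)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 0L, 1L))) {
    stop("edge signs must be in {-1, 0, 1}")
  }
  key <- paste(edges$drug, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (drug, target) edge(s): ",
         paste(utils::head(unique(sub("\r", " / ", key[duplicated(key)])), 3),
               collapse = "; "))
  }
  drugs <- sort(unique(c(edges$drug, as.character(drugs))))
  targets <- sort(unique(c(edges$target, as.character(targets))))
  both <- intersect(drugs, targets)
  if (length(both)) {
    stop("identifier(s) used as both drug and target: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, drugs = drugs, targets = targets),
            class = "signed_dtn")
}

#' @export
print.signed_dtn <- function(x, ...) {
  s <- summarize_network(x)
  cat("Signed bipartite drug-target network\n")
  cat(sprintf("  %d drugs, %d targets, %d edges\n",
              s$n_drugs, s$n_targets, s$n_edges))
  cat(sprintf("  signs: %d positive, %d negative, %d unsigned\n",
              s$n_positive, s$n_negative, s$n_unsigned))
  cat(sprintf("  pharmacological edges: %d\n", s$n_pharmacological))
  invisible(x)
}

#' Restrict a network to signed edges
#'
#' Keeps only edges with sign +1 or -1; nodes left without incident edges
#' are dropped. Most pair-level statistics are defined on this restriction.
#'
#' @param net A [signed_dtn()].
#' @return A `signed_dtn` with unsigned edges removed.
#' @export
restrict_to_signed <- function(net) {
  stopifnot(inherits(net, "signed_dtn"))
  signed_dtn(net$edges[net$edges$sign != 0L, , drop = FALSE])
}

#' Restrict a network to pharmacological (on-target) edges
#'
#' @param net A [signed_dtn()].
#' @return A `signed_dtn` containing only edges flagged pharmacological;
#'   isolated nodes dropped.
#' @export
restrict_to_pharmacological <- function(net) {
  stopifnot(inherits(net, "signed_dtn"))
  signed_dtn(net$edges[net$edges$pharmacological, , drop = FALSE])
}

#' Summarize a network's node and edge counts
#'
#' @param net A [signed_dtn()].
#' @return A one-row data.frame of class `dtn_summary` with columns
#'   `n_drugs`, `n_targets`, `n_edges`, `n_positive`, `n_negative`,
#'   `n_unsigned`, `n_pharmacological`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "signed_dtn"))
  e <- net$edges
  out <- data.frame(
    n_drugs = length(net$drugs),
    n_targets = length(net$targets),
    n_edges = nrow(e),
    n_positive = sum(e$sign == 1L),
    n_negative = sum(e$sign == -1L),
    n_unsigned = sum(e$sign == 0L),
    n_pharmacological = sum(e$pharmacological)
  )
  class(out) <- c("dtn_summary", "data.frame")
  out
}

#' Per-node degree and sign profile
#'
#' One row per node with total, positive and negative incident edge counts;
#' `n_total - n_positive - n_negative` is the number of unsigned edges.
#' Sorting by `n_total` descending reproduces connectivity-ranking views of
#' the network (hubs first).
#'
#' @param net A [signed_dtn()].
#' @return A data.frame with columns `node_id`, `side` ("drug"/"target"),
#'   `n_total`, `n_positive`, `n_negative`, sorted by side then decreasing
#'   `n_total`.
#' @export
degree_profiles <- function(net) {
  stopifnot(inherits(net, "signed_dtn"))
  e <- net$edges
  one_side <- function(ids, col, side) {
    if (!length(ids)) {
      return(data.frame(node_id = character(), side = character(),
                        n_total = integer(), n_positive = integer(),
                        n_negative = integer()))
    }
    f <- factor(e[[col]], levels = ids)
    out <- data.frame(
      node_id = ids,
      side = side,
      n_total = as.integer(table(f)),
      n_positive = as.integer(tapply(e$sign == 1L, f, sum, default = 0L)),
      n_negative = as.integer(tapply(e$sign == -1L, f, sum, default = 0L))
    )
    out[order(-out$n_total, out$node_id), ]
  }
  out <- rbind(one_side(net$drugs, "drug", "drug"),
               one_side(net$targets, "target", "target"))
  rownames(out) <- NULL
  out
}

#' Connected components of the bipartite graph
#'
#' @param net A [signed_dtn()].
#' @return A data.frame, one row per component sorted by size descending:
#'   `component` (1-based rank), `n_nodes`, `n_drugs`, `n_targets`,
#'   `drug_fraction`, `target_fraction` (fractions over the whole network),
#'   and `members` (list-column of node ids).
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "signed_dtn"))
  empty <- data.frame(component = integer(), n_nodes = integer(),
                      n_drugs = integer(), n_targets = integer(),
                      drug_fraction = numeric(), target_fraction = numeric())
  if (!length(net$drugs) && !length(net$targets)) {
    empty$members <- list()
    return(empty)
  }
  g <- igraph::graph_from_data_frame(
    net$edges[, c("drug", "target")], directed = FALSE,
    vertices = data.frame(name = c(net$drugs, net$targets))
  )
  comp <- igraph::components(g)
  member_split <- split(names(comp$membership), comp$membership)
  n_drugs <- vapply(member_split, function(m) sum(m %in% net$drugs), 0L)
  n_targets <- vapply(member_split, function(m) sum(m %in% net$targets), 0L)
  ord <- order(-(n_drugs + n_targets))
  out <- data.frame(
    component = seq_along(ord),
    n_nodes = (n_drugs + n_targets)[ord],
    n_drugs = n_drugs[ord],
    n_targets = n_targets[ord],
    drug_fraction = if (length(net$drugs)) n_drugs[ord] / length(net$drugs) else 0,
    target_fraction = if (length(net$targets)) n_targets[ord] / length(net$targets) else 0
  )
  out$members <- unname(member_split[ord])
  rownames(out) <- NULL
  out
}
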