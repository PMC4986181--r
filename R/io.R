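#' Load a signed drug-target network from a tab-separated edge list
#'
#' The file must have header columns `drug_id`, `target_id`, `action`,
#' `pharmacological`, one row per recorded action. `pharmacological` takes
#' values `yes`, `no` or `unknown`; `unknown` is treated as `no` (an action
#' not known to be the intended one is an off-target action).
#'
#' Several rows for one (drug, target) pair are collapsed to a single edge:
#' if all signable action labels agree in sign the edge takes that sign; if
#' signable labels conflict the edge gets sign 0 and is flagged
#' `conflicting`; the pharmacological flag is the OR over the rows.
#'
#' @param path Path to the edge-list file.
#' @param vocab A [moa_vocabulary()] used to sign the action labels.
#' @return A [signed_dtn()]. The attribute `"load_report"` holds a list with
#'   `rows_read`, `rows_collapsed` (rows merged away by the collapse rule),
#'   `unknown_labels` (labels in no vocabulary class) and `n_conflicting`.
#' @export
load_edge_list <- function(path, vocab = moa_vocabulary()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("drug_id", "target_id", "action", "pharmacological")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("edge list lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(tab)) stop("edge list is empty: ", path)

  both <- intersect(unique(tab$drug_id), unique(tab$target_id))
  if (length(both)) {
    row <- which(tab$drug_id %in% both | tab$target_id %in% both)[1]
    stop("identifier used as both drug and target (first offending row ",
         row, "): ", both[1])
  }

  lab <- normalize_label(tab$action)
  known <- lab %in% c(vocab$positive, vocab$negative, vocab$unclassifiable)
  unknown_labels <- sort(unique(lab[!known]))
  row_sign <- assign_sign(tab$action, vocab, warn_unknown = FALSE)
  row_pharm <- normalize_label(tab$pharmacological) == "yes"

  key <- paste(tab$drug_id, tab$target_id, sep = "\r")
  grp <- factor(key, levels = unique(key))
  collapse_sign <- function(s) {
    s <- unique(s[s != 0L])
    if (length(s) == 1L) s else 0L        # no signable label, or conflict
  }
  sign <- as.integer(tapply(row_sign, grp, collapse_sign))
  conflicting <- as.logical(tapply(row_sign, grp, function(s) {
    length(unique(s[s != 0L])) > 1L
  }))
  pharm <- as.logical(tapply(row_pharm, grp, any))
  first <- !duplicated(key)

  edges <- data.frame(
    drug = tab$drug_id[first],
    target = tab$target_id[first],
    sign = sign,
    pharmacological = pharm,
    conflicting = conflicting,
    stringsAsFactors = FALSE
  )
  net <- signed_dtn(edges)
  if (length(unknown_labels)) {
    warning("unknown action label(s) mapped to sign 0: ",
            paste(unknown_labels, collapse = ", "))
  }
  attr(net, "load_report") <- list(
    rows_read = nrow(tab),
    rows_collapsed = nrow(tab) - nrow(edges),
    unknown_labels = unknown_labels,
    n_conflicting = sum(conflicting)
  )
  net
}

#' Write a network as a tab-separated edge list
#'
#' Inverse of [load_edge_list()] for collapsed networks: each edge becomes
#' one row whose `action` column is a synthetic label carrying the sign
#' ("activator" for +1, "inhibitor" for -1, "binder" for 0), so that
#' reloading with the default vocabulary reproduces the network's signs.
#' Edges flagged `conflicting` are written as two rows ("activator" and
#' "inhibitor") so the conflict survives the round trip.
#'
#' @param net A [signed_dtn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "signed_dtn"))
  e <- net$edges
  action <- c("inhibitor", "binder", "activator")[e$sign + 2L]
  tab <- data.frame(
    drug_id = e$drug, target_id = e$target, action = action,
    pharmacological = ifelse(e$pharmacological, "yes", "no"),
    stringsAsFactors = FALSE
  )
  if (any(e$conflicting)) {
    ix <- which(e$conflicting)
    tab$action[ix] <- "activator"
    extra <- tab[ix, ]
    extra$action <- "inhibitor"
    tab <- rbind(tab, extra)
    tab <- tab[order(match(paste(tab$drug_id, tab$target_id),
                           paste(e$drug, e$target))), ]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a network summary
#'
#' @param s A summary from [summarize_network()].
#' @param path Optional path; when given, JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
summary_to_json <- function(s, path = NULL) {
  stopifnot(inherits(s, "dtn_summary"))
  json <- jsonlite::toJSON(as.list(s), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Format a network summary as an aligned text table
#'
#' @param s A summary from [summarize_network()].
#' @return Character vector of lines.
#' @export
format_summary_table <- function(s) {
  stopifnot(inherits(s, "dtn_summary"))
  labels <- c("n. of drugs", "n. of targets", "total number of edges",
              "n. of positive edges", "n. of negative edges",
              "n. of edges without sign", "n. of pharmacological edges")
  values <- c(s$n_drugs, s$n_targets, s$n_edges, s$n_positive, s$n_negative,
              s$n_unsigned, s$n_pharmacological)
  sprintf("%-28s %8d", labels, values)
}
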