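#' Mode-of-action sign vocabulary
#'
#' A vocabulary maps mode-of-action labels (as recorded in drug-target
#' databases: "agonist", "inhibitor", "blocker", ...) to one of three sign
#' classes: positive (+1), negative (-1) or unclassifiable (0). The default
#' vocabulary ships with the package and covers the 36 labels commonly used
#' for human drug-target actions: 8 positive, 12 negative and 16 that cannot
#' be assigned a direction (e.g. "binder", "modulator", "antibody").
#'
#' Matching is case-insensitive with internal whitespace collapsed, so
#' "Partial agonist" and "partial  agonist" are the same label. Labels that
#' contain commas ("inhibitor, competitive") are matched on the full string.
#'
#' @param positive,negative,unclassifiable Character vectors of labels. The
#'   three sets must be pairwise disjoint.
#' @return An object of class `moa_vocabulary`: a list with elements
#'   `positive`, `negative`, `unclassifiable` (normalized label sets).
#' @examples
#' v <- moa_vocabulary()
#' assign_sign("agonist", v)   # +1
#' assign_sign("blocker", v)   # -1
#' assign_sign("modulator", v) #  0
#' @export
moa_vocabulary <- function(positive = .default_positive_labels,
                           negative = .default_negative_labels,
                           unclassifiable = .default_unclassifiable_labels) {
  pos <- normalize_label(positive)
  neg <- normalize_label(negative)
  unc <- normalize_label(unclassifiable)
  if (anyDuplicated(c(pos, neg, unc))) {
    dup <- unique(c(pos, neg, unc)[duplicated(c(pos, neg, unc))])
    stop("vocabulary sign classes must be disjoint; duplicated label(s): ",
         paste(dup, collapse = ", "))
  }
  structure(list(positive = pos, negative = neg, unclassifiable = unc),
            class = "moa_vocabulary")
}

.default_positive_labels <- c(
  "agonist", "partial agonist", "activator", "stimulator", "inducer",
  "positive allosteric modulator", "potentiator", "positive modulator"
)

.default_negative_labels <- c(
  "inhibitor", "inhibitory allosteric modulator", "inhibitor, competitive",
  "antagonist", "partial antagonist", "negative modulator", "inverse agonist",
  "blocker", "suppressor", "desensitize the target", "neutralizer", "reducer"
)

.default_unclassifiable_labels <- c(
  "antibody", "cofactor", "modulator", "binder", "chaperone", "cleavage",
  "metabolizer", "ligand", "product of", "component of", "chelator",
  "cross-linking/alkylation", "intercalation", "adduct", "acetylation",
  "allosteric modulator"
)

#' Normalize an action label for vocabulary lookup
#'
#' Lowercases, trims, and collapses internal whitespace.
#'
#' @param x Character vector of labels.
#' @return Normalized character vector.
#' @keywords internal
normalize_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Map mode-of-action labels to edge signs
#'
#' @param label Character vector of action labels.
#' @param vocab A [moa_vocabulary()].
#' @param warn_unknown Warn (once per call, listing the labels) when a label
#'   is in none of the three classes. Unknown labels map to 0.
#' @return Integer vector of signs in `{+1, -1, 0}`.
#' @export
assign_sign <- function(label, vocab = moa_vocabulary(), warn_unknown = TRUE) {
  stopifnot(inherits(vocab, "moa_vocabulary"))
  lab <- normalize_label(label)
  sign <- integer(length(lab))
  sign[lab %in% vocab$positive] <- 1L
  sign[lab %in% vocab$negative] <- -1L
  known <- lab %in% c(vocab$positive, vocab$negative, vocab$unclassifiable)
  if (warn_unknown && any(!known)) {
    warning("unknown action label(s) mapped to sign 0: ",
            paste(unique(lab[!known]), collapse = ", "))
  }
  sign
}

#' Read a vocabulary from a tab-separated file
#'
#' Expects columns `label` and `sign_class` with `sign_class` in
#' `{positive, negative, unclassifiable}`.
#'
#' @param path File path.
#' @return A [moa_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "sign_class") %in% names(tab))) {
    stop("vocabulary file must have columns 'label' and 'sign_class'")
  }
  bad <- setdiff(unique(tab$sign_class),
                 c("positive", "negative", "unclassifiable"))
  if (length(bad)) {
    stop("invalid sign_class value(s): ", paste(bad, collapse = ", "))
  }
  moa_vocabulary(
    positive = tab$label[tab$sign_class == "positive"],
    negative = tab$label[tab$sign_class == "negative"],
    unclassifiable = tab$label[tab$sign_class == "unclassifiable"]
  )
}

#' Write a vocabulary to a tab-separated file
#'
#' @param vocab A [moa_vocabulary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "moa_vocabulary"))
  tab <- data.frame(
    label = c(vocab$positive, vocab$negative, vocab$unclassifiable),
    sign_class = rep(c("positive", "negative", "unclassifiable"),
                     times = lengths(vocab[c("positive", "negative",
                                             "unclassifiable")])),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.moa_vocabulary <- function(x, ...) {
  cat("Mode-of-action sign vocabulary\n")
  cat("  positive      :", length(x$positive), "labels\n")
  cat("  negative      :", length(x$negative), "labels\n")
  cat("  unclassifiable:", length(x$unclassifiable), "labels\n")
  invisible(x)
}
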