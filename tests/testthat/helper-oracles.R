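# Shared helpers: small random networks and independent brute-force oracles.

# Random signed bipartite network: distinct (drug, target) pairs drawn
# uniformly, signs +/-1, pharmacological flags Bernoulli(pharm_prob).
random_test_network <- function(n_drugs, n_targets, n_edges,
                                pharm_prob = 0.3, unsigned_prob = 0) {
  n_edges <- min(n_edges, n_drugs * n_targets)
  cells <- sample.int(n_drugs * n_targets, n_edges)
  sign <- sample(c(-1L, 1L), n_edges, replace = TRUE)
  if (unsigned_prob > 0) {
    sign[runif(n_edges) < unsigned_prob] <- 0L
  }
  signed_dtn(data.frame(
    drug = sprintf("d%03d", (cells - 1L) %% n_drugs + 1L),
    target = sprintf("t%03d", (cells - 1L) %/% n_drugs + 1L),
    sign = sign,
    pharmacological = runif(n_edges) < pharm_prob,
    stringsAsFactors = FALSE
  ))
}

# Brute-force pair-overlap oracle: explicit loop over all drug pairs and all
# targets, consulting the edge list directly.
oracle_shared_pairs <- function(net) {
  e <- net$edges[net$edges$sign != 0L, , drop = FALSE]
  drugs <- sort(unique(e$drug))
  sgn <- function(d, t) {
    row <- e[e$drug == d & e$target == t, ]
    if (nrow(row)) row$sign else NA_integer_
  }
  ph <- function(d, t) {
    row <- e[e$drug == d & e$target == t, ]
    if (nrow(row)) row$pharmacological else NA
  }
  rows <- list()
  if (length(drugs) >= 2) {
    for (a in seq_len(length(drugs) - 1)) {
      for (b in seq(a + 1, length(drugs))) {
        di <- drugs[a]; dj <- drugs[b]
        c_cnt <- c(pp = 0L, mm = 0L, pm = 0L)
        p_cnt <- c(pp = 0L, mm = 0L, pm = 0L)
        for (t in unique(e$target)) {
          si <- sgn(di, t); sj <- sgn(dj, t)
          if (is.na(si) || is.na(sj)) next
          pat <- if (si == 1 && sj == 1) "pp" else
            if (si == -1 && sj == -1) "mm" else "pm"
          c_cnt[pat] <- c_cnt[pat] + 1L
          if (isTRUE(ph(di, t)) && isTRUE(ph(dj, t))) {
            p_cnt[pat] <- p_cnt[pat] + 1L
          }
        }
        if (sum(c_cnt) > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            drug_i = di, drug_j = dj,
            c_pp = c_cnt[["pp"]], c_mm = c_cnt[["mm"]], c_pm = c_cnt[["pm"]],
            p_pp = p_cnt[["pp"]], p_mm = p_cnt[["mm"]], p_pm = p_cnt[["pm"]],
            t_i = sum(e$drug == di), t_j = sum(e$drug == dj),
            p_i = sum(e$drug == di & e$pharmacological),
            p_j = sum(e$drug == dj & e$pharmacological),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$drug_i, out$drug_j), ]
}

# Brute-force 4-cycle oracle: loop over drug pairs x target pairs, classify
# each full square by direct sign comparison.
oracle_4cycle_counts <- function(net) {
  e <- net$edges[net$edges$sign != 0L, , drop = FALSE]
  drugs <- sort(unique(e$drug))
  targets <- sort(unique(e$target))
  lookup <- new.env()
  for (k in seq_len(nrow(e))) {
    assign(paste(e$drug[k], e$target[k]), e$sign[k], envir = lookup)
  }
  sgn <- function(d, t) {
    key <- paste(d, t)
    if (exists(key, envir = lookup)) get(key, envir = lookup) else NA_integer_
  }
  counts <- c("(+,+/+,+)" = 0, "(+,+/-,-)" = 0, "(-,-/-,-)" = 0,
              "(+,+/+,-)" = 0, "(+,-/-,-)" = 0, "(+,-/+,-)" = 0)
  lab <- function(a, b) {
    if (a == 1 && b == 1) "+,+" else if (a == -1 && b == -1) "-,-" else "+,-"
  }
  if (length(drugs) >= 2 && length(targets) >= 2) {
    for (a in seq_len(length(drugs) - 1)) for (b in seq(a + 1, length(drugs))) {
      for (u in seq_len(length(targets) - 1)) {
        for (v in seq(u + 1, length(targets))) {
          s <- c(sgn(drugs[a], targets[u]), sgn(drugs[b], targets[u]),
                 sgn(drugs[a], targets[v]), sgn(drugs[b], targets[v]))
          if (anyNA(s)) next
          la <- lab(s[1], s[2]); lb <- lab(s[3], s[4])
          key <- paste0("(", min(la, lb), "/", max(la, lb), ")")
          counts[key] <- counts[key] + 1
        }
      }
    }
  }
  counts
}

# Exact binomial upper tail by direct summation of choose() terms,
# independent of stats::pbinom.
oracle_upper_tail <- function(xi, n, p) {
  if (xi <= 0) return(1)
  sum(vapply(seq(xi, n), function(k) choose(n, k) * p^k * (1 - p)^(n - k), 0))
}
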