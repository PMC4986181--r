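#' Configuration for the synthetic network generator
#'
#' Defaults emulate the signed human drug-target network at its published
#' scale: 1315 drugs, 820 targets, 4128 signed edges of which about 65.7%
#' are negative, heavy-tailed degree distributions on both sides, strongly
#' monochromatic drugs (a drug's signed actions almost always share one
#' sign), and roughly a quarter of edges flagged pharmacological.
#'
#' @param n_drugs,n_targets,n_edges Network size. `n_edges` counts distinct
#'   (drug, target) pairs and must not exceed `n_drugs * n_targets`.
#' @param negative_fraction Probability that a signed edge is negative.
#' @param monochromaticity Probability that a drug is monochromatic, i.e.
#'   all its signed edges carry the drug's personal sign.
#' @param degree_exponent Exponent of the power-law propensity distribution
#'   used for both drug and target degrees (larger = lighter tail).
#' @param pharm_fraction Probability an edge is flagged pharmacological.
#' @param unsigned_fraction Probability an edge is unsigned (sign 0).
#' @return A list of class `dtn_generator_config`.
#' @export
generator_config <- function(n_drugs = 1315L,
                             n_targets = 820L,
                             n_edges = 4128L,
                             negative_fraction = 2711 / 4128,
                             monochromaticity = 0.9,
                             degree_exponent = 2.5,
                             pharm_fraction = 2916 / 11332,
                             unsigned_fraction = 0) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
              n_edges = as.integer(n_edges),
              negative_fraction = negative_fraction,
              monochromaticity = monochromaticity,
              degree_exponent = degree_exponent,
              pharm_fraction = pharm_fraction,
              unsigned_fraction = unsigned_fraction)
  probs <- c("negative_fraction", "monochromaticity", "pharm_fraction",
             "unsigned_fraction")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$degree_exponent <= 0) stop("degree_exponent must be positive")
  if (cfg$n_drugs < 1L || cfg$n_targets < 1L || cfg$n_edges < 0L) {
    stop("n_drugs, n_targets must be >= 1 and n_edges >= 0")
  }
  if (as.double(cfg$n_edges) > as.double(cfg$n_drugs) * cfg$n_targets) {
    stop("n_edges exceeds the number of distinct (drug, target) pairs")
  }
  class(cfg) <- "dtn_generator_config"
  cfg
}

# Discrete Pareto propensities: heavy-tailed with tail index (exponent - 1).
sample_propensity <- function(n, exponent) {
  ceiling(stats::runif(n)^(-1 / (exponent - 1)))
}

#' Generate a synthetic signed bipartite drug-target network
#'
#' Endpoint propensities for drugs and targets are drawn from a discrete
#' power law, then `n_edges` distinct (drug, target) pairs are sampled with
#' probability proportional to the product of the endpoint propensities
#' (duplicates rejected), producing heavy-tailed degree sequences with hubs
#' on both sides.
#'
#' Signs follow a two-level scheme: each drug draws a personal sign
#' (negative with probability `negative_fraction`); with probability
#' `monochromaticity` the drug is monochromatic and all its signed edges
#' take the personal sign, otherwise every edge draws its sign
#' independently. Either way the expected negative fraction among signed
#' edges equals `negative_fraction`. Each edge is unsigned with probability
#' `unsigned_fraction` and pharmacological with probability
#' `pharm_fraction`, independently.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed; identical (config, seed) gives an
#'   identical network.
#' @return A [signed_dtn()].
#' @export
generate_network <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "dtn_generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  nd <- config$n_drugs; nt <- config$n_targets; ne <- config$n_edges
  w_drug <- sample_propensity(nd, config$degree_exponent)
  w_target <- sample_propensity(nt, config$degree_exponent)

  # rejection-sample distinct pairs; over-draw in batches
  seen <- character(0)
  drug_ix <- integer(0); target_ix <- integer(0)
  while (length(seen) < ne) {
    need <- ne - length(seen)
    batch <- max(need * 2L, 64L)
    d <- sample.int(nd, batch, replace = TRUE, prob = w_drug)
    t <- sample.int(nt, batch, replace = TRUE, prob = w_target)
    key <- paste(d, t)
    fresh <- !duplicated(key) & !(key %in% seen)
    d <- d[fresh]; t <- t[fresh]; key <- key[fresh]
    take <- seq_len(min(need, length(key)))
    seen <- c(seen, key[take])
    drug_ix <- c(drug_ix, d[take]); target_ix <- c(target_ix, t[take])
  }

  drug_ids <- sprintf("D%04d", seq_len(nd))
  target_ids <- sprintf("T%04d", seq_len(nt))

  personal <- ifelse(stats::runif(nd) < config$negative_fraction, -1L, 1L)
  mono <- stats::runif(nd) < config$monochromaticity
  edge_sign <- ifelse(mono[drug_ix], personal[drug_ix],
                      ifelse(stats::runif(ne) < config$negative_fraction,
                             -1L, 1L))
  unsigned <- stats::runif(ne) < config$unsigned_fraction
  edge_sign[unsigned] <- 0L
  pharm <- stats::runif(ne) < config$pharm_fraction

  signed_dtn(
    data.frame(drug = drug_ids[drug_ix], target = target_ids[target_ix],
               sign = as.integer(edge_sign), pharmacological = pharm,
               stringsAsFactors = FALSE),
    drugs = drug_ids, targets = target_ids
  )
}

# Save/restore global RNG state so generator calls do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
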