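#' Run the full signed-network analysis pipeline
#'
#' Orchestrates the whole analysis over one input network: ingest (file,
#' generator or fixture), restriction to signed edges, network summaries,
#' degree profiles and connected components, pair overlap statistics,
#' coherence probability, per-pair binomial enrichment and the 2-D
#' coherence histogram, the null-model ensemble, length-4 cycle counts and
#' fractions, and the two drug-pair screens. All artifacts are written as
#' TSV/JSON under `output_dir` together with a run manifest, and returned
#' invisibly as a list.
#'
#' Exactly one of `input`, `config`, `fixture` must be given.
#'
#' @param input Path to an edge-list TSV (see [load_edge_list()]).
#' @param config A [generator_config()] for a synthetic network.
#' @param fixture A fixture name for [generate_fixture()].
#' @param output_dir Directory for the artifacts (created if missing);
#'   `NULL` skips writing.
#' @param alpha Per-pair enrichment significance threshold.
#' @param null_realizations Size of the null-model ensemble; 0 skips it.
#' @param seed Integer seed driving the generator and the null ensemble.
#' @param adjust Multiple-testing handling for enrichment calls
#'   (`"none"` or `"BH"`).
#' @param vocab Vocabulary used when `input` is a file.
#' @return (Invisibly) a list with elements `network`, `signed`, `summary`,
#'   `summary_signed`, `degrees`, `components`, `overlaps`, `coherence`,
#'   `enrichment`, `histogram`, `null_stats`, `cycles`, `cycle_fractions`,
#'   `synergy_screen`, `side_effect_screen`, `manifest`.
#' @export
run_pipeline <- function(input = NULL, config = NULL, fixture = NULL,
                         output_dir = NULL, alpha = 0.05,
                         null_realizations = 100L, seed = 1L,
                         adjust = c("none", "BH"),
                         vocab = moa_vocabulary()) {
  adjust <- match.arg(adjust)
  sources <- !c(is.null(input), is.null(config), is.null(fixture))
  if (sum(sources) != 1L) {
    stop("exactly one of 'input', 'config', 'fixture' must be given")
  }
  t0 <- Sys.time()
  net <- if (!is.null(input)) {
    load_edge_list(input, vocab)
  } else if (!is.null(config)) {
    generate_network(config, seed = seed)
  } else {
    generate_fixture(fixture)
  }

  signed <- restrict_to_signed(net)
  res <- list(
    network = net,
    signed = signed,
    summary = summarize_network(net),
    summary_signed = summarize_network(signed),
    degrees = degree_profiles(net),
    components = connected_components(signed)
  )
  res$overlaps <- enumerate_shared_pairs(signed)
  if (nrow(res$overlaps)) {
    res$coherence <- coherence_probability(res$overlaps)
    rho <- res$coherence$rho
    if (rho > 0 && rho < 1) {
      res$enrichment <- binomial_enrichment(res$overlaps, rho, alpha,
                                            adjust = adjust)
      res$histogram <- coherence_histogram(res$overlaps, rho, alpha)
    }
  }
  if (null_realizations > 0L && nrow(signed$edges)) {
    res$null_stats <- null_ensemble_stats(signed, null_realizations, seed)
  }
  res$cycles <- enumerate_4cycles(signed)
  if (sum(res$cycles$n) >= 1) {
    res$cycle_fractions <- cycle_fractions(res$cycles)
  }
  res$synergy_screen <- screen_synergy(signed)
  res$side_effect_screen <- screen_side_effect(signed)

  res$manifest <- list(
    input = if (!is.null(input)) input else if (!is.null(fixture))
      paste0("fixture:", fixture) else "generator",
    config = if (!is.null(config)) unclass(config) else NULL,
    alpha = alpha, null_realizations = null_realizations, seed = seed,
    adjust = adjust,
    package_version = as.character(utils::packageVersion("sdtnet")),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(output_dir)) write_pipeline_artifacts(res, output_dir)
  invisible(res)
}

write_tsv <- function(x, path) {
  drop <- vapply(x, is.list, TRUE)
  utils::write.table(x[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Write the pipeline artifacts of a [run_pipeline()] result
#'
#' @param res A pipeline result list.
#' @param output_dir Directory (created if missing).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  summary_to_json(res$summary, p("summary.json"))
  summary_to_json(res$summary_signed, p("summary_signed.json"))
  writeLines(format_summary_table(res$summary_signed), p("summary_signed.txt"))
  write_tsv(res$degrees, p("degree_profiles.tsv"))
  write_tsv(res$components, p("components.tsv"))
  write_tsv(res$overlaps, p("pair_overlaps.tsv"))
  if (!is.null(res$coherence)) {
    jsonlite::write_json(unclass(res$coherence), p("coherence.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$enrichment)) write_tsv(res$enrichment, p("enrichment.tsv"))
  if (!is.null(res$histogram)) {
    write_tsv(res$histogram, p("coherence_histogram.tsv"))
  }
  if (!is.null(res$null_stats)) {
    jsonlite::write_json(
      res$null_stats[c("n_realizations", "mean_pairs_sharing_target",
                       "mean_total_pairwise_actions",
                       "mean_coherent_fraction")],
      p("null_ensemble.json"), auto_unbox = TRUE, digits = NA)
    write_tsv(res$null_stats$per_realization, p("null_realizations.tsv"))
  }
  write_tsv(res$cycles, p("cycle_counts.tsv"))
  if (!is.null(res$cycle_fractions)) {
    jsonlite::write_json(res$cycle_fractions, p("cycle_fractions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_tsv(res$synergy_screen$pairs, p("synergy_screen.tsv"))
  write_tsv(res$side_effect_screen$pairs, p("side_effect_screen.tsv"))
  jsonlite::write_json(
    list(synergy = as.list(res$synergy_screen$bucket_sizes),
         side_effect = as.list(res$side_effect_screen$bucket_sizes)),
    p("screen_buckets.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}
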