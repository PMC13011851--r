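#' Configuration for a full mining run
#'
#' Defaults follow the conventional thresholds of acupoint association-rule
#' mining: support >= 20%, confidence >= 80%, antecedents up to size 2, every
#' co-occurrence an edge (`min_weight = 1`), and a 1000-replicate random
#' baseline. The configuration is echoed verbatim into every report.
#'
#' @param input an [acu_corpus()], or a path to a corpus file
#' @param format corpus file format for path inputs (see [read_corpus()])
#' @param min_support,min_confidence,max_antecedent rule-mining thresholds
#' @param denominator_mode percent convention for the frequency table
#' @param min_weight edge-inclusion co-occurrence threshold
#' @param n_random random-graph replicates for the small-world baseline
#' @param seed RNG seed used by every stochastic stage
#' @param out_dir if non-NULL, stage artifacts are written here
#' @return list of class `mining_run_config`
#' @export
mining_run_config <- function(input,
                              format = "auto",
                              min_support = 0.20,
                              min_confidence = 0.80,
                              max_antecedent = 2L,
                              denominator_mode = "total_usages",
                              min_weight = 1L,
                              n_random = 1000L,
                              seed = 1L,
                              out_dir = NULL) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1,
            max_antecedent >= 1L, min_weight >= 1L, n_random >= 1L)
  structure(list(input = input, format = format,
                 min_support = min_support, min_confidence = min_confidence,
                 max_antecedent = as.integer(max_antecedent),
                 denominator_mode = denominator_mode,
                 min_weight = as.integer(min_weight),
                 n_random = as.integer(n_random),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "mining_run_config")
}

config_echo <- function(cfg) {
  cfg[c("min_support", "min_confidence", "max_antecedent", "denominator_mode",
        "min_weight", "n_random", "seed")]
}

#' Run the full prescription-mining pipeline
#'
#' Orchestrates corpus loading/validation, frequency analysis, Apriori
#' association-rule mining, co-prescription network construction, small-world
#' assessment, community detection, k-core decomposition, centrality analysis
#' and core-set selection as one reproducible run. Degenerate corpora (for
#' example a single one-point prescription) complete with warnings and empty
#' network results rather than failing. Each stage is logged via [message()].
#'
#' When `cfg$out_dir` is set, the stage artifacts are written there:
#' `report.json`, `freq.csv`, `rules.csv`, `cooccurrence.tsv`,
#' `graph.graphml`, `graph.gexf`, `edges.tsv`, `centrality.csv`,
#' `coreset.csv` (+ `.meta.json` sidecar) and `layout.csv`.
#'
#' @param cfg a [mining_run_config()]
#' @return list of class `acu_run_report`; every number in it is regenerable
#'   from `(input, config, seed)` (the `timestamp` field aside)
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "mining_run_config"))
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  corpus <- stage("corpus", {
    x <- if (inherits(cfg$input, "acu_corpus")) cfg$input
         else read_corpus(cfg$input, cfg$format)
    viol <- validate_corpus(x)
    if (nrow(viol) > 0L)
      stop("corpus fails validation: ", paste(unique(viol$reason), collapse = "; "))
    x
  })
  message(sprintf("[corpus] %d prescriptions, %d acupoints",
                  n_transactions(corpus), length(corpus_vocabulary(corpus))))

  freq <- stage("frequency", frequency_table(corpus, cfg$denominator_mode))
  rules <- stage("rules", association_rules(corpus, cfg$min_support,
                                            cfg$min_confidence, cfg$max_antecedent))
  if (nrow(rules) == 0L) warning("no association rules pass the thresholds")
  cooc <- stage("cooccurrence", cooccurrence_matrix(corpus))

  graph <- tryCatch(
    stage("network", suppressMessages(build_graph(cooc, cfg$min_weight))),
    error = function(e) { warning(conditionMessage(e)); NULL })

  sw <- cores <- comm <- cent <- core_set <- layout <- NULL
  if (!is.null(graph)) {
    sw <- stage("small_world", small_world_report(graph, cfg$n_random, cfg$seed))
    cores <- stage("kcore", kcore_decomposition(graph))
    comm <- stage("communities", detect_communities(graph, seed = cfg$seed))
    cent <- stage("centrality", centrality_table(graph))
    core_set <- stage("core_select",
                      select_core(cent, cores = cores, freq = freq,
                                  rules = rules, top_n = 2L))
    layout <- stage("layout", fr_layout(graph, iterations = 200L, seed = cfg$seed))
  } else {
    warning("network stages skipped: graph is empty at min_weight = ", cfg$min_weight)
  }

  report <- structure(list(
    corpus_summary = list(n_transactions = n_transactions(corpus),
                          vocabulary_size = length(corpus_vocabulary(corpus)),
                          total_usages = sum(lengths(corpus$items))),
    frequency = freq,
    rules = format_rules(rules),
    graph_summary = if (is.null(graph)) NULL else
      list(n_nodes = length(graph$nodes), n_edges = length(graph$from),
           total_edge_weight = sum(graph$weight)),
    small_world = if (is.null(sw)) NULL else unclass(sw),
    kcore = if (is.null(cores)) NULL else
      list(k_max = cores$k_max, core_set = cores$core_set,
           coreness = as.list(cores$coreness)),
    communities = if (is.null(comm)) NULL else
      list(n_communities = comm$n_communities, modularity = comm$modularity,
           assignment = as.list(comm$assignment)),
    core_set = if (is.null(core_set)) NULL else as.data.frame(core_set),
    core_combination = if (is.null(core_set)) NULL else
      attr(core_set, "core_combination"),
    config = config_echo(cfg),
    tool_version = as.character(utils::packageVersion("acumine")),
    schema_version = "1.0",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "acu_run_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    jsonlite::write_json(unclass(report), p("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(freq, p("freq.csv"), row.names = FALSE)
    utils::write.csv(format_rules(rules), p("rules.csv"), row.names = FALSE)
    write_cooccurrence(cooc, p("cooccurrence.tsv"))
    if (!is.null(graph)) {
      attrs <- merge(cent, data.frame(node = names(cores$coreness),
                                      coreness = as.integer(cores$coreness),
                                      community = as.integer(comm$assignment)),
                     by = "node")
      write_graphml(graph, p("graph.graphml"), node_attrs = attrs)
      write_gexf(graph, p("graph.gexf"), node_attrs = attrs)
      write_edgelist(graph, p("edges.tsv"))
      utils::write.csv(cent, p("centrality.csv"), row.names = FALSE)
      write_core_set(core_set, p("coreset.csv"))
      utils::write.csv(layout, p("layout.csv"), row.names = FALSE)
    }
    message("[artifacts] written to ", cfg$out_dir)
  }
  report
}

#' @export
print.acu_run_report <- function(x, ...) {
  cat("<acu_run_report>\n")
  cat(sprintf("  corpus: %d prescriptions, %d acupoints, %d usages\n",
              x$corpus_summary$n_transactions, x$corpus_summary$vocabulary_size,
              x$corpus_summary$total_usages))
  cat(sprintf("  rules passing thresholds: %d\n", nrow(x$rules)))
  if (!is.null(x$graph_summary))
    cat(sprintf("  network: %d nodes / %d edges; k_max = %d; %d communities\n",
                x$graph_summary$n_nodes, x$graph_summary$n_edges,
                x$kcore$k_max, x$communities$n_communities))
  if (!is.null(x$core_combination))
    cat("  core combination:", paste(x$core_combination, collapse = " + "), "\n")
  invisible(x)
}
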