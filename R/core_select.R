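#' Rank nodes by a single centrality metric
#'
#' @param cent data.frame with a `node` column and centrality columns (e.g.
#'   [centrality_table()] output or the `"centrality"` fixture with its `code`
#'   column)
#' @param metric one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"eigenvector"`
#' @return character vector of node codes, descending by the metric with
#'   lexicographic tie-break
#' @export
centrality_rank <- function(cent, metric = c("degree", "betweenness",
                                             "closeness", "eigenvector")) {
  metric <- match.arg(metric)
  node_col <- if ("node" %in% names(cent)) "node" else "code"
  if (!metric %in% names(cent)) stop("metric column missing: ", metric)
  cent[[node_col]][order(-cent[[metric]], cent[[node_col]])]
}

#' Select the core acupoint set
#'
#' Integrates the network evidence into a ranked core set. Default rule:
#' members are the maximum-k-core nodes (all nodes when no decomposition is
#' supplied), ranked by degree descending, ties broken by betweenness (rounded
#' to 1e-9 so exactly-tied hubs are not ordered by floating-point noise), then
#' by prescription frequency, closeness, eigenvector, and finally code. The
#' top `top_n` members form the reported "core combination" (the headline
#' point pair when `top_n = 2`).
#'
#' @param cent centrality data.frame ([centrality_table()] output or the
#'   centrality fixture)
#' @param cores optional [kcore_decomposition()] result restricting membership
#'   to the maximum core
#' @param freq optional [frequency_table()] output contributing the frequency
#'   score component
#' @param rules optional [association_rules()] output, echoed into the
#'   selection metadata (rules whose items all sit in the core set)
#' @param top_n size of the reported core combination (default 2)
#' @return data.frame of class `acu_core_set`, ranked, with score-component
#'   columns and attributes `core_combination` and `selection_rule`
#' @export
select_core <- function(cent, cores = NULL, freq = NULL, rules = NULL, top_n = 2L) {
  node_col <- if ("node" %in% names(cent)) "node" else "code"
  df <- data.frame(node = cent[[node_col]],
                   degree = cent$degree,
                   betweenness = cent$betweenness,
                   closeness = if ("closeness" %in% names(cent)) cent$closeness else NA_real_,
                   eigenvector = if ("eigenvector" %in% names(cent)) cent$eigenvector else NA_real_,
                   stringsAsFactors = FALSE)
  df$frequency <- if (is.null(freq)) 0L else {
    fc <- freq$count[match(df$node, freq$code)]
    ifelse(is.na(fc), 0L, fc)
  }
  if (!is.null(cores)) {
    if (length(cores$core_set) == 0L) stop("empty maximum core")
    df$in_max_core <- df$node %in% cores$core_set
    df <- df[df$in_max_core, , drop = FALSE]
    rule <- sprintf("max k-core (k = %d) ranked by degree", cores$k_max)
  } else {
    df$in_max_core <- NA
    rule <- "all nodes ranked by degree"
  }
  if (nrow(df) == 0L) stop("empty core set")
  bt <- round(df$betweenness, 9)
  cl <- round(ifelse(is.na(df$closeness), 0, df$closeness), 9)
  ev <- round(ifelse(is.na(df$eigenvector), 0, df$eigenvector), 9)
  o <- order(-df$degree, -bt, -df$frequency, -cl, -ev, df$node)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "core_combination") <- utils::head(df$node, top_n)
  attr(df, "selection_rule") <- rule
  if (!is.null(rules) && nrow(rules) > 0L) {
    inside <- vapply(seq_len(nrow(rules)), function(i)
      all(c(rules$antecedent_items[[i]], rules$consequent[i]) %in% df$node), TRUE)
    attr(df, "n_rules_within_core") <- sum(inside)
  }
  class(df) <- c("acu_core_set", "data.frame")
  df
}

#' @export
print.acu_core_set <- function(x, ...) {
  cat(sprintf("<acu_core_set> %d member(s); %s\n", nrow(x), attr(x, "selection_rule")))
  cat("core combination:", paste(attr(x, "core_combination"), collapse = " + "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a core set with its selection metadata
#'
#' CSV mirroring the centrality-table layout plus a JSON sidecar
#' (`<path>.meta.json`) recording the selection rule and core combination.
#' @param core_set an `acu_core_set`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_core_set <- function(core_set, path) {
  utils::write.csv(as.data.frame(core_set), path, row.names = FALSE)
  jsonlite::write_json(
    list(selection_rule = attr(core_set, "selection_rule"),
         core_combination = attr(core_set, "core_combination")),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
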