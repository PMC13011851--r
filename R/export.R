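xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# node_attrs: data.frame keyed by column `node`, or NULL.
node_attr_frame <- function(g, node_attrs) {
  if (is.null(node_attrs)) return(data.frame(node = g$nodes, stringsAsFactors = FALSE))
  stopifnot("node" %in% names(node_attrs))
  node_attrs[match(g$nodes, node_attrs$node), , drop = FALSE]
}

#' Export a graph as GraphML
#'
#' Writes node attributes (any extra columns of `node_attrs`) and the edge
#' `weight` attribute.
#' @param g an `acu_graph`
#' @param path output file
#' @param node_attrs optional data.frame with a `node` column plus attribute
#'   columns (e.g. the output of [centrality_table()])
#' @return `path`, invisibly
#' @export
write_graphml <- function(g, path, node_attrs = NULL) {
  na <- node_attr_frame(g, node_attrs)
  attr_cols <- setdiff(names(na), "node")
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  for (i in seq_along(attr_cols)) {
    type <- if (is.numeric(na[[attr_cols[i]]])) "double" else "string"
    w('  <key id="n%d" for="node" attr.name="%s" attr.type="%s"/>',
      i, xml_escape(attr_cols[i]), type)
  }
  w('  <key id="w" for="edge" attr.name="weight" attr.type="double"/>')
  w('  <graph edgedefault="undirected">')
  for (v in seq_along(g$nodes)) {
    w('    <node id="%s">', xml_escape(g$nodes[v]))
    for (i in seq_along(attr_cols))
      w('      <data key="n%d">%s</data>', i, xml_escape(format(na[[attr_cols[i]]][v])))
    w('    </node>')
  }
  for (e in seq_along(g$from)) {
    w('    <edge source="%s" target="%s">', xml_escape(g$nodes[g$from[e]]),
      xml_escape(g$nodes[g$to[e]]))
    w('      <data key="w">%s</data>', format(g$weight[e]))
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Export a graph as GEXF
#'
#' Minimal GEXF 1.3 with node attvalues and weighted undirected edges.
#' @inheritParams write_graphml
#' @return `path`, invisibly
#' @export
write_gexf <- function(g, path, node_attrs = NULL) {
  na <- node_attr_frame(g, node_attrs)
  attr_cols <- setdiff(names(na), "node")
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://gexf.net/1.3" version="1.3">')
  w('  <graph defaultedgetype="undirected">')
  if (length(attr_cols) > 0L) {
    w('    <attributes class="node">')
    for (i in seq_along(attr_cols)) {
      type <- if (is.numeric(na[[attr_cols[i]]])) "double" else "string"
      w('      <attribute id="%d" title="%s" type="%s"/>', i - 1L,
        xml_escape(attr_cols[i]), type)
    }
    w('    </attributes>')
  }
  w('    <nodes>')
  for (v in seq_along(g$nodes)) {
    if (length(attr_cols) == 0L) {
      w('      <node id="%s" label="%s"/>', xml_escape(g$nodes[v]), xml_escape(g$nodes[v]))
    } else {
      w('      <node id="%s" label="%s">', xml_escape(g$nodes[v]), xml_escape(g$nodes[v]))
      w('        <attvalues>')
      for (i in seq_along(attr_cols))
        w('          <attvalue for="%d" value="%s"/>', i - 1L,
          xml_escape(format(na[[attr_cols[i]]][v])))
      w('        </attvalues>')
      w('      </node>')
    }
  }
  w('    </nodes>')
  w('    <edges>')
  for (e in seq_along(g$from))
    w('      <edge id="%d" source="%s" target="%s" weight="%s"/>', e - 1L,
      xml_escape(g$nodes[g$from[e]]), xml_escape(g$nodes[g$to[e]]), format(g$weight[e]))
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}

#' Export a graph as an edge-list TSV
#' @param g an `acu_graph`
#' @param path output TSV with columns `from`, `to`, `weight`
#' @return `path`, invisibly
#' @export
write_edgelist <- function(g, path) {
  utils::write.table(
    data.frame(from = g$nodes[g$from], to = g$nodes[g$to], weight = g$weight),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
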