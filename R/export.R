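# Network export for visualisation tools (Gephi-compatible GEXF 1.2,
# GraphML, and plain node/edge TSV). All formats round-trip through the
# matching reader.

#' Export the merged network
#'
#' Writes node and edge tables with their attributes (fragment coordinates,
#' condition specificity, per-condition scores, and any annotation columns
#' previously joined onto `net$nodes`), optionally with layout coordinates.
#'
#' @param net `canvas_network`.
#' @param path output file (for `tsv`, the prefix: `<path>_nodes.tsv` and
#'   `<path>_edges.tsv`).
#' @param format `"gexf"`, `"graphml"` or `"tsv"`.
#' @param layout optional `canvas_layout` whose x/y are embedded.
#' @param annotations optional tibble keyed by `fragment_id` joined onto the
#'   node table before writing.
#' @return `path`, invisibly.
#' @export
write_network_export <- function(net, path, format = c("gexf", "graphml", "tsv"),
                                 layout = NULL, annotations = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(sprintf("unknown format '%s'",
                                                       format[1])))
  nodes <- net$nodes
  if (!is.null(annotations)) {
    nodes <- nodes |> left_join(annotations, by = "fragment_id")
  }
  if (!is.null(layout)) {
    nodes <- nodes |>
      left_join(tibble(fragment_id = layout$node, x = layout$x, y = layout$y),
                by = "fragment_id")
  }
  edges <- net$edges
  switch(format,
    tsv = {
      write_tsv_plain(nodes, paste0(path, "_nodes.tsv"))
      write_tsv_plain(edges, paste0(path, "_edges.tsv"))
    },
    graphml = write_graphml(nodes, edges, path),
    gexf = write_gexf(nodes, edges, path)
  )
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path file (or TSV prefix) produced by [write_network_export()].
#' @param format `"gexf"`, `"graphml"` or `"tsv"`.
#' @return List with `nodes` and `edges` tibbles.
#' @export
read_network_export <- function(path, format = c("gexf", "graphml", "tsv")) {
  format <- match.arg(format)
  switch(format,
    tsv = list(
      nodes = as_tibble(utils::read.delim(paste0(path, "_nodes.tsv"),
                                          stringsAsFactors = FALSE)),
      edges = as_tibble(utils::read.delim(paste0(path, "_edges.tsv"),
                                          stringsAsFactors = FALSE))
    ),
    graphml = read_graphml(path),
    gexf = read_gexf(path)
  )
}

# -- GraphML ------------------------------------------------------------------

#' @noRd
write_graphml <- function(nodes, edges, path) {
  g <- igraph::graph_from_data_frame(
    d = edges |> rename(from = "node1", to = "node2"),
    directed = FALSE,
    vertices = nodes |> relocate("fragment_id")
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @noRd
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vattrs <- igraph::vertex_attr(g)
  vattrs$id <- NULL
  nodes <- as_tibble(vattrs) |> rename(fragment_id = "name")
  el <- igraph::as_edgelist(g)
  edges <- as_tibble(igraph::edge_attr(g)) |>
    mutate(node1 = el[, 1], node2 = el[, 2]) |>
    relocate("node1", "node2")
  list(nodes = nodes, edges = edges)
}

# -- GEXF 1.2 -----------------------------------------------------------------

#' @noRd
gexf_type <- function(v) {
  if (is.logical(v)) "boolean"
  else if (is.integer(v)) "integer"
  else if (is.numeric(v)) "double"
  else "string"
}

#' @noRd
write_gexf <- function(nodes, edges, path) {
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  node_attr_cols <- setdiff(names(nodes), "fragment_id")
  edge_attr_cols <- setdiff(names(edges), c("node1", "node2"))
  add_attr_decls <- function(parent, cols, tbl, class) {
    decl <- xml2::xml_add_child(parent, "attributes", class = class)
    for (k in seq_along(cols)) {
      xml2::xml_add_child(decl, "attribute", id = as.character(k - 1),
                          title = cols[k], type = gexf_type(tbl[[cols[k]]]))
    }
  }
  add_attr_decls(graph, node_attr_cols, nodes, "node")
  add_attr_decls(graph, edge_attr_cols, edges, "edge")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nodes_el, "node", id = nodes$fragment_id[i],
                              label = nodes$fragment_id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (k in seq_along(node_attr_cols)) {
      val <- nodes[[node_attr_cols[k]]][i]
      if (!is.na(val)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(k - 1),
                            value = format(val, scientific = FALSE, trim = TRUE))
      }
    }
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1),
                              source = edges$node1[i], target = edges$node2[i])
    av <- xml2::xml_add_child(ed, "attvalues")
    for (k in seq_along(edge_attr_cols)) {
      val <- edges[[edge_attr_cols[k]]][i]
      if (!is.na(val)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(k - 1),
                            value = format(val, scientific = FALSE, trim = TRUE))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @noRd
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  parse_decls <- function(class) {
    decls <- xml2::xml_find_all(
      doc, sprintf(".//attributes[@class='%s']/attribute", class))
    tibble(id = xml2::xml_attr(decls, "id"),
           title = xml2::xml_attr(decls, "title"),
           type = xml2::xml_attr(decls, "type"))
  }
  cast <- function(v, type) {
    switch(type,
           integer = as.integer(v),
           double = as.numeric(v),
           boolean = as.logical(v),
           v)
  }
  collect <- function(xp, decls, base) {
    items <- xml2::xml_find_all(doc, xp)
    out <- base(items)
    for (r in seq_len(nrow(decls))) {
      vals <- vapply(items, function(it) {
        v <- xml2::xml_find_first(
          it, sprintf("./attvalues/attvalue[@for='%s']", decls$id[r]))
        if (inherits(v, "xml_missing")) NA_character_
        else xml2::xml_attr(v, "value")
      }, character(1))
      out[[decls$title[r]]] <- cast(vals, decls$type[r])
    }
    out
  }
  nodes <- collect(".//nodes/node", parse_decls("node"),
                   function(it) tibble(fragment_id = xml2::xml_attr(it, "id")))
  edges <- collect(".//edges/edge", parse_decls("edge"),
                   function(it) tibble(node1 = xml2::xml_attr(it, "source"),
                                       node2 = xml2::xml_attr(it, "target")))
  list(nodes = nodes, edges = edges)
}
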