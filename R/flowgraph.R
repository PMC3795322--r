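#' Build a family annotation flow graph
#'
#' The flow graph subsumes a family's annotations within one ontology
#' aspect.  Nodes are the terms annotating at least one family protein
#' after propagation; edges are the ontology edges between included terms,
#' oriented from generic parent to specific child -- the reverse of the
#' ontology's child-to-parent edges -- so that they depict proteins
#' "flowing down" toward more specific annotation.  Each edge carries the
#' child's protein count as weight.  By default transitively implied edges
#' (a parent-child edge whose terms are also connected through an included
#' intermediate) are omitted for a compact rendering.
#'
#' @param family A `protein_family`.
#' @param corpus A propagated `annotation_corpus`.
#' @param graph The `ontology_graph`.
#' @param aspect Aspect label.
#' @param relations Ontology relations drawn as edges.
#' @param reduce Omit transitively implied edges (default TRUE).
#' @return A `flow_graph`: list with `nodes` (data.frame: term, name,
#'   direct, count), `edges` (data.frame: parent, child, weight), `family`,
#'   `aspect` and `root`.
#' @export
build_flow_graph <- function(family, corpus, graph,
                             aspect = "molecular_function",
                             relations = "is_a", reduce = TRUE) {
  freqs <- family_frequencies(family, corpus, aspect = aspect)
  nodes <- data.frame(term = freqs$term,
                      name = graph$terms$name[match(freqs$term, graph$terms$id)],
                      direct = freqs$direct, count = freqs$count,
                      stringsAsFactors = FALSE)
  included <- nodes$term
  # ontology edges among included terms, reoriented parent -> child
  edges <- do.call(rbind, lapply(included, function(t) {
    p <- graph$parents[[t]]
    if (is.null(p) || !nrow(p)) return(NULL)
    p <- p[p$relation %in% relations & p$parent %in% included, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    data.frame(parent = p$parent, child = t, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  if (reduce && nrow(edges)) {
    kids <- split(edges$child, edges$parent)
    reach <- function(from) {
      seen <- character(); frontier <- from
      while (length(frontier)) {
        step <- setdiff(unlist(kids[frontier], use.names = FALSE), seen)
        seen <- c(seen, step); frontier <- step
      }
      seen
    }
    redundant <- vapply(seq_len(nrow(edges)), function(i) {
      others <- setdiff(kids[[edges$parent[i]]], edges$child[i])
      length(others) > 0L && edges$child[i] %in% reach(others)
    }, TRUE)
    edges <- edges[!redundant, , drop = FALSE]
  }
  edges$weight <- nodes$count[match(edges$child, nodes$term)]
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  root <- intersect(unname(graph$roots), included)
  structure(list(nodes = nodes, edges = edges, family = family$name,
                 aspect = aspect,
                 root = if (length(root)) root[1L] else NA_character_),
            class = "flow_graph")
}

#' @export
print.flow_graph <- function(x, ...) {
  cat("<flow_graph> ", x$family, " (", x$aspect, "): ", nrow(x$nodes),
      " terms, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export a flow graph to DOT format
#'
#' Directly annotated terms are drawn as gray, name-labelled nodes;
#' inherited-only terms (including the aspect root) as unlabelled white
#' nodes.  Edge pen width is linearly proportional to the protein flow,
#' scaled so the thinnest edge has width 1.
#'
#' @param flow A `flow_graph`.
#' @param path Optional output path; when `NULL` the DOT text is returned.
#' @return The DOT text (a character scalar), invisibly when written to
#'   `path`.
#' @export
export_dot <- function(flow, path = NULL) {
  esc <- function(s) gsub('"', '\\\\"', s)
  lines <- c(sprintf("digraph \"%s\" {", esc(flow$family)),
             "  rankdir=TB;",
             "  node [shape=ellipse, style=filled];")
  n <- flow$nodes
  labelled <- n$direct & !(n$term %in% flow$root)
  lines <- c(lines, sprintf(
    "  \"%s\" [label=\"%s\", fillcolor=\"%s\"];",
    esc(n$term),
    ifelse(labelled, esc(ifelse(is.na(n$name), n$term, n$name)), ""),
    ifelse(labelled, "gray80", "white")))
  if (nrow(flow$edges)) {
    pen <- flow$edges$weight / min(flow$edges$weight)
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [penwidth=%.3f, label=\"%d\"];",
      esc(flow$edges$parent), esc(flow$edges$child), pen,
      flow$edges$weight))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
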