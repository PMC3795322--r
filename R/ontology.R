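#' Parse an OBO flat file into an ontology graph
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 file and builds a rooted
#' directed acyclic graph of terms.  Only the tags `id`, `name`, `namespace`,
#' `is_a`, `relationship`, `alt_id` and `is_obsolete` are interpreted;
#' unknown tags and non-`[Term]` stanzas are ignored.  `regulates`
#' relationships may be stored but are never traversed by default, since
#' they can cross ontology aspects while `is_a`/`part_of` hold within a
#' single aspect.
#'
#' Obsolete terms are kept in the term table but their parent edges are
#' discarded, so they never take part in traversal.
#'
#' @param x Path to an OBO file, a single string of OBO text, or a character
#'   vector of lines.
#' @param relations Character vector of relationship types to load as edges.
#' @return An object of class `ontology_graph`: a list with elements
#'   `terms` (data.frame: id, name, namespace, obsolete), `parents` and
#'   `children` (per-term edge tables with a `relation` column), `alt_map`
#'   (named character vector mapping alternate ids to primary ids) and
#'   `roots` (named character vector, one root id per namespace).
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root", "namespace: molecular_function",
#'          "", "[Term]", "id: T:2", "name: child",
#'          "namespace: molecular_function", "is_a: T:1 ! root")
#' g <- parse_obo(obo)
#' ancestors(g, "T:2")
#' @seealso [ancestors()], [descendants()], [write_obo()]
#' @export
parse_obo <- function(x, relations = c("is_a", "part_of", "regulates")) {
  lines <- .as_lines(x)
  lines <- sub("\\s+$", "", lines)
  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts))
    .stop_input("OBO parse error: no stanzas found")
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))
  ids <- character(); names_ <- character(); nss <- character()
  obs <- logical()
  parent_child <- character(); parent_id <- character(); parent_rel <- character()
  alt_from <- character(); alt_to <- character()
  for (s in seq_along(stanza_starts)) {
    if (lines[stanza_starts[s]] != "[Term]") next
    body <- lines[seq(stanza_starts[s] + 1L, stanza_ends[s])]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    tags <- sub(":.*$", "", body)
    vals <- sub("^[^:]+:\\s*", "", body)
    vals <- sub("\\s*!.*$", "", vals)  # trailing comments
    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id))
      .stop_input("OBO parse error: [Term] stanza at line ",
                  stanza_starts[s], " has no id")
    ids <- c(ids, id)
    nm <- vals[tags == "name"][1]
    names_ <- c(names_, if (is.na(nm)) id else nm)
    ns <- vals[tags == "namespace"][1]
    nss <- c(nss, if (is.na(ns)) NA_character_ else ns)
    ob <- identical(tolower(vals[tags == "is_obsolete"][1]), "true")
    obs <- c(obs, isTRUE(ob))
    isa <- vals[tags == "is_a"]
    if (length(isa)) {
      parent_child <- c(parent_child, rep(id, length(isa)))
      parent_id <- c(parent_id, isa)
      parent_rel <- c(parent_rel, rep("is_a", length(isa)))
    }
    rel <- vals[tags == "relationship"]
    if (length(rel)) {
      rel_type <- sub("\\s.*$", "", rel)
      rel_tgt <- sub("^\\S+\\s+", "", rel)
      parent_child <- c(parent_child, rep(id, length(rel)))
      parent_id <- c(parent_id, rel_tgt)
      parent_rel <- c(parent_rel, rel_type)
    }
    alt <- vals[tags == "alt_id"]
    if (length(alt)) {
      alt_from <- c(alt_from, alt)
      alt_to <- c(alt_to, rep(id, length(alt)))
    }
  }
  if (anyDuplicated(ids))
    .stop_input("OBO parse error: duplicated term id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  terms <- data.frame(id = ids, name = names_, namespace = nss,
                      obsolete = obs, stringsAsFactors = FALSE)
  edges <- data.frame(child = parent_child, parent = parent_id,
                      relation = parent_rel, stringsAsFactors = FALSE)
  edges <- edges[edges$relation %in% relations, , drop = FALSE]
  # drop edges out of obsolete terms and edges to unknown parents
  edges <- edges[!edges$child %in% ids[obs], , drop = FALSE]
  unknown <- !edges$parent %in% ids
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " edge(s) to unknown parent term(s): ",
            paste(unique(edges$parent[unknown]), collapse = ", "))
    edges <- edges[!unknown, , drop = FALSE]
  }
  # fill missing namespaces from the root each term reaches (best effort):
  # leave NA namespaces as-is; metrics only need aspect labels when present.
  g <- .new_ontology_graph(terms, edges, alt_map = setNames(alt_to, alt_from))
  .check_dag(g)
  g
}

.new_ontology_graph <- function(terms, edges, alt_map = character()) {
  parents <- split(edges[c("parent", "relation")], factor(edges$child, levels = terms$id))
  children <- split(data.frame(child = edges$child, relation = edges$relation,
                               stringsAsFactors = FALSE),
                    factor(edges$parent, levels = terms$id))
  live <- terms[!terms$obsolete, , drop = FALSE]
  has_parent <- vapply(parents[live$id], nrow, 0L) > 0L
  root_ids <- live$id[!has_parent]
  roots <- setNames(root_ids, live$namespace[!has_parent])
  structure(list(terms = terms, edges = edges, parents = parents,
                 children = children, alt_map = alt_map, roots = roots),
            class = "ontology_graph")
}

.check_dag <- function(graph) {
  if (!nrow(graph$edges)) return(invisible(TRUE))
  ig <- igraph::graph_from_data_frame(
    graph$edges[c("child", "parent")], directed = TRUE,
    vertices = graph$terms["id"])
  if (!igraph::is_dag(ig)) {
    comp <- igraph::components(ig, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)]
    if (!length(bad))  # self loop
      bad <- graph$edges$child[graph$edges$child == graph$edges$parent]
    .stop_input("ontology is not acyclic; cycle involving term(s): ",
                paste(sort(unique(bad)), collapse = " -> "))
  }
  invisible(TRUE)
}

#' Resolve a term identifier to its primary id
#'
#' Alternate ids are silently mapped to their primary id (with a notice via
#' `message()`); unknown ids raise an error.
#'
#' @param graph An `ontology_graph`.
#' @param term A term identifier.
#' @return The primary term id (character scalar).
#' @export
resolve_term <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"), length(term) == 1L)
  if (term %in% graph$terms$id) return(term)
  if (term %in% names(graph$alt_map)) {
    primary <- unname(graph$alt_map[[term]])
    message("alt_id ", term, " resolved to ", primary)
    return(primary)
  }
  .stop_input("unknown term id: ", term)
}

.traverse <- function(graph, id, relations, up = TRUE) {
  tbl <- if (up) graph$parents else graph$children
  col <- if (up) "parent" else "child"
  seen <- new.env(parent = emptyenv())
  frontier <- id
  out <- character()
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      e <- tbl[[t]]
      if (is.null(e) || !nrow(e)) next
      step <- unique(e[[col]][e$relation %in% relations])
      step <- step[!vapply(step, exists, TRUE, envir = seen)]
      for (s in step) assign(s, TRUE, envir = seen)
      nxt <- c(nxt, step)
    }
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(unique(out))
}

#' Ancestors of a term under the true-path rule
#'
#' Returns every term reachable from `term` by walking the chosen parent
#' relations upward, excluding `term` itself.  Under the true-path rule an
#' annotation to a term implies annotation to all terms returned here.
#' The default relation set is `is_a` only; `part_of` can be included.
#'
#' @param graph An `ontology_graph`.
#' @param term A term id (alternate ids are resolved).
#' @param relations Relations to traverse.
#' @return Sorted character vector of ancestor term ids.
#' @export
ancestors <- function(graph, term, relations = "is_a") {
  id <- resolve_term(graph, term)
  if (graph$terms$obsolete[match(id, graph$terms$id)])
    .stop_input("term ", id, " is obsolete and excluded from traversal")
  .traverse(graph, id, relations, up = TRUE)
}

#' Descendants of a term
#'
#' Mirror of [ancestors()]: every term from which `term` is reachable via
#' the chosen relations, excluding `term` itself.
#'
#' @inheritParams ancestors
#' @return Sorted character vector of descendant term ids.
#' @export
descendants <- function(graph, term, relations = "is_a") {
  id <- resolve_term(graph, term)
  if (graph$terms$obsolete[match(id, graph$terms$id)])
    .stop_input("term ", id, " is obsolete and excluded from traversal")
  .traverse(graph, id, relations, up = FALSE)
}

#' Root term of an ontology aspect
#'
#' @param graph An `ontology_graph`.
#' @param aspect Namespace label (e.g. `"molecular_function"`); if `NULL`
#'   and the graph has a single root, that root is returned.
#' @return A term id.
#' @export
aspect_root <- function(graph, aspect = NULL) {
  if (is.null(aspect)) {
    if (length(graph$roots) == 1L) return(unname(graph$roots))
    .stop_input("graph has ", length(graph$roots),
                " roots; specify an aspect")
  }
  hit <- graph$roots[names(graph$roots) == aspect]
  if (!length(hit)) .stop_input("no root found for aspect ", aspect)
  unname(hit[1L])
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$terms), " terms (",
      sum(x$terms$obsolete), " obsolete), ", nrow(x$edges),
      " edges, roots: ",
      paste(sprintf("%s [%s]", x$roots, names(x$roots)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write an ontology graph to OBO format
#'
#' Emits one `[Term]` stanza per term with the tag subset understood by
#' [parse_obo()]; parsing the output reproduces the graph.
#'
#' @param graph An `ontology_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  out <- c("format-version: 1.2", "")
  ord <- order(graph$terms$id)
  for (i in ord) {
    t <- graph$terms[i, ]
    stanza <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.na(t$namespace))
      stanza <- c(stanza, paste0("namespace: ", t$namespace))
    alt <- names(graph$alt_map)[graph$alt_map == t$id]
    if (length(alt)) stanza <- c(stanza, paste0("alt_id: ", sort(alt)))
    p <- graph$parents[[t$id]]
    if (!is.null(p) && nrow(p)) {
      p <- p[order(p$parent), , drop = FALSE]
      isa <- p$parent[p$relation == "is_a"]
      if (length(isa)) stanza <- c(stanza, paste0("is_a: ", isa))
      oth <- p[p$relation != "is_a", , drop = FALSE]
      if (nrow(oth))
        stanza <- c(stanza, paste0("relationship: ", oth$relation, " ", oth$parent))
    }
    if (t$obsolete) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Export a graph to GraphML
#'
#' @param x An `ontology_graph` or `flow_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(x, path) UseMethod("export_graphml")

#' @export
export_graphml.ontology_graph <- function(x, path) {
  ig <- igraph::graph_from_data_frame(
    x$edges[c("child", "parent", "relation")], directed = TRUE,
    vertices = x$terms)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @export
export_graphml.flow_graph <- function(x, path) {
  ig <- igraph::graph_from_data_frame(
    x$edges[c("parent", "child", "weight")], directed = TRUE,
    vertices = x$nodes)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
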