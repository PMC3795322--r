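# Shared fixtures and independent oracles, all built in code.

# Binding subgraph: root -> binding -> {carbohydrate binding, pattern
# binding} -> polysaccharide binding (two is_a parents).
fig_obo <- function() c(
  "format-version: 1.2",
  "",
  "[Term]", "id: T:0001", "name: molecular_function",
  "namespace: molecular_function",
  "",
  "[Term]", "id: T:0002", "name: binding",
  "namespace: molecular_function", "is_a: T:0001 ! molecular_function",
  "",
  "[Term]", "id: T:0003", "name: carbohydrate binding",
  "namespace: molecular_function", "is_a: T:0002 ! binding",
  "",
  "[Term]", "id: T:0004", "name: pattern binding",
  "namespace: molecular_function", "is_a: T:0002 ! binding",
  "",
  "[Term]", "id: T:0005", "name: polysaccharide binding",
  "namespace: molecular_function",
  "is_a: T:0003 ! carbohydrate binding", "is_a: T:0004 ! pattern binding")

# 4-node diamond a -> {b, c} -> d
diamond_obo <- function() c(
  "[Term]", "id: D:a", "name: a", "namespace: molecular_function",
  "",
  "[Term]", "id: D:b", "name: b", "namespace: molecular_function",
  "is_a: D:a",
  "",
  "[Term]", "id: D:c", "name: c", "namespace: molecular_function",
  "is_a: D:a",
  "",
  "[Term]", "id: D:d", "name: d", "namespace: molecular_function",
  "is_a: D:b", "is_a: D:c")

# Minimal GAF rows: protein/term/evidence/aspect letter, optional NOT.
gaf_row <- function(protein, term, evidence = "IDA", aspect = "F",
                    qualifier = "") {
  paste("SDB", protein, protein, qualifier, term, "SREF:1", evidence, "",
        aspect, "", "", "protein", "taxon:0000", "20130101", "TEST", "", "",
        sep = "\t")
}

gaf_text <- function(...) c("!gaf-version: 2.1", ...)

# Independent reachability oracle on a raw edge table (child, parent).
brute_reach <- function(edges, from, up = TRUE) {
  key <- if (up) "child" else "parent"
  val <- if (up) "parent" else "child"
  seen <- character(); frontier <- from
  while (length(frontier)) {
    step <- setdiff(edges[[val]][edges[[key]] %in% frontier], seen)
    seen <- c(seen, step)
    frontier <- step
  }
  sort(seen)
}

# Exhaustive hypergeometric upper-tail oracle.
hyper_tail <- function(k, n, K, N) {
  j <- seq(k, min(n, K))
  if (!length(j)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Builtin scenarios are deterministic but expensive to rebuild; cache them
# (with their propagated corpus) across test files.
.scn_cache <- new.env(parent = emptyenv())
get_scenario <- function(name) {
  if (is.null(.scn_cache[[name]])) {
    scn <- make_scenario(name)
    scn$prop <- propagate_annotations(scn$corpus, scn$graph)
    .scn_cache[[name]] <- scn
  }
  .scn_cache[[name]]
}
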