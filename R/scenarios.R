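#' @rdname make_scenario
#' @export
list_scenarios <- function() c("PL3", "PL4", "PL5", "PL8", "PL22")

# A synthetic molecular-function ontology fragment shared by all builtin
# scenarios: a lyase branch with the specific polysaccharide-lyase leaves,
# a hydrolase branch, and a binding branch (with a multi-parent diamond at
# polysaccharide binding).  Ids use the SGO: prefix to mark them synthetic.
.scenario_terms <- list(
  c("SGO:0000001", "molecular_function", ""),
  c("SGO:0000002", "catalytic activity", "SGO:0000001"),
  c("SGO:0000003", "binding", "SGO:0000001"),
  c("SGO:0000004", "lyase activity", "SGO:0000002"),
  c("SGO:0000005", "carbon-oxygen lyase activity, acting on polysaccharides",
    "SGO:0000004"),
  c("SGO:0000006", "oligogalacturonide lyase activity", "SGO:0000005"),
  c("SGO:0000007", "pectate lyase activity", "SGO:0000005"),
  c("SGO:0000008", "pectin lyase activity", "SGO:0000005"),
  c("SGO:0000009", "hyaluronate lyase activity", "SGO:0000005"),
  c("SGO:0000010", "chondroitin-sulfate-ABC endolyase activity", "SGO:0000005"),
  c("SGO:0000011", "chondroitin AC lyase activity", "SGO:0000005"),
  c("SGO:0000012", "chondroitin-sulfate-ABC exolyase activity", "SGO:0000005"),
  c("SGO:0000013", "xanthan lyase activity", "SGO:0000005"),
  c("SGO:0000014", "poly(beta-D-mannuronate) lyase activity", "SGO:0000005"),
  c("SGO:0000015", "hydrolase activity", "SGO:0000002"),
  c("SGO:0000016", "carboxypeptidase activity", "SGO:0000015"),
  c("SGO:0000017", "carbohydrate binding", "SGO:0000003"),
  c("SGO:0000018", "pattern binding", "SGO:0000003"),
  c("SGO:0000019", "polysaccharide binding", "SGO:0000017|SGO:0000018"),
  c("SGO:0000020", "metal ion binding", "SGO:0000003"),
  c("SGO:0000021", "calcium ion binding", "SGO:0000020"),
  c("SGO:0000022", "protein binding", "SGO:0000003"))

#' Ontology used by the builtin synthetic scenarios
#'
#' @return An `ontology_graph` of 22 synthetic molecular-function terms.
#' @export
scenario_ontology <- function() {
  ids <- vapply(.scenario_terms, `[[`, "", 1L)
  nms <- vapply(.scenario_terms, `[[`, "", 2L)
  par <- vapply(.scenario_terms, `[[`, "", 3L)
  terms <- data.frame(id = ids, name = nms,
                      namespace = "molecular_function", obsolete = FALSE,
                      stringsAsFactors = FALSE)
  pl <- strsplit(par, "|", fixed = TRUE)
  edges <- data.frame(child = rep(ids, lengths(pl)),
                      parent = unlist(pl), relation = "is_a",
                      stringsAsFactors = FALSE)
  g <- .new_ontology_graph(terms, edges)
  .check_dag(g)
  g
}

.sgo <- function(i) sprintf("SGO:%07d", i)

#' Generate a builtin annotation scenario
#'
#' Deterministic synthetic fixtures reproducing the annotation structure of
#' characteristic polysaccharide-lyase family patterns:
#'
#' * `"PL22"`: a mono-specific family of 29 proteins of which 22 are
#'   annotated to the specific term and 7 only to its ancestor -- the
#'   textbook annotation-incompleteness case.
#' * `"PL5"`: a perfectly coherent mono-specific family (37 proteins, one
#'   shared specific term).
#' * `"PL3"`: 228 proteins all carrying one dominant term, with six rare
#'   off-lineage secondary terms (<= 2 direct annotations each) breaking
#'   coherence.
#' * `"PL4"`: a multi-functional family (43 proteins, 25 lyase carriers)
#'   whose most specific term is off the lyase lineage.
#' * `"PL8"`: 184 proteins with five asymmetric specific leaf descendants
#'   (supports 31/4/2/1/1) under a generic term carried by 180.
#'
#' Each scenario pads its corpus with filler background proteins (held in a
#' `FILLER` pseudo-family so that the union of families spans the whole
#' corpus); filler sizes are fixed per scenario to give the enrichment step
#' a realistic, corpus-scale contrast.  Family-side counts are realized
#' exactly, not sampled, so all downstream numbers are deterministic.
#'
#' @param name Scenario name, see [list_scenarios()].
#' @param dir Optional directory: when given, `<name>.obo`, `<name>.gaf`
#'   and `<name>_families.tsv` are written there.
#' @param seed Accepted for interface uniformity; builtin scenarios are
#'   fully deterministic.
#' @return List with elements `name`, `graph`, `corpus` (direct,
#'   unpropagated), `family`, `families` (study family plus `FILLER`) and
#'   `config` (the scenario's [pipeline_config()]).
#' @export
make_scenario <- function(name, dir = NULL, seed = 1L) {
  name <- match.arg(name, list_scenarios())
  graph <- scenario_ontology()
  p <- function(i) sprintf("%s_P%04d", name, i)
  f <- function(i) sprintf("BG%s_F%06d", name, i)
  ann <- function(proteins, term_index)
    data.frame(protein = proteins, term = .sgo(term_index),
               evidence = "IEA", aspect = "molecular_function",
               stringsAsFactors = FALSE)
  config <- pipeline_config()
  blocks <- switch(
    name,
    PL22 = {
      n_fill <- 971L
      list(ann(p(1:22), 6L), ann(p(23:29), 4L), ann(f(1:n_fill), 22L))
    },
    PL5 = {
      n_fill <- 963L
      list(ann(p(1:37), 14L), ann(f(1:n_fill), 22L))
    },
    PL4 = {
      n_fill <- 957L
      list(ann(p(1:43), 17L),          # carbohydrate binding, all members
           ann(p(1:16), 5L),           # specific lyase term
           ann(p(17:25), 4L),          # generic lyase only
           ann(p(c(11:16, 26)), 16L),  # carboxypeptidase, 6 overlapping
           ann(p(27:32), 2L),          # catalytic activity only
           ann(p(33), 21L),            # calcium ion binding singleton
           ann(f(1:700), 2L), ann(f(701:713), 21L), ann(f(714:957), 22L))
    },
    PL3 = {
      n_fill <- 9772L
      config <- pipeline_config(focus = .sgo(4L))
      list(ann(p(1:228), 7L),          # dominant pectate-lyase term
           ann(p(1:2), 8L),            # pectin lyase, 2 proteins
           ann(p(3:4), 22L), ann(p(5:6), 20L), ann(p(7:8), 17L),
           ann(p(9), 21L), ann(p(10), 18L), ann(p(11), 19L),
           ann(f(1:n_fill), 22L), ann(f(1:n_fill), 20L),
           ann(f(1:2000), 21L), ann(f(2001:4000), 19L))
    },
    PL8 = {
      n_fill <- 69816L
      config <- pipeline_config(focus = .sgo(5L))
      list(ann(p(1:31), 9L),           # hyaluronate lyase
           ann(p(32:35), 10L), ann(p(36:37), 11L), ann(p(38), 12L),
           ann(p(39), 13L),            # rare sibling leaves 4/2/1/1
           ann(p(40:180), 5L),         # generic specific term, 180 carriers
           ann(p(181), 4L),            # lyase only
           ann(p(c(1:177, 184)), 17L), # carbohydrate binding, 178
           ann(p(182:183), 20L),       # metal ion binding, 2
           ann(f(1:n_fill), 4L), ann(f(1:n_fill), 20L))
    })
  corpus <- annotation_corpus(do.call(rbind, blocks))
  members <- grep(paste0("^", name, "_P"), unique(corpus$annotations$protein),
                  value = TRUE)
  fillers <- setdiff(unique(corpus$annotations$protein), members)
  family <- protein_family(name, members)
  families <- list(family, protein_family("FILLER", fillers))
  names(families) <- c(name, "FILLER")
  scn <- list(name = name, graph = graph, corpus = corpus, family = family,
              families = families, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_obo(graph, file.path(dir, paste0(name, ".obo")))
    write_gaf(corpus, file.path(dir, paste0(name, ".gaf")))
    write_family_table(families, file.path(dir, paste0(name, "_families.tsv")))
  }
  scn
}

#' Random ontology and corpus generator for property testing
#'
#' Builds a random single-rooted DAG of `n_terms` terms organized in
#' levels (each non-root term has 1-2 parents drawn from strictly lower
#' levels, so acyclicity holds by construction) and annotates each of
#' `n_proteins` proteins with 1-3 random direct terms.  Fully reproducible
#' for a fixed seed.
#'
#' @param n_terms Number of terms (>= 1).
#' @param n_proteins Number of proteins.
#' @param depth Number of levels below the root.
#' @param p_part_of Probability that an edge is `part_of` instead of
#'   `is_a`.
#' @param seed Random seed.
#' @return List with elements `graph` (an `ontology_graph`) and `corpus`
#'   (an unpropagated `annotation_corpus`).
#' @export
random_dag_corpus <- function(n_terms, n_proteins, depth = 4L,
                              p_part_of = 0, seed = 1L) {
  stopifnot(n_terms >= 1, n_proteins >= 0, depth >= 1)
  withr::with_seed(seed, {
    ids <- sprintf("RND:%04d", seq_len(n_terms))
    terms <- data.frame(id = ids, name = paste("term", seq_len(n_terms)),
                        namespace = "molecular_function", obsolete = FALSE,
                        stringsAsFactors = FALSE)
    child <- character(); parent <- character(); relation <- character()
    if (n_terms > 1L) {
      level <- c(0L, ((seq_len(n_terms - 1L) - 1L) %% depth) + 1L)
      for (i in 2L:n_terms) {
        lower <- which(level < level[i])
        np <- min(length(lower), 1L + (stats::runif(1) < 0.3))
        ps <- if (length(lower) == 1L) lower else sample(lower, np)
        child <- c(child, rep(ids[i], length(ps)))
        parent <- c(parent, ids[ps])
        relation <- c(relation,
                      ifelse(stats::runif(length(ps)) < p_part_of,
                             "part_of", "is_a"))
      }
    }
    edges <- data.frame(child = child, parent = parent, relation = relation,
                        stringsAsFactors = FALSE)
    g <- .new_ontology_graph(terms, edges)
    .check_dag(g)
    ann <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
      k <- sample(1:3, 1L)
      data.frame(protein = sprintf("RP%05d", i),
                 term = ids[sample(n_terms, min(k, n_terms))],
                 evidence = "IEA", aspect = "molecular_function",
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ann)) ann <- data.frame()
    list(graph = g, corpus = annotation_corpus(ann))
  })
}
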