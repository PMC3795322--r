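#' Configuration for the annotation-extension pipeline
#'
#' @param alpha Enrichment significance level (default 0.01).
#' @param correction Multiple-testing correction ("BY" default).
#' @param min_support Minimum support-set size for a term to seed an
#'   extension proposal (default 10): terms annotating fewer proteins do
#'   not provide enough sequences to build a per-term classifier.
#' @param focus Optional focus term id: relevant terms are restricted to
#'   the focus lineage and candidate pools to carriers of the focus term.
#' @param allow,deny Optional manually curated term allow/deny lists
#'   applied after enrichment filtering.
#' @param aspect Ontology aspect analysed.
#' @param relations Relations used for propagation/traversal.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.01, correction = "BY",
                            min_support = 10L, focus = NULL,
                            allow = NULL, deny = NULL,
                            aspect = "molecular_function",
                            relations = "is_a") {
  stopifnot(alpha > 0, alpha < 1, min_support >= 1)
  structure(list(alpha = alpha, correction = correction,
                 min_support = as.integer(min_support), focus = focus,
                 allow = allow, deny = deny, aspect = aspect,
                 relations = relations),
            class = "pipeline_config")
}

#' Select the family's relevant annotation terms (pipeline step 1)
#'
#' Statistical enrichment filters out terms that are not characteristic of
#' the family; manually created allow/deny rules and an optional focus-
#' lineage restriction refine the selection.
#'
#' @param family A `protein_family`.
#' @param background A propagated `annotation_corpus`.
#' @param graph The `ontology_graph`.
#' @param config A [pipeline_config()].
#' @return Character vector of term ids (possibly empty, with a warning).
#' @export
select_relevant_terms <- function(family, background, graph,
                                  config = pipeline_config()) {
  enr <- term_enrichment(family, background, graph,
                         aspect = config$aspect, alpha = config$alpha,
                         correction = config$correction)
  sel <- enr$term[enr$significant]
  if (!is.null(config$allow)) sel <- intersect(sel, config$allow)
  sel <- setdiff(sel, config$deny)
  if (!is.null(config$focus)) {
    lineage <- c(resolve_term(graph, config$focus),
                 descendants(graph, config$focus,
                             relations = config$relations))
    sel <- intersect(sel, lineage)
  }
  if (!length(sel))
    warning("no relevant terms selected for family ", family$name)
  sel
}

#' Extension candidates for a term within a family
#'
#' The annotated family proteins that do not carry the term (directly or
#' through propagation) and therefore could potentially be annotated with
#' it.  When `within` is given, the pool is restricted to family proteins
#' carrying that (more generic) term, i.e. proteins already on the right
#' functional lineage.
#'
#' @param family A `protein_family`.
#' @param term Term id proposed for extension.
#' @param corpus A propagated `annotation_corpus`.
#' @param aspect Aspect label.
#' @param within Optional term id restricting the candidate pool to its
#'   carriers.
#' @return Sorted character vector of candidate accessions (disjoint from
#'   the term's support set).
#' @export
extension_candidates <- function(family, term, corpus,
                                 aspect = "molecular_function",
                                 within = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!isTRUE(corpus$propagated))
    .stop_input("corpus must be propagated first (see propagate_annotations)")
  pool <- .annotated_proteins(family, corpus, aspect)
  if (!is.null(within))
    pool <- intersect(pool, .term_carriers(corpus, within))
  sort(setdiff(pool, .term_carriers(corpus, term)))
}

.term_carriers <- function(corpus, t) {
  tt <- t
  unique(corpus$annotations[term == tt, protein])
}

#' Propose annotation extensions for a family (pipeline steps 1-4)
#'
#' For each relevant term (enrichment-filtered, see
#' [select_relevant_terms()]) whose support set -- the family proteins
#' already carrying the term -- reaches `min_support`, emits an extension
#' proposal pairing the support set (the training corpus for an external
#' per-term classifier) with the candidate set of family proteins lacking
#' the term.  Terms already carried by every candidate-pool protein yield
#' no proposal.  Proposals are emitted, not applied: the methodology is
#' semi-automatic and actual extension is delegated to
#' [apply_extension()] after external validation.
#'
#' @inheritParams select_relevant_terms
#' @return List of `extension_proposal` objects sorted by decreasing
#'   support size; each holds `family`, `term`, `term_name`, `support`,
#'   `candidates`, `min_support_met`, `coherence_before`,
#'   `coherence_after` and the `config` used.
#' @export
propose_extensions <- function(family, background, graph,
                               config = pipeline_config()) {
  relevant <- select_relevant_terms(family, background, graph, config)
  if (!length(relevant)) return(list())
  annotated <- .annotated_proteins(family, background, config$aspect)
  before <- go_occurrence(family, background, graph, aspect = config$aspect)
  proposals <- list()
  for (t in relevant) {
    support <- sort(intersect(annotated, .term_carriers(background, t)))
    candidates <- extension_candidates(family, t, background,
                                       aspect = config$aspect,
                                       within = config$focus)
    if (!length(candidates)) next
    if (length(support) < config$min_support) next
    prop <- structure(list(
      family = family$name, term = t,
      term_name = graph$terms$name[match(t, graph$terms$id)],
      support = support, candidates = candidates,
      min_support_met = TRUE,
      coherence_before = before, coherence_after = NA_real_,
      config = config), class = "extension_proposal")
    prop$coherence_after <- coherence_differential(prop, family,
                                                   background, graph)[["after"]]
    proposals[[t]] <- prop
  }
  ord <- order(-vapply(proposals, function(p) length(p$support), 0L),
               vapply(proposals, `[[`, "", "term"))
  unname(proposals[ord])
}

#' @export
print.extension_proposal <- function(x, ...) {
  cat("<extension_proposal> ", x$family, ": extend ", x$term,
      if (!is.na(x$term_name)) paste0(" (", x$term_name, ")"), "\n",
      "  support ", length(x$support), ", candidates ",
      length(x$candidates), "; GOoccurrence ",
      sprintf("%.3f -> %.3f", x$coherence_before, x$coherence_after),
      "\n", sep = "")
  invisible(x)
}

#' Apply an extension proposal to a corpus
#'
#' Adds the proposal's term as a direct annotation to every candidate
#' protein, with a distinguishing evidence code, and re-propagates.  Meant
#' for the explicit apply step of the semi-automatic workflow (e.g. after
#' external classifier confirmation).
#'
#' @param corpus An `annotation_corpus`.
#' @param proposal An `extension_proposal`.
#' @param graph The `ontology_graph`.
#' @param evidence Evidence code recorded for the new annotations.
#' @return A propagated `annotation_corpus` including the extensions.
#' @export
apply_extension <- function(corpus, proposal, graph, evidence = "IEA") {
  if (!length(proposal$candidates))
    return(propagate_annotations(corpus, graph,
                                 relations = proposal$config$relations))
  add <- data.table(protein = proposal$candidates, term = proposal$term,
                    evidence = evidence, aspect = proposal$config$aspect,
                    direct = TRUE)
  ann <- rbind(corpus$annotations[direct == TRUE], add)
  propagate_annotations(.new_corpus(.collapse_annotations(ann), FALSE),
                        graph, relations = proposal$config$relations)
}

#' Coherence differential of an extension proposal (pipeline step 5)
#'
#' GOoccurrence before and after hypothetically asserting the proposal's
#' term for all its candidates; the "after" value is a full recomputation
#' on the extended corpus.  Extending can only raise term frequencies, so
#' `after >= before`.
#'
#' @param proposal An `extension_proposal`.
#' @param family The `protein_family` the proposal belongs to.
#' @param corpus A propagated `annotation_corpus`.
#' @param graph The `ontology_graph`.
#' @return Named numeric vector `c(before = , after = )`.
#' @export
coherence_differential <- function(proposal, family, corpus, graph) {
  aspect <- proposal$config$aspect
  before <- go_occurrence(family, corpus, graph, aspect = aspect)
  extended <- apply_extension(corpus, proposal, graph)
  after <- go_occurrence(family, extended, graph, aspect = aspect)
  c(before = before, after = after)
}

#' Write extension proposals to JSON
#'
#' One record per proposal: family, term, support and candidate accessions
#' (the support list doubling as the accession list for external classifier
#' construction), coherence before/after, and the configuration snapshot as
#' provenance.
#'
#' @param proposals List of `extension_proposal` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proposals <- function(proposals, path) {
  recs <- lapply(proposals, function(p) list(
    family = p$family, term = p$term, term_name = p$term_name,
    support = p$support, candidates = p$candidates,
    support_size = length(p$support),
    candidate_count = length(p$candidates),
    min_support_met = p$min_support_met,
    coherence_before = p$coherence_before,
    coherence_after = p$coherence_after,
    config = unclass(p$config)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
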