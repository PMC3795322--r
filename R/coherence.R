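#' Corpus-wide term statistics: frequency and information content
#'
#' For each term annotating at least one protein in the (propagated) corpus,
#' computes the annotation probability `f(t)` = carriers / total proteins,
#' the information content `IC(t) = -log2 f(t)` (in bits) and a normalized
#' IC, `ic / max(ic)` over all annotated terms, so the rarest term(s) score
#' exactly 1.  Ubiquitous terms score an IC of 0.
#'
#' @param corpus A propagated `annotation_corpus`, used as the reference
#'   corpus for IC (a broad background corpus gives the most meaningful
#'   values).
#' @param aspect Optional aspect label to restrict the statistics to.
#' @return data.frame with columns `term`, `count`, `corpus_freq`, `ic`,
#'   `ic_norm`.
#' @export
term_stats <- function(corpus, aspect = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!corpus$protein_count)
    .stop_input("IC undefined on empty corpus")
  if (!isTRUE(corpus$propagated))
    .stop_input("corpus must be propagated first (see propagate_annotations)")
  ann <- corpus$annotations
  if (!is.null(aspect)) {
    asp <- aspect
    ann <- ann[aspect == asp]
  }
  if (!nrow(ann)) .stop_input("IC undefined: no annotations in aspect")
  n <- corpus$protein_count
  st <- ann[, .(count = uniqueN(protein)), by = term]
  st[, corpus_freq := count / n]
  st[, ic := -log2(corpus_freq)]
  mx <- max(st$ic)
  st[, ic_norm := if (mx > 0) ic / mx else 0]
  setorder(st, term)
  as.data.frame(st)
}

# The term scope over which GOscore/GOoccurrence aggregate: the distinct
# directly-asserted terms of family members (excluding aspect roots), with
# frequencies counted after propagation.
.term_scope <- function(freqs, graph, restrict_to = NULL,
                        relations = "is_a") {
  scope <- freqs[freqs$direct & !freqs$term %in% graph$roots, , drop = FALSE]
  if (!nrow(scope))  # degenerate corpus annotated only at the aspect root
    scope <- freqs[freqs$direct, , drop = FALSE]
  if (!is.null(restrict_to)) {
    keep <- c(resolve_term(graph, restrict_to),
              descendants(graph, restrict_to, relations = relations))
    scope <- scope[scope$term %in% keep, , drop = FALSE]
    if (!nrow(scope))
      .stop_input("restriction to descendants of ", restrict_to,
                  " leaves no scoped terms")
  }
  if (!nrow(scope))
    .stop_input("family has no scoped (non-root, directly asserted) terms")
  scope
}

#' Family annotation coherence report
#'
#' Computes both family metrics over the family's term scope -- the distinct
#' directly asserted terms of its members (aspect roots excluded), with
#' frequencies counted after true-path propagation:
#'
#' * GOoccurrence: the arithmetic mean of the within-family term
#'   frequencies.  Equals 1 exactly when every scoped term annotates every
#'   annotated family protein (perfect annotation coherence).
#' * GOscore: the maximum over scoped terms of
#'   `freq_fam(term) * ic_norm(term)`, an indicator of how specific the
#'   dominant, well-shared annotation of the family is.  Ties are broken by
#'   higher normalized IC, then lexicographic term id.
#'
#' @param family A `protein_family`.
#' @param corpus A propagated `annotation_corpus` holding the family's
#'   annotations.
#' @param graph The `ontology_graph`.
#' @param aspect Ontology aspect analysed (default molecular function).
#' @param stats Optional reference [term_stats()] table; defaults to
#'   statistics of `corpus` itself.  Supply stats from a broader background
#'   corpus to reproduce corpus-normalized IC values.
#' @param restrict_to Optional focus term: the scope is restricted to the
#'   focus term and its descendants, discarding off-lineage terms (e.g.
#'   secondary functional modules).
#' @param relations Relations used for the descendant restriction.
#' @return A `coherence_report`: list with `family`, `size` (annotated
#'   proteins), `go_score`, `go_occurrence`, `argmax_term`, and the scoped
#'   `terms` table (term, count, freq, ic_norm, product).
#' @export
family_coherence <- function(family, corpus, graph,
                             aspect = "molecular_function",
                             stats = NULL, restrict_to = NULL,
                             relations = "is_a") {
  freqs <- family_frequencies(family, corpus, aspect = aspect)
  n <- attr(freqs, "annotated_size")
  scope <- .term_scope(freqs, graph, restrict_to, relations)
  if (is.null(stats)) stats <- term_stats(corpus, aspect = aspect)
  scope$ic_norm <- stats$ic_norm[match(scope$term, stats$term)]
  if (anyNA(scope$ic_norm))
    .stop_input("reference stats lack term(s): ",
                paste(scope$term[is.na(scope$ic_norm)], collapse = ", "))
  scope$product <- scope$freq * scope$ic_norm
  ord <- order(-scope$product, -scope$ic_norm, scope$term)
  scope <- scope[ord, , drop = FALSE]
  rownames(scope) <- NULL
  structure(list(family = family$name, size = n,
                 go_score = scope$product[1L],
                 go_occurrence = mean(scope$freq),
                 argmax_term = scope$term[1L],
                 terms = scope),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat("<coherence_report> ", x$family, " (", x$size, " annotated proteins)\n",
      "  GOoccurrence = ", sprintf("%.3f", x$go_occurrence),
      "  GOscore = ", sprintf("%.3f", x$go_score),
      " (argmax ", x$argmax_term, ")\n",
      "  ", nrow(x$terms), " scoped terms\n", sep = "")
  invisible(x)
}

#' GOoccurrence: mean within-family term frequency
#'
#' @inheritParams family_coherence
#' @return Numeric scalar in (0, 1].
#' @export
go_occurrence <- function(family, corpus, graph,
                          aspect = "molecular_function",
                          restrict_to = NULL, relations = "is_a") {
  # GOoccurrence does not need IC values; skip computing reference stats
  freqs <- family_frequencies(family, corpus, aspect = aspect)
  scope <- .term_scope(freqs, graph, restrict_to, relations)
  mean(scope$freq)
}

#' GOscore: maximal frequency-weighted normalized information content
#'
#' @inheritParams family_coherence
#' @return Numeric scalar in \[0, 1\]; the realizing term is available via
#'   [family_coherence()].
#' @export
go_score <- function(family, corpus, graph, aspect = "molecular_function",
                     stats = NULL, restrict_to = NULL, relations = "is_a") {
  family_coherence(family, corpus, graph, aspect = aspect, stats = stats,
                   restrict_to = restrict_to, relations = relations)$go_score
}

#' Descendant-restricted GOoccurrence
#'
#' Recomputes GOoccurrence with the term scope restricted to a focus term
#' and its descendants.  Useful for families whose proteins carry secondary
#' functional modules: off-lineage terms with low counts depress the
#' unrestricted metric without reflecting the family's core function.
#'
#' @inheritParams family_coherence
#' @param focus The focus term id.
#' @return Numeric scalar.
#' @export
restricted_go_occurrence <- function(family, focus, corpus, graph,
                                     aspect = "molecular_function",
                                     relations = "is_a") {
  go_occurrence(family, corpus, graph, aspect = aspect,
                restrict_to = focus, relations = relations)
}

#' Coherence report table for a set of families
#'
#' One row per family in the layout Family / Size / GOocc / GOscore /
#' ArgmaxTerm, scores rounded to 3 decimal places.
#'
#' @param families List of `protein_family` objects.
#' @param corpus A propagated `annotation_corpus`.
#' @param graph The `ontology_graph`.
#' @param aspect Aspect label.
#' @param stats Optional reference [term_stats()] table.
#' @return data.frame with columns Family, Size, GOocc, GOscore, ArgmaxTerm.
#' @export
coherence_table <- function(families, corpus, graph,
                            aspect = "molecular_function", stats = NULL) {
  if (inherits(families, "protein_family")) families <- list(families)
  if (!length(families))
    return(data.frame(Family = character(), Size = integer(),
                      GOocc = numeric(), GOscore = numeric(),
                      ArgmaxTerm = character(), stringsAsFactors = FALSE))
  if (is.null(stats)) stats <- term_stats(corpus, aspect = aspect)
  rows <- lapply(families, function(f) {
    r <- family_coherence(f, corpus, graph, aspect = aspect, stats = stats)
    data.frame(Family = r$family, Size = r$size,
               GOocc = round(r$go_occurrence, 3L),
               GOscore = round(r$go_score, 3L),
               ArgmaxTerm = r$argmax_term, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a coherence report table to tab-separated text
#'
#' @param report Output of [coherence_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coherence_table <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
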