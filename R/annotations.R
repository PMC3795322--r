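#' Build an annotation corpus from a table of direct annotations
#'
#' The corpus is the package's central container: a set of protein-term
#' associations, each carrying an evidence code and an ontology aspect, plus
#' a flag distinguishing directly asserted annotations from ones inherited
#' through true-path propagation.  Duplicate (protein, term) pairs are
#' collapsed, retaining the union of their evidence codes.
#'
#' @param annotations data.frame with columns `protein`, `term` and
#'   optionally `evidence` (default "IEA") and `aspect`.
#' @return An object of class `annotation_corpus` with elements
#'   `annotations` (data.table: protein, term, evidence, aspect, direct),
#'   `protein_count` and `propagated`.
#' @export
annotation_corpus <- function(annotations) {
  ann <- as.data.table(annotations)
  if (!nrow(ann)) {
    ann <- data.table(protein = character(), term = character(),
                      evidence = character(), aspect = character(),
                      direct = logical())
    return(.new_corpus(ann, propagated = FALSE))
  }
  stopifnot(all(c("protein", "term") %in% names(ann)))
  if (is.null(ann$evidence)) ann[, evidence := "IEA"]
  if (is.null(ann$aspect)) ann[, aspect := NA_character_]
  ann[, direct := TRUE]
  ann <- .collapse_annotations(ann[, .(protein, term, evidence, aspect, direct)])
  .new_corpus(ann, propagated = FALSE)
}

.new_corpus <- function(ann, propagated) {
  setkey(ann, protein, term)
  structure(list(annotations = ann,
                 protein_count = uniqueN(ann$protein),
                 propagated = propagated),
            class = "annotation_corpus")
}

# Collapse duplicate (protein, term) rows: union of "|"-separated evidence
# codes, direct wins over propagated, aspect looked up per term.  Fully
# vectorized -- corpora can reach GOA-like sizes.
.collapse_annotations <- function(ann) {
  if (!nrow(ann))
    return(data.table(protein = character(), term = character(),
                      evidence = character(), aspect = character(),
                      direct = logical()))
  term_aspect <- unique(ann[!is.na(aspect), .(term, aspect)], by = "term")
  codes <- strsplit(ann$evidence, "|", fixed = TRUE)
  idx <- rep(seq_len(nrow(ann)), lengths(codes))
  ex <- data.table(protein = ann$protein[idx], term = ann$term[idx],
                   code = unlist(codes, use.names = FALSE),
                   direct = ann$direct[idx])
  setorder(ex, protein, term, code, -direct)
  ex <- unique(ex, by = c("protein", "term", "code"))
  g <- rleid(ex$protein, ex$term)
  ng <- g[length(g)]
  gsize <- tabulate(g, nbins = ng)
  first <- !duplicated(g)
  evidence <- ex$code[first]            # exact for single-code groups
  multi <- which(gsize > 1L)
  if (length(multi)) {
    sub <- ex[g %in% multi]
    evm <- sub[, .(e = paste(code, collapse = "|")), by = .(protein, term)]
    evidence[multi] <- evm$e            # groups appear in sorted order
  }
  out <- data.table(protein = ex$protein[first], term = ex$term[first],
                    evidence = evidence, aspect = NA_character_,
                    direct = as.logical(rowsum(as.integer(ex$direct), g)[, 1L] > 0L))
  if (nrow(term_aspect)) out[term_aspect, aspect := i.aspect, on = "term"]
  out
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus> ", nrow(x$annotations), " annotations (",
      sum(x$annotations$direct), " direct) over ", x$protein_count,
      " proteins; propagated: ", x$propagated, "\n", sep = "")
  invisible(x)
}

#' Read a GAF annotation file
#'
#' Parses GAF 2.1/2.2 tab-separated text.  Comment lines start with `!`.
#' Columns 2 (accession), 4 (qualifier), 5 (term), 7 (evidence code) and
#' 9 (aspect letter) are consumed; rows whose qualifier contains `NOT` are
#' excluded, and duplicate (protein, term) rows are collapsed with the union
#' of their evidence codes.
#'
#' @param x Path, single string, or character vector of lines.
#' @return An unpropagated `annotation_corpus` of direct annotations.
#' @export
parse_gaf <- function(x) {
  lines <- .as_lines(x)
  keep <- nzchar(lines) & !startsWith(lines, "!")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(annotation_corpus(data.frame()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L))
    .stop_input("GAF parse error: line ", lineno[which(nf < 15L)[1L]],
                " has ", nf[which(nf < 15L)[1L]],
                " columns (expected >= 15)")
  get_col <- function(i) vapply(fields, `[[`, "", i)
  qualifier <- get_col(4L)
  not <- grepl("(^|\\|)NOT($|\\|)", qualifier)
  ann <- data.table(protein = get_col(2L), term = get_col(5L),
                    evidence = get_col(7L),
                    aspect = .as_aspect(get_col(9L)),
                    direct = TRUE)[!not]
  if (!nrow(ann)) return(annotation_corpus(data.frame()))
  .new_corpus(.collapse_annotations(ann), propagated = FALSE)
}

#' Write the direct annotations of a corpus to a GAF 2.1 file
#'
#' Only directly asserted annotations are written (propagation is implied by
#' the true-path rule and is reapplied on read).  Multi-code evidence fields
#' are expanded to one row per code, so a parse/write/parse round trip
#' preserves the direct annotation set.
#'
#' @param corpus An `annotation_corpus`.
#' @param path Output path.
#' @param assigned_by Value for GAF column 15.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(corpus, path, assigned_by = "goherence") {
  ann <- corpus$annotations[direct == TRUE][order(protein, term)]
  codes <- strsplit(ann$evidence, "|", fixed = TRUE)
  n <- lengths(codes)
  idx <- rep(seq_len(nrow(ann)), n)
  aspect_letter <- names(.aspect_codes)[match(ann$aspect[idx], .aspect_codes)]
  aspect_letter[is.na(aspect_letter)] <- ""
  rows <- paste(
    "SDB", ann$protein[idx], ann$protein[idx], "", ann$term[idx],
    "SREF:0000001", unlist(codes), "", aspect_letter,
    "", "", "protein", "taxon:0000", "20130101", assigned_by, "", "",
    sep = "\t")
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}

#' Filter direct annotations by evidence code
#'
#' Annotations keep only the listed (or non-excluded) evidence codes; an
#' annotation whose codes are all removed is dropped.  Returns an
#' unpropagated corpus, since the filter changes the closure.
#'
#' @param corpus An `annotation_corpus`.
#' @param include Codes to keep (`NULL` = all).
#' @param exclude Codes to drop.
#' @return An `annotation_corpus` of the retained direct annotations.
#' @export
filter_evidence <- function(corpus, include = NULL, exclude = NULL) {
  ann <- corpus$annotations[direct == TRUE]
  codes <- strsplit(ann$evidence, "|", fixed = TRUE)
  keep_codes <- lapply(codes, function(cc) {
    if (!is.null(include)) cc <- intersect(cc, include)
    setdiff(cc, exclude)
  })
  keep <- lengths(keep_codes) > 0L
  ann <- ann[keep]
  ann[, evidence := vapply(keep_codes[keep], paste, "", collapse = "|")]
  .new_corpus(ann, propagated = FALSE)
}

#' Apply true-path propagation to a corpus
#'
#' Under the true-path rule, a protein annotated to a term is implicitly
#' annotated to all of that term's ancestors.  This adds one non-direct
#' annotation per (protein, ancestor) pair, inheriting the evidence of the
#' source annotation.  Terms not found in the graph (after alternate-id
#' resolution) and obsolete terms are dropped with a warning.  The operation
#' is idempotent: propagation always restarts from the direct annotations.
#'
#' @param corpus An `annotation_corpus`.
#' @param graph An `ontology_graph`.
#' @param relations Relations traversed for propagation (default `is_a`).
#' @return A propagated `annotation_corpus`; each protein's term set is
#'   closed under [ancestors()].
#' @export
propagate_annotations <- function(corpus, graph, relations = "is_a") {
  ann <- corpus$annotations[direct == TRUE]
  if (!nrow(ann)) return(.new_corpus(ann, propagated = TRUE))
  terms <- unique(ann$term)
  # resolve alternate ids
  alt <- terms[terms %in% names(graph$alt_map)]
  if (length(alt)) {
    map <- graph$alt_map[alt]
    message("resolved ", length(alt), " alt_id(s) to primary term ids")
    ann[term %in% alt, term := unname(map[term])]
    terms <- unique(ann$term)
  }
  unknown <- setdiff(terms, graph$terms$id)
  if (length(unknown)) {
    warning("dropping annotations to ", length(unknown),
            " unknown term(s): ", paste(head(sort(unknown), 5L), collapse = ", "))
    ann <- ann[!term %in% unknown]
  }
  obsolete <- intersect(unique(ann$term),
                        graph$terms$id[graph$terms$obsolete])
  if (length(obsolete)) {
    warning("dropping annotations to ", length(obsolete),
            " obsolete term(s): ", paste(head(sort(obsolete), 5L), collapse = ", "))
    ann <- ann[!term %in% obsolete]
  }
  if (!nrow(ann)) return(.new_corpus(ann, propagated = TRUE))
  # aspect from the graph when it declares namespaces, else as asserted
  ns <- graph$terms$namespace[match(ann$term, graph$terms$id)]
  ann[, aspect := fifelse(is.na(ns), aspect, ns)]
  anc <- lapply(unique(ann$term), function(t)
    ancestors(graph, t, relations = relations))
  names(anc) <- unique(ann$term)
  anc_dt <- data.table(term = rep(names(anc), lengths(anc)),
                       anc = unlist(anc, use.names = FALSE))
  if (nrow(anc_dt)) {
    prop <- merge(ann, anc_dt, by = "term", allow.cartesian = TRUE)
    anc_ns <- graph$terms$namespace[match(prop$anc, graph$terms$id)]
    prop <- prop[, .(protein, term = anc, evidence,
                     aspect = fifelse(is.na(anc_ns), aspect, anc_ns),
                     direct = FALSE)]
    ann <- rbind(ann[, .(protein, term, evidence, aspect, direct)], prop)
  }
  .new_corpus(.collapse_annotations(ann), propagated = TRUE)
}

#' Construct a protein family
#'
#' @param name Family label (e.g. `"PL4"`).
#' @param proteins Character vector of protein accessions.
#' @return An object of class `protein_family`.
#' @export
protein_family <- function(name, proteins) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, proteins = sort(unique(as.character(proteins)))),
            class = "protein_family")
}

#' @export
print.protein_family <- function(x, ...) {
  cat("<protein_family> ", x$name, ": ", length(x$proteins),
      " proteins\n", sep = "")
  invisible(x)
}

#' Read a family membership table
#'
#' Two tab-separated columns (family_id, protein_accession); lines starting
#' with `#` are comments.
#'
#' @param x Path, single string, or character vector of lines.
#' @return Named list of [protein_family()] objects.
#' @export
read_family_table <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    .stop_input("family table parse error: line ", bad[1L],
                " does not have 2 tab-separated columns")
  fam <- vapply(fields, `[[`, "", 1L)
  acc <- vapply(fields, `[[`, "", 2L)
  groups <- split(acc, fam)
  out <- lapply(names(groups), function(n) protein_family(n, groups[[n]]))
  names(out) <- names(groups)
  out
}

#' Write a family membership table
#'
#' @param families A `protein_family` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(families, path) {
  if (inherits(families, "protein_family")) families <- list(families)
  rows <- unlist(lapply(families, function(f)
    paste(f$name, f$proteins, sep = "\t")))
  writeLines(c("# family_id\tprotein_accession", rows), path)
  invisible(path)
}

# proteins of a family with >= 1 direct annotation in the aspect
.annotated_proteins <- function(family, corpus, aspect) {
  asp <- aspect
  ann <- corpus$annotations
  sort(unique(ann[direct == TRUE & aspect == asp &
                    protein %in% family$proteins, protein]))
}

#' Per-family term annotation frequencies
#'
#' For each term annotating at least one family protein (directly or through
#' propagation) in the chosen aspect, counts the family proteins carrying it
#' and divides by the family's annotated size (proteins with at least one
#' direct annotation in the aspect).  These are the within-family term
#' frequencies entering GOscore and GOoccurrence.
#'
#' @param family A `protein_family`.
#' @param corpus A propagated `annotation_corpus`.
#' @param aspect Ontology aspect label.
#' @return data.frame with columns `term`, `count`, `freq` and `direct`
#'   (whether the term is directly asserted by some family member).
#' @export
family_frequencies <- function(family, corpus,
                               aspect = "molecular_function") {
  stopifnot(inherits(family, "protein_family"),
            inherits(corpus, "annotation_corpus"))
  if (!isTRUE(corpus$propagated))
    .stop_input("corpus must be propagated first (see propagate_annotations)")
  annotated <- .annotated_proteins(family, corpus, aspect)
  n <- length(annotated)
  if (!n)
    .stop_input("family ", family$name, " has no proteins with direct ",
                aspect, " annotations")
  asp <- aspect
  ann <- corpus$annotations[protein %in% annotated & aspect == asp]
  freq <- ann[, .(count = uniqueN(protein), direct = any(direct)), by = term]
  freq[, freq := count / n]
  setorder(freq, term)
  out <- as.data.frame(freq[, .(term, count, freq, direct)])
  attr(out, "annotated_size") <- n
  out
}
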