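#' One-sided hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k` term carriers in a sample of `n`
#' proteins from a background of `N` proteins of which `K` carry the term
#' (the upper tail of the hypergeometric distribution, equivalently the
#' one-sided Fisher exact test in the enrichment direction).  Vectorized
#' over its arguments.
#'
#' @param k Family proteins carrying the term.
#' @param n Family annotated size.
#' @param K Background proteins carrying the term.
#' @param N Background size.
#' @return Numeric vector of p-values, `P(X >= k)`.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  stopifnot(all(k >= 0), all(n >= 1), all(N >= n), all(K <= N))
  if (any(k > pmin(n, K)))
    .stop_input("inconsistent table: k exceeds min(n, K); ",
                "family is not a subset of the background")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing adjustment of p-values
#'
#' Step-up false-discovery-rate adjustments: Benjamini-Yekutieli (valid
#' under arbitrary dependence; the default, multiplies by the harmonic
#' factor c(m) = sum 1/i), Benjamini-Hochberg, or none.  Adjusted values
#' never fall below the raw ones and are monotone in raw rank.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method One of "BY", "BH", "none".
#' @return Adjusted p-values, in input order.
#' @export
adjust_pvalues <- function(p, method = c("BY", "BH", "none")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    .stop_input("p-values must lie in [0, 1]")
  if (method == "none") return(p)
  p.adjust(p, method = method)
}

#' Per-family term enrichment against a background corpus
#'
#' Tests each scoped term of the family (its distinct directly asserted
#' terms, aspect roots excluded) for over-representation relative to the
#' background corpus, using the one-sided hypergeometric tail with counts
#' taken after true-path propagation.  The correction is applied across the
#' family's term list; significance uses the strict inequality
#' `p_adj < alpha`.
#'
#' @param family A `protein_family` whose proteins are a subset of the
#'   background corpus.
#' @param background A propagated `annotation_corpus` serving both as the
#'   source of the family's annotations and as the background.
#' @param graph The `ontology_graph`.
#' @param aspect Aspect label.
#' @param alpha Significance level (default 0.01).
#' @param correction Correction method passed to [adjust_pvalues()].
#' @param stats Optional reference [term_stats()] table for the reported
#'   normalized IC; defaults to stats of `background`.
#' @return data.frame sorted by adjusted p-value then descending normalized
#'   IC, with columns `term`, `name`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj`,
#'   `ic_norm`, `significant`.
#' @export
term_enrichment <- function(family, background, graph,
                            aspect = "molecular_function", alpha = 0.01,
                            correction = c("BY", "BH", "none"),
                            stats = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  correction <- match.arg(correction)
  freqs <- family_frequencies(family, background, aspect = aspect)
  n <- attr(freqs, "annotated_size")
  scope <- .term_scope(freqs, graph)
  if (is.null(stats)) stats <- term_stats(background, aspect = aspect)
  N <- background$protein_count
  K <- stats$count[match(scope$term, stats$term)]
  res <- data.frame(term = scope$term,
                    name = graph$terms$name[match(scope$term, graph$terms$id)],
                    k = scope$count, n = n, K = K, N = N,
                    stringsAsFactors = FALSE)
  res$p_raw <- hypergeom_enrichment(res$k, res$n, res$K, res$N)
  res$p_adj <- adjust_pvalues(res$p_raw, method = correction)
  res$ic_norm <- stats$ic_norm[match(res$term, stats$term)]
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, -res$ic_norm, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an enrichment table to tab-separated text
#'
#' Columns GO_term (name), p_corr (2 significant digits, scientific),
#' IC_norm (3 decimals) and Annotations (family carrier count).
#'
#' @param enrichment Output of [term_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  out <- data.frame(GO_term = enrichment$name,
                    p_corr = sprintf("%.2e", enrichment$p_adj),
                    IC_norm = sprintf("%.3f", enrichment$ic_norm),
                    Annotations = enrichment$k,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
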