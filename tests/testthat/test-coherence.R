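# Small corpus with known annotation probabilities: 8 proteins on a
# root -> {common, mid -> rare} ontology.
ic_fixture <- function() {
  g <- parse_obo(c("[Term]", "id: I:1", "name: root",
                   "",
                   "[Term]", "id: I:2", "name: common", "is_a: I:1",
                   "",
                   "[Term]", "id: I:3", "name: mid", "is_a: I:1",
                   "",
                   "[Term]", "id: I:4", "name: rare", "is_a: I:3"))
  rows <- c(vapply(1:8, function(i) gaf_row(sprintf("P%d", i), "I:2"), ""),
            gaf_row("P1", "I:3"), gaf_row("P2", "I:4"))
  list(graph = g,
       prop = propagate_annotations(parse_gaf(gaf_text(rows)), g))
}

test_that("information content is -log2 of corpus frequency, normalized to the rarest term", {
  fx <- ic_fixture()
  st <- term_stats(fx$prop)
  ic <- setNames(st$ic, st$term)
  icn <- setNames(st$ic_norm, st$term)
  # ubiquitous term: f = 1 -> IC = 0
  expect_equal(ic[["I:2"]], 0)
  expect_equal(icn[["I:2"]], 0)
  # f = 2/8 = 0.25 -> 2 bits; f = 1/8 -> 3 bits, the rarest -> norm 1
  expect_equal(ic[["I:3"]], 2)
  expect_equal(ic[["I:4"]], 3)
  expect_equal(icn[["I:4"]], 1)
  expect_equal(icn[["I:3"]], 2 / 3)
  expect_error(term_stats(annotation_corpus(data.frame())), "empty corpus")
})

test_that("IC is antitone along every edge after propagation", {
  for (seed in 101:120) {
    rc <- random_dag_corpus(15L, 30L, p_part_of = 0.2, seed = seed)
    prop <- propagate_annotations(rc$corpus, rc$graph,
                                  relations = c("is_a", "part_of"))
    st <- term_stats(prop)
    ic <- setNames(st$ic, st$term)
    e <- rc$graph$edges[rc$graph$edges$child %in% st$term, ]
    expect_true(all(e$parent %in% st$term))  # closure: parents annotated too
    expect_true(all(ic[e$child] >= ic[e$parent] - 1e-12))
  }
})

test_that("GOoccurrence is the mean scoped-term frequency", {
  scn <- get_scenario("PL22")
  # (1 + 22/29) / 2, the partial-annotation penalty
  expect_equal(go_occurrence(scn$family, scn$prop, scn$graph),
               (1 + 22 / 29) / 2)

  # scoped frequencies 1 (common), 2/4 (mid: direct on P1, inherited on
  # P2 through rare) and 1/4 (rare) average explicitly
  fx <- ic_fixture()
  fam <- protein_family("f", c("P1", "P2", "P3", "P4"))
  expect_equal(go_occurrence(fam, fx$prop, fx$graph),
               mean(c(1, 2 / 4, 1 / 4)))

  # identical annotation throughout -> exactly 1
  g <- fx$graph
  same <- propagate_annotations(parse_gaf(gaf_text(
    gaf_row("Q1", "I:4"), gaf_row("Q2", "I:4"), gaf_row("Q3", "I:4"))), g)
  expect_identical(go_occurrence(protein_family("mono", c("Q1", "Q2", "Q3")),
                                 same, g), 1)
})

test_that("GOscore maximizes freq x normalized IC, not the product of maxima", {
  fx <- ic_fixture()
  fam <- protein_family("f", sprintf("P%d", 1:5))
  # custom reference stats: freq 1.0 term at ic_norm 0.64 loses to
  # freq 0.8 term at ic_norm 0.9 (0.64 < 0.72)
  ann <- data.frame(protein = c(sprintf("P%d", 1:5), sprintf("P%d", 1:4)),
                    term = c(rep("I:2", 5), rep("I:3", 4)),
                    aspect = "molecular_function")
  prop <- propagate_annotations(annotation_corpus(ann), fx$graph)
  stats <- data.frame(term = c("I:1", "I:2", "I:3"),
                      ic_norm = c(0, 0.64, 0.9))
  rep <- family_coherence(fam, prop, fx$graph, stats = stats)
  expect_equal(rep$go_score, 0.8 * 0.9)
  expect_equal(rep$argmax_term, "I:3")

  # tie on the product resolves to the higher normalized IC
  stats2 <- data.frame(term = c("I:1", "I:2", "I:3"),
                       ic_norm = c(0, 0.72, 0.9))
  rep2 <- family_coherence(fam, prop, fx$graph, stats = stats2)
  expect_equal(rep2$go_score, 0.72)
  expect_equal(rep2$argmax_term, "I:3")
})

test_that("a fully covered single specific term gives GOscore = its normalized IC", {
  scn <- get_scenario("PL5")
  rep <- family_coherence(scn$family, scn$prop, scn$graph)
  st <- term_stats(scn$prop)
  expect_equal(rep$go_score,
               st$ic_norm[st$term == "SGO:0000014"])
  expect_equal(rep$go_occurrence, 1)
})

test_that("GOscore equals an exhaustive enumeration oracle", {
  for (seed in 201:210) {
    rc <- random_dag_corpus(15L, 40L, seed = seed)
    prop <- propagate_annotations(rc$corpus, rc$graph)
    fam <- protein_family("rand", sprintf("RP%05d", 1:15))
    st <- term_stats(prop)
    freqs <- family_frequencies(fam, prop)
    scoped <- freqs[freqs$direct & !freqs$term %in% rc$graph$roots, ]
    oracle <- max(scoped$freq * st$ic_norm[match(scoped$term, st$term)])
    expect_equal(go_score(fam, prop, rc$graph), oracle)
  }
})

test_that("descendant restriction removes off-lineage terms and can only use a smaller scope", {
  scn <- get_scenario("PL3")
  unrestricted <- go_occurrence(scn$family, scn$prop, scn$graph)
  restricted <- restricted_go_occurrence(scn$family, "SGO:0000004",
                                         scn$prop, scn$graph)
  # dominant term shared by all 228, six rare off-lineage terms removed
  expect_equal(restricted, (1 + 2 / 228) / 2)
  expect_gt(restricted, unrestricted)

  # focus at the aspect root removes nothing
  expect_equal(restricted_go_occurrence(scn$family, "SGO:0000001",
                                        scn$prop, scn$graph), unrestricted)

  # all scoped terms already inside the focus lineage: unchanged
  scn22 <- get_scenario("PL22")
  expect_equal(restricted_go_occurrence(scn22$family, "SGO:0000004",
                                        scn22$prop, scn22$graph),
               go_occurrence(scn22$family, scn22$prop, scn22$graph))

  # restriction that empties the scope is an error naming the focus
  expect_error(restricted_go_occurrence(scn22$family, "SGO:0000016",
                                        scn22$prop, scn22$graph),
               "SGO:0000016")
})

test_that("duplicate accession entries do not change family scores", {
  scn <- get_scenario("PL22")
  doubled <- protein_family("PL22", rep(scn$family$proteins, 2L))
  expect_equal(go_occurrence(doubled, scn$prop, scn$graph),
               go_occurrence(scn$family, scn$prop, scn$graph))
})

test_that("coherence tables mirror the report layout and round trip", {
  scn <- get_scenario("PL22")
  tab <- coherence_table(list(scn$family), scn$prop, scn$graph)
  expect_equal(names(tab), c("Family", "Size", "GOocc", "GOscore",
                             "ArgmaxTerm"))
  expect_equal(tab$GOocc, 0.879)
  expect_equal(tab$Size, 29L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coherence_table(tab, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back, tab)
  empty <- coherence_table(list(), scn$prop, scn$graph)
  expect_equal(nrow(empty), 0L)
})
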