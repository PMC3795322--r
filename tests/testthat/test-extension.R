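test_that("relevant-term selection respects enrichment, rules and focus", {
  scn <- get_scenario("PL3")
  # only the two dominant lyase-branch terms survive alpha = 0.01
  expect_setequal(select_relevant_terms(scn$family, scn$prop, scn$graph,
                                        pipeline_config()),
                  c("SGO:0000007", "SGO:0000008"))
  # a deny-list covering every enriched term empties the selection
  expect_warning(
    none <- select_relevant_terms(scn$family, scn$prop, scn$graph,
                                  pipeline_config(deny = c("SGO:0000007",
                                                           "SGO:0000008"))),
    "no relevant terms")
  expect_length(none, 0L)

  # focus restriction removes enriched off-lineage terms
  scn4 <- get_scenario("PL4")
  no_focus <- select_relevant_terms(scn4$family, scn4$prop, scn4$graph,
                                    pipeline_config())
  expect_true(all(c("SGO:0000016", "SGO:0000017") %in% no_focus))
  focused <- select_relevant_terms(scn4$family, scn4$prop, scn4$graph,
                                   pipeline_config(focus = "SGO:0000004"))
  lineage <- c("SGO:0000004", descendants(scn4$graph, "SGO:0000004"))
  expect_setequal(focused, intersect(no_focus, lineage))
  expect_false("SGO:0000016" %in% focused)
})

test_that("candidate sets complement support sets within the family", {
  scn <- get_scenario("PL22")
  cand <- extension_candidates(scn$family, "SGO:0000006", scn$prop)
  expect_length(cand, 7L)
  support <- intersect(scn$family$proteins,
                       scn$prop$annotations$protein[
                         scn$prop$annotations$term == "SGO:0000006"])
  expect_length(intersect(cand, support), 0L)
  expect_true(all(c(cand, support) %in% scn$family$proteins))
  # a term carried by everyone leaves no candidates
  expect_length(extension_candidates(scn$family, "SGO:0000004", scn$prop), 0L)

  scn4 <- get_scenario("PL4")
  expect_length(extension_candidates(scn4$family, "SGO:0000004", scn4$prop),
                18L)
})

test_that("proposals respect the minimum support-set size", {
  scn <- get_scenario("PL8")
  props <- propose_extensions(scn$family, scn$prop, scn$graph, scn$config)
  # of the five enriched specific leaves only one annotates enough
  # proteins to seed a support corpus
  expect_length(props, 1L)
  p <- props[[1]]
  expect_equal(p$term, "SGO:0000009")
  expect_length(p$support, 31L)
  expect_length(p$candidates, 149L)
  expect_true(p$min_support_met)
  expect_length(intersect(p$support, p$candidates), 0L)

  cfg1 <- scn$config
  cfg1$min_support <- 1L
  props1 <- propose_extensions(scn$family, scn$prop, scn$graph, cfg1)
  expect_length(props1, 5L)
  expect_equal(vapply(props1, function(p) length(p$support), 0L),
               c(31L, 4L, 2L, 1L, 1L))  # sorted by support size

  # a perfectly coherent family proposes nothing
  scn5 <- get_scenario("PL5")
  expect_length(propose_extensions(scn5$family, scn5$prop, scn5$graph,
                                   pipeline_config()), 0L)
})

test_that("the coherence differential matches a from-scratch recomputation", {
  scn <- get_scenario("PL22")
  props <- propose_extensions(scn$family, scn$prop, scn$graph, scn$config)
  expect_length(props, 1L)
  p <- props[[1]]
  d <- coherence_differential(p, scn$family, scn$prop, scn$graph)
  expect_equal(unname(d["before"]), (1 + 22 / 29) / 2)
  expect_equal(unname(d["after"]), 1)
  expect_equal(p$coherence_after, unname(d["after"]))

  # oracle: mutate the direct annotations by hand, round trip through GAF,
  # propagate, and average the scoped frequencies directly
  direct <- as.data.frame(scn$corpus$annotations[scn$corpus$annotations$direct])
  extra <- data.frame(protein = p$candidates, term = p$term,
                      evidence = "IEA", aspect = "molecular_function",
                      direct = TRUE)
  path <- withr::local_tempfile(fileext = ".gaf")
  write_gaf(annotation_corpus(rbind(direct[names(extra)], extra)), path)
  prop2 <- propagate_annotations(parse_gaf(path), scn$graph)
  ann <- as.data.frame(prop2$annotations)
  fam_ann <- ann[ann$protein %in% scn$family$proteins, ]
  scoped <- setdiff(unique(fam_ann$term[fam_ann$direct]), "SGO:0000001")
  n <- length(unique(fam_ann$protein[fam_ann$direct]))
  oracle_after <- mean(vapply(scoped, function(t)
    length(unique(fam_ann$protein[fam_ann$term == t])) / n, 0))
  expect_equal(unname(d["after"]), oracle_after)
})

test_that("an empty candidate set leaves the differential flat", {
  scn <- get_scenario("PL22")
  p <- structure(list(family = "PL22", term = "SGO:0000004",
                      candidates = character(), support = character(),
                      config = pipeline_config()),
                 class = "extension_proposal")
  d <- coherence_differential(p, scn$family, scn$prop, scn$graph)
  expect_equal(unname(d["before"]), unname(d["after"]))
})

test_that("applying a proposal reaches a fixed point", {
  scn <- get_scenario("PL22")
  props <- propose_extensions(scn$family, scn$prop, scn$graph, scn$config)
  extended <- apply_extension(scn$prop, props[[1]], scn$graph)
  expect_equal(go_occurrence(scn$family, extended, scn$graph), 1)
  again <- propose_extensions(scn$family, extended, scn$graph, scn$config)
  expect_false(props[[1]]$term %in% vapply(again, `[[`, "", "term"))
  expect_length(again, 0L)
})

test_that("proposal JSON export round trips the record fields", {
  scn <- get_scenario("PL22")
  props <- propose_extensions(scn$family, scn$prop, scn$graph, scn$config)
  path <- withr::local_tempfile(fileext = ".json")
  write_proposals(props, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$family, "PL22")
  expect_equal(back$term, "SGO:0000006")
  expect_equal(back$support_size, 22L)
  expect_equal(back$candidate_count, 7L)
  expect_equal(back$coherence_after, 1)
  expect_equal(sort(unlist(back$candidates)), props[[1]]$candidates)
})
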