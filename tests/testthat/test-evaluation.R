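two_doc_projects <- function(pred_spans, ref_spans, text = strrep("abcde ", 10)) {
  mk <- function(name, spans) {
    p <- annotation_project(name)
    add_document(p, annotation_record("fixtures", "d1", text, spans,
                                      project = name))
  }
  list(pred = mk("pred", pred_spans), ref = mk("ref", ref_spans))
}

test_that("hand-derived comparison: tp=1 fp=0 fn=1 gives P=1, R=0.5, F1=2/3", {
  ps <- two_doc_projects(denotations("T1", 0L, 9L, "A:1"),
                         denotations(c("T1", "T2"), c(0L, 10L), c(9L, 19L),
                                     c("A:1", "A:1")))
  rep <- compare_projects(ps$pred, ps$ref, "exact_span")
  expect_equal(rep$tp, 1L); expect_equal(rep$fp, 0L); expect_equal(rep$fn, 1L)
  expect_equal(rep$precision, 1.0)
  expect_equal(rep$recall, 0.5)
  expect_equal(rep$f1, 2 / 3)
})

test_that("identity comparison scores all ones; disjoint scores all zeros", {
  fx <- generate_corpus(corpus_spec(n_documents = 5, seed = 3))
  rep <- compare_projects(fx$project, fx$project, "exact_span")
  expect_equal(c(rep$precision, rep$recall, rep$f1), c(1, 1, 1))
  expect_equal(rep$fp + rep$fn, 0L)

  ps <- two_doc_projects(denotations("T1", 0L, 5L, "A:1"),
                         denotations("T1", 10L, 15L, "B:2"))
  rep0 <- compare_projects(ps$pred, ps$ref, "exact_span")
  expect_equal(c(rep0$precision, rep0$recall, rep0$f1), c(0, 0, 0))
})

test_that("overlap mode needs identifier equality and consumes references once", {
  # one predicted span overlapping two references: only one can match
  ps <- two_doc_projects(denotations("T1", 0L, 12L, "A:1"),
                         denotations(c("T1", "T2"), c(0L, 8L), c(6L, 14L),
                                     c("A:1", "A:1")))
  rep <- compare_projects(ps$pred, ps$ref, "overlap")
  expect_equal(rep$tp, 1L); expect_equal(rep$fn, 1L); expect_equal(rep$fp, 0L)
  # same span, wrong identifier: no credit under either mode
  ps2 <- two_doc_projects(denotations("T1", 0L, 6L, "A:1"),
                          denotations("T1", 0L, 6L, "B:2"))
  expect_equal(compare_projects(ps2$pred, ps2$ref, "overlap")$tp, 0L)
  expect_equal(compare_projects(ps2$pred, ps2$ref, "exact_span")$tp, 0L)
})

test_that("conservation and role symmetry hold on random fixture pairs", {
  for (seed in c(21, 22, 23)) {
    fx <- generate_corpus(corpus_spec(n_documents = 6, variant_rate = 0.3,
                                      ambiguity_rate = 0.2, seed = seed))
    pred <- strip_annotations(fx$project)
    pred <- suppressMessages(annotate_project(pred, fx$dictionary,
                                              match_config()))
    for (mode in c("exact_span", "overlap")) {
      fwd <- compare_projects(pred, fx$project, mode)
      expect_equal(fwd$tp + fwd$fn, n_annotations(fx$project))
      expect_equal(fwd$tp + fwd$fp, n_annotations(pred))
      # per-identifier tallies sum to the overall counts
      expect_equal(sum(fwd$per_identifier$tp), fwd$tp)
      expect_equal(sum(fwd$per_identifier$fp), fwd$fp)
      expect_equal(sum(fwd$per_identifier$fn), fwd$fn)
      rev <- compare_projects(fx$project, pred, mode)
      expect_equal(fwd$precision, rev$recall)
      expect_equal(fwd$recall, rev$precision)
    }
    # exact-span true positives are a subset of overlap true positives
    expect_lte(compare_projects(pred, fx$project, "exact_span")$tp,
               compare_projects(pred, fx$project, "overlap")$tp)
  }
})

test_that("comparison refuses disjoint projects and differing texts", {
  a <- annotation_project("a")
  a <- add_document(a, annotation_record("x", "1", "text one"))
  b <- annotation_project("b")
  b <- add_document(b, annotation_record("x", "2", "text two"))
  expect_error(compare_projects(a, b), "share no")
  b2 <- annotation_project("b2")
  b2 <- add_document(b2, annotation_record("x", "1", "different text"))
  expect_error(compare_projects(a, b2), class = "dictannot_alignment_error")
})

test_that("sampling is seeded, exhaustive at large k, and empty at k = 0", {
  fx <- generate_corpus(corpus_spec(n_documents = 10,
                                    terms_per_document = c(8L, 12L),
                                    seed = 8))
  total <- n_annotations(fx$project)
  expect_gte(total, 80L)
  all_s <- sample_annotations(fx$project, total + 50L, seed = 1)
  expect_equal(nrow(all_s), total)
  expect_equal(nrow(sample_annotations(fx$project, 0L, seed = 1)), 0L)

  s1 <- sample_annotations(fx$project, 10L, seed = 42)
  s2 <- sample_annotations(fx$project, 10L, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_annotations(fx$project, 10L, seed = 43)
  expect_false(identical(s1$begin, s3$begin))
  # context windows cover the denotation
  expect_true(all(mapply(grepl, gsub("([().*+?^$\\[\\]])", "\\\\\\1", s1$covered),
                         s1$context)))
})

test_that("version diffs capture additions, removals and object changes", {
  fx <- generate_corpus(corpus_spec(n_documents = 3, seed = 12))
  pred <- strip_annotations(fx$project)
  pred <- suppressMessages(annotate_project(pred, fx$dictionary, match_config()))
  # v1 = empty pre-annotation state, current = annotated
  d1 <- diff_versions(pred, "v1", "current")
  expect_equal(nrow(d1$added), n_annotations(pred))
  expect_equal(nrow(d1$removed), 0L)
  # a version against itself is empty
  d0 <- diff_versions(pred, "v1", "v1")
  expect_equal(nrow(d0$added) + nrow(d0$removed), 0L)
  # changing one denotation's obj shows up as one removed + one added
  key <- names(pred$records)[1]
  pred2 <- dictannot:::archive_current(pred)  # annotated state becomes v2
  pred2$records[[key]]$denotations$obj[1] <- "CHANGED:1"
  d2 <- diff_versions(pred2, "v2", "current")
  expect_equal(nrow(d2$added), 1L)
  expect_equal(nrow(d2$removed), 1L)
  expect_equal(d2$added$obj, "CHANGED:1")
  expect_error(diff_versions(pred, "v99"), "available")
})
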