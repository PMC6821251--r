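test_that("similarity matches the hand-enumerated bigram oracle", {
  expect_equal(similarity("eclampsia", "eclampsia", 2), 1.0)
  expect_equal(similarity("aaaa", "bbbb", 2), 0.0)
  # padded bigram multisets: 10 bigrams each, 8 shared, all counts 1:
  # cosine = 8 / sqrt(10 * 10) = 0.8
  expect_equal(similarity("eclampsia", "eclampsya", 2), 0.8)
  expect_equal(similarity("eclampsia", "eclampsya", 2),
               similarity("eclampsya", "eclampsia", 2))
})

test_that("the worked title example yields the single expected denotation", {
  title <- pe_title()
  doc <- sequence_title_abstract(title, "", "PubMed", "13184842")
  res <- annotate_text(doc, compile_index(pe_dictionary()), match_config())
  expect_equal(nrow(res), 1L)
  expect_equal(res$obj, "ORPHA:275555")
  covered <- substr(title, res$begin + 1L, res$end)
  expect_equal(covered, "pre-eclamptic toxemia")
  expect_equal(res$end - res$begin, 21L)
  # character-count oracle over the printed title
  m <- stringi::stri_locate_first_fixed(title, "pre-eclamptic toxemia")
  expect_equal(res$begin, m[1] - 1L)
  expect_equal(res$end, m[2])
})

test_that("repeated mentions produce one denotation per occurrence", {
  d <- dictionary("one", data.frame(label = "eclampsia", identifier = "X:1"))
  doc <- document("local", "t", "eclampsia eclampsia")
  res <- annotate_text(doc, compile_index(d), match_config())
  expect_equal(res$begin, c(0L, 10L))
  expect_equal(res$end, c(9L, 19L))
  expect_equal(res$obj, c("X:1", "X:1"))
  expect_equal(res$id, c("T1", "T2"))
})

test_that("an empty dictionary annotates nothing", {
  doc <- document("local", "t", "any text at all")
  res <- annotate_text(doc, compile_index(dictionary("empty")), match_config())
  expect_equal(nrow(res), 0L)
})

test_that("exact-mode soundness: every covered span normalizes to a matching label", {
  fx <- generate_corpus(corpus_spec(n_documents = 10, variant_rate = 0.3,
                                    seed = 101))
  idx <- compile_index(fx$dictionary)
  cfg <- match_config(longest_only = FALSE)
  for (key in names(fx$project$records)) {
    r <- fx$project$records[[key]]
    res <- annotate_text(r, idx, cfg)
    for (i in seq_len(nrow(res))) {
      norm <- normalize_label(substr(r$text, res$begin[i] + 1L, res$end[i]),
                              fx$dictionary$profile)
      expect_true(res$obj[i] %in% lookup_exact(idx, norm))
    }
  }
})

test_that("approximate-mode soundness: similarity to some label of obj meets the threshold", {
  fx <- generate_corpus(corpus_spec(n_documents = 8, variant_rate = 0.4,
                                    seed = 202))
  d <- fx$dictionary
  idx <- compile_index(d)
  cfg <- match_config(mode = "approximate", threshold = 0.85,
                      longest_only = FALSE)
  for (key in names(fx$project$records)) {
    r <- fx$project$records[[key]]
    res <- annotate_text(r, idx, cfg)
    for (i in seq_len(nrow(res))) {
      norm <- normalize_label(substr(r$text, res$begin[i] + 1L, res$end[i]),
                              d$profile)
      labs <- d$entries$normalized_label[d$entries$identifier == res$obj[i]]
      sims <- vapply(labs, similarity, numeric(1), a = norm,
                     n = d$profile$ngram_n)
      expect_gte(max(sims), 0.85)
    }
  }
})

test_that("annotation equals the brute-force all-substrings oracle", {
  specs <- list(corpus_spec(n_documents = 12, variant_rate = 0, seed = 31),
                corpus_spec(n_documents = 12, variant_rate = 0.4, seed = 32),
                corpus_spec(n_documents = 12, variant_rate = 0.2,
                            ambiguity_rate = 0.3, seed = 33))
  cfgs <- list(match_config(longest_only = FALSE),
               match_config(longest_only = FALSE, emit_all_identifiers = TRUE),
               match_config(mode = "approximate", threshold = 0.85,
                            longest_only = FALSE),
               match_config(mode = "approximate", threshold = 0.7,
                            longest_only = FALSE,
                            emit_all_identifiers = TRUE))
  for (spec in specs) {
    fx <- generate_corpus(spec)
    idx <- compile_index(fx$dictionary)
    for (cfg in cfgs) {
      for (key in names(fx$project$records)) {
        r <- fx$project$records[[key]]
        expect_equal(annotate_text(r, idx, cfg),
                     oracle_annotate(r$text, fx$dictionary, cfg),
                     label = sprintf("%s / %s", key, cfg$mode))
      }
    }
  }
})

test_that("longest_only output is a non-overlapping subset of the full output", {
  fx <- generate_corpus(corpus_spec(n_documents = 10, variant_rate = 0.2,
                                    seed = 44))
  # add a nested label to force genuine overlaps
  d <- add_entry(fx$dictionary, "growth factor", "GENE:0009")
  idx <- compile_index(d)
  saw_overlap_pruned <- FALSE
  for (key in names(fx$project$records)) {
    r <- fx$project$records[[key]]
    all <- annotate_text(r, idx, match_config(longest_only = FALSE))
    kept <- annotate_text(r, idx, match_config(longest_only = TRUE))
    sig <- function(df) paste(df$begin, df$end, df$obj)
    expect_true(all(sig(kept) %in% sig(all)))
    if (nrow(kept) < nrow(all)) saw_overlap_pruned <- TRUE
    if (nrow(kept) > 1L) {
      ord <- kept[order(kept$begin), ]
      gaps <- ord$begin[-1] - ord$end[-nrow(ord)]
      same_span <- ord$begin[-1] == ord$begin[-nrow(ord)] &
        ord$end[-1] == ord$end[-nrow(ord)]
      expect_true(all(gaps >= 0 | same_span))
    }
  }
  expect_true(saw_overlap_pruned)
})

test_that("approximate mode at threshold 1 equals exact mode on fixture corpora", {
  fx <- generate_corpus(corpus_spec(n_documents = 15, variant_rate = 0.3,
                                    seed = 55))
  idx <- compile_index(fx$dictionary)
  for (key in names(fx$project$records)) {
    r <- fx$project$records[[key]]
    expect_equal(
      annotate_text(r, idx, match_config(mode = "approximate", threshold = 1,
                                         longest_only = FALSE)),
      annotate_text(r, idx, match_config(mode = "exact", longest_only = FALSE)))
  }
})

test_that("lowering the threshold never removes a match", {
  fx <- generate_corpus(corpus_spec(n_documents = 10, variant_rate = 0.4,
                                    seed = 66))
  idx <- compile_index(fx$dictionary)
  thresholds <- c(1.0, 0.95, 0.85, 0.7)
  for (key in names(fx$project$records)) {
    r <- fx$project$records[[key]]
    prev <- NULL
    for (t in thresholds) {
      cur <- annotate_text(r, idx, match_config(mode = "approximate",
                                                threshold = t,
                                                longest_only = FALSE))
      if (!is.null(prev)) {
        sig <- function(df) paste(df$begin, df$end, df$obj)
        expect_true(all(sig(prev) %in% sig(cur)))
      }
      prev <- cur
    }
  }
})

test_that("identical spans with multiple identifiers follow the emit policy", {
  d <- dictionary("amb", data.frame(label = c("PE", "PE"),
                                    identifier = c("ORPHA:275555", "HGNC:8893")))
  doc <- document("local", "t", "PE was diagnosed")
  idx <- compile_index(d)
  one <- annotate_text(doc, idx, match_config())
  expect_equal(one$obj, "HGNC:8893")   # lexicographically smallest
  both <- annotate_text(doc, idx, match_config(emit_all_identifiers = TRUE))
  expect_setequal(both$obj, c("HGNC:8893", "ORPHA:275555"))
  expect_equal(unique(both$begin), 0L)
})

test_that("a declared profile expectation is enforced against the index", {
  d <- pe_dictionary()
  idx <- compile_index(d)
  cfg <- match_config(profile = normalization_profile(stemming = TRUE))
  expect_error(annotate_text(document("local", "t", "x"), idx, cfg),
               class = "dictannot_config_error")
})

test_that("batch annotation archives versions and re-runs are reproducible", {
  fx <- generate_corpus(corpus_spec(n_documents = 3, seed = 77))
  pred <- strip_annotations(fx$project)
  p1 <- suppressMessages(annotate_project(pred, fx$dictionary, match_config()))
  expect_equal(length(p1$versions), 1L)   # version counter += 1 per run
  expect_gt(n_annotations(p1), 0L)
  p2 <- suppressMessages(annotate_project(p1, fx$dictionary, match_config()))
  expect_equal(length(p2$versions), 2L)
  for (key in names(p2$records))
    expect_identical(p2$records[[key]]$denotations,
                     p1$records[[key]]$denotations)

  empty <- suppressMessages(annotate_project(annotation_project("none"),
                                             fx$dictionary, match_config()))
  expect_equal(attr(empty, "job_report")$documents, 0L)
})
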