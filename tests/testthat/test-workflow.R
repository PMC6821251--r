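test_that("an unchanged dictionary reproduces the previous iteration exactly", {
  fx <- generate_corpus(corpus_spec(n_documents = 5, seed = 61))
  pred <- strip_annotations(fx$project)
  it1 <- suppressMessages(run_iteration(pred, fx$dictionary,
                                        reference = fx$project))
  it2 <- suppressMessages(run_iteration(it1$project, fx$dictionary,
                                        reference = fx$project))
  expect_equal(it2$record$n_annotations, it1$record$n_annotations)
  d <- diff_versions(it2$project, "v2", "current")  # v2 = result of it1
  expect_equal(nrow(d$added) + nrow(d$removed), 0L)
})

test_that("deleting a planted noisy entry drives fp to zero at unchanged recall", {
  fx <- generate_corpus(corpus_spec(n_documents = 6, seed = 62))
  noisy <- plant_noise(fx$dictionary, fx$project, 2L, seed = 3)
  entries <- attr(noisy, "noise_entries")
  pred <- strip_annotations(fx$project)

  it1 <- suppressMessages(run_iteration(pred, noisy, reference = fx$project))
  expect_gt(it1$record$metrics$fp, 0L)
  expect_equal(it1$record$metrics$recall, 1.0)

  script <- data.frame(op = "delete", label = entries$label,
                       identifier = entries$identifier,
                       stringsAsFactors = FALSE)
  cleaned <- apply_change_script(noisy, script)
  it2 <- suppressMessages(run_iteration(it1$project, cleaned,
                                        reference = fx$project,
                                        changes = attr(cleaned, "changes")))
  expect_equal(it2$record$metrics$fp, 0L)
  expect_equal(it2$record$metrics$precision, 1.0)
  expect_equal(it2$record$metrics$recall, it1$record$metrics$recall)
  expect_gt(it1$record$metrics$precision, 0)
  expect_gt(it2$record$metrics$precision, it1$record$metrics$precision)
  # fewer annotations after noise reduction, as the loop intends
  expect_lt(it2$record$n_annotations, it1$record$n_annotations)
})

test_that("adding a withheld synonym strictly raises recall and annotation count", {
  fx <- generate_corpus(corpus_spec(n_documents = 8, seed = 63))
  planted <- unique(fx$plant_log$original_label)
  synonyms <- fx$dictionary$entries$label[!fx$dictionary$entries$label %in%
                                          default_vocabulary()$label[default_vocabulary()$canonical]]
  withheld <- intersect(planted, synonyms)[1]
  expect_false(is.na(withheld))
  wid <- fx$dictionary$entries$identifier[fx$dictionary$entries$label == withheld]
  incomplete <- delete_entry(fx$dictionary, withheld, wid)

  pred <- strip_annotations(fx$project)
  it1 <- suppressMessages(run_iteration(pred, incomplete,
                                        reference = fx$project))
  expect_lt(it1$record$metrics$recall, 1.0)

  restored <- add_entry(incomplete, withheld, wid)
  it2 <- suppressMessages(run_iteration(it1$project, restored,
                                        reference = fx$project,
                                        changes = list(attr(restored, "change"))))
  expect_gt(it2$record$metrics$recall, it1$record$metrics$recall)
  expect_gt(it2$record$n_annotations, it1$record$n_annotations)
})

test_that("iteration records log provenance and every version is reachable", {
  fx <- generate_corpus(corpus_spec(n_documents = 4, seed = 64))
  pred <- strip_annotations(fx$project)
  res <- suppressMessages(run_loop(
    pred, fx$dictionary, scripts = list(
      data.frame(op = "add", label = "PE", identifier = "DIS:0001",
                 stringsAsFactors = FALSE)),
    reference = fx$project))
  expect_length(res$records, 2L)
  expect_equal(vapply(res$records, `[[`, integer(1), "iteration"), 1:2)
  expect_equal(res$records[[1]]$n_entries, n_entries(fx$dictionary))
  expect_equal(res$records[[2]]$n_entries, n_entries(fx$dictionary) + 1L)
  expect_equal(res$records[[2]]$changes[[1]]$status, "added")
  # every archived version is named by some iteration record
  logged <- vapply(res$project$log, `[[`, character(1), "archived_as")
  tags <- vapply(res$project$versions, `[[`, character(1), "tag")
  expect_true(all(tags %in% logged))
  # without a reference, the record carries a sample instead of metrics
  s <- suppressMessages(run_iteration(strip_annotations(fx$project),
                                      fx$dictionary, sample_k = 5L))
  expect_null(s$record$metrics)
  expect_equal(nrow(s$record$sample), 5L)
})

test_that("replaying the same change script reproduces byte-identical annotations", {
  run_once <- function() {
    fx <- generate_corpus(corpus_spec(n_documents = 5, seed = 65))
    noisy <- plant_noise(fx$dictionary, fx$project, 2L, seed = 9)
    entries <- attr(noisy, "noise_entries")
    script <- data.frame(op = "delete", label = entries$label,
                         identifier = entries$identifier,
                         stringsAsFactors = FALSE)
    res <- suppressMessages(run_loop(strip_annotations(fx$project), noisy,
                                     scripts = list(script),
                                     reference = fx$project))
    serialize(lapply(res$project$records, `[[`, "denotations"), NULL,
              version = 2)
  }
  expect_identical(run_once(), run_once())
})

test_that("scripted noise reduction ends with fewer annotations than it started", {
  fx <- generate_corpus(corpus_spec(n_documents = 6, seed = 66))
  noisy <- plant_noise(fx$dictionary, fx$project, 3L, seed = 4)
  entries <- attr(noisy, "noise_entries")
  script <- data.frame(op = "delete", label = entries$label,
                       identifier = entries$identifier,
                       stringsAsFactors = FALSE)
  res <- suppressMessages(run_loop(strip_annotations(fx$project), noisy,
                                   scripts = list(script),
                                   reference = fx$project))
  first <- res$records[[1]]$n_annotations
  final <- res$records[[length(res$records)]]$n_annotations
  expect_lt(final, first)
})
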