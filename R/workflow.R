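# the revise-and-reannotate loop: run one iteration (annotate, benchmark or
# sample, log provenance), apply scripted dictionary changes, repeat

#' Run one iteration of the dictionary-refinement loop
#'
#' One sprint of the agile annotation cycle: annotate the project with the
#' current dictionary (archiving the previous annotation state as a new
#' version), then either benchmark against a reference project (when one
#' exists) or draw a seeded random sample for manual inspection (when none
#' does). An iteration record — dictionary name and entry count, matching
#' configuration, annotation count, metrics or sample, and the dictionary
#' changes since the previous iteration — is appended to the project log.
#'
#' @param project an [annotation_project()].
#' @param d the current [dictionary()].
#' @param cfg a [match_config()].
#' @param reference optional reference [annotation_project()] with gold
#'   denotations.
#' @param sample_k sample size drawn when no reference exists (default 10).
#' @param seed seed for the inspection sample.
#' @param changes optional list of change records (from
#'   [add_entry()]/[delete_entry()] or [apply_change_script()]) applied to
#'   the dictionary since the previous iteration, stored for provenance.
#' @return A list with elements `project` (the annotated project, log
#'   appended) and `record` (the iteration record).
#' @export
run_iteration <- function(project, d, cfg = match_config(), reference = NULL,
                          sample_k = 10L, seed = 1L, changes = NULL) {
  stopifnot(inherits(project, "annotation_project"), inherits(d, "dictionary"))
  project <- annotate_project(project, d, cfg)
  report <- attr(project, "job_report")
  record <- list(
    iteration = length(project$log) + 1L,
    dictionary = d$name,
    n_entries = n_entries(d),
    config = unclass(cfg),
    n_annotations = n_annotations(project),
    archived_as = report$archived_as,
    changes = changes)
  if (!is.null(reference)) {
    cmp <- compare_projects(project, reference, mode = "exact_span")
    record$metrics <- list(tp = cmp$tp, fp = cmp$fp, fn = cmp$fn,
                           precision = cmp$precision, recall = cmp$recall,
                           f1 = cmp$f1)
    record$comparison <- cmp
  } else {
    record$sample <- sample_annotations(project, sample_k, seed)
  }
  project$log[[length(project$log) + 1L]] <- record[setdiff(names(record),
                                                            "comparison")]
  list(project = project, record = record)
}

#' Apply a dictionary change script
#'
#' A change script is an append-only list of add/delete operations — the
#' reproducible, diffable form of "modify the dictionary" between loop
#' iterations. Each row is applied in order via [add_entry()] or
#' [delete_entry()]; the collected change records are attached as attribute
#' `"changes"`.
#'
#' @param d a [dictionary()].
#' @param script data frame with character columns `op` (`"add"` or
#'   `"delete"`), `label`, `identifier`.
#' @return The revised dictionary with attribute `"changes"` (list of change
#'   records).
#' @export
apply_change_script <- function(d, script) {
  stopifnot(inherits(d, "dictionary"), is.data.frame(script),
            all(c("op", "label", "identifier") %in% names(script)))
  changes <- list()
  for (i in seq_len(nrow(script))) {
    op <- script$op[i]
    d <- switch(op,
      add = add_entry(d, script$label[i], script$identifier[i]),
      delete = delete_entry(d, script$label[i], script$identifier[i]),
      abort_validation(sprintf("unknown change-script op '%s' (row %d)", op, i)))
    changes[[length(changes) + 1L]] <- attr(d, "change")
  }
  attr(d, "changes") <- changes
  d
}

#' Read a change script from a TSV file
#'
#' Three tab-separated columns per non-blank, non-comment line: `op`
#' (`add`/`delete`), `label`, `identifier`.
#'
#' @param path path to the script file.
#' @return A change-script data frame for [apply_change_script()].
#' @export
read_change_script <- function(path) {
  if (!is_string(path) || !file.exists(path))
    abort_user(sprintf("change script not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(stri_trim_both(lines)) &
                 !startsWith(stri_trim_both(lines), "#")]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      abort_user(sprintf("change-script line has fewer than 3 fields: %s", ln))
    data.frame(op = f[1], label = f[2], identifier = f[3],
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(op = character(), label = character(),
               identifier = character(), stringsAsFactors = FALSE)
}

#' Replay the refinement loop from scripted dictionary changes
#'
#' Runs an initial iteration with the starting dictionary, then one further
#' iteration per change script, applying each script before re-annotating.
#' With fixed seeds the whole replay is deterministic: identical inputs
#' reproduce identical final annotations.
#'
#' @param project an [annotation_project()].
#' @param d the starting [dictionary()].
#' @param cfg a [match_config()].
#' @param scripts list of change-script data frames, one per revision round
#'   (may be empty).
#' @param reference optional reference project for benchmarking.
#' @param sample_k,seed passed to [run_iteration()].
#' @return A list with `project`, `dictionary` (final state) and `records`
#'   (one iteration record per round).
#' @export
run_loop <- function(project, d, cfg = match_config(), scripts = list(),
                     reference = NULL, sample_k = 10L, seed = 1L) {
  res <- run_iteration(project, d, cfg, reference, sample_k, seed)
  records <- list(res$record)
  project <- res$project
  for (script in scripts) {
    d <- apply_change_script(d, script)
    res <- run_iteration(project, d, cfg, reference, sample_k, seed,
                         changes = attr(d, "changes"))
    project <- res$project
    records[[length(records) + 1L]] <- res$record
  }
  list(project = project, dictionary = d, records = records)
}
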