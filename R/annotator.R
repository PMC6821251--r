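# dictionary-based annotation of documents under a configurable matching
# criterion

# token: a run of letters/digits, with internal hyphens kept word-internal
# ("pre-eclamptic" is one token)
TOKEN_REGEX <- "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*"

token_spans <- function(text) {
  m <- stri_locate_all_regex(text, TOKEN_REGEX)[[1]]
  if (nrow(m) == 1L && is.na(m[1, 1])) m <- m[0, , drop = FALSE]
  m   # 1-based inclusive start/end
}

#' Matching configuration
#'
#' Fixes the matching criterion used by [annotate_text()]: exact matching
#' compares normalized candidate substrings against the index's exact map;
#' approximate matching retrieves candidate labels through the character
#' n-gram inverted index and accepts those with n-gram cosine
#' [similarity()] at or above `threshold`.
#'
#' @param mode `"exact"` or `"approximate"`.
#' @param threshold similarity threshold in `[0, 1]` for approximate mode
#'   (default 0.85).
#' @param longest_only when `TRUE` (default), overlapping matches are
#'   resolved longest-first (ties: leftmost) and the output is pairwise
#'   non-overlapping; when `FALSE` all matches are returned.
#' @param token_boundary_required when `TRUE` (default) candidate substrings
#'   are aligned to token boundaries.
#' @param max_candidate_tokens maximum candidate length in tokens
#'   (default 10).
#' @param emit_all_identifiers when a span matches a label carried by several
#'   identifiers: emit one denotation per identifier (`TRUE`) or only the
#'   lexicographically smallest identifier (`FALSE`, default).
#' @param profile optional [normalization_profile()] the index is expected to
#'   have been compiled under; a mismatch raises a configuration error.
#' @return An object of class `match_config`.
#' @export
match_config <- function(mode = c("exact", "approximate"), threshold = 0.85,
                         longest_only = TRUE, token_boundary_required = TRUE,
                         max_candidate_tokens = 10L,
                         emit_all_identifiers = FALSE, profile = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    abort_validation("`threshold` must be a number in [0, 1]")
  if (!is_count(max_candidate_tokens) || max_candidate_tokens < 1)
    abort_validation("`max_candidate_tokens` must be an integer >= 1")
  stopifnot(is_flag(longest_only), is_flag(token_boundary_required),
            is_flag(emit_all_identifiers))
  if (!is.null(profile)) stopifnot(inherits(profile, "norm_profile"))
  structure(list(mode = mode, threshold = threshold,
                 longest_only = longest_only,
                 token_boundary_required = token_boundary_required,
                 max_candidate_tokens = as.integer(max_candidate_tokens),
                 emit_all_identifiers = emit_all_identifiers,
                 profile = profile),
            class = "match_config")
}

#' @export
print.match_config <- function(x, ...) {
  cat(sprintf(
    "<match_config> mode=%s threshold=%.2f longest_only=%s token_boundary=%s max_tokens=%d all_ids=%s\n",
    x$mode, x$threshold, x$longest_only, x$token_boundary_required,
    x$max_candidate_tokens, x$emit_all_identifiers))
  invisible(x)
}

# identifiers matching one normalized candidate string, per config
match_candidate <- function(norm, index, cfg) {
  if (!nzchar(norm)) return(character(0))
  if (cfg$mode == "exact") return(lookup_exact(index, norm))
  lis <- candidate_labels(index, norm)
  if (length(lis) == 0L) return(character(0))
  ids <- character(0)
  for (li in lis) {
    lab <- index$labels[li]
    if (similarity(norm, lab, index$ngram_n) >= cfg$threshold)
      ids <- c(ids, lookup_exact(index, lab))
  }
  sort_radix(unique(ids))
}

#' Annotate a document with a dictionary index
#'
#' Scans candidate substrings of the document (token-boundary-aligned spans
#' of up to `max_candidate_tokens` tokens by default), normalizes each under
#' the index's profile and matches it against the dictionary per the
#' [match_config()]. Output denotations are sorted by (begin, end, obj) and
#' assigned ids `"T1"`, `"T2"`, ... in that order; with `longest_only` the
#' result is pairwise non-overlapping, selected longest-first with leftmost
#' winning ties (identical spans carrying different identifiers are kept
#' together when `emit_all_identifiers`).
#'
#' @param doc a [document()] (anything with a `$text` field works).
#' @param index a [compile_index()] result.
#' @param cfg a [match_config()].
#' @return A [denotations()] data frame; offsets are 0-based half-open into
#'   `doc$text`.
#' @examples
#' d <- dictionary("pe", data.frame(
#'   label = c("Pre-eclampsia", "pre-eclamptic toxemia"),
#'   identifier = "ORPHA:275555"))
#' doc <- document("PubMed", "13184842", paste0(
#'   "Individual blood differences in relation to pregnancy, with special ",
#'   "reference to the pathogenesis of pre-eclamptic toxemia."))
#' annotate_text(doc, compile_index(d), match_config())
#' @export
annotate_text <- function(doc, index, cfg = match_config()) {
  stopifnot(inherits(index, "lookup_index"), inherits(cfg, "match_config"))
  if (!is.null(cfg$profile) && !identical(unclass(cfg$profile),
                                          unclass(index$profile)))
    abort_user("index normalization profile does not match the one required by the matching configuration",
               class = "dictannot_config_error")
  text <- doc$text
  stopifnot(is_string(text))
  if (length(index$labels) == 0L) return(empty_denotations())

  spans <- candidate_spans(text, cfg, index)
  if (nrow(spans) == 0L) return(empty_denotations())

  rows <- vector("list", nrow(spans))
  for (k in seq_len(nrow(spans))) {
    s <- spans[k, 1]; e <- spans[k, 2]          # 1-based inclusive
    norm <- normalize_label(stri_sub(text, s, e), index$profile)
    ids <- match_candidate(norm, index, cfg)
    if (length(ids) == 0L) next
    if (!cfg$emit_all_identifiers) ids <- ids[1L]  # smallest, already sorted
    rows[[k]] <- data.frame(begin = s - 1L, end = e, obj = ids,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df) || nrow(df) == 0L) return(empty_denotations())
  df <- df[!duplicated(paste(df$begin, df$end, df$obj)), , drop = FALSE]
  if (cfg$longest_only) df <- select_longest(df)
  df$id <- ""
  finalize_denotations(df)
}

# candidate (start, end) 1-based inclusive character spans
candidate_spans <- function(text, cfg, index) {
  if (cfg$token_boundary_required) {
    toks <- token_spans(text)
    nt <- nrow(toks)
    if (nt == 0L) return(matrix(integer(0), ncol = 2))
    # in exact mode a candidate with more tokens than the longest label can
    # never match, so the scan window can be tightened without changing the
    # result; approximate mode keeps the configured window
    win <- if (cfg$mode == "exact")
      min(cfg$max_candidate_tokens, max(1L, index$max_label_tokens))
    else cfg$max_candidate_tokens
    out <- vector("list", nt)
    for (i in seq_len(nt)) {
      js <- i:min(nt, i + win - 1L)
      out[[i]] <- cbind(rep(unname(toks[i, 1]), length(js)),
                        unname(toks[js, 2]))
    }
    m <- do.call(rbind, out)
    dimnames(m) <- NULL
    m
  } else {
    # free spans: every substring whose length is within the range of label
    # lengths (approximate mode widens the range by the n-gram slack)
    lens <- stri_length(index$labels)
    lo <- max(1L, min(lens)); hi <- max(lens)
    if (cfg$mode == "approximate") {
      lo <- max(1L, lo - 2L); hi <- hi + 2L
    }
    n <- stri_length(text)
    out <- list()
    for (s in seq_len(n)) {
      es <- (s + lo - 1L):min(n, s + hi - 1L)
      es <- es[es >= s]
      if (length(es)) out[[length(out) + 1L]] <- cbind(rep(s, length(es)), es)
    }
    if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
  }
}

# longest-leftmost selection of pairwise non-overlapping spans; identical
# spans (differing only in obj) stand or fall together
select_longest <- function(df) {
  spans <- unique(df[, c("begin", "end")])
  spans <- spans[order_radix(-(spans$end - spans$begin), spans$begin), ,
                 drop = FALSE]
  kept <- spans[0, , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    b <- spans$begin[i]; e <- spans$end[i]
    if (nrow(kept) == 0L || all(e <= kept$begin | b >= kept$end))
      kept <- rbind(kept, spans[i, , drop = FALSE])
  }
  key <- paste(df$begin, df$end)
  df[key %in% paste(kept$begin, kept$end), , drop = FALSE]
}

#' Annotate every document of a project
#'
#' Compiles an index from the dictionary and annotates each document of the
#' project under the same matching configuration. The project's previous
#' annotations are archived as a new version (tagged `"v1"`, `"v2"`, ... in
#' order), never destroyed, and the project's provenance is updated to name
#' the dictionary and configuration that produced the current state. A job
#' report (documents processed/failed, denotations produced, version tag
#' assigned to the archive) is attached as attribute `"job_report"`.
#'
#' A failure on a single document is recorded in the report and the document
#' skipped; the job fails only if every document fails.
#'
#' @param project an [annotation_project()].
#' @param d a [dictionary()].
#' @param cfg a [match_config()].
#' @return The annotated project.
#' @export
annotate_project <- function(project, d, cfg = match_config()) {
  stopifnot(inherits(project, "annotation_project"), inherits(d, "dictionary"))
  index <- compile_index(d)
  project <- archive_current(project)

  keys <- names(project$records)
  failures <- character(0)
  n_denot <- 0L
  for (key in keys) {
    rec <- project$records[[key]]
    res <- tryCatch(annotate_text(rec, index, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", key, conditionMessage(res)))
      next
    }
    project$records[[key]]$denotations <- res
    n_denot <- n_denot + nrow(res)
  }
  if (length(keys) > 0L && length(failures) == length(keys))
    abort_user(paste0("annotation failed for every document:\n",
                      paste(failures, collapse = "\n")))
  project$provenance <- list(dictionary = d$name, n_entries = n_entries(d),
                             config = unclass(cfg))
  report <- list(documents = length(keys), failed = length(failures),
                 failures = failures, denotations = n_denot,
                 archived_as = if (length(project$versions))
                   project$versions[[length(project$versions)]]$tag else NA_character_)
  attr(project, "job_report") <- report
  message(sprintf("annotated project '%s': %d documents (%d failed), %d denotations",
                  project$name, report$documents, report$failed, n_denot))
  project
}
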