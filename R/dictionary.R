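#' Create a dictionary of label-identifier pairs
#'
#' A dictionary (lexicon) is a named, ordered collection of entries, each a
#' pair of a surface `label` expected to occur in text and the database or
#' ontology `identifier` it refers to. A label may map to several identifiers
#' and an identifier may have several labels; the identical (label,
#' identifier) pair occurs at most once. Each entry caches the normalization
#' of its label under the dictionary's active normalization profile.
#'
#' @param name dictionary name.
#' @param entries data frame with character columns `label` and `identifier`
#'   (may have zero rows).
#' @param profile a [normalization_profile()].
#' @return An object of class `dictionary`.
#' @examples
#' d <- dictionary("pre_eclampsia",
#'                 data.frame(label = c("Pre-eclampsia", "pre-eclamptic toxemia"),
#'                            identifier = "ORPHA:275555"))
#' n_entries(d)
#' @export
dictionary <- function(name, entries = NULL, profile = normalization_profile()) {
  stopifnot(is_string(name), inherits(profile, "norm_profile"))
  if (is.null(entries))
    entries <- data.frame(label = character(), identifier = character(),
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(entries),
            all(c("label", "identifier") %in% names(entries)))
  entries <- validate_entries(entries)
  entries <- entries[!duplicated(sprintf("%s\r%s", entries$label,
                                         entries$identifier)), , drop = FALSE]
  entries$normalized_label <- normalize_label(entries$label, profile)
  rownames(entries) <- NULL
  structure(list(name = name,
                 entries = entries[, c("label", "identifier", "normalized_label")],
                 profile = profile),
            class = "dictionary")
}

validate_entries <- function(entries) {
  entries$label <- stri_trim_both(as.character(entries$label))
  entries$identifier <- stri_trim_both(as.character(entries$identifier))
  bad_label <- !nzchar(entries$label)
  bad_id <- !nzchar(entries$identifier) |
    stri_detect_regex(entries$identifier, "\\s")
  if (any(bad_label))
    abort_validation("entry labels must be non-empty after trimming")
  if (any(bad_id))
    abort_validation("entry identifiers must be non-empty and contain no whitespace")
  entries
}

#' Number of entries in a dictionary
#' @param d a [dictionary()].
#' @return Integer entry count.
#' @export
n_entries <- function(d) {
  stopifnot(inherits(d, "dictionary"))
  nrow(d$entries)
}

#' @export
print.dictionary <- function(x, ...) {
  cat(sprintf("<dictionary> %s: %d entries, %d identifiers\n",
              x$name, nrow(x$entries), length(unique(x$entries$identifier))))
  invisible(x)
}

#' Load a dictionary from a tab-separated file
#'
#' The file dialect is two (or more) tab-separated columns — column 1 the
#' label, column 2 the identifier — with blank lines and `#`-prefixed comment
#' lines skipped. Duplicate (label, identifier) pairs are dropped; malformed
#' lines (fewer than two columns, empty label, identifier containing
#' whitespace) are skipped. A load report (lines read, entries kept,
#' duplicates dropped, malformed skipped) is attached as attribute
#' `"load_report"`.
#'
#' @param path path to the TSV file.
#' @param name dictionary name; defaults to the file name without extension.
#' @param profile a [normalization_profile()].
#' @return A [dictionary()].
#' @export
load_dictionary <- function(path, name = NULL, profile = normalization_profile()) {
  if (!is_string(path) || !file.exists(path))
    abort_user(sprintf("dictionary file not found: %s", path))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(stri_trim_both(lines)) & !startsWith(stri_trim_both(lines), "#")
  content <- lines[keep]
  fields <- strsplit(content, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 2L && nzchar(stri_trim_both(f[1])) &&
      nzchar(stri_trim_both(f[2])) &&
      !stri_detect_regex(stri_trim_both(f[2]), "\\s")
  }, logical(1))
  labels <- vapply(fields[ok], function(f) stri_trim_both(f[1]), character(1))
  ids <- vapply(fields[ok], function(f) stri_trim_both(f[2]), character(1))
  dup <- duplicated(sprintf("%s\r%s", labels, ids))
  d <- dictionary(name,
                  data.frame(label = labels[!dup], identifier = ids[!dup],
                             stringsAsFactors = FALSE),
                  profile)
  report <- list(lines_read = length(lines),
                 entries_kept = sum(!dup),
                 duplicates_dropped = sum(dup),
                 malformed_skipped = sum(!ok))
  if (report$entries_kept == 0L)
    warning(sprintf("dictionary '%s' loaded with zero valid entries", name))
  message(sprintf(
    "dictionary '%s': %d lines read, %d entries kept, %d duplicates dropped, %d malformed skipped",
    name, report$lines_read, report$entries_kept, report$duplicates_dropped,
    report$malformed_skipped))
  attr(d, "load_report") <- report
  d
}

#' Save a dictionary as a tab-separated file
#'
#' Entries are written sorted by (label, identifier) so repeated saves of the
#' same dictionary are byte-identical and diffs are stable.
#'
#' @param d a [dictionary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(d, path) {
  stopifnot(inherits(d, "dictionary"))
  e <- d$entries[order_radix(d$entries$label, d$entries$identifier), , drop = FALSE]
  writeLines(paste0(e$label, "\t", e$identifier), path, useBytes = FALSE)
  invisible(path)
}

#' Add or delete a dictionary entry
#'
#' `add_entry()` is idempotent on an existing pair; `delete_entry()` of an
#' absent pair is a no-op with a warning. Both return the revised dictionary
#' with a change record (attribute `"change"`) describing the action taken,
#' for loop provenance.
#'
#' @param d a [dictionary()].
#' @param label entry label (non-empty after trimming).
#' @param identifier entry identifier (non-empty, no whitespace).
#' @return The revised dictionary, with attribute `"change"` — a list with
#'   elements `action`, `label`, `identifier`, `status` and `n_entries`.
#' @examples
#' d <- dictionary("demo")
#' d <- add_entry(d, "eclampsia", "DIS:0001")
#' attr(d, "change")$status
#' @export
add_entry <- function(d, label, identifier) {
  stopifnot(inherits(d, "dictionary"))
  probe <- validate_entries(data.frame(label = label, identifier = identifier,
                                       stringsAsFactors = FALSE))
  present <- any(d$entries$label == probe$label &
                 d$entries$identifier == probe$identifier)
  if (present) {
    status <- "already present"
  } else {
    d$entries <- rbind(d$entries, data.frame(
      label = probe$label, identifier = probe$identifier,
      normalized_label = normalize_label(probe$label, d$profile),
      stringsAsFactors = FALSE))
    rownames(d$entries) <- NULL
    status <- "added"
  }
  attr(d, "change") <- list(action = "add", label = probe$label,
                            identifier = probe$identifier, status = status,
                            n_entries = nrow(d$entries))
  d
}

#' @rdname add_entry
#' @export
delete_entry <- function(d, label, identifier) {
  stopifnot(inherits(d, "dictionary"))
  label <- stri_trim_both(as.character(label))
  identifier <- stri_trim_both(as.character(identifier))
  hit <- d$entries$label == label & d$entries$identifier == identifier
  if (!any(hit)) {
    warning(sprintf("entry (%s, %s) not found in dictionary '%s'; nothing deleted",
                    label, identifier, d$name))
    status <- "absent"
  } else {
    d$entries <- d$entries[!hit, , drop = FALSE]
    rownames(d$entries) <- NULL
    status <- "deleted"
  }
  attr(d, "change") <- list(action = "delete", label = label,
                            identifier = identifier, status = status,
                            n_entries = nrow(d$entries))
  d
}
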