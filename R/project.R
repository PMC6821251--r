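# annotation projects: documents with their denotation sets, versioned
# across loop iterations

#' Create an annotation project
#'
#' A project is a named set of documents together with their denotations and
#' an append-only version history. Documents are keyed by
#' `sourcedb/sourceid`; duplicate keys are rejected. Each call to
#' [annotate_project()] archives the pre-existing denotation state as a new
#' version before replacing it, so earlier loop iterations remain available
#' to [diff_versions()].
#'
#' @param name project name.
#' @param documents optional list of [document()]s or annotation records to
#'   add.
#' @return An object of class `annotation_project`.
#' @export
annotation_project <- function(name, documents = list()) {
  stopifnot(is_string(name))
  p <- structure(list(name = name, records = list(), versions = list(),
                      provenance = NULL, log = list()),
                 class = "annotation_project")
  for (doc in documents) p <- add_document(p, doc)
  p
}

#' Add a document to a project
#'
#' @param project an [annotation_project()].
#' @param doc a [document()] or an annotation record
#'   ([annotation_record()]); documents start with an empty denotation set.
#' @param denotations optional [denotations()] table to attach.
#' @return The project with the document added.
#' @export
add_document <- function(project, doc, denotations = NULL) {
  stopifnot(inherits(project, "annotation_project"))
  if (inherits(doc, "dictannot_document"))
    doc <- annotation_record(doc$sourcedb, doc$sourceid, doc$text,
                             if (is.null(denotations)) empty_denotations()
                             else denotations,
                             project = project$name)
  stopifnot(inherits(doc, "annotation_record"))
  if (!is.null(denotations)) doc$denotations <- denotations
  key <- doc_key(doc$sourcedb, doc$sourceid)
  if (key %in% names(project$records))
    abort_validation(sprintf("project '%s' already contains document %s",
                             project$name, key))
  validate_record(doc)
  project$records[[key]] <- doc
  project
}

#' @export
print.annotation_project <- function(x, ...) {
  cat(sprintf("<annotation_project> %s: %d documents, %d denotations, %d archived versions\n",
              x$name, length(x$records), n_annotations(x), length(x$versions)))
  invisible(x)
}

#' Total number of denotations in a project
#' @param project an [annotation_project()].
#' @return Integer count over all documents.
#' @export
n_annotations <- function(project) {
  stopifnot(inherits(project, "annotation_project"))
  sum(vapply(project$records, function(r) nrow(r$denotations), integer(1)))
}

# snapshot the current denotation state as the next archived version
archive_current <- function(project) {
  tag <- paste0("v", length(project$versions) + 1L)
  snap <- lapply(project$records, function(r) r$denotations)
  project$versions[[length(project$versions) + 1L]] <-
    list(tag = tag, provenance = project$provenance, denotations = snap)
  project
}

version_tags <- function(project) {
  vapply(project$versions, function(v) v$tag, character(1))
}

# denotation snapshot for a tag ("current" = live records)
version_denotations <- function(project, tag) {
  if (identical(tag, "current"))
    return(lapply(project$records, function(r) r$denotations))
  tags <- version_tags(project)
  hit <- which(tags == tag)
  if (length(hit) == 0L)
    abort_user(sprintf("unknown version tag '%s'; available: %s", tag,
                       paste(c(tags, "current"), collapse = ", ")))
  project$versions[[hit[1]]]$denotations
}

#' Produce an un-annotated copy of a project
#'
#' Keeps the documents (texts and keys) but drops all denotations, versions
#' and provenance. Useful for deriving a prediction project from a gold
#' corpus before running [annotate_project()].
#'
#' @param project an [annotation_project()].
#' @param name name for the copy (default: `"<name>_pred"`).
#' @return A fresh [annotation_project()].
#' @export
strip_annotations <- function(project, name = paste0(project$name, "_pred")) {
  stopifnot(inherits(project, "annotation_project"))
  out <- annotation_project(name)
  for (key in names(project$records)) {
    r <- project$records[[key]]
    out <- add_document(out, annotation_record(r$sourcedb, r$sourceid, r$text,
                                               project = name))
  }
  out
}
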