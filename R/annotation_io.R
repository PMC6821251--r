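# standoff-annotation interchange: JSON records with text + denotations,
# and the on-disk project layout (one directory per project, one JSON file
# per document, plus a manifest)

#' Construct an annotation document record
#'
#' The per-document unit of the standoff interchange format: the sequenced
#' text plus its denotations, each anchored by 0-based half-open character
#' offsets into that exact text.
#'
#' @param sourcedb,sourceid document source coordinates.
#' @param text the sequenced character sequence.
#' @param denotations a [denotations()] data frame.
#' @param project optional owning project name.
#' @param version_tag optional version tag.
#' @return An object of class `annotation_record`.
#' @export
annotation_record <- function(sourcedb, sourceid, text,
                              denotations = empty_denotations(),
                              project = NULL, version_tag = NULL) {
  stopifnot(is_string(sourcedb), is_string(sourceid), is_string(text))
  rec <- structure(list(sourcedb = sourcedb, sourceid = sourceid, text = text,
                        denotations = denotations, project = project,
                        version_tag = version_tag),
                   class = "annotation_record")
  validate_record(rec)
  rec
}

#' Validate an annotation record
#'
#' Checks the record invariants: denotation ids unique within the record,
#' every span within `[0, nchar(text)]` with `begin < end`. Violations raise
#' a validation error naming the offending denotation ids.
#'
#' @param rec an [annotation_record()].
#' @return `rec`, invisibly, when valid.
#' @export
validate_record <- function(rec) {
  stopifnot(inherits(rec, "annotation_record"))
  d <- rec$denotations
  stopifnot(is.data.frame(d), all(c("id", "begin", "end", "obj") %in% names(d)))
  len <- stri_length(rec$text)
  dup <- unique(d$id[duplicated(d$id)])
  if (length(dup))
    abort_validation(sprintf("duplicate denotation id(s) in %s/%s: %s",
                             rec$sourcedb, rec$sourceid,
                             paste(dup, collapse = ", ")))
  bad <- d$begin < 0 | d$end > len | d$begin >= d$end
  if (any(bad))
    abort_validation(sprintf(
      "denotation span(s) out of bounds in %s/%s (text length %d): %s",
      rec$sourcedb, rec$sourceid, len,
      paste(sprintf("%s [%d,%d)", d$id[bad], d$begin[bad], d$end[bad]),
            collapse = ", ")))
  invisible(rec)
}

#' @export
print.annotation_record <- function(x, ...) {
  cat(sprintf("<annotation_record> %s/%s: %d characters, %d denotations\n",
              x$sourcedb, x$sourceid, stri_length(x$text), nrow(x$denotations)))
  invisible(x)
}

record_to_list <- function(rec) {
  den <- lapply(seq_len(nrow(rec$denotations)), function(i) {
    r <- rec$denotations[i, ]
    list(id = r$id, span = list(begin = r$begin, end = r$end), obj = r$obj)
  })
  out <- list(sourcedb = rec$sourcedb, sourceid = rec$sourceid,
              text = rec$text)
  if (!is.null(rec$project)) out$project <- rec$project
  if (!is.null(rec$version_tag)) out$version_tag <- rec$version_tag
  out$denotations <- den
  out
}

list_to_record <- function(x, where = "input") {
  for (key in c("text", "denotations"))
    if (is.null(x[[key]]))
      abort_validation(sprintf("%s: missing required key '%s'", where, key))
  den <- x$denotations
  rows <- lapply(seq_along(den), function(i) {
    dn <- den[[i]]
    if (is.null(dn$id) || is.null(dn$span) || is.null(dn$obj) ||
        is.null(dn$span$begin) || is.null(dn$span$end))
      abort_validation(sprintf(
        "%s: denotation %d lacks id/span{begin,end}/obj", where, i))
    data.frame(id = as.character(dn$id), begin = as.integer(dn$span$begin),
               end = as.integer(dn$span$end), obj = as.character(dn$obj),
               stringsAsFactors = FALSE)
  })
  d <- if (length(rows)) do.call(rbind, rows) else empty_denotations()
  annotation_record(sourcedb = if (is.null(x$sourcedb)) "local" else x$sourcedb,
                    sourceid = if (is.null(x$sourceid)) "unknown" else x$sourceid,
                    text = x$text, denotations = d,
                    project = x$project, version_tag = x$version_tag)
}

#' Write an annotation record as JSON
#'
#' Keys are emitted in a fixed order (`sourcedb`, `sourceid`, `text`,
#' optional `project`/`version_tag`, `denotations` with `id`,
#' `span{begin,end}`, `obj`) and the file is UTF-8, so output is diff-stable
#' and renderable by standoff-annotation viewers.
#'
#' @param rec an [annotation_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path) {
  validate_record(rec)
  json <- jsonlite::toJSON(record_to_list(rec), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an annotation record from JSON
#'
#' Parses and validates: spans are checked against the text length and
#' denotation ids for uniqueness; malformed JSON raises a parse error with
#' the parser's position information.
#'
#' @param path path to a JSON record file.
#' @return An [annotation_record()].
#' @export
read_record <- function(path) {
  if (!is_string(path) || !file.exists(path))
    abort_user(sprintf("record file not found: %s", path))
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  abort_user(sprintf("malformed JSON in %s: %s", path,
                                     conditionMessage(e)),
                             class = "dictannot_parse_error"))
  list_to_record(x, where = path)
}

#' Format a record's denotations as reference tuples
#'
#' One tuple per denotation, in `(begin, end)` order, formatted
#' `"(sourcedb: sourceid, begin-end, obj)"` with the identifier's first
#' namespace colon rendered with a following space (e.g.
#' `"ORPHA: 275555"`).
#'
#' @param rec an [annotation_record()].
#' @return Character vector of tuple strings.
#' @examples
#' rec <- annotation_record("PubMed", "13184842", strrep("x", 123),
#'                          denotations("T1", 101L, 122L, "ORPHA:275555"))
#' to_reference_tuples(rec)
#' @export
to_reference_tuples <- function(rec) {
  validate_record(rec)
  d <- rec$denotations
  if (nrow(d) == 0L) return(character(0))
  d <- d[order_radix(d$begin, d$end, d$obj), , drop = FALSE]
  obj <- sub(":", ": ", d$obj)
  sprintf("(%s: %s, %d-%d, %s)", rec$sourcedb, rec$sourceid, d$begin, d$end, obj)
}

## ---- project store on disk ------------------------------------------------

doc_filename <- function(sourcedb, sourceid) {
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  paste0(safe(sourcedb), "__", safe(sourceid), ".json")
}

denotations_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    list(id = df$id[i], span = list(begin = df$begin[i], end = df$end[i]),
         obj = df$obj[i]))
}

list_to_denotations <- function(x) {
  rows <- lapply(x, function(dn)
    data.frame(id = as.character(dn$id), begin = as.integer(dn$span$begin),
               end = as.integer(dn$span$end), obj = as.character(dn$obj),
               stringsAsFactors = FALSE))
  if (length(rows)) do.call(rbind, rows) else empty_denotations()
}

#' Write a project to a directory
#'
#' On-disk layout: one directory per project holding `manifest.json` (name,
#' document list, provenance, version history, iteration log) and a `docs/`
#' subdirectory with one JSON record per document in the interchange format
#' of [write_record()].
#'
#' @param project an [annotation_project()].
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_project <- function(project, dir) {
  stopifnot(inherits(project, "annotation_project"))
  dir.create(file.path(dir, "docs"), recursive = TRUE, showWarnings = FALSE)
  docs <- lapply(names(project$records), function(key) {
    r <- project$records[[key]]
    list(sourcedb = r$sourcedb, sourceid = r$sourceid,
         file = file.path("docs", doc_filename(r$sourcedb, r$sourceid)))
  })
  versions <- lapply(project$versions, function(v)
    list(tag = v$tag, provenance = v$provenance,
         denotations = lapply(v$denotations, denotations_to_list)))
  manifest <- list(name = project$name, documents = docs,
                   provenance = project$provenance, versions = versions,
                   log = project$log)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(dir, "manifest.json"), useBytes = TRUE)
  for (key in names(project$records)) {
    r <- project$records[[key]]
    r$project <- project$name
    write_record(r, file.path(dir, "docs", doc_filename(r$sourcedb, r$sourceid)))
  }
  invisible(dir)
}

#' Read a project from a directory
#'
#' @param dir directory written by [write_project()].
#' @return An [annotation_project()].
#' @export
read_project <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    abort_user(sprintf("no project manifest at %s", manifest_path))
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  p <- annotation_project(m$name)
  for (doc in m$documents) {
    rec <- read_record(file.path(dir, doc$file))
    p <- add_document(p, rec)
  }
  p$provenance <- m$provenance
  p$versions <- lapply(m$versions, function(v) {
    den <- lapply(v$denotations, list_to_denotations)
    list(tag = v$tag, provenance = v$provenance, denotations = den)
  })
  p$log <- m$log
  p
}
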