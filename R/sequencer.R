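# text sequencers: turn source documents into fixed character sequences so
# that downstream annotation offsets are unambiguous

#' Construct a document
#'
#' A document is an immutable character sequence produced by a sequencer,
#' identified by a source database name and a source id. All annotation
#' offsets produced downstream refer to this exact sequence; offsets are
#' 0-based and half-open.
#'
#' @param sourcedb source database name, e.g. `"PubMed"` or `"local"`.
#' @param sourceid source identifier within `sourcedb`.
#' @param text the character sequence.
#' @param section_offsets optional named list of `c(begin, end)` spans (one
#'   per section) within `[0, nchar(text)]`.
#' @return An object of class `dictannot_document`.
#' @export
document <- function(sourcedb, sourceid, text, section_offsets = NULL) {
  stopifnot(is_string(sourcedb), is_string(sourceid), is_string(text))
  len <- stri_length(text)
  if (!is.null(section_offsets)) {
    for (nm in names(section_offsets)) {
      sp <- section_offsets[[nm]]
      if (sp[1] < 0 || sp[2] > len || sp[1] > sp[2])
        abort_validation(sprintf("section '%s' span [%d,%d) outside [0,%d)",
                                 nm, sp[1], sp[2], len))
    }
  }
  structure(list(sourcedb = sourcedb, sourceid = sourceid, text = text,
                 section_offsets = section_offsets),
            class = "dictannot_document")
}

#' @export
print.dictannot_document <- function(x, ...) {
  cat(sprintf("<document> %s/%s: %d characters\n",
              x$sourcedb, x$sourceid, stri_length(x$text)))
  invisible(x)
}

#' Sequence a title and abstract into a document
#'
#' Joins title and abstract with a single newline (the separator is omitted
#' when the abstract is empty), applies canonical composed Unicode
#' normalization (NFC) once at sequencing time, and records the title and
#' abstract spans as section offsets. Re-sequencing identical input always
#' yields an identical character sequence.
#'
#' @param title title text (non-empty).
#' @param abstract abstract text (may be empty).
#' @param sourcedb,sourceid document source coordinates.
#' @return A [document()] with sections `title` and (when present)
#'   `abstract`.
#' @examples
#' doc <- sequence_title_abstract("AB", "CD", "PubMed", "1")
#' doc$text                      # "AB\nCD"
#' doc$section_offsets$abstract  # c(3, 5)
#' @export
sequence_title_abstract <- function(title, abstract = "", sourcedb = "PubMed",
                                    sourceid) {
  if (!is_string(title) || !nzchar(stri_trim_both(title)))
    abort_validation("title must be a non-empty string")
  if (!is_string(abstract)) abort_validation("abstract must be a string")
  title <- stri_trans_nfc(title)
  abstract <- stri_trans_nfc(abstract)
  nt <- stri_length(title)
  if (nzchar(abstract)) {
    text <- paste0(title, "\n", abstract)
    sections <- list(title = c(0L, nt),
                     abstract = c(nt + 1L, nt + 1L + stri_length(abstract)))
  } else {
    text <- title
    sections <- list(title = c(0L, nt))
  }
  document(sourcedb, sourceid, text, sections)
}

#' Sequence a plain-text file into a document
#'
#' Reads the file as UTF-8, normalizes line endings (CRLF and lone CR) to
#' `"\n"` and applies canonical composed Unicode normalization (NFC). The
#' transformation is deterministic: sequencing the same file twice yields an
#' identical character sequence.
#'
#' @param path path to a UTF-8 text file.
#' @param sourcedb,sourceid document source coordinates.
#' @return A [document()].
#' @export
sequence_plain_text <- function(path, sourcedb = "local", sourceid = NULL) {
  if (!is_string(path) || !file.exists(path))
    abort_user(sprintf("text file not found: %s", path))
  if (is.null(sourceid)) sourceid <- basename(path)
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!stringi::stri_enc_isutf8(txt)) {
    # locate the first undecodable byte for the error message
    off <- 0L
    for (i in seq_along(raw)) {
      piece <- rawToChar(raw[seq_len(i)])
      Encoding(piece) <- "UTF-8"
      if (!stringi::stri_enc_isutf8(piece)) { off <- i - 1L; break }
    }
    abort_user(sprintf("file %s is not valid UTF-8 (first bad byte at offset %d)",
                       path, off))
  }
  txt <- stri_replace_all_regex(txt, "\r\n?", "\n")
  txt <- stri_trans_nfc(txt)
  document(sourcedb, sourceid, txt)
}

#' Read title+abstract records from a delimited file
#'
#' Each non-blank, non-comment line holds three tab-separated fields:
#' `sourceid`, `title`, `abstract` (abstract may be empty). Each record is
#' sequenced with [sequence_title_abstract()].
#'
#' @param path path to the TSV file.
#' @param sourcedb source database name applied to every record.
#' @return A list of [document()] objects.
#' @export
read_title_abstract_records <- function(path, sourcedb = "PubMed") {
  if (!is_string(path) || !file.exists(path))
    abort_user(sprintf("record file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(stri_trim_both(lines)) &
                 !startsWith(stri_trim_both(lines), "#")]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      abort_user(sprintf("record line has fewer than 2 fields: %s", ln))
    sequence_title_abstract(f[2], if (length(f) >= 3L) f[3] else "",
                            sourcedb, f[1])
  })
}
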