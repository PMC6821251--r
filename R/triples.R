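# conversion of annotation projects to RDF triple statements, N-Triples
# export, and the cross-project co-occurrence query

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD_INT <- "http://www.w3.org/2001/XMLSchema#integer"
DEFAULT_BASE <- "http://dictannot.example.org/"

uenc <- function(x) utils::URLencode(x, reserved = TRUE)

node_project <- function(base, name) paste0(base, "projects/", uenc(name))
node_document <- function(base, sourcedb, sourceid)
  paste0(base, "docs/", uenc(sourcedb), "/", uenc(sourceid))
node_annotation <- function(base, project, sourcedb, sourceid, id)
  paste0(node_project(base, project), "/docs/", uenc(sourcedb), "/",
         uenc(sourceid), "/", uenc(id))
node_identifier <- function(base, obj) paste0(base, "id/", uenc(obj))
vocab <- function(base, term) paste0(base, "vocab#", term)

triple_frame <- function(subject = character(), predicate = character(),
                         object = character(), object_type = character()) {
  data.frame(subject = subject, predicate = predicate, object = object,
             object_type = object_type, stringsAsFactors = FALSE)
}

#' Convert a project's annotations to triple statements
#'
#' Emits exactly five statements per denotation — type, part-of (linking to
#' the document node), begin, end (typed integer literals) and denotes
#' (linking to the object identifier's node) — plus a constant overhead of
#' four statements per document (type, sourcedb, sourceid, text) and one per
#' project (type). Node identifiers are deterministic, URL-safe functions of
#' (project, sourcedb, sourceid, denotation id) under `base`; the document
#' node does not depend on the project, so two projects over the same
#' document share it. The annotation node lives under the project node, so
#' project membership is recoverable from the node identifier alone.
#'
#' @param project an [annotation_project()].
#' @param base base URI prefix (default
#'   `"http://dictannot.example.org/"`).
#' @return A data frame of statements with columns `subject`, `predicate`,
#'   `object` and `object_type` (`"uri"`, `"literal"` or `"int"`).
#' @export
annotations_to_triples <- function(project, base = DEFAULT_BASE) {
  stopifnot(inherits(project, "annotation_project"), is_string(base))
  pn <- node_project(base, project$name)
  out <- list(triple_frame(pn, RDF_TYPE, vocab(base, "Project"), "uri"))
  for (key in names(project$records)) {
    r <- project$records[[key]]
    dn <- node_document(base, r$sourcedb, r$sourceid)
    out[[length(out) + 1L]] <- triple_frame(
      subject = c(dn, dn, dn, dn),
      predicate = c(RDF_TYPE, vocab(base, "sourcedb"),
                    vocab(base, "sourceid"), vocab(base, "text")),
      object = c(vocab(base, "Document"), r$sourcedb, r$sourceid, r$text),
      object_type = c("uri", "literal", "literal", "literal"))
    d <- r$denotations
    for (i in seq_len(nrow(d))) {
      an <- node_annotation(base, project$name, r$sourcedb, r$sourceid, d$id[i])
      out[[length(out) + 1L]] <- triple_frame(
        subject = rep(an, 5L),
        predicate = c(RDF_TYPE, vocab(base, "partOf"), vocab(base, "begin"),
                      vocab(base, "end"), vocab(base, "denotes")),
        object = c(vocab(base, "Denotation"), dn, as.character(d$begin[i]),
                   as.character(d$end[i]), node_identifier(base, d$obj[i])),
        object_type = c("uri", "uri", "int", "int", "uri"))
    }
  }
  do.call(rbind, out)
}

escape_ntriples <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_ntriples <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Write triple statements as N-Triples
#'
#' @param triples a statement data frame from [annotations_to_triples()].
#' @param path output `.nt` file path.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(triples, path) {
  stopifnot(is.data.frame(triples))
  obj <- character(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    obj[i] <- switch(triples$object_type[i],
      uri = sprintf("<%s>", triples$object[i]),
      int = sprintf("\"%s\"^^<%s>", triples$object[i], XSD_INT),
      literal = sprintf("\"%s\"", escape_ntriples(triples$object[i])),
      stop("unknown object_type: ", triples$object_type[i]))
  }
  lines <- sprintf("<%s> <%s> %s .", triples$subject, triples$predicate, obj)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read triple statements from an N-Triples file
#'
#' Parses the subset of N-Triples emitted by [write_ntriples()]: URI
#' subjects/predicates, and URI, plain-literal or xsd:integer objects.
#'
#' @param path path to an `.nt` file.
#' @return A statement data frame (see [annotations_to_triples()]).
#' @export
read_ntriples <- function(path) {
  if (!is_string(path) || !file.exists(path))
    abort_user(sprintf("N-Triples file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(stri_trim_both(lines))]
  pat <- "^<([^>]*)> <([^>]*)> (.*) \\.$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    abort_user(sprintf("cannot parse N-Triples line(s): %s",
                       paste(utils::head(lines[bad], 3), collapse = " | ")),
               class = "dictannot_parse_error")
  subject <- vapply(m, `[[`, character(1), 2)
  predicate <- vapply(m, `[[`, character(1), 3)
  objraw <- vapply(m, `[[`, character(1), 4)
  object <- character(length(objraw))
  object_type <- character(length(objraw))
  int_pat <- paste0("^\"([0-9]+)\"\\^\\^<", XSD_INT, ">$")
  for (i in seq_along(objraw)) {
    o <- objraw[i]
    if (startsWith(o, "<")) {
      object[i] <- sub("^<(.*)>$", "\\1", o); object_type[i] <- "uri"
    } else if (grepl(int_pat, o)) {
      object[i] <- sub(int_pat, "\\1", o); object_type[i] <- "int"
    } else {
      object[i] <- unescape_ntriples(sub("^\"(.*)\"$", "\\1", o))
      object_type[i] <- "literal"
    }
  }
  triple_frame(subject, predicate, object, object_type)
}

#' Rule-based sentence segmentation
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and an uppercase letter, with an exception list of common
#' abbreviations (`e.g.`, `i.e.`, `et al.`, `Fig.`, `Dr.`, `vs.`, `cf.`,
#' `No.`, `ca.`). A replaceable component: any function returning 0-based
#' half-open sentence spans can stand in for it in [cooccurrence_query()].
#'
#' @param text the document text.
#' @return A two-column integer matrix of 0-based half-open `(begin, end)`
#'   sentence spans covering the non-empty sentences in order.
#' @export
split_sentences <- function(text) {
  stopifnot(is_string(text))
  n <- stri_length(text)
  if (n == 0L) return(matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("begin", "end"))))
  abbrev <- c("e.g", "i.e", "et al", "al", "fig", "figs", "dr", "vs", "cf",
              "no", "ca", "approx", "etc")
  cand <- stri_locate_all_regex(text, "[.!?]+(?=\\s+\\p{Lu})")[[1]]
  breaks <- integer(0)
  if (!(nrow(cand) == 1L && is.na(cand[1, 1]))) {
    for (i in seq_len(nrow(cand))) {
      before <- stri_sub(text, max(1L, cand[i, 1] - 12L), cand[i, 1] - 1L)
      last <- stri_trans_tolower(
        stri_replace_all_regex(before, ".*?([A-Za-z.]+)$", "$1"))
      last <- sub("\\.$", "", last)
      if (!(last %in% abbrev)) breaks <- c(breaks, cand[i, 2])  # 1-based end
    }
  }
  bounds <- c(0L, breaks, n)
  spans <- matrix(integer(0), ncol = 2)
  for (j in seq_len(length(bounds) - 1L)) {
    b <- bounds[j]; e <- bounds[j + 1L]
    # trim leading whitespace of the sentence
    while (b < e && grepl("^\\s$", stri_sub(text, b + 1L, b + 1L))) b <- b + 1L
    if (b < e) spans <- rbind(spans, c(b, e))
  }
  dimnames(spans) <- list(NULL, c("begin", "end"))
  spans
}

# index of the sentence containing 0-based offset `pos` (first span whose
# half-open interval contains it); NA when none
sentence_of <- function(spans, pos) {
  hit <- which(spans[, 1] <= pos & pos < spans[, 2])
  if (length(hit)) hit[1] else NA_integer_
}

#' Cross-project co-occurrence query over exported triples
#'
#' Answers the one query family the triple export exists for: find every
#' pair of a denotation from project `project_a` and one from `project_b`
#' that co-occur in the same document (scope `"document"`) or the same
#' sentence (scope `"sentence"`, using [split_sentences()]). Operates purely
#' on the statement set — annotation spans, document texts and project
#' membership are all recovered from the triples.
#'
#' @param triples a statement data frame ([annotations_to_triples()] output,
#'   possibly concatenated over several projects, or [read_ntriples()]).
#' @param project_a,project_b project names present in the statement set.
#' @param scope `"document"` or `"sentence"`.
#' @param base base URI prefix used at export time.
#' @return A data frame with one row per co-occurring pair: `sourcedb`,
#'   `sourceid`, `begin_a`, `end_a`, `obj_a`, `begin_b`, `end_b`, `obj_b`
#'   and `context` (the covering sentence for sentence scope, the span from
#'   the first to the last involved character for document scope).
#' @export
cooccurrence_query <- function(triples, project_a, project_b,
                               scope = c("document", "sentence"),
                               base = DEFAULT_BASE) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(triples), is_string(project_a), is_string(project_b))
  known <- triples$subject[triples$predicate == RDF_TYPE &
                           triples$object == vocab(base, "Project")]
  for (nm in c(project_a, project_b))
    if (!(node_project(base, nm) %in% known))
      abort_user(sprintf("project '%s' not present in the triple set", nm))

  anns <- extract_annotations(triples, base)
  docs <- extract_documents(triples, base)
  a <- anns[anns$project_node == node_project(base, project_a), , drop = FALSE]
  b <- anns[anns$project_node == node_project(base, project_b), , drop = FALSE]

  out <- list()
  for (dnode in intersect(unique(a$doc), unique(b$doc))) {
    text <- docs$text[docs$node == dnode]
    sdb <- docs$sourcedb[docs$node == dnode]
    sid <- docs$sourceid[docs$node == dnode]
    da <- a[a$doc == dnode, , drop = FALSE]
    db <- b[b$doc == dnode, , drop = FALSE]
    spans <- if (scope == "sentence") split_sentences(text) else NULL
    for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db))) {
      if (scope == "sentence") {
        si <- sentence_of(spans, da$begin[i])
        sj <- sentence_of(spans, db$begin[j])
        if (is.na(si) || is.na(sj) || si != sj) next
        ctx <- stri_sub(text, spans[si, 1] + 1L, spans[si, 2])
      } else {
        lo <- min(da$begin[i], db$begin[j]); hi <- max(da$end[i], db$end[j])
        ctx <- stri_sub(text, lo + 1L, hi)
      }
      out[[length(out) + 1L]] <- data.frame(
        sourcedb = sdb, sourceid = sid,
        begin_a = da$begin[i], end_a = da$end[i], obj_a = da$obj[i],
        begin_b = db$begin[j], end_b = db$end[j], obj_b = db$obj[j],
        context = ctx, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    sourcedb = character(), sourceid = character(),
    begin_a = integer(), end_a = integer(), obj_a = character(),
    begin_b = integer(), end_b = integer(), obj_b = character(),
    context = character(), stringsAsFactors = FALSE)
  res <- res[order_radix(res$sourcedb, res$sourceid, res$begin_a, res$begin_b,
                         res$obj_a, res$obj_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

extract_annotations <- function(triples, base) {
  is_ann <- triples$predicate == RDF_TYPE &
    triples$object == vocab(base, "Denotation")
  nodes <- triples$subject[is_ann]
  get1 <- function(node, pred) {
    v <- triples$object[triples$subject == node & triples$predicate == pred]
    if (length(v)) v[1] else NA_character_
  }
  idprefix <- paste0(base, "id/")
  df <- data.frame(
    node = nodes,
    doc = vapply(nodes, get1, character(1), vocab(base, "partOf")),
    begin = as.integer(vapply(nodes, get1, character(1), vocab(base, "begin"))),
    end = as.integer(vapply(nodes, get1, character(1), vocab(base, "end"))),
    obj = vapply(nodes, function(nd) {
      v <- get1(nd, vocab(base, "denotes"))
      utils::URLdecode(sub(idprefix, "", v, fixed = TRUE))
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  # annotation nodes live under <project-node>/docs/...
  df$project_node <- sub("/docs/.*$", "", df$node)
  df
}

extract_documents <- function(triples, base) {
  is_doc <- triples$predicate == RDF_TYPE &
    triples$object == vocab(base, "Document")
  nodes <- unique(triples$subject[is_doc])
  get1 <- function(node, pred) {
    v <- triples$object[triples$subject == node & triples$predicate == pred]
    if (length(v)) v[1] else NA_character_
  }
  data.frame(
    node = nodes,
    sourcedb = vapply(nodes, get1, character(1), vocab(base, "sourcedb")),
    sourceid = vapply(nodes, get1, character(1), vocab(base, "sourceid")),
    text = vapply(nodes, get1, character(1), vocab(base, "text")),
    stringsAsFactors = FALSE, row.names = NULL)
}
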