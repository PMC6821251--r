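# shared fixtures and independent oracles used across the suite

# the two-entry pre-eclampsia dictionary and the title it is exercised on
pe_dictionary <- function(profile = normalization_profile()) {
  dictionary("pre_eclampsia",
             data.frame(label = c("Pre-eclampsia", "pre-eclamptic toxemia"),
                        identifier = "ORPHA:275555",
                        stringsAsFactors = FALSE),
             profile)
}

pe_title <- function() {
  paste0("Individual blood differences in relation to pregnancy, with ",
         "special reference to the pathogenesis of pre-eclamptic toxemia.")
}

# brute-force annotation oracle: tests every token-boundary substring (up to
# the configured window) directly against every dictionary entry, with no
# index, no candidate retrieval and no tie-breaking
oracle_annotate <- function(text, dict, cfg) {
  prof <- dict$profile
  toks <- stringi::stri_locate_all_regex(
    text, "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*")[[1]]
  if (nrow(toks) == 1L && is.na(toks[1, 1]))
    toks <- toks[0, , drop = FALSE]
  labs <- dict$entries$normalized_label
  ids_all <- dict$entries$identifier
  rows <- list()
  nt <- nrow(toks)
  for (i in seq_len(nt)) {
    for (j in i:min(nt, i + cfg$max_candidate_tokens - 1L)) {
      s <- unname(toks[i, 1]); e <- unname(toks[j, 2])
      norm <- normalize_label(stringi::stri_sub(text, s, e), prof)
      if (!nzchar(norm)) next
      hit <- if (cfg$mode == "exact") {
        labs == norm
      } else {
        vapply(labs, function(l) similarity(norm, l, prof$ngram_n) >= cfg$threshold,
               logical(1), USE.NAMES = FALSE)
      }
      ids <- sort(unique(ids_all[hit]), method = "radix")
      if (length(ids) == 0L) next
      if (!cfg$emit_all_identifiers) ids <- ids[1]
      rows[[length(rows) + 1L]] <-
        data.frame(begin = s - 1L, end = e, obj = ids,
                   stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(begin = integer(), end = integer(), obj = character(),
               stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$begin, df$end, df$obj, method = "radix"), , drop = FALSE]
  df$id <- if (nrow(df)) paste0("T", seq_len(nrow(df))) else character(0)
  rownames(df) <- NULL
  df[, c("id", "begin", "end", "obj")]
}

# direct in-memory co-occurrence oracle over two projects (the check for the
# query computed over exported triples)
oracle_cooccurrence <- function(project_a, project_b, scope = "document") {
  out <- list()
  for (key in intersect(names(project_a$records), names(project_b$records))) {
    ra <- project_a$records[[key]]; rb <- project_b$records[[key]]
    da <- ra$denotations; db <- rb$denotations
    spans <- if (scope == "sentence") split_sentences(ra$text) else NULL
    for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db))) {
      if (scope == "sentence") {
        si <- which(spans[, 1] <= da$begin[i] & da$begin[i] < spans[, 2])[1]
        sj <- which(spans[, 1] <= db$begin[j] & db$begin[j] < spans[, 2])[1]
        if (is.na(si) || is.na(sj) || si != sj) next
        ctx <- stringi::stri_sub(ra$text, spans[si, 1] + 1L, spans[si, 2])
      } else {
        lo <- min(da$begin[i], db$begin[j]); hi <- max(da$end[i], db$end[j])
        ctx <- stringi::stri_sub(ra$text, lo + 1L, hi)
      }
      out[[length(out) + 1L]] <- data.frame(
        sourcedb = ra$sourcedb, sourceid = ra$sourceid,
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
  res <- res[order(res$sourcedb, res$sourceid, res$begin_a, res$begin_b,
                   res$obj_a, res$obj_b, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# a small two-document project pair sharing texts, annotated from different
# "projects" (disease vs chemical), for triple/co-occurrence tests
make_project_pair <- function() {
  t1 <- "Aspirin reduced the risk. Eclampsia was observed in the cohort."
  t2 <- "Severe eclampsia cases received aspirin during the trial."
  mk <- function(name, spans) {
    p <- annotation_project(name)
    p <- add_document(p, annotation_record("fixtures", "d1", t1, spans$d1,
                                           project = name))
    add_document(p, annotation_record("fixtures", "d2", t2, spans$d2,
                                      project = name))
  }
  loc <- function(text, needle) {
    m <- stringi::stri_locate_first_fixed(text, needle)
    c(m[1] - 1L, m[2])
  }
  a1 <- loc(t1, "Eclampsia"); a2 <- loc(t2, "eclampsia")
  b1 <- loc(t1, "Aspirin"); b2 <- loc(t2, "aspirin")
  disease <- mk("disease", list(
    d1 = denotations("T1", a1[1], a1[2], "DIS:0001"),
    d2 = denotations("T1", a2[1], a2[2], "DIS:0001")))
  chemical <- mk("chemical", list(
    d1 = denotations("T1", b1[1], b1[2], "CHEM:0001"),
    d2 = denotations("T1", b2[1], b2[2], "CHEM:0001")))
  list(disease = disease, chemical = chemical)
}

# random ad-hoc document text built from a word pool that includes
# dictionary surfaces, for oracle-equivalence property tests
random_doc_text <- function(dict, n_words = 40) {
  words <- c(default_filler_pool(), dict$entries$label)
  paste(sample(words, n_words, replace = TRUE), collapse = " ")
}
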