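# synthetic corpus generation: filler text with planted term mentions at
# recorded offsets, gold denotations, a matching dictionary, and a plant log
# -- so annotation, evaluation and the revise-and-reannotate loop are
# testable without any external corpus

#' Default fixture vocabulary
#'
#' A small obstetric/biomedical vocabulary of canonical labels, identifiers
#' and synonyms. Chosen so that no surface is a token-substring of another
#' surface: every false positive or negative in a generated corpus is then
#' attributable to a planted perturbation or noise entry, never to nested
#' labels.
#'
#' @return A data frame with columns `label`, `identifier`, `canonical`.
#' @export
default_vocabulary <- function() {
  data.frame(
    label = c("eclampsia", "gestational toxemia",
              "proteinuria", "albuminuria",
              "hypertension", "elevated blood pressure",
              "placental growth factor", "PGF",
              "fms-like tyrosine kinase", "FLT1",
              "acetylsalicylic acid", "aspirin",
              "amniocentesis",
              "oligohydramnios"),
    identifier = c("DIS:0001", "DIS:0001", "DIS:0002", "DIS:0002",
                   "DIS:0003", "DIS:0003", "GENE:0001", "GENE:0001",
                   "GENE:0002", "GENE:0002", "CHEM:0001", "CHEM:0001",
                   "PROC:0001", "DIS:0004"),
    canonical = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                  TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Default filler word pool
#'
#' Common scientific-prose words used as inter-mention filler. None of them
#' equals any full surface of [default_vocabulary()], so dictionary matches
#' on filler text can only come from deliberately planted noise entries.
#'
#' @return Character vector of filler words.
#' @export
default_filler_pool <- function() {
  c("the", "of", "and", "in", "with", "patients", "study", "observed",
    "levels", "during", "clinical", "samples", "results", "increased",
    "reduced", "analysis", "cohort", "measured", "plasma", "serum",
    "weeks", "after", "before", "between", "among", "showed",
    "significant", "association", "risk", "group", "maternal", "onset",
    "severe", "cases", "controls", "markers", "expression", "tissue")
}

#' Specification for a synthetic corpus
#'
#' @param n_documents number of documents to generate.
#' @param vocabulary data frame with columns `label`, `identifier`,
#'   `canonical` (see [default_vocabulary()]).
#' @param terms_per_document integer range `c(min, max)` of planted mentions
#'   per document.
#' @param ambiguity_rate fraction of planted mentions whose surface is also
#'   registered in the dictionary under a second identifier.
#' @param variant_rate fraction of planted mentions perturbed before
#'   planting (case change, doubled internal whitespace, or a
#'   single-character edit that never crosses a token boundary).
#' @param filler_pool word pool for filler text; must not contain any
#'   vocabulary surface.
#' @param seed integer seed; all generator output is a pure function of the
#'   spec including this seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_documents = 20L, vocabulary = default_vocabulary(),
                        terms_per_document = c(2L, 5L), ambiguity_rate = 0,
                        variant_rate = 0, filler_pool = default_filler_pool(),
                        seed = 1L) {
  stopifnot(is.data.frame(vocabulary),
            all(c("label", "identifier", "canonical") %in% names(vocabulary)))
  if (!is_count(n_documents))
    abort_validation("`n_documents` must be a non-negative integer")
  if (n_documents > 0L && nrow(vocabulary) == 0L)
    abort_validation("vocabulary must be non-empty when n_documents > 0")
  for (rate in list(ambiguity_rate, variant_rate))
    if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
        rate < 0 || rate > 1)
      abort_validation("rates must be numbers in [0, 1]")
  stopifnot(length(terms_per_document) == 2L,
            terms_per_document[1] >= 1L,
            terms_per_document[2] >= terms_per_document[1])
  if (any(filler_pool %in% vocabulary$label))
    abort_validation("filler pool must not contain vocabulary surfaces")
  structure(list(n_documents = as.integer(n_documents),
                 vocabulary = vocabulary,
                 terms_per_document = as.integer(terms_per_document),
                 ambiguity_rate = ambiguity_rate,
                 variant_rate = variant_rate,
                 filler_pool = filler_pool,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

perturb_surface <- function(surface, kind) {
  switch(kind,
    none = surface,
    case = {
      first <- stri_sub(surface, 1L, 1L)
      flipped <- if (first == stri_trans_tolower(first))
        stringi::stri_trans_toupper(first) else stri_trans_tolower(first)
      paste0(flipped, stri_sub(surface, 2L))
    },
    whitespace = {
      sp <- stri_locate_all_regex(surface, " ")[[1]]
      if (nrow(sp) == 0L || is.na(sp[1, 1])) return(perturb_surface(surface, "case"))
      at <- sp[sample.int(nrow(sp), 1L), 1]
      paste0(stri_sub(surface, 1L, at), " ", stri_sub(surface, at + 1L))
    },
    edit = {
      # substitute one interior letter; never touches spaces or hyphens, so
      # tokenization of the perturbed surface is unchanged
      letters_at <- which(strsplit(surface, "", fixed = TRUE)[[1]] %in% letters)
      interior <- letters_at[letters_at > 1L & letters_at < stri_length(surface)]
      if (length(interior) == 0L) return(perturb_surface(surface, "case"))
      at <- interior[sample.int(length(interior), 1L)]
      old <- stri_sub(surface, at, at)
      repl <- sample(setdiff(letters, old), 1L)
      paste0(stri_sub(surface, 1L, at - 1L), repl, stri_sub(surface, at + 1L))
    })
}

#' Generate a synthetic annotated corpus
#'
#' Builds `n_documents` documents of filler sentences with vocabulary
#' mentions planted at recorded offsets, the gold project whose denotations
#' exactly cover the planted (possibly perturbed) surfaces with their true
#' identifiers, the dictionary containing every canonical label and synonym
#' (plus second-identifier entries for ambiguous surfaces), and a plant log
#' recording every mention and perturbation. Fully deterministic per spec.
#'
#' @param spec a [corpus_spec()].
#' @return A list with elements `project` (gold [annotation_project()]),
#'   `dictionary` ([dictionary()]) and `plant_log` (data frame with columns
#'   `sourceid`, `begin`, `end`, `identifier`, `surface`, `original_label`,
#'   `perturbation`).
#' @examples
#' fx <- generate_corpus(corpus_spec(n_documents = 3, seed = 7))
#' fx$project
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  vocab <- spec$vocabulary
  project <- annotation_project("gold")
  log_rows <- list()
  ambiguous_labels <- character(0)

  for (di in seq_len(spec$n_documents)) {
    sourceid <- sprintf("doc%04d", di)
    range <- spec$terms_per_document
    n_terms <- range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
    text <- ""
    dens <- empty_denotations()
    for (ti in seq_len(n_terms)) {
      vi <- sample.int(nrow(vocab), 1L)
      surface <- vocab$label[vi]
      kind <- "none"
      if (spec$variant_rate > 0 && stats::runif(1) < spec$variant_rate)
        kind <- sample(c("case", "whitespace", "edit"), 1L)
      planted <- perturb_surface(surface, kind)
      if (spec$ambiguity_rate > 0 && stats::runif(1) < spec$ambiguity_rate)
        ambiguous_labels <- union(ambiguous_labels, surface)

      pre <- sample(spec$filler_pool, sample(2:5, 1L))
      post <- sample(spec$filler_pool, sample(2:4, 1L))
      pre[1] <- paste0(stringi::stri_trans_toupper(stri_sub(pre[1], 1, 1)),
                       stri_sub(pre[1], 2))
      prefix <- paste0(paste(pre, collapse = " "), " ")
      begin <- stri_length(text) + stri_length(prefix)        # 0-based
      end <- begin + stri_length(planted)
      sentence <- paste0(prefix, planted, " ",
                         paste(post, collapse = " "), ". ")
      text <- paste0(text, sentence)
      dens <- rbind(dens, denotations(sprintf("G%d", ti), begin, end,
                                      vocab$identifier[vi]))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        sourceid = sourceid, begin = begin, end = end,
        identifier = vocab$identifier[vi], surface = planted,
        original_label = surface, perturbation = kind,
        stringsAsFactors = FALSE)
    }
    text <- sub(" $", "", text)
    project <- add_document(project,
                            annotation_record("fixtures", sourceid, text,
                                              dens, project = "gold"))
  }

  entries <- vocab[, c("label", "identifier")]
  if (length(ambiguous_labels)) {
    alt <- data.frame(label = ambiguous_labels,
                      identifier = paste0("ALT:",
                                          sprintf("%04d", seq_along(ambiguous_labels))),
                      stringsAsFactors = FALSE)
    entries <- rbind(entries, alt)
  }
  d <- dictionary("fixture_dictionary", entries)
  plant_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(sourceid = character(), begin = integer(), end = integer(),
               identifier = character(), surface = character(),
               original_label = character(), perturbation = character(),
               stringsAsFactors = FALSE)
  list(project = project, dictionary = d, plant_log = plant_log)
}

#' Plant noise entries into a dictionary
#'
#' Adds entries whose labels are filler words that occur in the project's
#' texts but never inside a gold span and never as an existing dictionary
#' label — so every annotation they produce is a false positive by
#' construction. This is the raw material for replaying the noise-reduction
#' direction of the dictionary-refinement loop.
#'
#' @param d the fixture [dictionary()].
#' @param project the gold [annotation_project()] from [generate_corpus()].
#' @param n_noisy_entries number of noise entries to add.
#' @param seed integer seed for the (deterministic) choice of filler words.
#' @return The dictionary with `n_noisy_entries` added entries (identifiers
#'   `NOISE:0001`, ...); the added entries are recorded in attribute
#'   `"noise_entries"`.
#' @export
plant_noise <- function(d, project, n_noisy_entries, seed = 1L) {
  stopifnot(inherits(d, "dictionary"), inherits(project, "annotation_project"),
            is_count(n_noisy_entries))
  if (n_noisy_entries == 0L) {
    attr(d, "noise_entries") <- data.frame(label = character(),
                                           identifier = character(),
                                           stringsAsFactors = FALSE)
    return(d)
  }
  gold_tokens <- character(0)
  filler_tokens <- character(0)
  for (key in names(project$records)) {
    r <- project$records[[key]]
    toks <- token_spans(r$text)
    den <- r$denotations
    for (i in seq_len(nrow(toks))) {
      b <- toks[i, 1] - 1L; e <- toks[i, 2]    # 0-based half-open
      word <- stri_sub(r$text, toks[i, 1], toks[i, 2])
      in_gold <- nrow(den) > 0L && any(den$begin < e & b < den$end)
      if (in_gold) gold_tokens <- c(gold_tokens, word)
      else filler_tokens <- c(filler_tokens, word)
    }
  }
  norm <- function(x) normalize_label(x, d$profile)
  forbidden <- unique(c(norm(gold_tokens), d$entries$normalized_label))
  candidates <- unique(filler_tokens)
  candidates <- candidates[!(norm(candidates) %in% forbidden)]
  candidates <- sort_radix(candidates)
  if (length(candidates) < n_noisy_entries)
    abort_validation(sprintf(
      "only %d distinct filler words available for %d noise entries",
      length(candidates), n_noisy_entries))
  picked <- with_seed(seed, sample(candidates, n_noisy_entries))
  noise <- data.frame(label = picked,
                      identifier = sprintf("NOISE:%04d", seq_along(picked)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(noise)))
    d <- add_entry(d, noise$label[i], noise$identifier[i])
  attr(d, "noise_entries") <- noise
  d
}
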