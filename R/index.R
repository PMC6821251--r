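# lookup index: exact map + character n-gram inverted index over normalized
# labels

PAD_CHAR <- "\u0001"  # boundary padding; never occurs in normalized text

# padded character n-gram multiset of a string
char_ngrams <- function(x, n) {
  if (n == 1L) {
    if (!nzchar(x)) return(character(0))
    return(strsplit(x, "", fixed = TRUE)[[1]])
  }
  pad <- strrep(PAD_CHAR, n - 1L)
  x2 <- paste0(pad, x, pad)
  len <- stri_length(x2)
  if (len < n) return(character(0))
  starts <- seq_len(len - n + 1L)
  stri_sub(x2, starts, starts + n - 1L)
}

#' Character n-gram cosine similarity
#'
#' Similarity between two normalized strings, computed as the cosine of their
#' character n-gram count vectors, where each string is padded with n-1
#' boundary characters on each side so that word-initial and word-final
#' characters carry positional information. Symmetric; equals 1 exactly when
#' the two n-gram multisets are identical, and 0 when they are disjoint.
#'
#' @param a,b non-empty normalized strings.
#' @param n n-gram order (>= 1).
#' @return A similarity in `[0, 1]`.
#' @examples
#' similarity("eclampsia", "eclampsya", 2)
#' @export
similarity <- function(a, b, n = 2L) {
  stopifnot(is_string(a), nzchar(a), is_string(b), nzchar(b),
            is_count(n), n >= 1)
  ga <- char_ngrams(a, as.integer(n))
  gb <- char_ngrams(b, as.integer(n))
  if (length(ga) == 0L || length(gb) == 0L) return(0)
  ta <- table(ga); tb <- table(gb)
  shared <- intersect(names(ta), names(tb))
  if (length(shared) == 0L) return(0)
  dot <- sum(as.numeric(ta[shared]) * as.numeric(tb[shared]))
  dot / sqrt(sum(as.numeric(ta)^2) * sum(as.numeric(tb)^2))
}

#' Compile a lookup index from a dictionary
#'
#' Builds (a) an exact map from each normalized label to the set of
#' identifiers it denotes, and (b) a character n-gram inverted index over the
#' normalized labels (n from the dictionary's normalization profile), used
#' for approximate candidate retrieval. Labels shorter than 2 characters
#' after normalization are indexed but flagged as high-noise, since
#' one-character labels overwhelmingly generate false positives in literature
#' text.
#'
#' Indexes are plain snapshots of the dictionary: rebuild after
#' [add_entry()]/[delete_entry()].
#'
#' @param d a [dictionary()].
#' @return An object of class `lookup_index`.
#' @export
compile_index <- function(d) {
  stopifnot(inherits(d, "dictionary"))
  e <- d$entries
  labels <- unique(e$normalized_label)
  exact <- new.env(parent = emptyenv(), size = max(16L, length(labels)))
  for (lab in labels) {
    ids <- sort_radix(unique(e$identifier[e$normalized_label == lab]))
    assign(lab, ids, envir = exact)
  }
  ngram <- new.env(parent = emptyenv(), size = max(16L, 4L * length(labels)))
  n <- d$profile$ngram_n
  for (li in seq_along(labels)) {
    for (g in unique(char_ngrams(labels[li], n))) {
      ngram[[g]] <- c(ngram[[g]], li)
    }
  }
  token_counts <- vapply(labels, function(lab) {
    m <- stri_locate_all_regex(lab, TOKEN_REGEX)[[1]]
    if (nrow(m) == 0L || is.na(m[1, 1])) 1L else nrow(m)
  }, integer(1), USE.NAMES = FALSE)
  high_noise <- labels[stri_length(labels) < 2L]
  structure(list(exact = exact, labels = labels, ngram = ngram,
                 ngram_n = n, profile = d$profile,
                 max_label_tokens = if (length(token_counts)) max(token_counts) else 0L,
                 high_noise = high_noise,
                 dictionary_name = d$name,
                 n_entries = nrow(e)),
            class = "lookup_index")
}

#' @export
print.lookup_index <- function(x, ...) {
  cat(sprintf("<lookup_index> dictionary '%s': %d entries, %d normalized labels, %d-gram index%s\n",
              x$dictionary_name, x$n_entries, length(x$labels), x$ngram_n,
              if (length(x$high_noise))
                sprintf(" (%d high-noise short labels)", length(x$high_noise))
              else ""))
  invisible(x)
}

#' Exact lookup of a normalized label
#'
#' @param index a [compile_index()] result.
#' @param normalized a normalized label string.
#' @return Character vector of identifiers (empty when absent).
#' @export
lookup_exact <- function(index, normalized) {
  stopifnot(inherits(index, "lookup_index"))
  if (!is_string(normalized)) return(character(0))
  ids <- get0(normalized, envir = index$exact, inherits = FALSE)
  if (is.null(ids)) character(0) else ids
}

# label indices sharing at least one n-gram with the query string
candidate_labels <- function(index, normalized) {
  grams <- unique(char_ngrams(normalized, index$ngram_n))
  if (length(grams) == 0L) return(integer(0))
  hits <- lapply(grams, function(g) index$ngram[[g]])
  sort(unique(unlist(hits)))
}
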