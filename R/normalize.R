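#' Normalization profile for dictionary labels and text
#'
#' A normalization profile fixes how surface strings are canonicalized before
#' matching, so that a dictionary label and a text substring compare equal
#' whenever they differ only in case, spacing, Unicode representation or
#' (optionally) inflection. The steps are applied in a fixed order:
#' trim, case folding, internal whitespace collapse, Unicode compatibility
#' (NFKC) folding, per-token stemming.
#'
#' @param case_fold fold to lower case (default `TRUE`).
#' @param whitespace_collapse collapse runs of internal whitespace to a single
#'   space (default `TRUE`).
#' @param unicode_fold apply Unicode compatibility (NFKC) folding, mapping
#'   e.g. ligatures and full-width forms to their compatibility equivalents
#'   (default `TRUE`).
#' @param stemming apply an English suffix-stripping stemmer to each
#'   alphabetic token, iterated to a fixed point so that normalization is
#'   idempotent (default `FALSE`).
#' @param ngram_n character n-gram order used by the approximate-matching
#'   index and similarity; must be >= 1 (default 2).
#' @return An object of class `norm_profile`.
#' @examples
#' p <- normalization_profile()
#' normalize_label("  Pre-Eclampsia ", p)
#' @export
normalization_profile <- function(case_fold = TRUE, whitespace_collapse = TRUE,
                                  unicode_fold = TRUE, stemming = FALSE,
                                  ngram_n = 2L) {
  stopifnot(is_flag(case_fold), is_flag(whitespace_collapse),
            is_flag(unicode_fold), is_flag(stemming))
  if (!is_count(ngram_n) || ngram_n < 1)
    abort_validation("`ngram_n` must be an integer >= 1")
  structure(list(case_fold = case_fold,
                 whitespace_collapse = whitespace_collapse,
                 unicode_fold = unicode_fold,
                 stemming = stemming,
                 ngram_n = as.integer(ngram_n)),
            class = "norm_profile")
}

#' @export
print.norm_profile <- function(x, ...) {
  on <- function(f) if (f) "on" else "off"
  cat(sprintf(
    "<norm_profile> case_fold=%s whitespace_collapse=%s unicode_fold=%s stemming=%s ngram_n=%d\n",
    on(x$case_fold), on(x$whitespace_collapse), on(x$unicode_fold),
    on(x$stemming), x$ngram_n))
  invisible(x)
}

#' Normalize a surface string under a profile
#'
#' Pure, deterministic and idempotent: applying the function to its own
#' output returns the same string for every profile.
#'
#' @param label character vector of surface strings.
#' @param profile a [normalization_profile()].
#' @return character vector of normalized strings.
#' @examples
#' normalize_label("Toxemia   with  convulsions", normalization_profile())
#' @export
normalize_label <- function(label, profile = normalization_profile()) {
  stopifnot(is.character(label), inherits(profile, "norm_profile"))
  x <- stri_trim_both(label)
  if (profile$case_fold) x <- stri_trans_tolower(x)
  if (profile$whitespace_collapse) x <- stri_replace_all_regex(x, "\\s+", " ")
  if (profile$unicode_fold) x <- stri_trans_nfkc(x)
  if (profile$stemming) x <- vapply(x, stem_string_fixpoint, character(1),
                                    USE.NAMES = FALSE)
  x
}

# stem every alphabetic run in the (already lower-cased) string, repeating
# until stable; suffix strippers are not idempotent in a single pass
# (e.g. "relational" -> "relate" -> "relat"), and matching compares
# normalize(text) against normalize(label), so the cached normal form must be
# a fixed point
stem_string_fixpoint <- function(x, max_iter = 10L) {
  for (i in seq_len(max_iter)) {
    y <- stem_string_once(x)
    if (identical(y, x)) return(x)
    x <- y
  }
  x
}

stem_string_once <- function(x) {
  m <- stri_locate_all_regex(x, "[a-z]+")[[1]]
  if (nrow(m) == 0L || is.na(m[1, 1])) return(x)
  out <- character(0)
  pos <- 1L
  n <- stri_length(x)
  for (r in seq_len(nrow(m))) {
    s <- m[r, 1]; e <- m[r, 2]
    if (s > pos) out <- c(out, stri_sub(x, pos, s - 1L))
    out <- c(out, porter_stem(stri_sub(x, s, e)))
    pos <- e + 1L
  }
  if (pos <= n) out <- c(out, stri_sub(x, pos, n))
  paste0(out, collapse = "")
}

## ---- Porter (1980) suffix-stripping stemmer -------------------------------
## Hand-rolled because no stemmer library ships with this toolchain; follows
## the original five-step rule tables. Operates on a single lower-case ASCII
## word; words of <= 2 letters are returned unchanged.

# consonant test at position i of a letter vector; y counts as a consonant
# only when not preceded by a consonant cannot apply, i.e. y after a
# consonant is a vowel
pt_is_cons <- function(ch, i) {
  c0 <- ch[i]
  if (c0 %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c0 == "y") {
    if (i == 1L) return(TRUE)
    return(!pt_is_cons(ch, i - 1L))
  }
  TRUE
}

pt_types <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  vapply(seq_along(ch), function(i) pt_is_cons(ch, i), logical(1))
}

# m in the [C](VC){m}[V] decomposition of the stem
pt_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  runs <- rle(pt_types(stem))$values   # TRUE = consonant run
  m <- 0L
  if (length(runs) > 1L)
    for (j in seq_len(length(runs) - 1L))
      if (!runs[j] && runs[j + 1L]) m <- m + 1L
  m
}

pt_has_vowel <- function(stem) nzchar(stem) && any(!pt_types(stem))

pt_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  ch[n] == ch[n - 1L] && pt_is_cons(ch, n)
}

# *o: stem ends consonant-vowel-consonant, final consonant not w, x or y
pt_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  pt_is_cons(ch, n - 2L) && !pt_is_cons(ch, n - 1L) && pt_is_cons(ch, n) &&
    !ch[n] %in% c("w", "x", "y")
}

pt_ends <- function(w, suf) {
  nw <- nchar(w); ns <- nchar(suf)
  nw > ns && substr(w, nw - ns + 1L, nw) == suf
}

pt_chop <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

# apply the first matching (suffix -> replacement) rule whose stem condition
# holds; rules is a list of c(suffix, replacement); cond takes the stem
pt_rule_set <- function(w, rules, cond) {
  for (r in rules) {
    if (pt_ends(w, r[[1]])) {
      stem <- pt_chop(w, r[[1]])
      if (cond(stem)) return(paste0(stem, r[[2]]))
      return(w)   # longest matching suffix decides, even if condition fails
    }
  }
  w
}

#' Porter stemmer
#'
#' Single pass of the classic five-step English suffix-stripping algorithm
#' over each element of `x`. Inputs are expected to be lower-case words;
#' words shorter than three letters are returned unchanged. Used token-wise
#' by [normalize_label()] when the profile enables stemming (there it is
#' iterated to a fixed point so normalization stays idempotent).
#'
#' @param x character vector of lower-case words.
#' @return character vector of stems.
#' @examples
#' porter_stem(c("caresses", "ponies", "relational", "convulsions"))
#' @export
porter_stem <- function(x) {
  vapply(x, porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(w) {
  if (nchar(w) <= 2L || !grepl("^[a-z]+$", w)) return(w)

  # step 1a
  if (pt_ends(w, "sses")) w <- pt_chop(w, "es")
  else if (pt_ends(w, "ies")) w <- pt_chop(w, "es")
  else if (!pt_ends(w, "ss") && pt_ends(w, "s")) w <- pt_chop(w, "s")

  # step 1b
  if (pt_ends(w, "eed")) {
    if (pt_measure(pt_chop(w, "eed")) > 0L) w <- pt_chop(w, "d")
  } else {
    stripped <- FALSE
    if (pt_ends(w, "ed") && pt_has_vowel(pt_chop(w, "ed"))) {
      w <- pt_chop(w, "ed"); stripped <- TRUE
    } else if (pt_ends(w, "ing") && pt_has_vowel(pt_chop(w, "ing"))) {
      w <- pt_chop(w, "ing"); stripped <- TRUE
    }
    if (stripped) {
      if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (pt_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- substr(w, 1L, nchar(w) - 1L)
      } else if (pt_measure(w) == 1L && pt_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (pt_ends(w, "y") && pt_has_vowel(pt_chop(w, "y")))
    w <- paste0(pt_chop(w, "y"), "i")

  # step 2
  w <- pt_rule_set(w, list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"),
    c("iveness", "ive"), c("fulness", "ful"), c("ousness", "ous"),
    c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
  ), function(s) pt_measure(s) > 0L)

  # step 3
  w <- pt_rule_set(w, list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  ), function(s) pt_measure(s) > 0L)

  # step 4 (ordering matters: "ement" before "ment" before "ent")
  for (suf in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")) {
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, suf)
      ok <- pt_measure(stem) > 1L
      if (suf == "ion")
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (pt_ends(w, "e")) {
    stem <- pt_chop(w, "e")
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_cvc(stem))) w <- stem
  }

  # step 5b
  if (pt_measure(w) > 1L && pt_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l")
    w <- substr(w, 1L, nchar(w) - 1L)

  w
}
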