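# internal helpers shared across modules

#' @importFrom stringi stri_trim_both stri_trans_tolower stri_trans_nfkc
#'   stri_trans_nfc stri_replace_all_regex stri_locate_all_regex stri_sub
#'   stri_length stri_detect_regex stri_enc_toutf8
NULL

abort_user <- function(msg, class = "dictannot_user_error", ...) {
  stop(structure(
    class = c(class, "dictannot_user_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(msg, ...) {
  abort_user(msg, class = "dictannot_validation_error", ...)
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# locale-independent ordering (radix is byte-wise, stable across platforms)
order_radix <- function(...) order(..., method = "radix")

sort_radix <- function(x) sort(x, method = "radix")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)
}

#' Construct a denotation table
#'
#' Denotations are the unit of standoff annotation: a character span plus the
#' identifier (object) it denotes. They are represented throughout the package
#' as a data frame with columns `id`, `begin`, `end` and `obj`. Offsets are
#' 0-based and half-open: `begin` is the index of the first character of the
#' span, `end` the index one past the last, so `end - begin` is the span
#' length.
#'
#' @param id character vector of denotation ids (unique within a document).
#' @param begin,end integer vectors of 0-based, half-open character offsets.
#' @param obj character vector of object identifiers (e.g. `"ORPHA:275555"`).
#' @return A data frame with columns `id`, `begin`, `end`, `obj`.
#' @examples
#' denotations("T1", 101L, 122L, "ORPHA:275555")
#' @export
denotations <- function(id = character(), begin = integer(),
                        end = integer(), obj = character()) {
  data.frame(id = as.character(id), begin = as.integer(begin),
             end = as.integer(end), obj = as.character(obj),
             stringsAsFactors = FALSE)
}

empty_denotations <- function() denotations()

# sort denotations by (begin, end, obj) and assign ids T1..Tn
finalize_denotations <- function(df) {
  if (nrow(df) == 0L) return(empty_denotations())
  df <- df[order_radix(df$begin, df$end, df$obj), , drop = FALSE]
  df$id <- paste0("T", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("id", "begin", "end", "obj")]
}

# key under which a document is filed inside a project
doc_key <- function(sourcedb, sourceid) paste0(sourcedb, "/", sourceid)
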