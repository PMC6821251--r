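# comparison of annotation projects (precision/recall/F1), random sampling
# for manual inspection, and version diffs for regression testing

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# greedy one-to-one matching of predicted against reference denotations of
# one document, ordered by (begin, end); returns per-denotation outcome
match_denotations <- function(pred, ref, mode) {
  pred <- pred[order_radix(pred$begin, pred$end, pred$obj), , drop = FALSE]
  ref <- ref[order_radix(ref$begin, ref$end, ref$obj), , drop = FALSE]
  consumed <- rep(FALSE, nrow(ref))
  matched <- rep(FALSE, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    hit <- if (mode == "exact_span") {
      which(!consumed & ref$begin == pred$begin[i] & ref$end == pred$end[i] &
              ref$obj == pred$obj[i])
    } else {
      which(!consumed & ref$obj == pred$obj[i] &
              pmax(ref$begin, pred$begin[i]) < pmin(ref$end, pred$end[i]))
    }
    if (length(hit)) {
      consumed[hit[1]] <- TRUE
      matched[i] <- TRUE
    }
  }
  list(pred = pred, ref = ref, matched = matched, consumed = consumed)
}

#' Compare two annotation projects
#'
#' Scores a predicted project against a reference over their shared
#' documents. Under `exact_span` a predicted denotation is a true positive
#' iff a reference denotation has the identical span and object; under
#' `overlap` it suffices that the spans overlap by at least one character
#' and the objects are equal. Matching is one-to-one and greedy in (begin,
#' end) order: each reference denotation is consumable once. Unmatched
#' predicted denotations are false positives, unconsumed reference
#' denotations false negatives.
#'
#' @param predicted,reference [annotation_project()]s sharing at least one
#'   document key; shared documents must have identical text.
#' @param mode `"exact_span"` or `"overlap"`.
#' @return An object of class `comparison_report`: overall `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, a `per_identifier` data frame with the
#'   same quantities per object identifier, and `match_mode`.
#' @examples
#' # predicted {(0,9,A)} against reference {(0,9,A), (10,19,A)}:
#' # tp=1, fp=0, fn=1 -> precision 1, recall 0.5, F1 2/3
#' @export
compare_projects <- function(predicted, reference,
                             mode = c("exact_span", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(predicted, "annotation_project"),
            inherits(reference, "annotation_project"))
  shared <- intersect(names(predicted$records), names(reference$records))
  if (length(shared) == 0L)
    abort_user("the two projects share no (sourcedb, sourceid) document key")
  for (key in shared)
    if (!identical(predicted$records[[key]]$text, reference$records[[key]]$text))
      abort_user(sprintf("document %s has differing text in the two projects; re-sequence before comparing", key),
                 class = "dictannot_alignment_error")

  ids <- character(0)
  tallies <- list()
  for (key in shared) {
    m <- match_denotations(predicted$records[[key]]$denotations,
                           reference$records[[key]]$denotations, mode)
    tallies[[key]] <- m
    ids <- union(ids, union(m$pred$obj, m$ref$obj))
  }
  ids <- sort_radix(ids)
  per <- data.frame(identifier = ids, tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (m in tallies) {
    for (j in which(m$matched)) {
      k <- match(m$pred$obj[j], per$identifier); per$tp[k] <- per$tp[k] + 1L
    }
    for (j in which(!m$matched)) {
      k <- match(m$pred$obj[j], per$identifier); per$fp[k] <- per$fp[k] + 1L
    }
    for (j in which(!m$consumed)) {
      k <- match(m$ref$obj[j], per$identifier); per$fn[k] <- per$fn[k] + 1L
    }
  }
  pm <- Map(function(tp, fp, fn) prf(tp, fp, fn), per$tp, per$fp, per$fn)
  per$precision <- vapply(pm, `[[`, numeric(1), "precision")
  per$recall <- vapply(pm, `[[`, numeric(1), "recall")
  per$f1 <- vapply(pm, `[[`, numeric(1), "f1")

  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  overall <- prf(tp, fp, fn)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = overall$precision, recall = overall$recall,
                 f1 = overall$f1, per_identifier = per, match_mode = mode,
                 n_documents = length(shared)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s over %d document(s)\n",
              x$match_mode, x$n_documents))
  cat(sprintf("  tp=%d fp=%d fn=%d  precision=%.4f recall=%.4f f1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Render a comparison report
#'
#' @param report a [compare_projects()] result.
#' @param format `"table"` for a tab-delimited table (overall row plus one
#'   row per identifier) or `"json"`.
#' @return A character vector of lines (`"table"`) or a JSON string.
#' @export
render_report <- function(report, format = c("table", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "comparison_report"))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                         pretty = TRUE, digits = NA)))
  }
  header <- "identifier\ttp\tfp\tfn\tprecision\trecall\tf1"
  fmt <- function(id, tp, fp, fn, p, r, f)
    sprintf("%s\t%d\t%d\t%d\t%.4f\t%.4f\t%.4f", id, tp, fp, fn, p, r, f)
  lines <- c(header,
             fmt("OVERALL", report$tp, report$fp, report$fn,
                 report$precision, report$recall, report$f1))
  per <- report$per_identifier
  for (i in seq_len(nrow(per)))
    lines <- c(lines, fmt(per$identifier[i], per$tp[i], per$fp[i], per$fn[i],
                          per$precision[i], per$recall[i], per$f1[i]))
  lines
}

#' Randomly sample denotations for manual inspection
#'
#' Draws a uniform sample without replacement over all denotations of the
#' project — the stand-in for benchmark comparison when no gold standard
#' exists. Deterministic for a fixed seed. Each sampled item carries a
#' context window of up to 40 characters on each side of the span.
#'
#' @param project an [annotation_project()].
#' @param k sample size; the sample has `min(k, total)` items.
#' @param seed integer RNG seed.
#' @param context_chars context width on each side (default 40).
#' @return A data frame with columns `key`, `id`, `begin`, `end`, `obj`,
#'   `covered` and `context`.
#' @export
sample_annotations <- function(project, k, seed = 1L, context_chars = 40L) {
  stopifnot(inherits(project, "annotation_project"), is_count(k))
  pool <- list()
  for (key in names(project$records)) {
    r <- project$records[[key]]
    d <- r$denotations
    if (nrow(d) == 0L) next
    d$key <- key
    d$covered <- stri_sub(r$text, d$begin + 1L, d$end)
    lo <- pmax(1L, d$begin + 1L - context_chars)
    hi <- pmin(stri_length(r$text), d$end + context_chars)
    d$context <- stri_sub(r$text, lo, hi)
    pool[[key]] <- d
  }
  cols <- c("key", "id", "begin", "end", "obj", "covered", "context")
  if (length(pool) == 0L) {
    out <- data.frame(key = character(), id = character(), begin = integer(),
                      end = integer(), obj = character(),
                      covered = character(), context = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  all <- do.call(rbind, pool)[, cols]
  rownames(all) <- NULL
  take <- min(as.integer(k), nrow(all))
  if (take == 0L) return(all[0, , drop = FALSE])
  idx <- with_seed(seed, sample.int(nrow(all), take))
  out <- all[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diff two versions of a project's annotations
#'
#' Set difference of denotations (by document key, span and object) between
#' two archived versions, or between a version and the live state (tag
#' `"current"`). The diff is empty iff the versions are identical, which
#' makes it the regression check of the revise-and-reannotate loop.
#'
#' @param project an [annotation_project()].
#' @param v_old,v_new version tags (see [annotate_project()]; `"current"`
#'   refers to the live denotation state).
#' @return A list with `added` and `removed` data frames (columns `key`,
#'   `begin`, `end`, `obj`) and `per_document` counts.
#' @export
diff_versions <- function(project, v_old, v_new = "current") {
  stopifnot(inherits(project, "annotation_project"))
  old <- version_denotations(project, v_old)
  new <- version_denotations(project, v_new)
  flat <- function(snap) {
    rows <- lapply(names(snap), function(key) {
      d <- snap[[key]]
      if (is.null(d) || nrow(d) == 0L)
        return(data.frame(key = character(), begin = integer(),
                          end = integer(), obj = character(),
                          stringsAsFactors = FALSE))
      data.frame(key = key, begin = d$begin, end = d$end, obj = d$obj,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(key = character(), begin = integer(),
                                        end = integer(), obj = character(),
                                        stringsAsFactors = FALSE)
    out
  }
  fo <- flat(old); fnw <- flat(new)
  sig <- function(df) paste(df$key, df$begin, df$end, df$obj, sep = "\r")
  added <- fnw[!(sig(fnw) %in% sig(fo)), , drop = FALSE]
  removed <- fo[!(sig(fo) %in% sig(fnw)), , drop = FALSE]
  rownames(added) <- rownames(removed) <- NULL
  keys <- sort_radix(union(added$key, removed$key))
  per_document <- data.frame(
    key = keys,
    added = vapply(keys, function(k) sum(added$key == k), integer(1)),
    removed = vapply(keys, function(k) sum(removed$key == k), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(added = added, removed = removed, per_document = per_document)
}
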