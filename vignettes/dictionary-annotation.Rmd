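---
title: "Dictionary-based annotation: models, matching criteria and the refinement loop"
author: "dictannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-based annotation: models, matching criteria and the refinement loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictannot)
```

## The model

`dictannot` treats named-entity recognition and normalization as a
dictionary lookup problem. A dictionary is a set of (label, identifier)
pairs: labels are surface strings expected in running text, identifiers
point into a database or ontology. The task is: given a dictionary and a
set of target texts, return every text span that refers to a dictionary
entity, annotated with that entity's identifier. This trades the
generalization power of trained models for something end users value more:
every output is explainable by a dictionary entry, so every error is
*fixable* by editing the dictionary.

Three design commitments follow:

1. **Texts are sequenced once and never change.** A *sequencer* converts a
   source document (title + abstract, or a plain-text file) into a fixed
   character sequence; all annotation offsets refer to that exact sequence.
   Offsets are 0-based and half-open — the span (101, 122) has length 21,
   which is the length of `"pre-eclamptic toxemia"`; this convention is the
   only one under which span length equals `end - begin`. Unicode is
   canonically composed (NFC) at sequencing time and never re-normalized
   later, the title/abstract separator is a single newline, and line
   endings are normalized to `"\n"`, so re-sequencing identical input is
   byte-identical.

2. **Annotations are standoff.** A denotation is `(id, begin, end, obj)`
   kept separately from the text, serialized in a fixed-key JSON
   interchange format (`text`, `sourcedb`, `sourceid`, `denotations` with
   `id`/`span{begin,end}`/`obj`) that third-party standoff viewers can
   render. Reading validates spans against the text length and ids for
   uniqueness; writing is key-ordered and UTF-8, hence diff-stable.

3. **Everything is versioned.** A project (documents + denotations) archives
   its previous annotation state each time it is re-annotated, so any two
   iterations can be diffed — the regression-testing backbone of the
   refinement loop.

## String normalization

Labels and candidate substrings are compared after normalization under a
profile applied in a fixed order: trim → case fold → internal whitespace
collapse → Unicode compatibility fold (NFKC) → per-token stemming. The
order matters only across fold/stem (stemming expects lower-case input);
fixing it makes cached normal forms reproducible.

Stemming uses the classic Porter five-step suffix stripper, implemented in
the package and validated against the algorithm's published example stems.
One deliberate deviation from a single-pass stemmer: the normalization step
iterates stemming to a fixed point (e.g. `relational → relate → relat`,
then stable). Single-pass suffix strippers are not idempotent, but a cached
normal form must be — matching compares `normalize(text)` with
`normalize(label)`, and an unstable normal form would make equality depend
on how many times a string had passed through the pipeline. The fixed point
is reached in at most a few iterations; `porter_stem()` itself remains the
single-pass algorithm.

Stemming is off by default: for lexicons of names and noun phrases it
mostly adds ambiguity, and the profile exposes it for the cases (verbal or
adjectival labels) where it helps.

## Matching criteria

Candidate substrings are token-boundary aligned spans of up to
`max_candidate_tokens` (default 10) tokens, where a token is a run of
letters/digits with internal hyphens kept word-internal — `pre-eclamptic`
is one token, which is what makes the hyphenated biomedical vocabulary
work. Two modes:

* **exact** — the normalized candidate must equal a normalized label
  (hash-map lookup).
* **approximate** — candidate labels are retrieved through a character
  n-gram inverted index and accepted when the cosine similarity of padded
  character n-gram count vectors reaches `threshold` (default 0.85, n = 2
  from the profile). Padding with n−1 boundary markers makes word edges
  count: `similarity("eclampsia", "eclampsya", 2)` is exactly 0.8 (10
  bigrams each, 8 shared). Retrieval through the inverted index is
  lossless: any pair with positive cosine shares at least one n-gram, so
  the index can only discard candidates with similarity 0.

Defaults (threshold 0.85, n = 2) were fixed once as reasonable values for
single-character edits in words of typical biomedical length — a
length-9 word with one substitution scores 0.8, with case/whitespace
variants already absorbed by normalization — and are exposed in
`match_config()` rather than tuned per corpus.

Overlap resolution (`longest_only`, on by default) keeps a pairwise
non-overlapping subset chosen longest-first with leftmost winning ties;
identical spans carrying several identifiers are kept together when
`emit_all_identifiers` is set, otherwise the lexicographically smallest
identifier is emitted, making output order-independent and deterministic.
Two properties worth knowing:

* With `longest_only` off, the match set is monotone: lowering the
  threshold never removes a match, and approximate mode at threshold 1
  returns exactly the exact-mode matches. Recall measured on the raw match
  set is therefore non-increasing in the threshold.
* With `longest_only` on, monotonicity can fail: a lower threshold can
  admit a *longer* spurious span that displaces a correct shorter one.
  This is inherent to longest-match tagging, not an implementation
  accident, and is the reason the package's invariants are stated on the
  raw match set.

Exact mode tightens the scan window to the longest label's token count (a
longer candidate can never compare equal); approximate mode keeps the full
configured window, since a long candidate can still clear the threshold
against a shorter label.

## Evaluation

`compare_projects()` scores predicted against reference denotations over
the documents the two projects share (texts must be identical — offsets are
meaningless otherwise). Matching is greedy one-to-one in (begin, end)
order; each reference denotation is consumable once. The choice of
discipline is the only free parameter: `exact_span` requires identical
spans, `overlap` requires ≥ 1 shared character; both require identifier
equality, because normalization correctness — not just span finding — is
the task. One-to-one consumption keeps the conservation identities
`tp + fp = |predicted|` and `tp + fn = |reference|` exact, which in turn
gives the role symmetry `precision(A,B) = recall(B,A)`. Precision, recall
and F1 are defined as 0 when their denominators vanish.

When no reference exists, `sample_annotations()` draws a seeded uniform
sample without replacement, each item with ±40 characters of context — the
manual-inspection stand-in for benchmarking, sized for quick human review.

## Triple export and co-occurrence

`annotations_to_triples()` emits exactly five statements per denotation
(type, part-of → document node, begin, end as typed integer literals,
denotes → identifier node) plus four per document (type, sourcedb,
sourceid, text) and one per project. Node identifiers are deterministic
URL-safe functions of (project, sourcedb, sourceid, denotation id) under a
configurable base prefix. The document node is project-independent, so
projects annotating the same document share it; project membership of an
annotation is carried by the annotation node's URI prefix, keeping the
per-denotation statement count at five. The export is plain N-Triples, and
`cooccurrence_query()` answers the one query family the export exists for —
pairs of denotations from two projects co-occurring in a document or a
sentence — working purely from the statement set, so querying the export
and querying the in-memory projects are interchangeable (a tested
equivalence).

Sentence segmentation is rule-based: split on sentence-final punctuation
followed by whitespace and an uppercase letter, with an exception list of
common abbreviations (`e.g.`, `et al.`, `Fig.`, …). It is deliberately a
small, documented, replaceable component, not a linguistic claim. The
query's context is the covering sentence (sentence scope) or the span from
the first to the last involved character (document scope).

## The synthetic corpus generator

`generate_corpus()` exists so that every pipeline stage is testable without
downloading anything. It emulates the *statistical structure* the
refinement workflow assumes — synonymy (a small obstetric vocabulary with
canonical labels and synonyms), surface variation (`variant_rate` of
planted mentions perturbed by case change, doubled whitespace, or a
single-character edit that never crosses a token boundary), and ambiguity
(`ambiguity_rate` of mentions whose surface is registered under a second
identifier). Mentions are planted into filler sentences at recorded
offsets; the gold denotations cover exactly the planted surfaces, and a
plant log records every decision. Two deliberate generator properties make
loop experiments exact rather than statistical:

* filler words are drawn from a fixed pool disjoint from all vocabulary
  surfaces, so a dictionary entry added over filler (`plant_noise()`)
  produces *only* false positives, with a count equal to the word's corpus
  frequency;
* no vocabulary surface is a token-substring of another, so nested-label
  overlaps cannot produce unplanned false positives.

Defaults (20 documents, 2–5 mentions each, rates 0) are the baseline
conditions; tests and the acceptance script vary document counts
(typically 4–42 per corpus, ≤ 500 characters per document, dictionaries
≤ 30 entries) and rates (0–0.5) explicitly. Everything is a pure function
of the spec including its seed; two runs are byte-identical.

What passing on this generator does *not* show: robustness to real MEDLINE
language — abbreviations, apposition, coordination ellipsis, nested and
discontinuous mentions, genuine word-sense ambiguity. The generator is
structural, not linguistic, and claims about real corpora still require a
reference annotation.

## The refinement loop

`run_iteration()` is one sprint: annotate (archiving the previous state as
a new version), then benchmark against a reference if one exists or draw an
inspection sample if not, and append an iteration record (dictionary name
and size, configuration, annotation count, metrics or sample, changes since
the previous iteration) to the project log. Dictionary changes between
iterations are expressed as append-only change scripts (add/delete rows)
rather than in-place edits, which makes a whole loop replayable: same
inputs, same seeds, byte-identical final annotations — a tested property.
The two canonical loop directions are noise reduction (delete entries whose
matches are false positives: precision rises, recall untouched) and
coverage improvement (add missing synonyms: recall and annotation count
rise strictly).

The loop has no stopping rule by design: quality targets are the
operator's, so the loop exposes metrics and leaves termination to the user
or the change script.

## Numerical and degenerate-input choices

* Ties in overlap resolution: longer wins, then leftmost, then identifier
  order — fully deterministic.
* Metrics with empty denominators are 0, so empty projects compare without
  special cases.
* Labels normalizing to under 2 characters are indexed but flagged
  high-noise (`compile_index()` reports them); one-character labels are
  overwhelmingly false-positive generators in literature text.
* Duplicate (label, identifier) pairs are dropped at construction;
  `add_entry()` of an existing pair and `delete_entry()` of an absent pair
  are no-ops with recorded status, so change scripts are idempotent.
* All randomness (generation, sampling) flows through explicit seeds and
  restores the caller's RNG state.

## Known limitations

* No word-sense disambiguation: an ambiguous label either emits all its
  identifiers or the lexicographically smallest, never a context-dependent
  choice.
* No abbreviation expansion or machine-learned matching.
* The n-gram cosine criterion is one reasonable approximate-matching
  choice, isolated behind `match_config()`; other similarity functions
  would slot in behind the same interface.
* Greedy positional one-to-one matching in evaluation is deterministic but
  not a maximum matching; role symmetry is exact for exact-span matching
  and holds on the generated corpora for overlap matching.
* The sentence splitter is heuristic; sentence-scope co-occurrence results
  are only as good as its segmentation.
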