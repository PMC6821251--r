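# dictannot

Dictionary-based annotation of biomedical text with an agile,
revise-and-reannotate workflow.

## The problem

Biomedical researchers who need named-entity recognition and normalization
over their own specialized literature rarely need a trained NLP system —
they need a *lexicon they control*. `dictannot` implements that workflow end
to end: build a dictionary of (label, identifier) pairs, annotate a corpus
with it, inspect or benchmark the result, revise the dictionary, and
re-annotate, with every iteration versioned and regression-testable.

A dictionary is a set of pairs

    Δ = {(l₁, i₁), …, (l_k, i_k)}

where each label *l* is a surface string expected in text and each
identifier *i* points into a database or ontology (`ORPHA:275555`,
`HGNC:8893`, …). One identifier may have many labels (synonyms) and one
label may map to several identifiers (ambiguity). Annotation produces
*standoff* denotations: `(begin, end, obj)` tuples with 0-based, half-open
character offsets into a fixed, sequenced text, so a denotation like
`(PubMed: 13184842, 101-122, ORPHA: 275555)` is unambiguous forever.

Matching is criterion-driven: candidate substrings aligned to token
boundaries are normalized (trim → case fold → whitespace collapse → Unicode
NFKC → optional per-token Porter stemming) and either looked up exactly or
scored by character n-gram cosine similarity against the lexicon, with a
configurable threshold. Evaluation reports precision/recall/F1 under
exact-span or overlap matching, overall and per identifier:

    P = TP / (TP + FP),  R = TP / (TP + FN),  F1 = 2PR / (P + R)

Annotations can also be exported as RDF-style triple statements (5 per
denotation) and queried for cross-project co-occurrence — e.g. *documents
(or sentences) containing a disease mention from one project and a gene
mention from another*.

## A worked example

The package ships the classic two-entry pre-eclampsia lexicon
(`inst/extdata/preeclampsia.tsv`):

```r
library(dictannot)

d <- load_dictionary(system.file("extdata", "preeclampsia.tsv",
                                 package = "dictannot"), "pre_eclampsia")
#> dictionary 'pre_eclampsia': 2 lines read, 2 entries kept, 0 duplicates
#> dropped, 0 malformed skipped

doc <- sequence_title_abstract(
  paste0("Individual blood differences in relation to pregnancy, with ",
         "special reference to the pathogenesis of pre-eclamptic toxemia."),
  "", "PubMed", "13184842")

res <- annotate_text(doc, compile_index(d), match_config())
res
#>   id begin end          obj
#> 1 T1   101 122 ORPHA:275555

to_reference_tuples(annotation_record("PubMed", "13184842", doc$text, res))
#> [1] "(PubMed: 13184842, 101-122, ORPHA: 275555)"
```

The single denotation covers `"pre-eclamptic toxemia"` (21 characters) and
normalizes it to the Orphanet identifier for pre-eclampsia — the second
dictionary entry matched even though the first (`"Pre-eclampsia"`) does not
occur verbatim.

The refinement loop in miniature, on a synthetic corpus with planted gold
mentions:

```r
fx <- generate_corpus(corpus_spec(n_documents = 8, seed = 340))
noisy <- plant_noise(fx$dictionary, fx$project, 3, seed = 11)

it1 <- run_iteration(strip_annotations(fx$project), noisy,
                     reference = fx$project)
it1$record$metrics[c("fp", "precision", "recall")]
#> $fp [1] 19   $precision [1] 0.62   $recall [1] 1

cleaned <- apply_change_script(noisy, data.frame(
  op = "delete", label = attr(noisy, "noise_entries")$label,
  identifier = attr(noisy, "noise_entries")$identifier))
it2 <- run_iteration(it1$project, cleaned, reference = fx$project)
it2$record$metrics[c("fp", "precision", "recall")]
#> $fp [1] 0   $precision [1] 1   $recall [1] 1
```

Deleting the noisy entries drives false positives to zero and precision to
1 while recall is untouched — the noise-reduction direction of the loop.
Adding a withheld synonym runs the coverage direction the same way.

A command-line interface covering the whole workflow (dictionary editing,
project preparation, annotation, comparison, sampling, version diffs,
triple export, co-occurrence queries, scripted loops) is shipped as
`inst/cli/dictannot`; run it with no arguments for usage.

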