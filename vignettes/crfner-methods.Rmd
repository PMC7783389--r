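---
title: "Tagging chemical and gene/protein mentions with linear-chain CRFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tagging chemical and gene/protein mentions with linear-chain CRFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crfner)
```

## The problem

Abstracts of biomedical publications mention small molecules ("dasatinib",
"sphingosine-1-phosphate", "GRN-529") and genes or proteins ("SAMHD1",
"reverse transcriptase") in free text.  Annotated corpora in the CHEMDNER
and ChemProt tradition store these mentions as *standoff* records: character
offsets into the title or abstract plus the mention string and a type.
`crfner` trains sequence taggers on such corpora and applies them to new
abstracts, then supports two downstream analyses: selecting candidate
inhibitor names by chemical-protein co-occurrence, and differencing the
protein-name inventories of two document groups.

## Data model and formats

A `ner_document` carries `doc_id`, `title`, `abstract` and two span layers
(`entities` gold, `predicted`).  Offsets are 0-based half-open and count
Unicode code points; every span must satisfy *slice-equals-text*, and both
the reader and the writer enforce it — a mismatched offset is an error
naming the span, never a silent repair, so a mis-declared offset convention
fails loudly instead of corrupting data.

Two tab-separated dialects are supported.  The CHEMDNER-like dialect
addresses each section separately with a `T`/`A` code; the ChemProt-like
dialect has no section code, so its offsets are interpreted against the
concatenation `title + TAB + abstract` and the section is recovered from
the offset position.  Real ChemProt entity files type chemicals simply as
`CHEMICAL`; the writer additionally accepts the seven chemical subtypes in
that column (and the reader understands both), because otherwise a typed
corpus could not round-trip through the dialect.  Entity classes follow the
corpora: the seven CHEMDNER types imply class CHEMICAL, `GENE-Y`/`GENE-N`
imply GENE — genes and proteins are deliberately one class, as the source
corpora do not separate them.

## Tokenization and span encoding

`wp_tokenize` implements word-punctuation tokenization: maximal runs of
word characters (letters, digits, underscore) or of non-word non-space
characters.  "sphingosine-1-phosphate" becomes five tokens; offsets are
kept so that tokens always equal their source slices and the text is
reconstructable (lossless tokenization).

Spans map to per-token **SOBIE** labels: `S` single-token entity, `B`/`E`
first/last token of a multi-token entity, `I` interior, `O` outside.  Two
boundary policies were genuinely open and are resolved as follows:

* *Misaligned spans* (a boundary strictly inside a token): the whole token
  is included, with a warning.  Labels stay total and recall is preserved;
  the alternative (dropping the span) silently loses training signal.
* *Ill-formed predicted label sequences*: decoding is lenient and
  deterministic — an `I`/`E` without an open `B` opens an entity, a `B` not
  continued by `I`/`E` closes as a single token.  This maximizes the
  mentions extracted from imperfect tagger output; the repair rules are
  exercised directly in the tests.

## Features

Each token yields one feature map (realized as `name=value` indicator
atoms): the word and lowercase form; `isupper`, `istitle`, `isdigit`,
`hasdigits`, `hassymbols` (a character that is neither alphanumeric nor
underscore); cue-lexicon flags; stop-word flag; suffixes `word[n-3:n]` and
`word[n-2:n]` (whole word when shorter); first character; length; POS tag.
Each token also carries full copies of its neighbours' base features under
`prev:`/`next:` prefixes — a ±1 context window — with `BOS`/`EOS` flags at
sequence boundaries, and a constant `bias` atom.  Sequences are built per
section, so windows never cross the title/abstract boundary.

Design choices worth stating:

* The single "is a non-specific term" cue feature is split into
  `isnonspecific_C` (chemical cues such as "inhibit", "chemical") and
  `isnonspecific_G` (gene/protein cues such as "target", "genes"), because
  the cue lists are marked C/G and one term may carry both marks; one
  boolean would discard that information.  The shipped lists are small
  curated seeds and are user-replaceable via `load_lexicon`.
* `length` is emitted both raw and bucketed (1, 2, 3, 4–6, 7–10, >10);
  linear models exploit categorical indicators better than a
  string-compared integer, and the raw value is retained for fidelity.
* POS tagging is an injectable provider (any function words → tags).  The
  default is a deterministic rule tagger (closed-class lists plus suffix
  rules) so the package carries no heavyweight model; a Penn-treebank
  tagger can be substituted without touching anything else.

## The CRF

`crf_fit` maximizes

$$\ell(w) = \sum_i \big[\mathrm{score}(x_i, y_i) - \log Z(x_i)\big]
  - c_2 \lVert w \rVert^2 - c_1 \lVert w \rVert_1$$

with state weights per (atom, label) and transition weights per label pair
(indicator transitions only, which keeps the model standard and the
enumeration oracle simple).  All inference is in log space: the partition
function by the forward recursion with log-sum-exp stabilization, gradients
by forward-backward marginals, decoding by Viterbi.  The dynamic programs
are compiled (Rcpp); the plain-R scorer `sequence_score` is kept
independent of them, and the test suite checks both against brute-force
enumeration over all $|L|^T$ labelings on small instances, plus gradients
against central finite differences.

Numerical and interface choices:

* Atoms unseen at training time are ignored at prediction (standard
  behaviour for indicator CRFs).
* Viterbi ties are broken toward the earliest alphabet label at the latest
  differing position, implemented by strict-improvement scans in alphabet
  order; with all-zero weights the decoder deterministically emits the
  first alphabet label.
* Optimization is L-BFGS-B from zero weights; the L1 term enters through
  its exact subgradient (0 at 0).  `tolerance` (default `1e-4`) is the
  relative objective-improvement stopping threshold and `max_iterations`
  (default 100) the iteration cap; hitting the cap returns the current
  weights with a warning and a `converged = FALSE` flag.  Defaults
  `c1 = c2 = 0.1` are sensible regularization weights for corpora of this
  size.  On the default synthetic corpus the fits typically reach the
  iteration cap while already decoding held-out text near-perfectly; the
  flag reports the optimizer's state, not the tagger's usefulness.
* Training is deterministic given the data and configuration; the recorded
  seed governs derived procedures (fold assignment in
  `tune_hyperparameters` and `cross_validate`).

Hyperparameters can be selected by k-fold cross-validated macro-F1 over a
configuration grid; ties go to the smallest `(c1, c2)` lexicographically,
preferring the sparser model.

## The four models and their combination

Model (i) tags chemical spans with SOBIE; model (ii) tags gene/protein
spans; model (iii) labels tokens with the chemical subtype
(`{O} ∪` types observed in training); model (iv), `apply_combined`, is the
*sequential* composition: decode chemical spans, assign each decoded span a
subtype by majority vote of the type model's token labels (ties go to the
earliest tied token's type; an all-`O` span becomes `UNSPECIFIED`), then
decode gene spans independently.  Chemical and gene layers may overlap — a
token can belong to both — because nothing in the downstream analyses
requires exclusivity and keeping both maximizes recall.  Prediction never
mutates its input; gold and predicted layers coexist on the document.

## Evaluation conventions

Token-level metrics are one-vs-rest per label with the macro row the
unweighted mean over all labels *including* `O` — that convention is forced
by the arithmetic of the per-label tables this field publishes, whose
average rows equal the unweighted means of all listed labels.  Entity-level
metrics require exact (section, start, end) matches.  The document-level
inhibitor evaluation counts names: a recognized name not in the document's
gold set adds one FP, a gold name not recognized adds one FN.  Zero
denominators define a metric as 0.  Display rounding is 4 decimals for
corpus tables and 2 for document-level results.

## Case-study pipelines

*Candidate inhibitors*: predicted chemicals of types FORMULA (mostly ions)
and FAMILY (compound classes, not specific molecules) are filtered out;
a document then proposes its remaining chemical names iff it also carries
at least one predicted protein span.  Name normalization is deliberately
shallow — case-folding plus stripping flanking punctuation — because
profile counts in this workflow are over surface names; synonym merging
belongs to the resolver stage (`lookup_names`), an injectable interface
whose default is an offline stub backed by a local TSV (file
`resolver_stub_synthetic.tsv`, a synthetic stand-in for a real
PubChem/UniProt lookup, which is out of scope).  Unresolvable names are
reported as `MISS` — the false-positive filter — and a resolver failure
degrades to `MISS` with a warning rather than aborting the pipeline.

*Profile differencing*: for two groups of abstracts, shared documents are
first removed by id (`exclude_docs`), each group's unique normalized
protein names are collected with provenance (`build_profile`), and
`diff_profiles` partitions them into overlap and group-specific sets, whose
sizes obey |unique A| + |overlap| = |A| by construction (property-tested).

## The synthetic corpus

`generate_corpus` emulates what the pipeline assumes of real corpora:
abstracts of filler vocabulary (a fixed shipped word list, for
reproducibility) with planted, token-aligned mentions — per chemical type a
distinct surface pattern (coined lowercase names with drug-like suffixes
for TRIVIAL, hyphen/digit systematic names, 2–5 letter uppercase
abbreviations, element-symbol formulas with digits, letters-dash-digits
identifiers, "tri- and di-…" coordinated pairs for MULTIPLE, plural class
nouns for FAMILY) and two gene patterns (uppercase symbol with digit,
"<name> protein") — plus cue words placed adjacent to mentions with
probability `cue_rate`.  Defaults: 60 words per abstract, 3 chemical and 3
gene mentions expected per document, near-uniform type mix, `cue_rate`
0.5.  The patterns are chosen so each type is distinguishable from the
Table-of-features orthography (case, digits, symbols, suffixes); otherwise
the type model could not beat chance and end-to-end tests would be
vacuous.

What passing on synthetic data does and does not show: it demonstrates that
the machinery — features, encoding, training, decoding, composition,
evaluation — is correct and learnable end to end, with entity F1 above 0.9
on held-out generated documents (the suite trains on 400 and evaluates on
100, sizes at which the signal is comfortably learnable on one CPU).  It
does not certify real-corpus accuracy: real mentions share vocabulary with
ordinary text, types overlap in surface form, and annotation is noisy, so
published-corpus scores are substantially below the synthetic ceiling.
Real-corpus training runs through exactly the same `read_corpus` →
`train_span_model` path.

`generate_grouped_profiles` plants gene-name inventories with exact sizes
and overlap, the fixture for profile-difference arithmetic at realistic
scale (478 and 1,443 names sharing 75).

## Known limitations

* The POS rule tagger is crude; feature quality on real corpora improves
  with a substituted statistical tagger.
* Transition weights are label-pair indicators; no feature-conjoined
  transitions.
* The resolver stub performs exact/synonym lookup only; it is an interface
  placeholder for live database queries, which the package intentionally
  does not perform.
* Molecular-weight filtering of candidates (which needs structure lookups)
  is out of scope; the type filter is the only chemical filter applied.
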