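---
title: "Mining antibody donations from acknowledgement sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining antibody donations from acknowledgement sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ackminer)
```

## The problem

When a lab donates an antibody to another lab, the gift usually leaves no
trace in databases — only a sentence in the receiving paper's
acknowledgement section: *"We thank K. Mackie (Indiana University) for the
CB1 antibody"*. This package mines such sentences from JATS/PMC full-text
XML and turns them into structured donation records: **donor**, **donor
affiliation**, **antibody name** and **attribute tags** (primary,
secondary, monoclonal, polyclonal). Two extraction algorithms are provided,
a hand-written rule system and a bootstrapped pattern learner, together
with an evaluation harness, a gold-annotation format, and a synthetic
corpus generator that makes every stage testable without any download.

## Corpus harvesting

Full-text articles are scanned with a shallow, linear regex pass rather
than a full DOM parse — only one section is wanted, and building the
complete parse tree of every article is needlessly expensive. Two tiers are
tried: the JATS `<ack>` element, then a textual `Acknowledg(e)?ments?`
heading followed by paragraph text up to the next section heading (which
covers legacy depositions; the choice of elements is this package's own, as
upstream archives are not uniform). Inline tags are stripped, entities
decoded, whitespace collapsed, and text is NFC-normalized before any
matching (archive text mixes typographic quotes and dashes). An `<ack>`
that opens and never closes is the one malformation treated as an error;
everything else degrades to "no section".

Documents are kept when the section contains *antibody* or *antibodies* as
a case-insensitive whole word; hyphens count as boundaries, so
"antibody-producing" matches and "antibodylike" does not. Whole-word rather
than substring matching is a deliberate tightening of a crude keyword
search. Note the filter is by design recall-oriented: "thanks … for advice
on antibody cocktails" passes it with no donation present.

## NLP adapter contracts

The extractors only consume four contracts — tokenization, a dictionary
membership test, named-entity mentions, and a constituency parse — so any
production tagger or parser can be plugged in. The shipped backend is a
deterministic fixture:

* **Tokenizer**: whitespace splitting with punctuation split off; brackets
  become their own tokens (the affiliation heuristic needs them), while
  abbreviation periods ("Dr.", initials such as "Y.") stay attached. Token
  indices are 1-based and character spans 1-based inclusive, matching R's
  `substr` semantics; the source string travels with the token table so
  every extracted string is an exact substring of the input.
* **Dictionary**: a compact curated English word list
  (`inst/extdata/english-words.txt`, function words plus common
  acknowledgement vocabulary), configurable per backend. Lookup lowercases
  and strips trailing periods. Hyphenated tokens are words only if listed
  whole, so "anti-tubulin" fails the test and is eligible as an antibody
  name. The dictionary is deliberately small: an over-complete lexicon
  would swallow antibody-like tokens, and the test is the load-bearing step
  of name extraction.
* **Entity tagger**: longest-match, left-to-right gazetteer lookup over
  person/organization/location lists (ties prefer person). This makes tests
  independent of any model weights; the cost is that the fixture NER is
  *perfect on planted names and blind to everything else* — see
  "What passing tests do and do not show" below.
* **Parser**: a small chunking grammar — optional determiner plus nominal
  run forms an NP; an NP followed by *of*/*to* and a bare nominal run
  merges into a larger NP, so the lowest NP over "UL7" in
  "antibody to UL7" spans all three tokens. Unknown tokens are treated as
  nominal, which is the right default for acknowledgements (unseen tokens
  are nearly always names). Unparseable input degrades to a flat tree
  rather than failing.

## Rule-based extraction

Every occurrence of *antibody*/*antibodies* anchors one candidate record.
Context windows of `window = 4` tokens either side (clipped at sentence
boundaries) drive the field rules:

1. **Antibody name** — the first token in the left window, scanning
   nearest-to-farthest, that is neither a dictionary word nor inside an
   entity mention (punctuation-only tokens are never candidates). If the
   left window yields nothing *and* the anchor is followed by *of*/*to*
   within the right window ("the antibody to UL7"), the right window is
   scanned the same way. Gating the right scan on the preposition keeps the
   window from firing on unrelated following clauses.
2. **Attributes** — the subset of {primary, secondary, monoclonal,
   polyclonal} present in the left window.
3. **Donor** — the nearest person mention entirely left of the antibody
   name (or of the anchor when no name was found: sentences like "thank X
   for providing antibodies" still carry a donor). This search is
   *unbounded* — donor names routinely sit far from the antibody mention —
   and paragraph-wide by default (`donor_scope = "sentence"` restricts it).
4. **Affiliation** — affiliations almost always follow the donor in
   brackets, so the rule takes the organization mention closest to the
   donor whose span lies strictly between donor and anchor; ties break to
   the leftmost.

Records with neither donor nor antibody are suppressed, and anchors
yielding the same (donor, antibody) pair within one paragraph are
deduplicated — a singular and a plural keyword in one sentence would
otherwise double-count. No name normalization is applied at extraction
time: "Keith Gull" and "K. Gull" stay distinct records, and word-order
variants of an organization stay distinct, a known limitation inherited by
the frequency tables.

## Bootstrapped pattern learning

The learner starts from seed antibody names and alternates two steps:

* **Induction** — for every sentence occurrence of a known name, take the
  leaves of the name's *immediate parent noun phrase* and replace the name
  with a `TARGET` wildcard, e.g. `the mouse TARGET antibody`. Patterns made
  of `TARGET` plus only stop-words (e.g. `the TARGET`) are discarded: more
  than two rounds of unpruned learning visibly amplifies noisy rules.
* **Matching** — each pattern is slid over every sentence; literals match
  case-insensitively, and the token(s) aligned with `TARGET` become a new
  name.

Both sets grow monotonically; two iterations are the default (the point at
which, in practice, extraction quality peaks before noisy rules creep in).
`TARGET` may absorb up to three tokens so multi-token names are reachable,
under constraints chosen here: no span token may be a stop-word, attribute
tag, anchor keyword or punctuation, and spans longer than one token must
consist of non-dictionary tokens. Without the last constraint the pattern
`TARGET antibody` also matches the two-token span "mouse TAG1" inside "the
mouse TAG1 antibody", and the learner invents spurious patterns from the
junk name in the next round. Names are tracked lowercased (matching is
case-insensitive anyway); records keep the surface form, so provenance is
preserved. Donors and affiliations of bootstrap records are completed with
the same context rules as above, anchored at the matched name's position.

There is no randomness anywhere in either extractor; identical input and
backend give identical output, which the suite checks.

## Gold annotations and evaluation

Gold annotations live in a documented XML schema
(`document / text / annotation / donation / resource / attribute /
entity`): one `<annotation>` per annotator, donations carrying free-form
resource labels (antibody, cell-line, fly stock, …) so non-antibody
bio-resources can be annotated, and non-donation person/organization
mentions kept for NER work. Character offsets are deliberately optional —
annotated strings are validated as substrings of the text instead, and
violations are located, warned about and kept. Read/write round-trips are
identity; other annotation dialects can be mapped into `gold_document()`
by a small converter.

Because the matching criterion behind any published accuracy figure is
rarely fully specified, the policy here is explicit and embedded in every
report: case-folding, punctuation stripping, honorific stripping, exact
match after normalization, and *match any annotator*. Per-field accuracy is
the fraction of distinct normalized gold values (pooled across annotators,
antibody-labelled donations only) recovered by at least one prediction in
the same document; the headline number is the arithmetic mean of the
donor, affiliation and antibody accuracies, printed with integer rounding.
This denominator choice keeps the score in [0, 1] even when predictions
outnumber gold donations; the counts behind every ratio are part of the
report so alternative definitions can be recomputed. Inter-annotator
agreement is the fraction of filled annotation fields on which annotator
pairs agree under the same policy, with donations aligned by position.

## The synthetic corpus

`generate_corpus()` is a template engine with known ground truth, not a
corpus mimic. Donation sentences come in active
("We thank P (O) for providing the X antibody."), plural, passive
("P is thanked for the antibody to X.") and nameless
("… for generously providing antibodies.") forms; distractors cover
funding, manuscript-reading and the advice-with-keyword false-positive
case. Antibody names are alphanumeric codes ("UL7"-style) or "anti-"
compounds, generated so they are provably absent from the dictionary —
the dictionary test is load-bearing and must be exercised
deterministically. Default rates (90% of documents with a donation, 20%
passive voice, 60% bracketed affiliations, 30% attributes, 70%
distractors, 10% multi-donation) describe a keyword-filtered
acknowledgement stream in which donation reports dominate, passive voice
is the minority form and extraneous thanks are common; they are fixed
once here and not tuned per analysis. A single seeded RNG drives
generation, the session RNG stream is left untouched, and identical
configurations generate identical corpora.

**What passing tests do and do not show.** On template-only text with the
planted gazetteers, the rule extractor scores 1.0 on all fields and
bootstrapping from a 40-name seed subset recovers 100% of planted names in
two iterations — the suite asserts both, and both extractors are checked
record-for-record against naive brute-force reference implementations on
500 generated paragraphs. These are *correctness* results: they show the
implementations compute exactly the specified rules. They are not
*robustness* results. Real acknowledgements bring NER errors (a college
tagged as a person), unlisted dictionary words, free word order and
donor-name variants; published accuracies for this family of methods on
expert-annotated real text sit near 50–70% per field, and a perfect
gazetteer cannot reproduce that error profile. The generator was
deliberately not tuned to imitate those error rates — accuracy numbers
faked by calibrated noise would carry no information.

## Numerical and degenerate-input choices

* Tokens are indexed 1-based with inclusive character spans (R idiom); all
  span arithmetic in the package follows this single convention.
* Window width defaults to 4 tokens; windows clip at sentence boundaries
  (`.`, `!`, `?`).
* Ties: donor search cannot tie (strictly ordered ends); affiliation ties
  break leftmost; `top_k` ties break lexicographically.
* Empty inputs: empty corpora yield empty record tables; an empty seed set
  is an error; bootstrapping an empty corpus returns the seeds and no
  patterns; agreement over a set with no doubly-annotated document is an
  error rather than a silent `NaN`.
* `yearly_trend` emits the union of years present in the records and years
  covered by the corpus counts, so zero-donation years appear explicitly;
  missing corpus sizes yield `NA` rates with a warning.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
a 50-document annotated benchmark and a 200-document template-only corpus
for end-to-end recovery, 500 paragraphs for the brute-force equivalence
checks, and a 6-sentence corpus for pattern-learning reproduction. These
sizes give stable results for deterministic algorithms while keeping the
default check runs quick on a laptop.

## Known limitations

* Donor-name variants are not normalized ("Keith Gull" vs "K. Gull"); an
  optional case-folding normalizer exists only at reporting time.
* The fixture NER sees exactly its gazetteers; production use requires
  plugging a statistical tagger into the backend contract.
* The keyword filter misses donations phrased without the two keywords
  ("antiserum", "monoclonal against …").
* Pattern matching is literal: morphological variants of pattern literals
  do not match, and patterns never cross sentence boundaries.
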