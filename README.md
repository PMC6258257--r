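# ackminer

Mining **antibody donations** from the acknowledgement sections of
biomedical articles.

Labs routinely donate antibodies to one another, and the only public trace
of such a gift is usually a sentence like *"We thank K. Mackie (Indiana
University) for the CB1 antibody"* in the receiving paper's
acknowledgements. `ackminer` harvests acknowledgement sections from
JATS/PMC full-text XML, keeps the ones mentioning *antibody*/*antibodies*,
and extracts structured donation records — donor, donor affiliation,
antibody name and attribute tags (primary, secondary, monoclonal,
polyclonal) — with two algorithms:

* **Rule-based extraction.** Each keyword occurrence anchors context
  windows of *W* = 4 tokens. The antibody name is the first token in the
  left window that is neither an English dictionary word nor part of a
  named entity; when the left window is empty of candidates and the anchor
  is followed by *of*/*to* ("the antibody to UL7"), the right window is
  scanned instead. The donor is the nearest person entity left of the name
  (unbounded window), and the affiliation is the organization entity
  closest to the donor while still left of the anchor.
* **Bootstrapped pattern learning.** Starting from seed antibody names,
  every sentence occurrence of a known name contributes a pattern: the
  leaves of the name's immediate parent noun phrase with the name replaced
  by a `TARGET` wildcard (e.g. `the mouse TARGET antibody`). Patterns are
  matched back over the corpus to harvest new names, and the two steps
  alternate (2 iterations by default). Donors and affiliations are then
  completed with the rule-based context procedures.

The package also ships a gold-annotation XML schema with readers/writers
and inter-annotator agreement, a per-field evaluation harness with an
explicit matching policy, a deterministic synthetic-corpus generator with
known ground truth, corpus-level reporting (top donors / antibodies /
journals, donations per 1000 articles per year), and a small CLI
(`exec/ackminer`).

## Worked example

```r
library(ackminer)

be <- nlp_backend(persons = c("Y. Nishiyama", "K. Mackie"),
                  organizations = "Indiana University")
ack <- acknowledgement(paste(
  "Dr. Y. Nishiyama is thanked for the antibody to UL7.",
  "K. Mackie (Indiana University) provided the monoclonal CB1 antibody."),
  article_id = "PMC0001")
extract_donations(ack, be)[, c("donor", "affiliation", "antibody", "attributes")]
#>          donor        affiliation antibody attributes
#> 1 Y. Nishiyama               <NA>      UL7           
#> 2    K. Mackie Indiana University      CB1 monoclonal
```

`UL7` is found by the right-context rule (the anchor is followed by *to*),
`CB1` by the left-context dictionary test; each record's donor is the
nearest person entity to its left, and the bracketed organization becomes
the affiliation.

Pattern learning from sentences covering the five canonical donation
contexts:

```r
sents <- c("We used the mouse TAG1 antibody",
           "rabbit TAG2 antibodies were a gift",
           "TAG3 monoclonal antibodies were provided",
           "We thank John for TAG4 antibody",
           "She is thanked for antibody to TAG5")
run_bootstrap(sents, paste0("TAG", 1:5), nlp_backend(), n_iterations = 2)
#> <bootstrap_state: 5 names (5 seeded), 5 patterns, 2 iteration(s)>
#> patterns:
#>   antibody to TARGET
#>   rabbit TARGET antibodies
#>   TARGET antibody
#>   TARGET monoclonal antibodies
#>   the mouse TARGET antibody
```

End-to-end on a generated corpus with known ground truth:

```r
corp <- generate_corpus(synth_config(n_documents = 50, rng_seed = 1))
recs <- extract_donations_corpus(corp$acks, corp$backend)
evaluate_documents(recs, corp$gold)
#> Extraction accuracy (match any annotator)
#>   donor        100%  (50/50)
#>   affiliation  100%  (29/29)
#>   antibody     100%  (43/43)
#>   mean         100%
#> <match_policy: exact +case-fold +strip-punctuation +strip-honorifics>
```

The counts are gold field values recovered / gold field values present;
perfect scores on template text with planted gazetteers are the expected
correctness check (the generator's gazetteer NER makes no errors — see the
methods vignette, `vignettes/antibody-donation-mining.Rmd`, for what this
does and does not demonstrate about real text).

## Command line

```sh
ackminer simulate --n 50 --seed 1 --out-dir corpus/
ackminer extract-rule --in corpus/ack.jsonl --gazetteers corpus/ --out records.jsonl
ackminer bootstrap --in corpus/ack.jsonl --seeds seeds.txt --iters 2 --out boot.jsonl
ackminer evaluate --pred records.jsonl --gold corpus/gold.xml
ackminer report --in records.jsonl --key donor --k 5
```
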