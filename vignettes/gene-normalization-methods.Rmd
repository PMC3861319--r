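---
title: "Methods: multistage gene name normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multistage gene name normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genenorm)
```

This vignette is the package's own account of its method: the model behind
each pipeline stage, the tunable parameters and their defaults, what the
synthetic corpus generator does and does not emulate, and the numerical
and design choices made where the design was genuinely open.

## The pipeline model

Gene name normalization maps each tagged gene/protein mention in an
abstract to a unique EntrezGene-style identifier. `genenorm` decomposes
the task into four stages, each a pure function of its inputs, so the
whole pipeline is deterministic: identical inputs always produce
byte-identical predictions.

**Pre-processing.** Tagged mentions arrive as character spans; the tagger
that produced them is outside the package. Two families of false
positives are pruned before matching: (i) mentions whose final token is a
family-style suffix (`genes`, `proteins`, `enzymes`, `receptors`,
`domain`, `subunit`, `cDNA`, `mRNA`, `family`, `subfamily`), which name
groups of genes rather than a specific gene; and (ii) mentions whose
immediately adjacent word matches a context rule — a following `cells`
(a cell line, matched case-insensitively) or a preceding `Yeast` (a
non-human gene, matched case-preserved, since lower-case "yeast" mid-
sentence is weaker evidence). Both lists are deliberately exactly the
documented examples and nothing more; both are configurable. The
"adjacent word" is defined as the maximal non-whitespace token next to
the span with surrounding punctuation stripped — the simplest definition
that yields a testable contract.

Long forms followed by a bracketed short form ("tumor necrosis factor
(TNF)") are paired when every alphabetic character of the short form
occurs in order in the long form — a simplified Schwartz–Hearst
criterion. It is cheap, deterministic, and errs toward pairing; a paired
mention shares its candidate identifiers with its partner in both
directions.

**Term normalization.** All matching is performed on a canonical form:
lower case, hyphens replaced by spaces, stop words (`of`, `the`, `and`)
removed, whitespace collapsed. Hyphens are mapped to spaces rather than
deleted so that "BAT-1" and "BAT 1" coincide; the space-deleted reading
("BAT1") is additionally produced at match time as an orthographic
variant, covering both interpretations. Normalization is applied
symmetrically to lexicon synonyms, mentions, context entities and
blacklist entries — one rule set everywhere, so matching never depends
on which side of the comparison a string came from.

**Dictionary matching.** Exact lookup goes through the variant closure of
the mention: space deletions, space insertions at letter–digit
boundaries, and standalone Arabic numerals 1–20 swapped with Roman
numerals (and vice versa), closed under each other. The Roman range is
capped at 20 on purpose: beyond XX, letters such as C or L are too
ambiguous with ordinary gene-name characters. Mentions with no exact hit
fall back (when enabled) to a brute-force Jaro–Winkler scan over every
normalized synonym in the lexicon. The acceptance threshold defaults to
0.90: a high bar that admits close orthographic rewrites ("serum- and
glucocorticoid-induced protein kinase" against "serum/glucocorticoid
regulated kinase") while limiting the family-name false positives this
stage is known to introduce. Returned candidates are capped at the
`top_k = 10` best identifiers to bound the downstream disambiguation
cost; ties order by descending score then ascending numeric identifier
for reproducibility. Approximate matching here *is* the brute-force
definition — any future indexing optimization must stay
oracle-equivalent to it.

**Ambiguity resolution.** A mention with several candidate identifiers is
resolved by strict precedence:

1. a single candidate needs no decision;
2. if the document's gene2pubmed links intersect the candidate set in
   exactly one identifier, that curated link decides — curated evidence
   outranks string similarity, and the singleton guard keeps the shortcut
   from masking genuine ambiguity;
3. otherwise the candidate with the highest semantic similarity to the
   document context wins.

The context is the set of all entities tagged in the abstract (including
the mention itself, which mirrors the worked BAT1 scenario), normalized
and deduplicated by default — duplicated context strings would otherwise
double-count evidence in the edge-sum mode. A candidate's extended
semantic information is its four gene_info fields — Symbol, chromosome,
map_location, description — each taken as a single vertex (the
description is deliberately not tokenized; one field, one vertex).
Jaro–Winkler scores form the weights of the complete bipartite graph
between fields and context entities, and the semantic similarity is the
total weight of the maximum-weight matching, found with Munkres'
assignment algorithm (`mode = "munkres"`). The alternative
`mode = "sum_all"` sums *every* edge weight with no matching step; it is
retained as the comparison baseline. The matching step is what stops a
single context entity from rewarding all four fields at once — with
plain summing, a candidate whose every field is mediocre everywhere can
outscore a candidate with two perfect field matches.

Candidates missing from gene_info score 0 rather than erroring (the
lexicon and gene_info may legitimately be out of sync); remaining ties
break by ascending numeric identifier, making the decision total and
deterministic.

**Filtering.** Normalized results whose mention equals a blacklisted
family name are removed last (the final pipeline stage, where stage-wise
accounting shows its precision effect most clearly). Equality is
whole-string after normalization, never substring containment: the
documented counter-example — the family "Zinc finger protein" versus the
specific gene "Zinc finger protein 51" — forces exactly this semantics.

## Numerical choices

* **Jaro similarity** uses the standard definition: matching window
  `floor(max(|s1|,|s2|)/2) − 1`, transpositions counted as half the
  mismatches among matched characters; two empty strings score 1, one
  empty string scores 0.
* **Jaro–Winkler** uses the canonical parameterization `p = 0.1`, prefix
  cap 4, and accepts `p` up to 0.25 (the usual admissibility bound).
  These are the published defaults of the metric; nothing in the method
  calls for deviating from them.
* **The assignment solver** is the O(n³) Hungarian algorithm with
  row/column potentials. Rectangular weight matrices are padded to square
  with zero-weight dummies; dummy pairs are excluded from the reported
  matching, so the result is a complete one-sided matching of size
  `min(|U|, |V|)`. Oracle equality against brute-force permutation search
  is asserted at tolerance 1e−9 (double-precision sums).
* **Scoring** reports unrounded precision/recall/F percentages as the API
  contract; display rounding is half-up to one decimal, because that is
  how published tables are rounded (base R's `round()` rounds half to
  even). The F-score is computed from unrounded precision and recall;
  published tables that round before combining can differ in the last
  digit, which is why the tests pin precision and recall directly and
  assert F only where the rounding is unambiguous.

## The synthetic corpus generator

`fixture_spec()` / `generate_fixture()` build a complete toy corpus:
synonym lexicon, gene_info, gene2pubmed, blacklist, abstracts with tagged
spans, and gold annotations at both the identifier and the mention level.
Its defaults are the package's study conditions, chosen once:

* `n_genes = 60`, `n_docs = 40`, 2–4 gene mentions per document — small
  enough that every stage runs in seconds, large enough that every
  planted phenomenon occurs many times per corpus.
* `ambiguity_rate = 0.3` of mention slots use a shared alias carried by a
  group of three genes, so exact matching yields three candidates. For
  every such mention the generator plants the true gene's symbol, map
  location and long-form name as additional tagged entities in the same
  abstract — the same discriminating-context pattern as the BAT1
  scenario. Group members are kept structurally separable (distinct
  leading chromosome digits, distinct long-name templates), and an alias
  group is used at most once per document with no independent mention of
  any other member, so the planted context is never contaminated by
  evidence for a wrong candidate.
* `variant_rate = 0.3` of slots render the symbol as an orthographic
  variant (hyphenated, spaced, Roman numeral, lower case) — reachable by
  exact matching through the variant closure.
* `fuzzy_rate = 0.15` of slots render a perturbed long name (a
  character-level edit) that no variant reaches but Jaro–Winkler at 0.90
  does — these mentions are what the approximate stage recalls.
* `family_rate = 0.1` plants blacklisted family-name decoys that only
  approximate matching can (wrongly) link to a specific member gene —
  these are what the filter removes.
* `g2p_rate = 0.2` of documents receive gene2pubmed links for their gold
  genes, exercising the curated shortcut without letting it decide every
  ambiguous case.

Generation is driven entirely by the seed; identical seeds give
byte-identical corpora (checksummed in the manifest), and the caller's
RNG state is restored afterwards.

**What the generator does not emulate.** Gene names are template-drawn
pseudo-words, not real nomenclature; context entities are planted, not
discovered; document length, mention density and the ambiguity structure
of real abstracts (where context evidence is implicit, partial and
noisy) are all idealized. Passing the planted-recovery tests therefore
shows that the machinery is correct — that discriminating evidence, when
present, is found and used — not that real-corpus accuracy would reach
any particular level. The published full-corpus figures depend on a
specific tagger, lexicon and annotated test set that are not shipped
here; only their count arithmetic and the qualitative orderings
(matching-based similarity ≥ edge-sum similarity; approximate matching
raises recall; filtering restores precision) are reproduced, on corpora
of the sizes above. The mode-comparison test uses a larger corpus
(80 genes, 80 documents, `ambiguity_rate = 0.5`, `fuzzy_rate = 0`) so
that well over 100 ambiguous mentions are measured, and sets
`fuzzy_rate = 0` because accidentally ambiguous approximate matches
carry no planted context and hence are outside the "fully discriminating
contexts" premise of the 100%-recovery claim.

## Known limitations

* Jaro–Winkler is prefix-heavy: short strings with a shared leading
  character (chromosome "1" against map location "19q13") score
  deceptively high, which is why discriminating metadata matters and why
  the generator separates group members structurally.
* The approximate matcher is a linear scan per unmatched mention —
  entirely adequate at corpus scales of thousands of synonyms, but an
  inverted-index retrieval layer would be needed for web-scale lexica.
* Stop words, suffix lists and context rules default to exactly their
  documented example sets; real deployments will want to extend them,
  which every entry point supports.
* The gene2pubmed shortcut trusts its input file; a stale or wrong link
  that singles out one candidate will override similarity evidence by
  design.
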