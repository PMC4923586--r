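---
title: "Demographic content analysis of health social media: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic content analysis of health social media: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

People discuss drugs, disorders, symptoms and treatments on social networks,
drug-review sites and health forums, and what they discuss differs by who they
are. Given a corpus of posts with (partly observed, partly inferable) author
demographics — gender, age, ethnicity, US region, writing level — this package
answers two questions per demographic group: *how* does the group write
(sentiment, emotion) and *what* does it disproportionately write about
(distinctive terms, disorders, drugs)?

Everything downstream of data collection is implemented: relevance filtering,
text normalization, lexicon scoring, dictionary concept tagging, demographic
inference, and the distinctive-item statistic. Crawling and platform APIs are
out of scope; corpora arrive as JSON-lines files (`read_corpus()`), and a
synthetic generator (`generate_corpus()`) provides corpora with known ground
truth for validation.

# The distinctive-item statistic

For a demographic attribute (say gender), only posts whose author carries the
attribute enter the analysis; the groups partition those posts. For an item
$w$ (a term stem or a concept id) and group $g$,

$$\mathrm{Freq}_g(w) = \frac{\text{occurrences of } w \text{ in } g\text{'s posts}}{\text{number of posts in } g},$$

$$\mathrm{RelDif}_g(w) = \frac{\mathrm{Freq}_g(w) - \overline{\mathrm{Freq}}(w)}{\overline{\mathrm{Freq}}(w)},$$

where $\overline{\mathrm{Freq}}(w)$ is the *unweighted* mean of the per-group
frequencies. Two consequences are used as built-in self-checks: the relative
differences of an item sum to zero across groups, and with two groups they are
exactly antisymmetric.

Rare items are removed before the statistic: an item must occur at least
$\max(0.0001\,N, 30)$ times, where $N$ is the total number of posts annotated
for the attribute — i.e. in at least 0.01% of those posts, with a floor of 30
when 0.01% of $N$ falls below 30. Reported lists keep the top
$k = 10$ items per group with $\mathrm{RelDif} > 0.1$ (items within 10% of the
cross-group average are considered not distinctive enough to display). Ties
are broken by higher average frequency, then lexicographically, making output
deterministic. "Occurrences" counts every token occurrence; a per-post binary
variant is available (`count = "posts"`).

Two open choices are resolved as follows and deliberately not made clever:
the minimum-occurrence denominator is the attribute-wide post total (not
per-group), and every post of a multi-post user counts separately (all the
statistics are per-post; users are never down-weighted).

# Text normalization

Tokenization lowercases and splits on punctuation, keeping hashtags
(`#bcsm`), alphanumeric tokens (`b12`) and apostrophes intact; symbols and
emoji become `other`-tagged tokens rather than errors. Stop words (bundled
editable list) are *flagged*, not deleted — the relevance filter ignores the
flag, the distinctive-term stream drops flagged tokens, and the phrase
matcher allows them inside multiword phrases but not as one-word matches.
All remaining tokens are stemmed with a faithful implementation of the
original Porter algorithm; hashtags are exempt. Porter is applied exactly
once on each side of every comparison (posts and lexicon entries pass through
the same normalizer). It is worth noting that Porter stems are not fixed
points of the algorithm (a stem ending in a lone "s" loses it on a second
pass), which is why the pipeline never re-stems already-stemmed text.

Part-of-speech tags select sentiment senses. The default tagger is a small
rule/suffix tagger (closed-class seed lists, `-ly` adverbs, adjectival and
verbal suffixes); anything it cannot classify is tagged `other`, which the
lexicon lookup treats as "no POS information" and matches POS-insensitively.
Any external tagger can be plugged in through `pos_tag(tokens, tagger =)`,
a function from surfaces to same-length coarse tags. Tagging happens before
stemming, on surfaces.

# Sentiment and emotion scoring

The sentiment lexicon assigns each (stemmed) phrase a triple
(positive, negative, objective) summing to 1; the loader derives the
objective score, rejects rows violating the sum within 1e-6, and collapses
multiple senses of one (stems, POS) pair by unweighted averaging (sense
ranks, if present in the source file, are ignored). Phrases are mapped by a
greedy longest-match scan: at each token the longest lexicon phrase starting
there is taken and the cursor advances past it, so "heart attack" always
beats its prefix "heart"; at equal length a POS-agreeing entry beats a
POS-agnostic one. A post's sentiment is the unweighted mean of its matched
triples. Posts with no match are *unscored* and excluded from group
denominators — scoring them as fully objective would make groups with
unmatched vocabulary look artificially neutral.

The emotion lexicon flags word stems with eight basic emotions. A post
carries emotion $e$ iff at least one of its stems carries $e$; a group's
emotion percentage is $100\times$ (flagged posts)/(scored posts). All eight
emotions are computed; the default rendered table reports the six paired
ones (anger, fear, trust, disgust, anticipation, surprise), and the other
two remain in the long-format output. The percentage semantics (share of
posts containing the emotion, rather than mean word fraction) was chosen
because it is bounded, interpretable, and admits a natural two-proportion
test.

Group contrasts test each group against the union of the other groups:
a two-sided two-proportion z-test (`prop.test`, no continuity correction)
for emotion percentages and Welch's t-test for sentiment means, flagged at
$P \le .05$. No multiple-testing correction is applied to the flags; a
Benjamini–Hochberg column (`p_value_bh`) is attached as a clearly-labelled
extension for readers who want it.

# Concept annotation

A dictionary tagger stands in for a full UMLS concept mapper: concepts carry
a CUI-like id, synonyms (normalized with the same pipeline as posts) and one
of the 15 coarse semantic groups; matching reuses the greedy longest-match
contract. Misclassifications of the kind a general-purpose mapper makes on
social text (the bare letter "i" as an immunologic factor, "bad" as an
organic chemical) are handled reproducibly: `concept_frequency_report()`
orders annotations by frequency for review, and an editable blacklist of
(surface, concept) pairs suppresses confirmed mistakes. Analysis keeps the
Disorders and Chemicals & Drugs groups; the other 13 are annotated
internally and filtered. Concepts are counted once per occurrence to mirror
term-frequency semantics. Any UMLS-derived TSV in the documented layout can
replace the bundled ~50-concept fixture dictionary.

# Demographic inference

*Gender and ethnicity.* First names and surnames are looked up in frequency
tables (the layout SSA baby-name counts and Census surname shares reduce
to); a label is assigned only when its share reaches a dominance threshold —
0.95 for gender, 0.80 for ethnicity — otherwise the user stays unlabelled.
The thresholds favour precision over coverage: a wrong label silently
contaminates a group, while an unlabelled user merely shrinks it. Inferred
values are marked `classified` in per-attribute provenance fields; reported
values are never overwritten.

*Writing level.* Each post is graded with Flesch–Kincaid,
$0.39\,\frac{\text{words}}{\text{sentences}} + 11.8\,\frac{\text{syllables}}{\text{words}} - 15.59$,
with this package's documented modifications: sentences are counted from
terminal punctuation with a floor of one, syllables from a vowel-group
heuristic with a silent-e rule and a floor of one per word, and the grade is
clamped to $[0, 16]$ so the reporting bins cover the range. A user's level
is the mean of their per-post grades (pooling token counts instead would let
prolific users change the formula's inputs). Bins: $[0,6) \to$ 0–5,
$[6,10) \to$ 6–9, $[10,16] \to$ 10–16; the edges are this package's choice,
stated rather than inherited.

*Region.* US state codes map to the four Census Bureau regions (DC counted
in the South). Age uses the closed integer bins 0–17, 18–34, 35–44, 45–64,
65+.

# The synthetic generator

`generate_corpus()` draws each post's tokens i.i.d. from its author-group's
multinomial over three vocabularies: *planted terms* (default: 10 inert
digit-bearing strings, each at per-token rate 0.03 in its target group and
0.01 elsewhere — a 3:1 enrichment whose closed-form expected relative
difference, $(r_g - \bar r)/\bar r = \pm 0.5$ for two groups, is returned in
a ground-truth manifest), *sentiment words* from the bundled lexicon
(default 0.05 positive + 0.05 negative per token), and *background filler*.
Per post and emotion, one word of that emotion is appended with a configured
per-post probability (default 0.2), so expected emotion percentages are
known exactly. Defaults: 2 gender groups × 5000 posts, Poisson lengths with
mean 20, one user per post, no missingness; attribute values, missingness
and multi-post users are configurable.

The background vocabulary defaults to 50,000 words. The size matters: the
minimum-occurrence threshold exists because real vocabularies are
long-tailed, with most word types far rarer than the 0.01%/30-occurrence
bar. At the default corpus size (~200k tokens) a 50,000-word background
gives filler words a mean count near 3, well under the floor of 30, so the
threshold does the job it does on real text. A background small enough that
every filler word clears the threshold would instead let pure multinomial
noise compete with planted signal — a property of the corpus, not of the
method.

What the generator does *not* emulate: syntax or word order (everything
downstream is token/phrase based, so bag-of-words suffices — but the
generator does emit multiword phrases as adjacent tokens so the longest
matcher is exercised), temporal dynamics, user networks, spelling noise, and
topic correlation between vocabulary and demographics beyond the planted
design. Passing the validation suite therefore demonstrates correctness of
the statistics and plumbing on corpora with known structure, not performance
on real social text.

# Numerical and validation choices

- Sum-to-one tolerances: 1e-6 at loading and scoring; the zero-sum identity
  of relative differences is asserted at 1e-9.
- Degenerate inputs: empty corpora, single-group partitions, empty
  dictionaries and all-missing attributes raise immediately with the stage
  named; malformed corpus lines are skipped and counted, fatal only past 50%.
- Determinism: a generator seed fixes the corpus byte-for-byte; the pipeline
  itself is deterministic, so rerunning a config reproduces report bundles
  byte-identically.
- Validation sizes (chosen once): oracle-equivalence corpora of 200 posts
  (the chain is compared item-for-item, to 1e-12, against a brute-force
  recount written without the package's indexing); recovery at 2 × 5000
  posts; null calibration with 1000 replicates at 500 posts/group (rejection
  rate expected in [0.02, 0.09] at α = .05); power with 200 replicates at
  1000 posts/group under 0.40-vs-0.25 emotion injection (expected ≥ 0.95);
  matcher equivalence on 1000 random token strings against an exhaustive
  maximal-match scan.

# Known limitations

Keyword relevance filtering uses exact token-boundary surface matching —
consumer abbreviations absent from the list (e.g. "ivf") are missed, as is
inherent to keyword filters. Dictionary concept tagging has no variant
generation or disambiguation beyond POS and the blacklist. Name-based
classifiers inherit the biases of their frequency tables and label only
dominant names. The readability heuristic counts syllables approximately;
grades are comparable within the pipeline rather than calibrated against
human judgments. Negation ("not happy") is not handled in sentiment scoring.
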