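---
title: "Detecting and summarising localised events in geo-tagged tweet streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and summarising localised events in geo-tagged tweet streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twevent)
```

## The surveillance model

`twevent` treats a stream of geo-tagged tweets as a syndromic-surveillance
signal. An *event* is a real-world occurrence that produces a substantial,
localised burst of tweets matching one keyword group (an illness symptom such
as *vomit*, or an emotion such as *sadness*) inside one geographic area. The
pipeline reduces the stream to daily count series per (keyword group, area)
and applies aberration detection to each series independently.

The assumptions this rests on:

* tweet coordinates are accurate enough that a convex hull around a
  population centre captures the local conversation;
* symptom/emotion vocabulary is stable enough that a static keyword-group
  configuration captures the relevant tweets (matching is by consecutive
  token phrases, so `flu` never fires inside `flute`);
* daily counts are roughly stationary outside events, with a weekly
  periodicity (weekends busier) and heavy zero-skew in small areas.

## Detection

**Geographic areas.** DBSCAN over great-circle (haversine) distance groups a
sample of tweet coordinates into density clusters; each cluster becomes a
convex hull, and points outside every hull fall into a reserved noise sink
excluded from analysis. DBSCAN border points are order-dependent by
construction; we fix the scan order to input order and expand neighbourhoods
first-in-first-out, so results are reproducible and testable against a
reference implementation. Overlapping hulls are resolved by smallest area
(the more specific area wins); hull boundaries count as inside. `eps` (km)
and `min_points` have no universal defaults — they depend on the fixture's
point density — and are therefore exposed in `tnt_config()` and set
explicitly wherever a model is built.

**Weekly normalisation.** Counts are divided by a trailing weekday factor
`f(w) = mean(count | weekday w) / mean(count)` over the previous 56 days
(14 days of history minimum, else `f = 1`; factors floored at 0.1). The
scheme is causal (no look-ahead) and exactly flattens a stationary weekly
pattern once the window is full. With under eight weeks of history the
per-weekday means rest on two or three observations and the factors are
noisy; early in a series this can inflate a normalised count, which is one
reason a severity filter on top of the raw detectors is essential.

**EARS C2/C3.** C2 flags day *t* when the count exceeds the mean of a 7-day
sliding baseline by more than 3 baseline standard deviations (sample sd,
floored at 0.5 so an all-zero baseline still defines a trigger). The
pipeline default places the baseline at days *t−9 … t−3* — the standard EARS
placement with a 2-day guard band. The guard band matters for sharp bursts:
with the baseline abutting the tested day, the first burst day enters the
second burst day's baseline and suppresses it, so a 2-day burst yields a
1-day alarm whose gist is then often too small to summarise. The
`c2_flags()` primitive itself defaults to no gap, and `c2_gap_days = 0`
restores the abutting variant. C3 is formalised as "at least 2 C2 alarms in
the trailing 3 days"; the CDC cumulative-exceedance form is available as
`c3_mode = "cdc"`. A day is alarmed when either detector fires, and maximal
runs of alarmed days form one alarm — an alarm ends only when both
detectors go quiet.

**Severity and spam.** Because small-area counts are zero-skewed, alarm
strength uses medians: `mu = (observation − median) / MAD` with the median
and the median absolute deviation taken over *all* prior counts of the
series, and `mu_max` the maximum over the alarm's days. The MAD is floored
at 1 (configurable): a half of all historical days identical would otherwise
make the statistic infinite. The event filters are `mu_max >= 4` (the
balanced operating point of the threshold sweep on the packaged evaluation
table; 6 trades recall for precision 1) and a tweets-per-author ratio of at
most 1.5 — a one-author flood is spam, and the spam label takes precedence
when both filters fail. Thresholds are compared as "at or above" for
severity and "strictly above" for spam rejection.

**The noise filter.** For symptom groups, a pluggable classifier can strip
tweets that mention symptoms without self-reporting them ("flu research" vs
"flu got me"). The shipped trainer is a ridge-penalised logistic regression
over binary bag-of-words features; the model is a plain
vocabulary/weights/bias triple, so an externally trained linear predicate
drops in unchanged. Its published-scale accuracy is not reproducible here
(the original labelled corpus is unavailable); tests instead verify the
interface on separable synthetic labels.

## Summarisation (Terms–News–Tweets)

For an event, the *gist* is the matching tweets in the event's area and
period, and the *baseline* the same filter over the preceding 28 days.
Events with fewer than 30 gist tweets are not summarised. The stopword list
is a standard English list plus the 200 most frequent tokens of the tweet
corpus (the whole tie group at the cut is kept). Candidate unigrams/bigrams
must appear in at least 5 % of gist tweets (per-tweet presence is binary;
bigrams join adjacent tokens *after* stopword removal, so "air pollution"
survives an intervening "the"). Enrichment over the baseline is a one-sided
Fisher exact test (hypergeometric tail, α = 0.05, no multiple-testing
correction — the selection keeps only the top two unigrams and bigrams
anyway), and the triggering primary keyword is appended.

**News linkage.** Each term queries a local news corpus (the pluggable
replacement for a manual web search): articles in the event window plus one
day (next-day reporting), ranked by cosine between the term and a TF-IDF
document vector with title tokens counted twice. A term's retrieved set is
*coherent* when its PCSS — the mean of all pairwise TF-IDF cosines minus
their population standard deviation — is at least −0.08. Body vectors are
Lancaster-stemmed unigrams with `tf · ln(N/df)` over the retrieved set
itself, so a stem present in every retrieved article vanishes. Coherent
terms must additionally be *related* to at least one other coherent term:
the cross-set PCSS over title vectors (unigrams+bigrams+trigrams, no
stemming) must reach 0.05. Two numerical choices here are deliberate
deviations from the obvious reading:

* *Title IDF corpus.* Computing IDF over only the two compared title sets
  annihilates exactly the shared story vocabulary that signals relatedness
  (a feature in every title has `idf = 0`), to the point that two searches
  retrieving the *same* articles score as unrelated. Title IDF therefore
  comes from the full news corpus titles; the per-pair union remains the
  fallback when no corpus is supplied.
* *Relatedness threshold.* The cross-PCSS of two title sets with disjoint
  vocabulary is exactly 0 (all cosines 0, zero spread), so any non-positive
  threshold would relate everything to everything. The default is the small
  positive 0.05; coherence keeps the −0.08 operating point, which was tuned
  on article bodies where cosines are never exactly zero.

Articles of the surviving ("good") terms are ranked by cosine to their
set's arithmetic-mean vector, merged, deduplicated keeping the higher score,
and capped at five. Tweets are ranked the same way (unstemmed unigram
TF-IDF over the tweet set, ties by timestamp then id): the *GTT* list ranks
the whole gist, the *STT* list ranks the gist filtered to tweets containing
a good term, falling back to the extracted terms, and is omitted when no
terms were significant.

## The synthetic generator

`scenario_config()` fixes the study conditions the tests and the acceptance
script run under: two Gaussian-scatter cities (6 km spread, 85 % of tweets
in-cluster, the rest on a broad background), three keyword groups at a
Poisson baseline of λ = 5 tweets/day per (city, group) over 70 days, weekday
multipliers giving weekends ≈ 15–20 % more activity, one injected 2-day 6×
burst carrying four planted vocabulary terms (two unigrams, two bigrams;
emitted with probability 0.8 per burst tweet), one 20-tweet single-author
spam burst, five planted news articles sharing an anchor headline phrase and
a story detail pool, and twelve distractor articles in three internally
coherent off-topic groups, one of which runs concurrently with the event.
Background text is drawn from a 230-word Zipf-weighted common pool plus a
rare tail, sized so the corpus-derived top-200 stopword cut lands inside the
common pool and safely above the planted terms' frequency.

What the generator does *not* emulate: real tweet language (texts are
vocabulary scaffolding, so nothing is learned about tokenising slang or
misspellings), seasonal trends, population-dependent baselines, retweet
cascades, or adversarial spam. Passing the synthetic recovery suite
therefore shows the machinery is correct and calibrated under its stated
conditions, not that the operating thresholds are optimal for any particular
real stream.

## Degenerate inputs and tie-breaks

Clusters with fewer than three distinct or all-collinear points cannot form
a polygon and are dropped with a warning. An empty history errors in
`mu_statistic`; alarm days with no history are skipped in `mu_max`. Term
selection breaks p-value ties by higher gist count, then lexicographically.
Search and ranking ties break by date/timestamp then id. The event-id
scheme (two keyword letters + area code + start day-month) disambiguates
collisions with a numeric suffix. Problem sizes in the shipped tests —
70-day series, ~2,000-tweet streams, 100-seed repetitions, exhaustive
Fisher tables to margin 30 — were chosen as the smallest sizes at which the
statistical properties under test are stable.

## Limitations

Detection is per-series; multi-cause events in one series are summarised as
one event. There is no seasonal baseline, so annual cycles (e.g. hayfever)
inflate μ against an off-season history. The convex-hull geometry cannot
represent concave regions, which is why overlapping hulls need the
smallest-area rule. The published corpus-scale results (alarm counts over
months of national data, classifier accuracy, human-coded match rates)
cannot be recomputed here and are not claimed by this package.
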