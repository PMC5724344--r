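---
title: "Retrieval model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctsearch` is a desk-scale content-based retrieval engine for head-CT
study corpora: bag-of-visual-words image indexing and stemmed-text
indexing in a single inverted index, with text, image, combined and
filtered search, an evaluation harness, and a synthetic phantom
generator. This vignette explains the model, the parameters that matter,
the deliberately open design points and how they were resolved, and what
the synthetic data does and does not establish.

## Retrieval unit and index

The unit of retrieval is the *study*: an ordered set of CT slices plus
its report document (anamnesis — the clinical question — and the report
text) and patient metadata. Text stems and visual words share one
physical inverted index under the namespaces `t:<stem>` and `v:<int>`;
text postings are study-level (`image_id` empty), visual postings are
image-level. Indexing runs in two phases. The initial batch build trains
the visual vocabulary and indexes the whole corpus; background indexing
then adds new studies against the *frozen* vocabulary, never retraining
it, so batch and incremental builds over the same studies are
byte-identical once serialized. Whether text stems unseen during the
initial build should be indexed in the background phase is genuinely
underdetermined for a system whose visual vocabulary is frozen; we index
them by default (an *open* text lexicon, because silently dropping new
clinical vocabulary degrades search for exactly the newest studies) and
provide `strict_text = TRUE` for the literal frozen-lexicon reading.

A study that fails to process during a batch is skipped and recorded as
`failed` in the manifest rather than aborting the build: background
indexing over a live archive must be resilient to single malformed
studies.

## Image representation

CT intensities are Hounsfield units spanning roughly −1000 (air) to
+1000 and beyond (bone). Raw HU dynamic range would swamp soft-tissue
texture in any gradient statistic, so slices are first passed through the
standard *brain window* (center 40 HU, width 80 HU) and scaled to [0, 1];
bone and air saturate and the parenchymal range occupies the full scale.
Descriptors are computed on a dense grid — 16-pixel patches at stride 8 —
as 4×4-cell, 8-orientation gradient-orientation histograms
(128 dimensions), magnitude-weighted and L2-normalized. Patches whose
windowed intensity variance falls below 10⁻⁴ are discarded; this removes
the flat air background and uniform parenchyma, keeping roughly the
skull ring, tissue boundaries and lesions. All descriptor parameters are
configuration (`descriptor_config()`), not claims about any particular
clinical system.

A rectangular region of interest is honored by *filtering the full-image
grid by patch center* rather than re-gridding the crop. This makes the
ROI result an exact subset of the full-image result — the subset
invariant `counts(roi) ≤ counts(full)` holds exactly — at the cost of
slightly fuzzy ROI edges (a patch whose center is inside but whose
support pokes outside is kept). Coordinates are 0-based and half-open
throughout.

The vocabulary is plain *k*-means (default *k* = 256 over at most
100 000 sampled descriptors) with k-means++ initialization under a fixed
seed and Lloyd iterations capped at 25, so vocabulary building is fully
deterministic given the descriptor sample and seed. Quantization assigns
each descriptor to the nearest centroid by Euclidean distance with exact
ties broken toward the lower centroid index — a total, reproducible rule
that an exhaustive scan can verify.

## Text representation

Tokenization lowercases, splits sentences on `.!?`, and keeps
alphanumeric runs. Negation filtering removes, within each sentence, the
first negation cue and everything after it; negation never crosses a
sentence boundary. This cue-to-sentence-end scope is the simplest rule
consistent with the observed behavior of deployed report-search systems
(whose negation handling is known to be imperfect), and the cue lexicon
is a plain-text file so new filtering rules can be added without code
changes. The shipped cues are English plus the Finnish "ei" as a
localization placeholder.

Stemming is pluggable; the default is our implementation of the Porter
(1980) algorithm, with an identity stemmer for exact-term work. Stems
carry raw counts only. *No importance weighting exists anywhere in text
scoring*: a study's score for a query is the number of distinct query
stems present in its postings. This makes "combinations" of query words a
ranked-AND — studies matching all stems outrank partial matches — rather
than a hard AND, which would be unable to return the partial matches that
real report search visibly produces.

The default field scope is `report_only`. Indexing the anamnesis
alongside the report (`report_and_anamnesis`) reproduces a
well-documented failure mode — studies retrieved because the *question*
("Suspected haemorrhage?") contains the sought term without the finding
being confirmed — and is retained precisely so that the two behaviors can
be compared on synthetic corpora.

## Search modes and ranking

All orderings are total and deterministic (scores, then ids), so runs are
reproducible and comparable against brute-force oracles.

* **Text**: score = distinct matched stems, ties by total matched
  frequency, then study id. Filters apply before truncation to the
  100-study cap.
* **Image**: per-image score = distinct shared visual words with the
  query bag; images below `min_shared` (default 1 — the threshold is a
  named, configurable concept rather than a fixed constant) are dropped;
  per study the top 5 images are kept (ties to the lower image id) and
  the study score is its best image's score.
* **Combined**: studies matching both modalities always precede
  single-modality matches. Raw stem counts and shared-word counts are
  incommensurable, so each modality is min-max normalized *over the
  studies matching that modality*; the both-block orders by the sum of
  normalized scores, and the trailing block merges text-only and
  image-only studies by their single normalized score with image matches
  first on ties. The choice of normalization set and the trailing-block
  merge rule are documented decisions, not fidelity claims: "results
  matching either query independently" does not by itself fix an
  intra-block order. A degenerate normalization range (all candidates
  equal) maps to 1, so a single matching study still counts fully.

The caps — 100 studies per page, 5 shown images per study — are the
system's fixed presentation constants, held in `index_config()`.

## Synthetic phantom generator

The generator emulates a hospital export at desk scale: per study, an
elliptical skull ring (1000 HU) around brain parenchyma (40 HU) on an air
background (−1000 HU), with one of four ground-truth classes — a
hyperdense haemorrhage blob (80 HU), a hypodense infarct wedge (10 HU),
scattered bright calcification dots (400 HU), or normal. The HU palette
mimics real head-CT contrast ordering (haemorrhage just above brain and
saturating the brain window; infarct below; calcification hard-saturated)
and is a fixture constant, not a radiometric claim. Lesion geometry is
jittered per seed inside the brain ellipse — retrieval must not depend on
one fixed shape — and the brain ellipse itself is jittered slightly
between studies because real heads vary; without that anatomical
variation, normal studies would be near-duplicates of each other.
Per-slice Gaussian noise (default 5 HU) is added and pixels are rounded
to integer HU so DICOM round trips are lossless. All slices of a study
share one 2-D geometry; 3-D lesion continuity is a non-goal.

Reports are drawn from class-matched templates: every class has at least
three asserting sentences, two negated forms ("No *finding* seen.") and
question-form anamneses ("Suspected *finding*?"). A lesion study asserts
its own finding and may negate another; a normal study only negates. This
makes the negation filter and the anamnesis-scope distinction exercisable
with known ground truth. Corpus class counts follow largest-remainder
rounding of the requested mix, and every study's seed derives
deterministically from the corpus seed.

Defaults are 12 slices of 128² pixels. The test suite and the acceptance
script run smaller problems — 64² slices, 1–2 slices per study,
vocabularies of 16–256 words, corpora of 3–150 studies — which are this
package's chosen desk-scale study conditions; the self-retrieval check
uses the default 256-word vocabulary, and the retrieval-quality check
runs 40 queries against an 80-study, four-class corpus.

What passing these tests shows: the indexing and ranking rules are
implemented exactly (oracle equivalence), the engine retrieves identical
images perfectly, and the visual representation carries enough class
signal on high-contrast phantoms to beat the 0.25 same-class chance level
by a wide margin (mean study-level P@10 ≈ 0.35 under the conditions
above). What it does not show: performance on real CT, where lesions are
textured, low-contrast and confusable, anatomy varies qualitatively, and
reports are free prose in an inflected language. The phantom's pixel
statistics are deliberately minimal; no anatomical realism is attempted.

## Numerical and degenerate-input choices

* Exact quantization ties → lowest centroid index; all ranking ties →
  ascending study/image id.
* `k` ≥ distinct descriptors: the distinct vectors become the centroids
  (zero inertia) with a warning when `k` had to shrink.
* Featureless query images (no patch above the variance threshold) are a
  query error, not an empty page, so the caller can distinguish "nothing
  similar" from "nothing to search with".
* Precision@k with fewer than `k` results uses min(k, n) as denominator:
  reported aggregates would otherwise not be consistent with fixed-k
  denominators when some queries return short pages. Both the per-query
  mean and the pooled aggregate are reported, since either aggregation is
  defensible; reported rates round to nearest integer percent with the
  unrounded value retained.
* Markings with rank gaps are rejected (incomplete marking), mirroring
  how skipped tasks are detected in practice.
* Index persistence is staged-then-renamed so failures never leave a
  partial index; manifests carry MD5 checksums of the postings and
  centroid files, and loading verifies them plus the format version.
* DICOM output stores pixels with RescaleIntercept −1024/slope 1 so
  integer HU values round-trip exactly; the in-package reader/writer
  covers exactly this uncompressed Explicit-VR-Little-Endian subset.

## Known limitations

Finnish morphology is out of scope (the stemmer interface is the
extension point); there is no medical-concept normalization, so the
engine cannot know which terms are diagnostically significant; no
geometric verification or learned descriptors; no result pagination or
relevance feedback; background indexing models the archive interface as
a watched directory, not a live PACS/RIS connection.
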