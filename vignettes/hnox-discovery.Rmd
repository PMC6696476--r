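---
title: "Motif-based discovery of candidate NO-binding proteins and heme spectral-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based discovery of candidate NO-binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnoxscout)
```

## The problem

Heme Nitric Oxide/Oxygen (H-NOX) domains let bacteria and animals sense
nitric oxide through a heme cofactor whose proximal histidine is displaced
when NO binds. Plant genomes encode no full H-NOX domain, but complex
multi-domain plant proteins can carry a *reduced* H-NOX center: just the
handful of conserved residues that accommodate heme b — a proximal
histidine, a heme-flattening proline, and the YxSxR signature that
hydrogen-bonds the heme propionates. Such centers are invisible to
BLAST-level homology search because the conserved residues are few and far
apart. They are, however, exactly what a flexible-gap pattern can find.

`hnoxscout` implements that search strategy end to end:

1. **Motif grammar** — flexible-gap patterns such as
   `Hx(12)Px(14,16)YxSxR`: fixed residues separated by bounded wildcard
   gaps (`x` = one residue, `x(n)` = exactly *n*, `x(n,m)` = between *n*
   and *m*).
2. **Motif extraction** — building such a pattern from an alignment of
   functional centers whose critical columns are annotated.
3. **Relaxation** — dropping an interior fixed residue (e.g. the proline,
   which in bacterial H-NOX domains tunes oxygen affinity rather than NO
   binding) and merging the flanking gaps: `Hx(12)Px(14,16)YxSxR` becomes
   `Hx(27,29)YxSxR`, a strictly more permissive pattern with the same span.
4. **Proteome scanning** — exhaustive enumeration of every realization of
   the pattern on every protein, with locus-level candidate aggregation.
5. **Spectral validation** — a rule-based classifier for the heme UV/Vis
   states that wet-lab follow-up of a candidate produces, plus analyses of
   NO-titration saturation and post-saturation dissociation series.
6. **Synthetic data** — seeded generators for proteomes with planted motif
   instances and for state-templated spectra, so every stage is tested
   against exact ground truth.

## The motif model

A motif is an ordered token list: `FIXED` tokens carry one of the 20
standard amino-acid letters; `GAP` tokens carry bounds
`1 <= min <= max`. Canonical form — enforced by `parse_motif()` and
produced by every operation — merges adjacent gaps by summing bounds and
requires fixed tokens at both ends, so a motif is always anchored and its
occupied span is always between `sum(min)` and `sum(max)` residues
(`span_bounds()`). For both H-NOX patterns above that is 33–35 residues,
consistent with a center printed as spanning residues 357 (H) through 391
(R): 35 positions.

Relaxation (`relax()`) turns one interior fixed token into a `gap(1,1)`
and merges; because merging sums bounds, span bounds are invariant and the
language only grows. Both properties are tested: the former exactly, the
latter with `language_contains()`, an enumeration oracle that generates
every string the inner motif matches (over a small alphabet) and checks it
against the outer motif, refusing explicitly — never truncating silently —
when the enumeration budget would be exceeded.

Design choices worth stating:

* `X` is the gap symbol of the dialect, so it can never be a fixed
  residue; the degenerate codes B, Z, J, U, O are rejected at fixed
  positions too. On the *sequence* side those letters are allowed: they can
  sit inside a gap but never satisfy a fixed token — the conservative
  reading, which never claims a fixed-residue identity that is not there.
* Parsing is case-insensitive; canonical output is upper-case.
* No PROSITE character classes (`[...]`/`{...}`): the dialect used for the
  H-NOX search does not need them, and the grammar stays extensible.

## Scanning semantics

`find_matches()` enumerates **all realizations**: every
`(start, gap-length vector)` whose fixed residues agree with the sequence,
ordered by `(start, end, gap vector)`. A
`LEFTMOST_SHORTEST_PER_ANCHOR` policy keeps one realization per anchor
(the lexicographically smallest gap vector). Candidate counting is always
by distinct sequence ID, so realization multiplicity never inflates
protein counts. Coordinates are 1-based inclusive throughout, matching
protein residue numbering (H357 means the 357th residue).

Internal `*` terminators split a sequence into segments scanned
independently — a match never crosses a stop codon's translation. `-` and
`.` are stripped on FASTA input with a warning. The scanner is
deterministic; there is no randomness anywhere in discovery.

Correctness is established against a deliberately naive brute-force oracle
(every start, every gap vector, a per-token walk) on >1000 random
sequences per test run, plus planted-instance recovery and an analytic
calibration: under an i.i.d. residue model the expected number of
realizations is

$$E = \sum_{g} \left(L - \mathrm{span}(g) + 1\right)^{+} \prod_{k} f(r_k),$$

summing over gap vectors *g* and fixed residues *r_k*
(`expected_random_hits()`). For `Hx(27,29)YxSxR` on 10,000 uniform
residues this gives 0.1869 expected realizations; Monte Carlo totals over
200 seeded 1000-mers are required to sit within 3 Poisson sigma of the
closed form.

Locus collapsing normalizes AGI gene-model identifiers
(`At4g01160.2` → `AT4G01160`) so isoforms of one locus form a single
candidate; any non-AGI identifier is grouped verbatim. The original
search's published counts (4 strict candidates widening to 34 after
dropping the proline) left ambiguous whether 34 counts gene models or
loci, and which proteome release was queried; reproducing those absolute
numbers therefore requires an external proteome download and is outside
the test scope. The pipeline test instead reproduces the *widening
structure* exactly — 4 planted strict instances plus 30 relaxed-only
instances yield reported counts of 4 and 34 matching records.

## Motif extraction from center alignments

`build_motif()` consumes an alignment whose *critical columns* — the
functionally annotated heme-contact residues — are user-supplied, not
inferred: the original centers were chosen by functional annotation, and
conservation scoring is deliberately out of scope. Each critical column
must carry one unanimous residue and no alignment gap; each stretch
between consecutive critical columns becomes a bounded gap whose limits
are the min and max residue counts over rows. A stretch that is empty in
some row would break the anchoring semantics (`gap(min >= 1)`) and is an
error, as are residues outside the outermost critical columns (the motif
could not describe them). `validate_alignment()` reports every violation;
its report is empty exactly when `build_motif()` will succeed.

The reconstruction property ties builder and grammar together: realizing a
motif at its extreme gap vectors, padding with `-`, and rebuilding from
the fixed-token columns returns the original motif.

## Heme spectral states

The classifier encodes the canonical Soret-band assignments for a
histidine-ligated heme b protein:

| state | Soret (nm) | other bands |
|---|---|---|
| ferric, His-ligated | 408 | broad ~530 absorption |
| ferrous 6-coordinate (dithionite-reduced) | 418 | beta 525, alpha 553 |
| ferrous 5c-nitrosyl (NO-bound, His displaced) | 398 | — |
| free hemin | 436 | broad ~400 shoulder |
| apoprotein | none | — |

Rules are ordered and window-based (defaults ±4 nm around Soret centers,
±5 for hemin, ±6 for alpha/beta; all configurable via
`heme_state_windows()`): no Soret → apo; Soret in the hemin window → free
hemin; Soret at 418 **with** both alpha and beta bands → ferrous 6c; Soret
at 398 → 5c-NO (no alpha/beta requirement — those bands vanish on NO
binding); Soret at 408 → ferric; otherwise `AMBIGUOUS` with the partially
matching candidates listed. The 6c test precedes the 398/408 tests so the
alpha/beta requirement disambiguates a 418 nm Soret from nearby shoulders.
The transient 6-coordinate NO intermediate (~420 nm) is deliberately *not*
a built-in state — it was not observed in the study this models — but
custom windows can represent it.

Peak detection subtracts a linear baseline estimated on the flat 570–600 nm
tail, finds local maxima above a topographic-prominence threshold
(default 0.02 AU), and refines each apex to sub-grid precision with a
half-height centroid bounded by the peak's prominence cols (3-point
parabolic interpolation is the fallback for peaks only a few points wide).
The centroid was chosen over a plain 3-point parabola because broad Soret
bands (sigma 10–14 nm) on a 1-nm grid carry little curvature at the apex:
at a signal-to-noise ratio of 20 the parabola's position error is ~1–2 nm
worst-case, while the bounded centroid keeps the RMS error below 0.5 nm
for band widths up to sigma = 14 nm. Worst-case single-draw error for very
broad bands at SNR exactly 20 remains information-limited (~1 nm); the
classification windows (±4 nm) absorb this comfortably.

Smoothing (`smooth_spectrum()`) is moving least-squares polynomial
fitting — Savitzky-Golay on the uniform interior, with symmetric window
shrinkage at the ends so the grid is unchanged; polynomials up to the
fitting order are reproduced exactly. `classify_spectrum()` smooths by
default (window 11 points, order 2): at 0.01 AU noise this keeps spurious
noise prominences well below the 0.02 AU peak threshold, which is what
holds classification accuracy above 95% in the seeded-noise tests.

## Titration and dissociation

`analyze_titration()` implements the operational saturation criterion used
at the bench: donor addition has saturated the protein when further
addition causes no further spectral change. Concretely, the saturation
index is the smallest step from which on *all* consecutive max-norm
spectral differences stay below the tolerance (default 0.005 AU). Indices
are 1-based, as is idiomatic in R — a series of identical spectra
saturates at index 1. The analysis is invariant under joint scaling of
absorbance and tolerance. Because raw consecutive spectra are compared,
the tolerance must exceed the expected noise-difference amplitude
(roughly `3 * sqrt(2) * noise_sd` at 251 grid points); the synthetic
titration tests use noise at or below 0.003 AU against the 0.005 AU
tolerance accordingly.

`gen_titration()` drives the mixture with a one-site binding isotherm,
fraction bound $f = c/(K_\mathrm{app} + c)$, between the clean ferrous and
5c-NO template spectra. This yields a closed-form oracle for the
saturation index (the first step where the isotherm increment times the
max-norm distance between end-state spectra drops below tolerance), which
the analysis must reproduce exactly. A variant with doubled
$K_\mathrm{app}$ — emulating a heme-pocket mutant with halved apparent NO
affinity — must saturate at a donor concentration at least as high as the
reference; this mirrors the experimental observation that roughly twice
the NO source was needed to saturate the H357L mutant, kept here as an
ordering property rather than a quantitative claim.

`analyze_dissociation()` watches a post-NO-saturation time series for the
return of the ferric 408 nm Soret — the spectral signature of slow NO
release and re-oxidation — by classifying each spectrum and reporting the
first ferric time point. `gen_dissociation()` mixes 5c-NO toward ferric
with first-order kinetics $1 - e^{-kt}$; the detected recovery time must
match a clean-mixture classification oracle within one sampling interval,
and a faster rate (the mutant's quicker NO loss) must recover no later
than a slower one. No chemical kinetics are modelled beyond this: the
analysis is purely spectral-state detection over time.

## What the generators do and do not emulate

The proteome generator draws i.i.d. residues (uniform by default,
arbitrary frequencies supported), plants motif realizations with uniformly
sampled gap vectors, and in *exclusive* mode re-rolls any record whose
scan result differs from the recorded truth — making the truth table
exact, which is what the 100%-recall tests rely on. AGI-style identifiers
with optional `.2` isoform duplicates (sharing the planted region,
truncated shortly after it) exercise locus collapsing. Real proteomes are
not i.i.d. — they have composition bias, repeats, domain structure and
homologous families — so passing calibration here validates the scanner's
arithmetic, not any claim about the true-positive rate on a real proteome.

Synthetic spectra are sums of Gaussian bands on a linear baseline with
i.i.d. Gaussian noise. Real heme spectra have asymmetric band shapes,
correlated baseline drift and instrument artifacts; the classifier uses
only peak positions and prominences, which is why Gaussian templates are
an adequate test bed for it, and why its verdicts on real data should be
reviewed whenever `AMBIGUOUS` calls or borderline prominences appear.

Every generator takes a mandatory seed and is byte-reproducible.

## Problem sizes and numerical choices

The shipped tests run the scanner-vs-oracle comparison on 1020 random
sequences (lengths up to 60), Monte Carlo calibration on 200 random
1000-mers, and classifier accuracy on 500 seeded noisy spectra
(251-point grids, 350–600 nm) — sizes chosen so the whole suite completes
in about two minutes while keeping the Poisson and binomial margins
meaningful. Ties in peak prominence are broken by detection order;
gap-vector ties in match ordering are broken lexicographically; all
floating-point comparisons in the analyses are plain `<` against stated
tolerances, with no hidden epsilons.

## Limitations

* Absolute reproduction of the published Arabidopsis candidate lists
  requires the (unstated) proteome release and is not attempted offline;
  locus handling is tested synthetically.
* The motif grammar has no character classes and no unanchored patterns.
* The classifier is a window rule-set, not a fitted spectral model; it
  reports `AMBIGUOUS` rather than guessing when windows conflict.
* Dissociation analysis reports classifier crossover times, not rate
  constants.

## A minimal session

```{r example, eval = FALSE}
strict <- parse_motif("Hx(12)Px(14,16)YxSxR")
relaxed <- relax(strict, fixed_token_index(strict, "P"))
format_motif(relaxed)            # "Hx(27,29)YxSxR"

pr <- gen_proteome(20, 500, motif = strict, n_plants = 4, seed = 1)
ms <- scan_proteome(relaxed, pr$records)
collapse_to_loci(ms)

sp <- gen_spectrum(spectrum_template("ferrous", noise_sd = 0.005), seed = 2)
classify_spectrum(sp)

tit <- gen_titration(K_app = 50, seq(0, 1000, 25), seed = 3)
analyze_titration(tit, tolerance = 0.005)
```
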