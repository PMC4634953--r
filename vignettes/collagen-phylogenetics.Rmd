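---
title: "From ancient collagen peptides to phylogenies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ancient collagen peptides to phylogenies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagenphylo)
```

## The problem

Type 1 collagen is the dominant protein of bone and survives in fossils an
order of magnitude longer than DNA. Shotgun proteomics of ancient bone
therefore yields peptide-spectrum matches (PSMs) against the two collagen
chains (COL1A1, COL1A2) of long-extinct taxa — for example Pleistocene
giant ground sloths — from which partial amino-acid sequences can be
assembled and placed on a phylogeny of extant mammals. The data are,
however, noisy in characteristic ways: search engines produce false
positive matches, coverage is partial (typically 56–77% of the molecule
per analysis) and varies between duplicate specimens, hydroxylation of
proline/lysine and deamidation of asparagine/glutamine shift peptide
masses, and leucine/isoleucine are isobaric and cannot be distinguished
at all. `collagenphylo` implements the complete workflow — filtering,
consensus assembly, fingerprint comparison and maximum-likelihood
phylogenetics — together with a seeded generator of synthetic degraded
datasets so that every stage is testable without access to raw mass
spectra.

## Stage by stage

### In-silico digestion and mass arithmetic

Trypsin cleaves after K and R; collagen's frequent `-K-P-` / `-R-P-`
motifs make the *trypsin/P* convention (cleave even before proline) the
appropriate rule, and it is what `tryptic_digest()` implements, with up
to a configurable number of missed cleavages and the C-terminal peptide
always emitted. `peptide_mass()` sums monoisotopic residue masses plus
water and applies the modification deltas at full precision
(carbamidomethyl-C +57.021464, hydroxylation/oxidation +15.994915,
deamidation +0.984016 Da); the commonly printed 2-dp values would
accumulate error over long peptides. Methionine oxidation is
mass-identical to K/P hydroxylation; whether M counts as an eligible
oxidation site is a flag (`include_met_ox`), off by default to match the
error-tolerant search convention and on for decoy-style searches.

### Target–decoy filtering (the HFPS rule)

Each analysis is filtered at the *highest false positive score*: the
maximum score among decoy PSMs of that analysis. `filter_by_hfps()`
keeps target matches scoring **strictly above** that threshold ("greater
than", not "at least"), so by construction no retained match is as weak
as the strongest known false positive and the decoy-estimated FDR of the
retained set is zero. `fdr_percent()` reports the conventional
`100 · decoys/targets` summary (the source workflow tabulates an FDR
without giving its formula; this estimator is the simplest and is
documented so the reports are interpretable). The both-specimens rule
(`replicate_intersection()`) keys matches by (stripped peptide sequence,
chain, reference position) by default; modification state is ignored
because PTMs are diagenetic and vary between specimens, and a `"seq"`
key is available because it is genuinely ambiguous whether position
should participate.

### Consensus assembly

`assemble_consensus()` writes each covered alignment site from its
peptides; uncovered sites are `X`, and sites that are indels in other
taxa are `?` (driven by the reference alignment, not inferred). Where
peptides disagree, the residue with the greatest summed PSM score wins
and an exact tie yields `X` — the original workflow resolved conflicts
manually, and an automated pipeline needs a deterministic rule.
Isobaric harmonisation (`normalize_isobaric()`) replaces proteomic I/L
calls at mixed columns by the column's more abundant letter, never
touching database-derived references, with ties keeping the observed
letter. Chains are concatenated via a single `R` linker residue
(`concatenate_chains()`), giving 1056 + 1 + 1041 = 2098 columns at the
default chain lengths. Variation counts (`count_variations()`) only
consider columns determined in both sequences; replicate-confirmed
counts (`count_confirmed_variations()`) additionally require both fossil
specimens to agree, and in `run_full()` the unconfirmed counts are
computed on the either-specimen consensus so confirmed ≤ unconfirmed
holds by construction.

### MALDI fingerprint comparison

Peptide-mass fingerprints are compared by the number of shared peaks
among each spectrum's 100 most intense peaks (`top_n_peaks()`, ties at
the cutoff resolved to the lower m/z). `shared_peak_count()` builds a
one-to-one matching greedily by ascending m/z distance — preventing one
peak from matching many — within a tolerance of ±0.2 Da by default, a
conventional externally calibrated PMF window (the source workflow does
not state its tolerance); a ppm mode is available. The statistic is
symmetric, bounded by the smaller list, and monotone in the tolerance.

### Maximum likelihood under JTT + I + G

The phylogenetic engine is self-contained. The model embeds the
published JTT exchangeabilities and frequencies (a `+F` variant takes
observed frequencies); the rate matrix is scaled to one expected
substitution per site per unit branch length. Rate heterogeneity uses
equal-probability discrete-gamma categories with **mean-of-bin** rates
(not medians — the two differ numerically; the mean version integrates
to exactly 1), and under `+I` the gamma rates are divided by
`1 − p_inv` so the model's overall mean rate stays 1 — the convention of
the major ML programs. `X`, `?` and `-` are all fully missing: their tip
partials are vectors of ones, so an all-missing column contributes
exactly zero log-likelihood.

Transition matrices come from a symmetric eigendecomposition of
`diag(π)^{1/2} Q diag(π)^{−1/2}`, which guarantees a real spectrum for
the reversible generator and lets branch-length changes reuse the
decomposition. Likelihoods are computed by Felsenstein pruning over
compressed site patterns with per-node rescaling against underflow.
Branch lengths are optimized one at a time by bounded Brent search
(bounds `[1e-8, 20]`, tolerance `1e-6`) in a depth-first sweep that
maintains partial-likelihood "messages" on both sides of the current
edge, so a candidate length costs one 20×patterns product per category
rather than a full pruning pass; a proposal is accepted only if it does
not decrease the likelihood, making sweeps monotone. Model parameters
(`alpha ∈ [0.05, 20]`, `p_inv ∈ [0, 0.8]`) are fitted by coordinate-wise
bounded search interleaved with branch re-optimization.

Topology search starts from neighbor joining on pairwise-deletion
p-distances (taxon pairs with no overlapping determined sites get 1.5×
the largest observed distance) and hill-climbs over nearest-neighbour
interchanges: both rearrangements of every internal edge are scored, the
best strictly improving one is accepted, branch lengths are
re-optimized, and the loop repeats to a local optimum — deterministic
given its inputs. Bootstrap support resamples alignment columns (as
pattern weights, so patterns are compressed once), re-runs the search
per replicate under the fixed fitted model, and maps bipartition
frequencies onto the ML tree; the default is 100 replicates at desk
scale, with the replicate count a parameter for users who want the
conventional thousands. Trees are rooted for display on the outgroup's
pendant edge at its midpoint (`root_at_outgroup()`); under a reversible
model the root placement leaves the likelihood unchanged.

## The synthetic-data generator

`simulation_config()` encodes the study conditions: two chains of 1056
and 1041 aligned residues, per-specimen coverage drawn from U(0.56,
0.77), two specimens per fossil taxon, Mascot-like scores (targets
N(60, 15²), decoys N(15, 6²), decoy set sized at 2% of targets),
collagen PTM rates (hydroxylation 0.4 per eligible K/P, deamidation 0.3
per N/Q — ancient bone is heavily deamidated), 25 MALDI noise peaks in
the 700–3700 m/z window, and a Yule tree scaled to a root-to-tip depth
of 0.08 expected substitutions/site, the magnitude implied by real
mammalian collagen divergence (platypus-to-placental collagen differs by
roughly 10%). Gamma shape 0.5 and invariant proportion 0.2 describe a
conserved structural protein. All randomness flows from one master seed
via fixed offsets, so identical configurations give byte-identical
outputs.

Degradation digests the true chain (≤2 missed cleavages) and retains
each peptide by an independent Bernoulli draw whose probability is
calibrated by root-finding so the **expected** union coverage equals the
specimen's target; the realised per-seed coverage of a single chain then
has a sampling SD of about 5 percentage points, which is why calibration
checks are asserted on means over seeds rather than per seed. Decoys are
reversed-sequence peptides, the standard target-decoy construction.
Simulated fingerprints place peaks at unmodified singly protonated
peptide masses with log-normal intensities plus uniform noise peaks;
PTMs are deliberately not applied there so that identical sequences give
identical m/z sets.

What the generator does *not* emulate: genuine Mascot score
distributions (ours are Gaussian caricatures), correlated peptide loss
(real diagenesis removes regions, which `mask_to_coverage()` mimics
separately with geometric X blocks), chromatographic or fragment-level
effects, isotope envelopes, and collagen's Gly-X-Y positional
constraint (deliberately off by default because the inference model —
JTT — has no positional structure, and tests should match the model
they test). Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not robustness to
every artefact of real ancient-protein data.

## Validation experiments and numerical choices

Four seeded experiments back the package's claims; their problem sizes
are the package's chosen desk-scale defaults:

* **Likelihood correctness.** On 1,000 random instances with ≤5 taxa and
  ≤4 sites (random trees, random alpha/p_inv/k, ~20% missing symbols),
  the pruning log-likelihood agrees with a brute-force sum over all
  internal-node state assignments to better than 1e-8.
* **Topology recovery.** Twenty 8-taxon simulations at the generator's
  defaults (2098 sites), with two non-outgroup taxa masked to 60%
  coverage, are re-analysed end to end. At this collagen-realistic
  divergence the ML tree equals the true tree in most but not all
  replicates; in the replicates where it differs, re-optimizing the true
  topology shows the search had found a tree at least as likely as the
  truth, i.e. the limit is statistical information, not the optimizer.
  Bootstrap support (100 replicates) for the deepest true split is also
  reported.
* **Parameter recovery.** Alpha and p_inv are refit on data simulated at
  alpha = 0.5, p_inv = 0.2 with 5,000 sites. This experiment uses 20
  taxa at root-to-tip depth 0.5 — deliberately deeper and denser than
  the generator default — because the two parameters trade off along a
  nearly flat likelihood ridge otherwise: on shallow 8-taxon data the
  joint MLE can sit at p_inv ≈ 0.1 while exceeding the truth's
  likelihood, so a recovery experiment there would measure the ridge,
  not the estimator.
* **Fingerprint divergence.** Fifty replicate proteins with 1–40
  injected substitutions show a strongly negative Spearman correlation
  between substitution count and shared top-100 peaks.

Degenerate inputs are handled explicitly: empty peak lists, alignments
with unknown symbols, non-standard residues (rejected with the offending
position — selenocysteine and ambiguity codes are errors, not silently
skipped), taxa without overlapping sites, trees with fewer than four
taxa (returned unchanged by NNI), and analyses without decoys (an error
directing the caller to supply a decoy set or explicit threshold).

## Known limitations

The NNI candidate step scores rearrangements with inherited branch
lengths before re-optimizing the accepted one; on likelihood-flat edges
this keeps the starting resolution, which is the correct behaviour for a
deterministic local search but means star-like regions are resolved
arbitrarily. FDR reporting uses the simple decoys/targets estimator, not
q-values. The COL1A2-only mode (`chain_mode = "a2-only"`) analyses the
alpha-2 block alone for comparison with reference sets that lack
alpha-1 sequences. Bayesian analysis and substitution-model selection
are out of scope, as is any re-scoring of spectra: search-engine scores
are consumed, never computed.
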