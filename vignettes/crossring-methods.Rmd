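---
title: "Cross-ring fragment prediction for sodiated glycans: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ring fragment prediction for sodiated glycans: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossring)
```

## The problem

Cross-ring dissociation of singly charged sodium-adducted carbohydrates in
collision-induced dissociation (CID) produces A-type fragment ions whose
neutral losses are diagnostic of the glycosidic linkage: an aldo-hexose at
the reducing end sheds 120, 90 or 60 Da depending on whether the next
residue is attached at O2, O3 or O4, and a 1→6 linkage shows all three
losses. These peaks are routinely used to call linkages. Beyond the
dominant loss, CID spectra contain weak cross-ring peaks that a naive
reading would attribute to other linkages — i.e. to a sample mixture. The
mechanistic picture implemented here explains those minor peaks as
intrinsic products of the same reducing-end chemistry, so a single
structure can account for the whole cross-ring pattern.

`crossring` turns that mechanism into an executable reaction network:
given a glycan structure it enumerates the dissociation pathways, computes
every fragment's elemental composition and m/z (tracking ¹⁸O labels atom
by atom), classifies pathways into major/minor/trace tiers from bundled
transition-state barrier data, and uses the tiered predictions to annotate
peak lists and rank candidate linkages. A separate toolkit implements the
geometric screening used to pick reactant candidates from 3D conformer
ensembles.

## The mechanistic model

The reducing-end residue is modeled as a chain of six carbons C1…C6, each
carrying its oxygen (O5 is the ring oxygen, a hydroxyl in the open-chain
form). Three elementary moves generate all reducing-end pathways:

1. **Ring opening (RO).** Hydrogen transfer from the anomeric hydroxyl to
   O5 with cleavage of the O5–C1 bond (O5–C2 for keto-hexoses) yields the
   open-chain carbonyl form. This requires a free anomeric hydroxyl:
   methyl glycosides and residues glycosylated through their anomeric
   carbon have no reducing-end chemistry, which is why cross-ring
   dissociation is localized at the reducing end.
2. **Hydrogen shifts (`m<i>_<j>`).** Hydrogen migration from O<sub>j</sub>
   to O<sub>i</sub> relocates the carbonyl from C<sub>i</sub> to
   C<sub>j</sub>. The allowed move set is the adjacent 1,2-shifts plus the
   long-range O1-mediated 1↔4, 1↔5 and 1↔6 shifts. A shift needs a free
   hydroxyl at the destination: a glycosylated or N-acetylated position
   cannot donate the hydrogen.
3. **Retro-aldol cleavage (`c<k>`).** The bond between C<sub>k</sub> and
   C<sub>k+1</sub> cleaves when the carbonyl sits β to it — at
   C<sub>k−1</sub> or C<sub>k+2</sub> — with concomitant hydrogen transfer
   from the β-hydroxyl (O<sub>k+1</sub> when the carbonyl is at
   C<sub>k−1</sub>, O<sub>k</sub> when at C<sub>k+2</sub>). That hydroxyl
   must also be free. This second condition is essential: for a 1→3-linked
   disaccharide the direct `c2` cleavage is impossible because O3 carries
   the glycosidic bond, so the dominant route must detour through the
   1,2-shift (`RO→m1_2→c3`), exactly as observed.

**Partitioning.** A cleavage splits the chain into C1…C<sub>k</sub> and
C<sub>k+1</sub>…C6. Compositions are tracked per carbon unit (CH₂O,
adjusted for N-acetyl, O-methyl, ¹⁸O labels and glycosidic attachments,
with glycosyl subtrees riding on their attachment oxygen), so retained +
lost always equals the precursor exactly and a single ¹⁸O label ends up in
exactly one partition. The observed ion is the partition containing the
glycosidically attached moiety; for a free monosaccharide it is the
partition opposite the carbonyl-bearing neutral. Both partitions are
computed; tautomeric detail is deliberately not modeled — only
compositions are observable in m/z.

**Secondary dissociation.** The retained piece re-enters enumeration (its
carbonyl re-forms at the cleavage carbon if the original carbonyl left
with the neutral), up to `secondary_depth = 2` stages. This reproduces the
two-stage losses: glucose 203 → 143 → 83, and the labeled-species losses
of 122 and 92 Da that are 30/60/90-Da losses followed by loss of the
labeled C1 as CH₂¹⁸O (32 Da).

**Non-reducing-end pathways.** The residue not at the reducing end can
fragment only through high-barrier routes (ring-opening analogues RO1′ and
RO2′, the direct c0′,3′ cleavage, and follow-up migrations). The available
characterization of these routes is product-level, not atom-level, so they
are implemented as a catalog of (step sequence, neutral-loss composition) pairs — losses of
120, 90, 30, 60 and 120 Da respectively — applied to every unsubstituted
aldo-hexose whose anomeric oxygen is blocked. The follow-up migrations are
attached to both RO1′ and RO2′ parents since their parentage is not
resolved further. HexNAc non-reducing residues are skipped: no product
data exist for them, and extrapolating the unsubstituted-hexose losses
would fabricate compositions. These pathways are always classified trace.

## Barrier data and tier classification

Transition-state barriers are bundled as versioned data
(`inst/extdata/barrier_table.csv`, hash via `barrier_table_version()`),
never computed. Three data qualities appear and are flagged per entry:
numeric barriers in kJ/mol; ordinal ranks where only an energy ordering is
known (`rank_only`); and the sentinel 300 with qualifier `gt_300` for
"more than 300 kJ/mol". One triple of shift barriers is mapped to
m1_4/m1_5/m1_6 by sentence order in the source data and is flagged
`order_inferred`. Species are keyed by a linkage signature that ignores
anomeric configuration and isotope labels (barriers are insensitive to
both at this resolution).

`classify()` orders reducing-end primary pathways by **(step count, then
rate-limiting barrier or rank, then reactant-state accessibility, then
label)** and calls the first one major. Step count leads deliberately: for
the 1→3 disaccharide the m1_5 shift has the lowest barrier of the shift
reactions, yet the m1_2 route dominates experimentally because m1_5 routes
need more sequential steps and have fewer accessible reactant states. A
pure lowest-barrier rule would mis-rank that system; the step-count-first
ordering reproduces every observed major fragment (245/275/305 for the Man
disaccharides, 277 labeled 1→3, 286 for GlcNAc-Man). Accessibility ranks
(direct retro-aldol most accessible, then m1_2, m1_4, m1_5, m1_6) encode
the reactant-state counting argument: fewer geometric restrictions mean
more accessible conformers.

Other reducing-end primaries are minor when their rate-limiting barrier is
within `window = 50` kJ/mol of the species minimum (or when only ordinal
data exist), trace beyond it or at the `gt_300` sentinel. Secondary
products of major/minor pathways are minor. For species entirely absent
from the barrier table — notably any 1→6 linkage, for which no barrier
data exist — tiers fall back to the diagnostic dominant-loss map (1→2:
120; 1→3: 90; 1→4: 60; 1→6: 60, 90 and 120 all major), which is exactly
the loss triad the mechanism enumeration itself produces for a 1→6
attachment.

## Mass conventions

Monoisotopic masses from CODATA/IUPAC values; the cation m/z subtracts the
electron mass. ¹⁸O adds 2.00425 Da. Nominal m/z is the nearest integer of
the monoisotopic value, matching the unit-resolution linear-ion-trap
convention in which all diagnostic values (245, 247, 305, …) are quoted.
Mass conservation holds to 1e-4 Da on every pathway by construction and is
property-tested. Domon–Costello labels (e.g. `0,2A2`) are attached as
annotation metadata for single-stage cross-ring ions; they play no role in
the computation.

## Annotation and linkage calling

`annotate()` matches observed peaks to the nearest predicted fragment
within ±0.3 Da (configurable; the default reflects unit-resolution
ion-trap data), flagging unmatched peaks and ambiguous assignments (several
predicted pathways or peaks within tolerance).

`infer_linkage()` scores candidates on rank-based tier agreement rather
than absolute intensities, since the mechanism provides no quantitative
intensity model: each predicted major contributes its observed relative
intensity (so a missing dominant loss costs the candidate); observed peaks
explained as the candidate's minors contribute positively when small and
negatively when as intense as the base peak (a dominant "minor"
contradicts the tier structure — this is what separates a genuine 1→6
pattern from a 1→2 spectrum with small companions); cross-ring peaks the
candidate cannot explain at all count against it. Because explained minors
never penalize, a spectrum with a dominant 120-Da loss plus weak 60/90-Da
losses is called as a single 1→2 structure with
`mixture_required = FALSE` instead of a linkage mixture. Scores are
invariant to uniform intensity rescaling; with no cross-ring matches at
all the result is flagged uninformative rather than guessed. Score
calibration is ordinal only — the absolute score values carry no meaning
beyond their ordering.

## Conformer-candidate screening

The screening procedure selects reactant candidates for a
hydrogen-transfer reaction from a conformer ensemble: a structure
qualifies when (1) Na⁺ coordinates the donor or acceptor oxygen within 2.5
Å and (2) the donor–acceptor distance lies in 3–3.5 Å. If fewer than
`min_candidates = 2000` qualify, the upper donor–acceptor bound widens in
0.5 Å steps (to a 6 Å hard bound) — needed for reactions like the C6→C1
hydrogen migration where few conformers satisfy 3 Å — and the lowest-energy
candidates are then taken with a stable, index-tie-broken sort. Widening
is monotone: it never removes a previously passing structure before the
energy cut. The step size and hard bound are package defaults; the source
procedure specifies only "gradually increased".

Supporting descriptors:

* **Cremer–Pople puckering** (q, θ, φ) with ring atoms in the
  conventional order O5, C1…C5 and the standard phase convention (θ = 0°
  or 180° for ideal chairs). θ/φ conventions vary between
  implementations, so the convention is fixed and tested: rigid motions
  leave (q, θ, φ) unchanged; rotating the atom indexing by an even offset
  shifts φ by multiples of 120°, an odd offset maps θ → 180° − θ. At the
  poles (ideal chairs) φ is degenerate and not meaningful.
* **Na–O coordination number**: Σ (1−(r/r₀)ⁿ)/(1−(r/r₀)ᵐ), continuous at
  r = r₀ (value n/m). Defaults r₀ = 2.5 Å, n = 6, m = 12 are declared
  package assumptions — the functional form and parameters are not
  specified by the source procedure.
* **USR shape descriptors** for deduplication: 12 moments (mean, spread,
  cube-rooted skew) of atom distances to four reference points (centroid,
  farthest-from-centroid, farthest-from-that, closest-to-centroid);
  similarity 1/(1 + mean absolute difference). Deduplication is greedy in
  energy order with a 0.97 default threshold ("highly similar" is not
  quantified in the source; 0.97 keeps rigid-motion copies out while
  retaining distinct conformers in the synthetic tests).

Energies are read from the ensemble file (multi-frame XYZ with `E=`
comments, kJ/mol); an external energy evaluator can be attached upstream
but none ships with the package — quantum-chemistry energetics
(DFTB/DFT), metadynamics propagation, constrained optimization and
transition-state/IRC searches are out of scope by design.

## Synthetic data: what it emulates and what it does not

`gen_spectrum()` emulates the peak structure of unit-resolution ion-trap
CID spectra: peaks at the predicted fragment m/z with tier-ordered
intensities (major:minor:trace = 100:5:1 — the qualitative "very low"
minor intensities made concrete; the ratios are synthetic, not measured),
optional Gaussian m/z jitter and multiplicative intensity noise, plus
uniform noise peaks kept > 1 Da from every true peak so ground truth stays
unambiguous at the 0.3 Da tolerance. It does **not** emulate isotope
envelopes, detector saturation, chemical noise near true peaks, or real
intensity physics — so passing round-trip tests demonstrates internal
consistency of prediction→annotation→linkage-calling, not quantitative
intensity realism on instrument data.

`gen_ensemble()` plants screening ground truth: exactly `n_pass`
conformers of a small Na⁺/two-oxygen/carbon-skeleton cluster satisfy both
geometric criteria by construction; the rest violate at least one —
sodium placed 2.7–4 Å away on the far side of the donor (failing criterion
1 against both oxygens), or donor–acceptor distances below 3 Å or above
the 6 Å widening bound (failing criterion 2 under any admissible window).
Energies are exponential with mean 20 kJ/mol, a realistic within-ensemble
conformer energy spread. Generators are bit-reproducible per seed and
restore the caller's RNG state.

## Numerical choices and degenerate inputs

* Pathway enumeration allows revisiting carbonyl positions within the
  shift budget (default 3 per stage); duplicate m/z from distinct routes
  are collapsed in spectra with the best tier kept, and annotation flags
  them ambiguous.
* Tie-breaks everywhere are deterministic: step count, then
  barrier/rank, then accessibility, then the lexicographic step label;
  energy sorts use stable index tie-breaks.
* Degenerate geometry (collinear rings) raises an error in `puckering()`;
  empty ensembles and empty peak lists are errors, not silent results.
* The five-residue N-glycan string parses verbatim (Greek/arrow notation
  normalized); its computed sodiated nominal mass is 974. MS³ bookkeeping
  is exercised at the disaccharide stage (406 → fragments), where computed
  and quoted values agree.

## Test problem sizes

The suite checks enumeration against an independent brute-force oracle
(shift sequences ≤ 3 on single hexose chains, seven blocking patterns),
mass/label conservation across every enumerated pathway of seven species,
linkage recovery for all four linkages with and without noise, planted
screening recovery at n = 100 / n_pass = 30, and descriptor invariance
under random rigid motions. These sizes are chosen to cover every rule
branch while keeping the whole suite fast; the mechanism itself is exact
integer arithmetic, so larger sizes would add runtime, not information.

## Known limitations

* No quantitative intensity model: tiers are ordinal; Boltzmann weights
  (T_eff = 800 K default, explicitly not a fitted value) are an ordering
  aid only.
* Stereochemistry is a name tag: Glc/Man/Gal are mass-identical here, and
  barriers are looked up by linkage signature, so stereo-isomers sharing a
  signature share predictions.
* Only singly charged [M+Na]⁺ ions under CID; protonated/deprotonated
  species and HCD/ETD/ECD chemistry are explicitly out of scope.
* Furanose rings and multiply charged ions are not modeled; ketoses use
  the linear-form mechanism only.
* Non-reducing-end products are catalog-based (no atom-level label
  tracking on that ring) and limited to unsubstituted aldo-hexoses.
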