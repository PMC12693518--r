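---
title: "Reading BER repair-patch sizes from mass-labeled probes"
author: "bermass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading BER repair-patch sizes from mass-labeled probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bermass)
```

## The assay in one paragraph

Base excision repair (BER) removes a damaged base — uracil, or an abasic
deoxyribose — and resynthesizes the surrounding strand. The resynthesized
tract may be one nucleotide (short-patch BER) or several (long-patch BER),
and the distinction matters because different DNA polymerases and nucleases
drive the two modes. The assay this package supports measures tract length
directly: a plasmid probe carries a defined lesion with fully
$^{13}\mathrm{C},^{15}\mathrm{N}$-substituted ("heavy") dGMP residues
immediately 3′ of it (or heavy dAMPs 5′ of it, for the upstream-excision
readout). Repair synthesis replaces heavy residues with normal-mass
nucleotides, so each replaced label lowers the mass of a restriction
fragment spanning the lesion by

$$\Delta m = 10\,(m_{^{13}C} - m_{^{12}C}) + 5\,(m_{^{15}N} - m_{^{14}N})
          = 15.0187\ \mathrm{Da},$$

identical for dAMP and dGMP (both have 10 C and 5 N). After repair, the
fragment is released by restriction digestion, analyzed by negative-mode
ESI-QTOF in the 900–1800 m/z window, and each observed species is
deconvolved to neutral mass as $M = (m/z + 1.008)\,z$. The number of heavy
residues lost — hence the patch size — is read off a ladder of theoretical
masses spaced 15.0187 Da apart.

## Probe architecture

The generated default probe is a 2000-nt circular molecule. Around the
lesion it embeds, in order: a unique Nt.BspQI site and a unique Nb.BbvCI
site (the two nicking enzymes that excise the strand segment during the
oligonucleotide-swap construction of the physical substrate), a PstI site
(bead-capture digest), and the analysis cassette. Random filler sequence
completes the plasmid; spurious occurrences of any constrained recognition
site in mutable positions are mutated away deterministically, and
`validateDesign()` re-checks every constraint on the finished object.

Two cassette layouts exist:

* **Patch-size probe** (`labelSide = "downstream_G"`). The lesion is a U
  replacing the second T of the NdeI site CATATG, with six heavy dGMPs
  immediately 3′ of it. NdeI + HaeII release a 19-nt analysis fragment whose
  5′ end is two nucleotides upstream of the lesion. Patch sizes 1–6 nt are
  mass-distinguishable (patch $k$ removes $k-1$ labels); $k \ge 7$ merges
  into an open "≥7-nt" bin. Because restriction enzymes read U as T, the
  intact probe is cleavable by NdeI, uracil removal by UDG (U → abasic)
  blocks cleavage, and repair (U → T) restores it — the assay's built-in
  authenticity check, which `simulateDiagnostic()` reproduces.

* **5′-excision probe** (`labelSide = "upstream_A"`). Four heavy dAMPs sit
  immediately 5′ of the lesion; HaeII + PstI release a 20-nt fragment.
  Excision of $j$ nucleotides upstream removes $\min(j, 4)$ labels, giving
  classes 0–3 nt plus "≥4-nt". The patch length is mass-silent here
  (downstream replacement swaps light residues for light ones), which the
  ladder builder asserts at construction time.

One design point is forced rather than chosen: four contiguous adenines
cannot sit immediately 5′ of a T inside CATATG (the site fixes C or T two
positions upstream of either T). A probe therefore cannot simultaneously
have the lesion inside the NdeI diagnostic site *and* four informative
upstream labels. The excision probe gives up the diagnostic site (its
validation check reports "not applicable"); the patch probe keeps it. The
published substrates resolve this with sequences from supplementary
material not reproduced here; the generated cassettes reproduce the class
structure of the assay, not the exact published sequence.

## Coordinates and conventions

All coordinates are 1-based and intervals closed, the R/Bioconductor
convention; every TSV/JSON output states this in its header. Restriction
cuts leave 5′-phosphate/3′-hydroxyl chemistry, and fragment masses are
computed as the sum of 5′-monophosphate residue formulas minus one water
per phosphodiester bond, with an HPO~3~ correction for 5′-hydroxyl ends.
Residue formulas — including the abasic site (AP), its NaBH~4~-reduced
ring-opened form (rAP = AP + H~2~) and the tetrahydrofuran analog
(F = AP − O) — ship as editable JSON data, not code, as does the enzyme
table.

Two constants deserve comment. The charge-carrier mass defaults to 1.008 Da
per charge because that is the printed reduction the assay uses; the
physically exact proton mass (1.007276 Da) is selectable
(`proton = PROTON_EXACT`) and changes nothing at the assay's mass accuracy.
And matching operates on **average** (envelope-collapsed) masses by
default, because both the simulator and apex-height quantification treat a
species as one Gaussian peak rather than an isotopologue comb;
monoisotopic matching is available for centroided isotope-resolved data.

## From trace to composition

`pickPeaks()` takes local maxima above
$\max(\mathrm{baseline} + 5\sigma_{\mathrm{noise}},\ 1\%\ \mathrm{of\ max})$,
with the baseline estimated as the median intensity and the noise floor as
the upper-side MAD (deviations above the median), which stays correct when
the lower noise tail clips at zero intensity. Centroids are refined by
parabolic interpolation; maxima closer than `minPeakDist` (default
0.05 m/z, to be scaled up for broader peaks) are merged because they are
noise ripples on one physical peak. Reported heights are
baseline-subtracted apex heights; areas are computed but unused.

`assignPeaks()` deconvolves every peak at every charge state in the
ladder's range and accepts matches within an absolute neutral-mass
tolerance of 0.35 Da. That single knob works across charge states because
the discriminations that matter are ≥1 Da at neutral level: adjacent
classes differ by 15.019 Da, and the closest pair in the whole ladder — the
unrepaired substrate versus the 2-nt product, pinned by chemistry at
$+14.016 - 15.019 = -1.003$ Da — is still three tolerances apart. A peak
matching two entries within tolerance is flagged ambiguous and excluded
from quantification (an equal-split option exists but is off: exclusion is
conservative and auditable).

`quantifyComposition()` implements the assay's stated readout: the
proportion of each repair product is its summed apex height (all charge
states) divided by the total height of all repair products. Whether the
published quantification summed charge states or read a single one is not
stated; the sum is used here and documented. The unrepaired substrate is
excluded from that denominator and reported as a separate fraction of the
total assigned signal, so the repair-class proportions are invariant to how
much substrate went unrepaired.

## What the simulator emulates — and what it does not

`simulateSpectrum()` places one Gaussian peak per (class, charge state) at
the class's average-mass m/z, with height proportional to (ground-truth
proportion) × (charge-envelope weight), on a 0.005 m/z grid over 900–1800
m/z, plus a constant baseline (1) and Gaussian noise (sd 2, against a
strongest-peak scale of 1000). The charge envelope is a discrete Gaussian
over z = 4–8 centered at z = 6 with unit spread — chosen so a ~6 kDa
fragment shows three charge states (z = 4, 5, 6) inside the window, as a
QTOF would. Peak sigma is 0.02 m/z, a resolving power of ~2 × 10^4^ at m/z
1000; this resolves the 1.003 Da unrepaired/2-nt gap (0.15 m/z at z = 6),
as the real instrument does. Replicate composition tables are drawn from a
Dirichlet with precision 200, putting the replicate scatter of a 50%
component near 3.5 percentage points — the scale of the assay's reported
between-experiment variation.

Not emulated: isotopologue fine structure (quantification is apex-based, so
peaks are envelope-collapsed; an isotope-resolved mode would require area
integration), adducts beyond deprotonation, chromatographic effects,
in-source decay, and the nicked/gapped side products that the physical
protocol removes enzymatically before MS. Consequently, passing end-to-end
recovery here demonstrates that the deconvolution–assignment–quantification
chain is unbiased and correctly scaled for well-resolved spectra; it does
not certify robustness to overlapping isotope envelopes or to adduct-rich
real spectra.

## The statistics layer

Replicate proportions are compositional: nonnegative and summing to one.
Before model fitting, `closeComposition()` replaces zeros with a
pseudocount (default 10^-6^; the magnitude is a declared default, not an
inferred one) and renormalizes each row onto the open simplex.

`fitDirichlet()` uses the common (one-parameter-set) Dirichlet
parametrization with log link, $\alpha_{id} = \exp(x_i\beta_d)$, maximized
by BFGS with the analytic digamma gradient from a moment-matched start
(max 500 iterations); the fitted optimum never falls below the start, and
group-wise expected compositions are $\alpha/\sum\alpha$. The global group
test in `lrtGlobal()` is the likelihood ratio with $D(G-1)$ degrees of
freedom referred to the upper chi-square tail. Per-component inference
(`betaComponentTests()`) fits a beta regression per class — logit mean
link, constant precision, maximum likelihood — and tests the group effect
by likelihood ratio, with Benjamini–Hochberg adjustment across classes
(`bhAdjust()`, a validated wrapper over `stats::p.adjust`).

Two practical notes. First, classes that are structural zeros in a dataset
(never observed above 0.5%) are dropped by the command-line statistics
runner before fitting: with three replicates per group, retaining five
all-zero classes overparameterizes the model and destabilizes the
optimizer. Second, the chi-square reference for the global LRT is an
asymptotic one. At this assay's typical three-to-six replicates per group
it is measurably anticonservative (empirical size ≈ 0.08–0.11 at a nominal
0.05 with D = 3 and six replicates per group; nominal by 25 per group) — a
property of the test, not of the implementation, which is verified to be
calibrated at larger n. For small designs `lrtGlobal(..., pvalue =
"bootstrap")` provides a parametric-bootstrap p-value under the fitted
null, which is calibrated by construction; the chi-square default is kept
because it is the assay's stated analysis.

Note also that the step-up BH map is monotone and order-preserving but not
idempotent (re-adjusting adjusted q-values inflates them again by
$m/\mathrm{rank}$); only the former properties are guaranteed and tested.

## Degenerate inputs and tie-breaks

* A circular molecule with zero cuts digests to a single full-length
  "uncut" record, not an error; nicking enzymes are rejected by
  `digestProbe()` and usable only as site-uniqueness annotations.
* A probe with no informative labels collapses all repaired outcomes into
  one class; `enumerateOutcomes()` warns rather than fails.
* A ladder entry with no charge state inside the window triggers a warning;
  the ladder is still returned.
* Zero repair-class signal is an explicit "no repair detected" error in
  quantification; an all-zero composition row is an input error in closure.
* A class with numerically constant proportions yields an NA row in the
  beta tests (degenerate fit) while the other classes are still tested.
* Equal-height maxima within one merge window keep the first-occurring
  apex (deterministic).

## Problem sizes used in validation

The shipped tests exercise: 100 generated probes for the digest and
diagnostic-logic sweeps; 20 simulated spectra for mean end-to-end recovery
(mean maximum class error ≈ 0.006, asserted < 0.03); 3-replicate pooled
recovery at five reported compositions (asserted within 5 percentage
points); 1000 null simulations for the LRT size at six replicates per
group and 150 at 25 per group; 500 replicates for Dirichlet concentration
recovery (within 10%); and 120 simulations for beta-regression interval
coverage. These sizes were chosen so the full suite runs in well under a
minute per module while keeping Monte-Carlo error comfortably below each
assertion's margin.

## Known limitations

* The generated probe sequences satisfy the published design constraints
  but are not the published sequences; absolute fragment masses therefore
  differ from the paper's while all mass *differences* — the quantities the
  assay reads — are exact.
* Dual-labeled probes (heavy A upstream *and* heavy G downstream) are
  representable but not enumerable as a joint (excision, patch) product
  space; the collision checker will flag the resulting mass degeneracies,
  and the two separate probes remain the supported design, mirroring the
  assay's own practice.
* The mzML reader takes the first MS1 scan only and is intended for
  convenience; the canonical input is the two-column m/z–intensity TSV.
* Quantification trusts apex heights; saturating detectors or merged peaks
  (resolving power below ~10^4^ at these fragment sizes) would bias it, as
  the unrepaired/2-nt proximity demonstrates.
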