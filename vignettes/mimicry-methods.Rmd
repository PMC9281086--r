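---
title: "Methods: scanning for molecular mimicry between tumor epitopes and bacterial proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for molecular mimicry between tumor epitopes and bacterial proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicryscan)
```

## The problem

CD8+ T cells recognise 9-residue peptides presented on HLA class I
molecules. Because a single T-cell receptor is highly cross-reactive, a
bacterial peptide that closely resembles a tumor-associated antigen (TAA)
epitope -- in sequence and in the spatial conformation of its TCR-facing
residues -- may prime T cells that also recognise the tumor. mimicryscan
implements the discovery and characterisation side of that question for
gut-microbiome proteomes: find bacterial nonamers homologous to TAA
epitopes, characterise the substitutions, check that the peptides would
bind the restricting HLA allele, and compare the backbone geometry of
paired peptides.

## Homology search: exhaustive ungapped scanning

Heuristic database searches (BLAST against a live online protein database)
are not reproducible at desk scale: results change with database versions
and search parameters, and the hit set cannot be re-derived from the
inputs. Because every alignment of interest here is a gapless nonamer
pairing, `scan_proteome()` instead slides each epitope across every
protein one residue at a time and keeps every window with at least
`min_identity` identical positions. This is exact, complete and
database-version independent; on any fixed FASTA input two runs give the
same answer. The default floor of 5/9 identities (about 51%) admits the
weakest homologs reported in this setting; it is a parameter, not a
constant. Windows containing ambiguity codes (X/B/Z/U/O) are skipped by
default because epitopes are defined over the 20 standard residues.
Overlapping windows are all reported; `unique_peptides()` provides the
collapsed per-peptide view used for affinity averaging.

The test suite holds the scanner to an independent brute-force enumeration
on hundreds of randomised small instances (up to 20 proteins of up to 60
residues), and to exact recovery of homologs planted by the synthetic
module.

## What counts as a conservative substitution

The distinction between conservative and non-conservative replacements
drives the per-position statistics, but there is no single canonical
definition. The default `substitution_scheme()` partitions the 20 residues
into six physicochemical classes -- aliphatic {A,V,L,I,M}, aromatic
{F,W,Y}, polar-uncharged {S,T,N,Q,C}, positive {K,R,H}, negative {D,E} and
special {G,P} -- and calls a mismatch conservative when both residues fall
in the same class. This grouping reproduces the colour-coding of every
worked alignment in this domain that we model (I/V, L/M, L/V are all
conservative). A second mode calls a mismatch conservative when its
BLOSUM62 score is non-negative; it is provided for sensitivity analysis,
because class partitions and substitution matrices disagree at the margins
(e.g. A/S scores +1 in BLOSUM62 but crosses class boundaries here).

Positions are 1-based in every user-facing table; the worked MAGE-A3 pair
KVAELVHFL/KIAELVHFL differs exactly at position 2. For the MAGE-A10 pair
GLYDGMEHL/GMYDGLEHV the package reports all three mismatching positions
(2, 6 and 9); position 9 is an HLA-A*02:01 anchor, and callers who want to
discuss TCR-facing positions only can mask anchors downstream --
the package does not silently drop them.

## Binding thresholds and the PWM stand-in

Affinity thresholds follow the field's convention: strong binder below
100 nM, high affinity below 10 nM, with a stability criterion (half-life
above 1 h) applied whenever a stability prediction is present. When
`stability_h` is missing the call is affinity-only rather than failing:
stability predictions are typically only generated for the candidate
bacterial peptides, not for the reference TAAs.

Neural-network predictors are external tools with their own licences and
versions, so predictions are treated as *data*: `import_predictions()`
reads a peptide/allele/affinity/stability table and classifies it. So that
the pipeline also runs fully self-contained, `pwm_predictor()` provides a
deliberately transparent position-weight-matrix stand-in: a 9 x 20
log-odds matrix summed over positions, min-max normalised to a score
s in [0, 1], mapped to nanomolar as 50000^(1 - s) -- the standard transform
that places s = 1 at 1 nM and s = 0 at 50 000 nM, keeping the 10/100 nM
thresholds meaningful on synthetic runs. It is a stand-in for pipeline
plumbing, not a binding model; nothing in the statistics depends on its
accuracy.

Affinity summaries use strict inequalities ("lower than the mean", "lower
than the paired TAA") and, by default, average over distinct
(antigen, peptide) pairs rather than over repeated genomic occurrences of
the same peptide; `distinct_peptides = FALSE` switches to
occurrence weighting.

## Alignment-population statistics

`identity_distribution()` and `identity_summary()` tabulate identity
counts per antigen, including the share of hits with 6 or 7 identical
residues. `per_position_stats()` tallies identical / conservative /
non-conservative calls at each of the 9 positions; the three percentages
sum to 100 at every position by construction, and `glance()` returns the
cross-position averages.

`build_pfm()` computes position frequency matrices from raw, unweighted
hit sequences (no clustering or down-weighting of near-duplicates --
the simplest fully reproducible choice). Information content per position
is the uniform-background Shannon form log2(20) - H, which is what logo
stack heights encode; with a non-uniform background the Kullback-Leibler
divergence is used instead. Consensus ties are broken alphabetically and
flagged rather than hidden. `consensus_match()` checks the consensus
against the paired TAA position by position.

`stretch_match_probability(k)` is the probability that k specified
positions agree between two independent peptides drawn uniformly over 20
residues: (1/20)^k, i.e. 1.5625e-8 at k = 6 and 1.953125e-12 at k = 9.
The per-stretch form carries no positional or combinatorial correction --
that is the only form consistent with both printed endpoints of the range
it quantifies. An `any_window` variant multiplying by the (10 - k)
possible windows is provided but is an upper bound, clearly distinct from
the primary statistic. Probability annotations on hit tables use the
longest run of consecutive identical positions; a hit with no identical
position gets probability 1 (the empty product) and is flagged.

## Structural comparison

`read_peptide_structure()` loads PDB ATOM records (bio3d underneath),
keeps blank/'A' alternate locations, maps declared chains to roles
(peptide, HLA, beta-2-microglobulin, TCR alpha/beta) and enforces a
peptide length of 8-11 residues. `contact_map()` assigns a peptide residue
to a contact category when any of its heavy atoms lies within 4.0 A
(configurable) of any heavy atom of the corresponding chain; hydrogens
are excluded because crystal structures usually lack them, and b2m is
never a contact category. TCR-facing positions are read off the contact
map when TCR chains are present, and fall back to the static central set
{4,5,6,7,8} otherwise (positions 2 and 9 are the HLA anchors for the
alleles modelled here).

Angles are measured by descriptors naming 3 (planar) or 4 (dihedral)
atoms by peptide position and atom name. The default descriptor set per
TCR-facing position is the C-alpha planar angle through the flanking
residues plus the side-chain orientation dihedral N-CA-CB-(terminal heavy
atom); `backbone_descriptors()` builds phi/psi/CA-trace sets instead, and
any custom set can be supplied. Dihedrals follow the IUPAC sign
convention (verified in the tests against bio3d's independent
implementation); a magnitude-only comparison mode exists because the
source material never states whether signed values were compared.

The identity criterion is relative: two angles are "identical" when their
circular absolute difference is at most 10% of the reference angle's
magnitude. A relative criterion is unpassable near zero degrees, so an
absolute floor of 5 degrees applies when the reference magnitude is below
50 degrees -- an implementation choice documented here precisely because
the underlying description does not address near-zero angles. Since the
denominator of a "percentage of identical values" can be read per pair or
pooled, `glance()` on a comparison reports the pooled percentage plus
per-kind (planar/dihedral) percentages, and per-pair percentages are one
`group_by()` away from the tidy table.

## The synthetic-data module

Real inputs for this analysis are a moving target (live protein
databases, licensed predictors, crystal structures). The synthetic module
generates every input the pipeline needs, deterministically from (args,
seed):

- `generate_proteome()` draws residues i.i.d. from a background
  (uniform 1/20 by default, matching the probability model's assumption;
  a Swiss-Prot-like composition is available via `aa_background()`).
- `plant_homolog()` overwrites a random non-overlapping window with a
  sequence differing from an epitope at exactly k positions drawn under a
  class policy, and records everything in a ledger that predicts the
  scanner's output at the planted location exactly.
- `generate_ideal_peptide()` builds idealized nonamer backbones (standard
  bond lengths/angles, trans peptide bonds) with caller-specified phi/psi
  torsions by natural-extension-reference-frame construction; measured
  torsions equal the requested ones to better than 1e-3 degrees.
  `hla_groove_torsions()` supplies a fixed extended-with-central-bulge
  conformation resembling how nonamers sit in the class I groove.

What the synthetic data does *not* emulate: phylogenetic structure,
codon-level evolution, realistic domain composition, true binding
physics, or crystal-quality side-chain geometry (side chains are CB
stubs). Consequently, green tests demonstrate correctness of the
machinery -- exact window accounting, exact class bookkeeping, exact
geometry -- not biological conclusions about real proteomes; a real-data
rerun swaps in FASTA files, a prediction TSV and PDB entries (e.g. the
1AO7 and 7JYV complexes) via the same config surface.

## Numerical and design choices

- Scanning and classification are exact integer computations; no
  tolerances apply.
- Percentages are computed at full precision; round only at presentation.
- PFM columns sum to 1 within 1e-9 (asserted in tests); information
  content is clamped only by arithmetic, never post-hoc.
- Angle comparisons use circular differences on degrees, so 179 vs -179
  differ by 2, not 358.
- Degenerate geometry (coincident points, collinear dihedral frames)
  raises errors instead of returning NaN.
- The demo pipeline uses 2 epitopes x 2 phyla x 40 proteins of 80-200
  residues with 6 planted homologs per epitope per phylum (0-3
  conservative substitutions, cycling) -- enough to exercise every stage
  while keeping a full run in seconds; all sizes are config entries.
- Every output file carries the package version, a hash of the
  analysis-relevant config (the output directory is excluded, so where
  results land cannot change what they contain) and the seed; identical
  config + seed yields byte-identical files.

## Known limitations

- Nonamers only; 8/10/11-mer epitopes are out of scope in this version.
- No gapped alignment, no E-values or match statistics beyond the
  identity filter and the stretch probability model.
- The PWM stand-in is not a calibrated binding predictor.
- No docking, energy minimisation, side-chain rebuilding, or mmCIF input.
- The structural layer compares geometry of given (or idealized)
  coordinates; it does not model how a substituted side chain would
  repack in the groove.
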