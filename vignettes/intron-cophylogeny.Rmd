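---
title: "Detecting mitochondrial group I introns and testing their mode of transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mitochondrial group I introns and testing their mode of transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Group I introns are self-splicing, mobile genetic elements. In sponges
and corals they occasionally sit inside the mitochondrial cox1 gene,
usually encoding a LAGLIDADG homing endonuclease — the enzyme that cuts
intronless alleles and thereby drives the intron's own spread. Two
transmission modes can explain the scattered distribution of these
introns across distantly related animals: strict vertical inheritance
followed by many independent losses, or occasional horizontal transfer
between lineages. The two modes leave different phylogenetic
fingerprints. Treating the intron as a parasite of the gene that hosts
it turns the question into a host–parasite co-phylogeny problem: under
vertical transmission the intron tree must be congruent with the cox1
tree; host switches break the congruence at identifiable links.

`cophylointron` implements that complete line of analysis: locating and
characterising introns relative to an intronless reference CDS,
estimating maximum-likelihood trees for the cox1 ("host") and intron
("parasite") partitions, and running three complementary co-speciation
tests. A synthetic-data module generates datasets with known
transmission histories so that every stage is verifiable end to end.

## Intron detection

`map_to_reference()` aligns a query cox1 sequence globally against an
intronless reference CDS (Needleman–Wunsch via Biostrings; match 2,
mismatch −3, gap open −8, gap extension −1, all overridable). The
alignment is nucleotide-level throughout: with these scores a
kilobase-scale insertion is always recovered as a single run of gaps in
the reference, and exon divergence in the ranges relevant here (well
above 70 % identity) does not disturb the mapping, so a protein-guided
mapping layer would add complexity without changing any result. A query
whose aligned exon identity falls below 40 % is rejected as unsuitable
rather than mapped badly.

Coordinates are 1-based on the reference CDS, starting at the A of the
start codon, and an insertion is named by the last reference position
preceding it — so "intron 723" sits between reference positions 723 and
724. This convention is load-bearing: an off-by-one changes the intron's
name. One genuine subtlety is that an insertion whose boundary repeats
the flanking exon base can be placed at more than one site with an
identical alignment score (the gap can "slide"). `detect_insertions()`
therefore left-normalises every insertion — the run is shifted to its
smallest equivalent site, rotating the inserted sequence accordingly —
making the reported `(site, sequence)` pair a canonical representative
that does not depend on the aligner's arbitrary choice.

`find_orfs()` translates each insertion on both strands and all three
frames under a configurable genetic code (default NCBI table 4, the
mold/protozoan/coelenterate mitochondrial code of demosponge
mitochondria, in which TGA encodes tryptophan). ORFs run from the first
ATG after the previous stop to the next stop codon, must reach 50 amino
acids (stop excluded) by default, and are scanned for the LAGLIDADG
peptide with at most one mismatch. Internal TGA codons are counted
because they discriminate a mitochondrial from a nuclear reading: an ORF
that is intact under table 4 but interrupted under the standard code
cannot be a nuclear gene.

`column_stats()` classifies alignment columns as constant, variable, and
parsimony-informative (at least two states each carried by at least two
sequences), using only unambiguous residues; a column that is constant
among its unambiguous residues counts as constant. Missing data is
`-`/`?`/`N` (`X` for protein matrices). `pairwise_identity()` reports
matches over aligned positions from the same global aligner, excluding
columns gapped in both sequences and counting gap-versus-base columns as
mismatches; identity figures from other tools can differ by a few points
because the denominator convention is not standardised.

## The likelihood engine

The engine implements time-reversible nucleotide models up to GTR, with
TrN as the two-transition-rate special case, plus discrete-gamma rate
variation (default 4 categories) and an invariant-sites class. Rate
matrices are scaled to one expected substitution per site at
stationarity, so branch lengths are in substitutions/site. Gamma
categories are equal-probability classes represented by their medians
(renormalised to mean 1); this differs slightly from mean-based
discretisation (as used by phangorn), which is why cross-checks against
other software should fix the category rates or use a single category.
With a proportion `p_inv` of invariant sites the gamma rates are
inflated by 1/(1 − p_inv), and the invariant class is implemented
simply as a rate-0 category — the pruning recursion needs no special
case. Ambiguity codes contribute a partial likelihood of 1 over their
compatible states; base frequencies default to the empirical
frequencies of the data.

Likelihoods are computed by Felsenstein pruning in C++ over compressed
site patterns. Branch lengths are optimised by per-branch Brent line
searches bounded to [1e−8, 20] substitutions/site; the optimiser keeps
outside ("above") and inside ("below") partial likelihood vectors so
that evaluating one branch's likelihood profile costs O(patterns × 16)
independent of tree size, and a slow full-recomputation implementation
is retained as an internal cross-check. No likelihood rescaling is
performed, which is safe for the tens of taxa this package targets but
would underflow at many hundreds of taxa — a deliberate scope limit.
Model parameters (exchangeabilities, gamma shape, invariant proportion)
are optimised numerically on log/logit scales, alternating with
branch-length sweeps until the log-likelihood improves by less than
1e−4.

`ml_search()` hill-climbs from a neighbor-joining start (JC-corrected
distances; saturated pairs replaced by 1.25 × the largest finite
distance). Each round screens every NNI neighbour with a single
likelihood evaluation at current branch lengths, re-optimises the
branch lengths of the few best candidates, and accepts the best strictly
improving move; ties are broken by the first candidate encountered in
the deterministic enumeration order, so an alignment with no signal
(identical sequences) simply returns the optimised starting tree.
Random SPR proposals can be mixed in (`moves = c("NNI", "SPR")`,
seeded). At the ≤ 25-taxon scale of these analyses the NNI climb
reaches the exhaustive-search optimum in the suite's oracle tests; a
full TBR implementation was judged unnecessary for this problem size.

## The three co-speciation tests

**Reciprocal AU tests.** For each dataset, every candidate topology is
re-optimised (branch lengths and model) to obtain site-wise
log-likelihoods, which are then resampled by the RELL approximation
(sites are resampled; nothing is re-optimised) at ten bootstrap sizes,
r ∈ {0.5, 0.6, …, 1.4} × the sequence length, with 10,000 replicates
per scale by default. The per-scale win frequencies BP(r) are converted
to probits and the two-parameter model z(r) = d√r + c/√r is fitted by
weighted least squares; the approximately unbiased p-value is
1 − Φ(d − c). A topology that never wins at any scale is reported as
p = 0 and one that always wins as p = 1 (the fit is undefined there);
if fewer than two scales give interior win frequencies the scale-1
proportion is used. Two identical site-likelihood vectors make the test
degenerate; it then returns p = 1 for all topologies with a warning.
"Reciprocal" means each partition's data tests the other partition's ML
topology.

**Non-parametric Huelsenbeck–Bull LRT.** The statistic is
d = 2(lnL₀ − lnL₁). lnL₀ constrains both partitions to the ML topology
of their concatenation while letting each partition keep its own model
and branch lengths; lnL₁ gives each partition its own topology. The
one-tree model is nested in the two-tree model, so d ≤ 0 up to
optimisation tolerance. The null distribution is built by non-parametric
bootstrap: each replicate resamples columns of each partition
independently, concatenates them, and randomises which columns belong to
which partition before recomputing d. Both pseudo-partitions of a
replicate then draw from the same blended site pool — data generated
under the one-tree hypothesis — so the null captures the incongruence
expected from finite sampling alone. The p-value is the plain proportion
of null statistics below the observed one, with no continuity
correction. An alternative null that shuffles the taxon-to-taxon pairing
between partitions is exposed (`null = "pair-shuffle"`) for comparison,
but it calibrates d against *maximal* incongruence — its p-values
approach 1 under both hypotheses — so it is not used for testing.
Null-replicate tree searches run at a documented reduced effort (one
optimisation round, single-candidate NNI acceptance); the observed
statistic uses the full search.

**ParaFit.** Patristic distance matrices of the two trees are embedded
by principal coordinates analysis: Gower double-centering of −½d²,
eigendecomposition, axes scaled by the square root of their
eigenvalues, axes with eigenvalues below 1e−8 × the largest dropped and
negative-eigenvalue axes never retained. Raw patristic distances are
not guaranteed Euclidean, so the Lingoes correction (adding
c₁ = |λ_min| to all squared off-diagonal distances) is applied when
needed; a square-root transform of the distances, which makes tree
metrics exactly embeddable, is available via `sqrt_dist = TRUE`. With
host coordinates B, parasite coordinates C and the binary hosts ×
parasites association matrix A, the global statistic is the sum of
squared entries of BᵀAC, and ParaFitLink1 for a link is the drop in
that statistic when the link is removed. The permutation null
randomises, independently for each parasite, which host it attaches to;
the same permutation stream serves the global and all per-link tests,
and p-values use the add-one estimate (1 + #{null ≥ obs})/(1 + n). The
absolute magnitude of the statistic depends on the coordinate scaling
convention (recorded in the result object), so only significance
patterns, not raw statistic values, are comparable across
implementations. A `drop_hosts` argument re-runs the test with chosen
taxa excluded, supporting leave-taxa-out sensitivity analyses.

The two test families ask opposite questions: the AU/LRT null is
*congruence* (rejection indicates horizontal transfer), the ParaFit
null is *random association* (rejection indicates at least some
co-divergence). On a dataset where an intron co-diverged in most
lineages but switched hosts a few times, the LRT rejects while ParaFit
remains significant — exactly the disagreement the synthetic end-to-end
checks reproduce.

## The synthetic-data generator

`simulate_host_tree()` draws Yule trees conditioned on n tips (crown
start, exponential waiting times, a final exponential stretch after the
n-th lineage), with tip labels assigned by a random permutation so that
labelled topologies are exchangeable. `simulate_cophylogeny()` sweeps
the host tree forward in time: the parasite duplicates at every host
speciation; host-switch events arrive at `switch_rate` per lineage-time
and copy the sampled donor lineage's parasite into a recipient drawn
uniformly among the other lineages alive at that moment, replacing the
recipient's parasite; losses terminate a parasite lineage. Exact event
counts can be forced for controlled experiments. With no events the
parasite tree is topologically identical to the host tree; each switch
is an SPR-like perturbation; heavy loss thins the intron-bearing taxa
the way real surveys find introns in only a minority of sampled
sponges. Uniform recipient choice is the minimal assumption — nothing
in the data motivates a distance-dependent transfer kernel.

`simulate_alignment()` evolves sites down a tree from stationary root
states with per-site rate classes; a single clock factor per partition
(`rate_scale`) converts time-trees to substitution-trees, which is how
the empirically faster evolution of intron sequences relative to cox1
is emulated (`simulate_cophylo_dataset()` defaults: 0.15 for the host
partition, 0.30 for the intron). Default partition lengths are 630 and
1078 bp — the lengths of the cox1 and intron matrices in the motivating
study — and the default model is GTR+Γ+I with moderately AT-rich base
frequencies typical of sponge mitochondria (A 0.28, C 0.16, G 0.20,
T 0.36), shape 0.5 and 20 % invariant sites.

What the generator does *not* emulate: within-host polymorphism and
coalescent effects, indels other than whole-intron insertion,
codon-structure and selection on cox1, alignment error, and base
composition heterogeneity across lineages. Green synthetic checks
therefore demonstrate the correctness and calibration of the machinery,
not robustness to every artefact of real sequence data.

## Problem sizes in the test suite

The statistical-calibration checks run at sizes chosen to make the
whole suite a desk-scale job while keeping Monte-Carlo error small
relative to the tested bands: the LRT type-I experiment uses 200
codivergence datasets of 6 taxa with 150 bp partitions under JC and 99
bootstrap replicates each; ParaFit type-I uses 500 random-association
datasets of 10 taxa with 99 permutations; power experiments use the
2-switch, 12-taxon, 2 kb-per-partition alternative (10 datasets, 49
replicates) for the LRT and 60 codivergent 12-taxon datasets for
ParaFit. JC is used in the calibration loops because the tests'
operating characteristics are properties of the procedure, not of the
substitution model, and it keeps each of the ~20,000 null tree searches
cheap. The acceptance script re-runs the pipeline's principal
computations at the study's partition lengths (630/1078 bp, 12 taxa)
with 99 LRT replicates and 999 permutations.

## Known limitations

* No likelihood rescaling: intended for tens, not hundreds, of taxa.
* TBR branch swapping is not implemented; NNI (+ random SPR) suffices at
  this scale but gives weaker guarantees on rugged likelihood surfaces
  with many taxa.
* The AU implementation follows the standard WLS fit; it does not
  implement the maximum-likelihood fitting refinement of the original
  program, so fourth-decimal differences from other AU implementations
  are expected.
* ParaFitLink2, the Cailliez correction, and event-based co-phylogeny
  reconciliation are out of scope.
* Bayesian inference (site-heterogeneous CAT models, posterior
  probabilities) is out of scope; node support, where wanted, comes from
  the bootstrap machinery.
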