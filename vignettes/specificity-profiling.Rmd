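---
title: "Profiling extended protease cleavage specificity from substrate phage display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling extended protease cleavage specificity from substrate phage display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagespec)
```

## The problem

Neutrophil serine proteases — elastase (hNE), proteinase 3 (hPR-3) and
their orthologs — cleave after small aliphatic residues at P1, but their
*extended* specificity (the preference pattern across the residues
flanking the scissile bond) determines which physiological substrates
they actually attack. One productive experimental route to that pattern
is substrate phage display: a T7 library displaying random nonamer
peptides as `PGG(X)9HHHHHH` fusions is immobilized on Ni-NTA via the
C-terminal His6 tag, the protease releases phages whose displayed
peptide it can cleave, released phages are amplified and re-panned over
several rounds, and the selected inserts are sequenced and aligned into
the Schechter–Berger subsite frame (P5…P1 | P1′…P4′, the scissile bond
between P1 and P1′). The aligned block becomes a consensus profile,
which is then validated with recombinant tandem-thioredoxin reporter
substrates and can be used to scan protein sequences for candidate
cleavage sites.

`phagespec` implements that whole workflow as testable code: a
stochastic simulator of the biopanning selection, the anchored
alignment, position-matrix inference, reporter-substrate modeling, and
proteome scanning. Everything is tibble-in / tibble-out and pipe
friendly.

## The subsite frame and residue classes

The frame is fixed at nine subsites, P5–P4′, with P1 at index 5; wider
frames are rejected rather than silently truncated. Residues are grouped
into six side-chain classes — aromatic (F, Y, W), negatively charged
(D, E), positively charged (K, R), small aliphatic (G, A), larger
aliphatic (V, L, I, P), hydrophilic (S, T, H, N, Q, C, M) — a partition
of the 20 standard residues used both for the alignment objective and
for logo coloring. Non-standard letters (B, Z, X, U, `*`) are hard
errors in matrix construction and alignment, but merely skip the
affected window (with a count) during scanning, where dirty database
sequences are routine.

## The position matrix

An aligned block of nonamers (each with a copy count and an anchor — the
nonamer position sitting at P1) is summarized as a position frequency
matrix with pseudocount smoothing,

$$f_{j,a} = \frac{c_{j}(a) + \alpha\, b_a}{N_j + \alpha},$$

and a log-odds matrix $\log_2(f_{j,a}/b_a)$ in bits. Defaults:
$\alpha = 1$ with a uniform background $b_a = 1/20$. The pseudocount
avoids $-\infty$ log-odds for residues unseen among ~100 clones; one
pseudo-observation is small against the 96-clone samples this method
produces. Log base 2 keeps scores and information content in bits, the
convention of sequence logos. The background is configurable (e.g. a
proteome composition for scanning); the uniform default matches the
uniform residue usage of the randomized library itself.

Frame cells that fall outside a nonamer (anchors near the ends) can be
filled from the constant capsid context (`PGG`/`HHHHHH`) or excluded.
The default is to exclude (`context = "mask"`): the context residues are
properties of the display vector, not of the selected peptides, and
filling them in inflates Gly/His frequencies at the outer subsites.
Context fill remains available for reproducing display-format-faithful
tables. Column normalization is exact to 1e-9 after every construction
and after class collapse; information content
$IC_j = \log_2 20 + \sum_a f_{j,a}\log_2 f_{j,a}$ is bounded by
$[0, \log_2 20]$, and logo letter heights are $f_{j,a}\,IC_j$ so they
stack to the column IC.

## The biopanning simulator

The generator exists so every downstream stage can be tested without any
laboratory data. It emulates the published selection design: a library
of unique random nonamers (protocol scale $5\times10^7$; scaled default
$10^5$), five rounds of panning with roughly library-sized binding per
round, ten washes (not modeled individually — see below), and 120 clones
picked / 96 sequenced after the last round.

Each round: `min(bound, total)` phages bind (sampled without
replacement, so per-clone bound counts never exceed abundances); each
bound phage releases independently with probability

$$p = p_{bg} + (1 - p_{bg})\,
  \mathrm{logistic}\big(\beta \cdot \mathrm{dose} \cdot (s_{max} - s_0)\big),$$

where $s_{max}$ is the clone's best log-odds score over the eight
nine-residue windows of the displayed 18-mer whose P1 falls inside the
randomized nonamer (cleavage in the constant regions would release all
clones alike and is absorbed into $p_{bg}$); released clones are
amplified back to the bound size by multinomial resampling (unbiased —
clone-specific growth rates are ignored). A control arm models the PBS
mock selection with $p = p_{bg}$ alone.

The release model is this package's own construction; the experiment
only constrains its outcome. Its parameters, chosen once:

* `p_bg = 1e-3` per round — background release absorbing wash losses and
  nonspecific elution.
* `beta = 0.25` per bit $\approx 1/(R \ln 2)$ for $R = 5$ rounds. Under
  weak selection the cumulative five-round weight of a clone scales as
  $e^{R\beta \ln 2\, s} = 2^{s}$ at this slope, i.e. like its true
  preference ratio — the condition under which the final released pool
  reads as an approximately unbiased sample of the specificity profile,
  which is precisely the interpretive assumption made when a final-round
  clone table is aligned into a consensus.
* `s0` = maximal attainable matrix score + 1.5 bits — even the optimal
  substrate is released in well under half of the bound phages per
  round, reflecting incomplete single-pass cleavage during the brief
  protease incubation.

Together these defaults place simulated five-round enrichment factors
(protease released / control released) in the tens-to-hundreds-fold
range characteristic of this protocol, still growing at round five
rather than saturated. The `dose` multiplier expresses relative enzyme
amount (the laboratory contrast of ~50 ng hNE vs 2 µg hPR-3 maps to a
dose ratio, not to different models).

Two calibration notes. First, with $\beta = 0$ the logistic term is the
constant 1/2, so a zero-specificity *enzyme* still releases phages —
flat selection is not the same as no enzyme. The enrichment-estimator
null therefore compares two arms *sharing* the release model
(`run_biopanning(..., control = "shared")`), whose ratio is an estimator
of 1; against a PBS control the same run would measure total activity,
not specificity. Second, the simulator does not model per-wash losses,
phage growth kinetics, library synthesis bias, or sequencing errors;
passing recovery tests therefore demonstrate correctness of the
selection arithmetic and inference chain, not robustness to those
real-data artifacts.

### What the ground truth looks like

`elastase_truth_matrix("hNE")` encodes the qualitative picture of a
broad elastase: P1 mass 0.55/0.25/0.10 on Val/Ile/Ala, Ser elevated at
P1′ (0.30), and every other subsite mildly aliphatic-biased
(V/L/I/A/P ≈ 0.40 jointly). The `hPR3` variant shifts P1 toward
Val > Ala with secondary aromatic/Thr acceptance and no Ile; `xPR3`
prefers Ala over Val. These are simulation ground truths and enzyme
presets, not measured kinetic constants.

## Anchored consensus alignment

The alignment reconstructs algorithmically what is traditionally done by
eye: place each selected nonamer so that one of its P1-compatible
residues (the anchor set from the enzyme's primary specificity) sits at
P1, maximizing cross-peptide coherence. The objective is the weighted
count of same-class peptide pairs per column,

$$J = \sum_j w_j \sum_c \binom{n_{jc}}{2} - \lambda \sum_{p\,\in\,\text{weak}} m_p,$$

counting copy numbers, with the four P1-proximal columns up-weighted
two-fold by default (they carry the specificity signal; the outer
columns are noisier) and weak-tier anchors (e.g. Ala for hNE) penalized
by $\lambda = 0.5$ per copy — admissible but disfavored, matching an
enzyme that tolerates but does not prefer them. Only nonamer residues
enter the objective; the constant capsid context is never allowed to
drive placement (it would reward pushing frames off the randomized
region, since every clone shares `PGG`/`HHHHHH`).

Search proceeds exactly as a human would: peptides with fewest candidate
anchors are fixed first, ambiguous peptides are then placed greedily to
fit the emerging pattern, and placements are polished by coordinate
ascent (plus pairwise re-placement for small blocks), which provably
never decreases $J$. When the total assignment space is small (at most
20,000 combinations) the package instead enumerates it exhaustively:
development testing showed single-peptide ascent can lodge in local
optima on small blocks, and exact solving guarantees both the global
optimum and order-invariance there; realistic 96-clone blocks use the
greedy path. Ties prefer the anchor closest to the nonamer center (it
keeps the informative flanks inside the frame), then the leftmost.
Peptides with no anchor or non-standard residues go to a discard report,
never silently dropped.

## Reporter substrates

The tandem-thioredoxin reporter is modeled as
`Met + Trx + GS + insert + VD + Trx + His6`: two *E. coli* thioredoxin-A
domains joined by a linker whose 6–9-residue cleavable core sits between
the BamHI-encoded Gly-Ser and the SalI-encoded Val-Asp, with a
C-terminal His6 tag. Exact vector-derived residues beyond GS/VD/His6 are
not modeled, so absolute masses carry a ±1 kDa tolerance; masses are
isotope-averaged (gel scale), and cleavage conserves mass to one water
(0.018 kDa).

`predict_cleavage()` scores only windows whose P1 lies in the linker at
an anchor-compatible residue — an accessibility mask encoding the
observation that natively folded thioredoxin resists cleavage. If no
insert site reaches the score threshold (default 0 bits, i.e.
better-than-background), the window centered on the SalI-encoded Val is
evaluated and reported as `sal_fallback` — the secondary cleavage
observed on gels when the inserted test sequence itself is refractory.
Weak-tier P1 residues are penalized 1 bit (a two-fold odds reduction,
the same 0.5 factor as in alignment). `sds_mode = TRUE` lifts the
domain mask, emulating the detergent-opened state in which
thioredoxin-internal sites also become cleavable. The bundled substrate
panel table marks rows whose flanking scaffold is reconstructed from
the stated design rather than printed verbatim (`inferred = TRUE`).

## Scanning

`scan_sequence()` slides the nine-residue frame along a protein,
reports 1-based P1 positions (cleavage after P1), and ranks hits by
score then position. The default threshold is the 99.9th percentile of
scores on $10^5$ background-composition windows, computed with a fixed
internal seed so it is a deterministic property of the matrix; there is
no community-standard cutoff for this kind of score, and a fixed
background quantile at least has a stated false-positive meaning.
Scores are sequence-only: no structural-accessibility correction is
applied, and folded proteins are often resistant at sites their
sequence alone would flag — scan output is a candidate list, not a
substrate prediction.

## Problem sizes and determinism

The package's own test suite and the bundled acceptance script run the
simulator at the scaled sizes (`n0 = bound = 1e5`, five rounds, 96
sequenced clones) for the recovery analysis, 20 replicates for the null
calibration at `n0 = 2e4`, 50 replicates for the enrichment-growth
property, and 100 seeded trials for planted-site scan recovery; these
sizes give stable statistics at desk-scale runtimes. All stochastic
entry points take explicit seeds, restore RNG state on exit, and produce
bit-identical outputs under a fixed seed; the pipeline writes a
provenance stamp (package version, seed, config hash) into every
artifact, and repeated runs of the same configuration are
byte-identical.

## Known limitations

* The release model is a two-parameter logistic stand-in for cleavage
  kinetics; scores are relative preferences, not $k_{cat}/K_m$.
* Amplification is unbiased multinomial; real phage growth-rate
  variation can distort selections.
* The alignment objective formalizes "fit the pattern" as same-class
  pair counting; other coherence measures (entropy-based, PWM-likelihood
  EM) are possible and the objective is swappable.
* Reporter masses omit unknown vector-derived residues (±1 kDa), and the
  accessibility mask is binary.
* Scanning is sequence-only and single-site; no disorder prediction, no
  multi-site interactions, no MEROPS-style database integration.
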