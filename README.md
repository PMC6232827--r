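# phagespec

Determining the **extended cleavage specificity** of a protease — its
preference pattern across the residues flanking the scissile bond — from
**substrate phage display**, and putting that profile to work.

Neutrophil serine proteases such as elastase (hNE) and proteinase 3
(hPR-3) cleave after small aliphatic residues (Val, Ala, Ile) at P1, but
which proteins they attack *in vivo* is governed by the surrounding
subsites. The experimental route modeled here displays a library of
random nonamer peptides on T7 phage as `PGG(X)9HHHHHH` fusions
immobilized on Ni-NTA via the His6 tag; protease treatment releases
clones whose peptide is cleavable, released phages are amplified and
re-panned over five rounds, and the sequenced inserts are aligned into
the Schechter–Berger subsite frame

```
P5  P4  P3  P2  P1 | P1' P2' P3' P4'
                   ^ scissile bond
```

by anchoring a P1-compatible residue at P1. The aligned block becomes a
position frequency / log-odds matrix

    f[j,a] = (c_j(a) + α·b_a) / (N_j + α),   S(w) = Σ_j log2( f[j,w_j] / b_j )

used to design tandem-thioredoxin reporter substrates and to scan
protein sequences for ranked candidate cleavage sites.

`phagespec` implements the full chain as a tidyverse-style R package:

| stage | functions |
|---|---|
| biopanning simulation | `generate_library()`, `release_probability()`, `simulate_round()`, `run_biopanning()` |
| consensus alignment | `candidate_anchors()`, `align_nonamers()`, `alignment_objective()`, `consensus_report()` |
| specificity matrices | `build_pfm()`, `information_content()`, `class_collapse()`, `score_window()`, `export_logo_data()` |
| reporter substrates | `build_construct()`, `construct_mass()`, `fragment_masses()`, `predict_cleavage()`, `substrate_panel()` |
| proteome scanning | `scan_sequence()`, `scan_fasta()`, `score_threshold()` |
| pipeline | `run_config()`, `run_pipeline()` |

Results are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods. The simulator exists so the whole inference chain
is testable without laboratory data: its ground truth is an explicit
position matrix, and recovery of that truth is part of the test suite.

## Worked example

Simulate an hNE-like selection at scaled size (library and binding
capacity 1e5, five rounds, 96 sequenced clones), align the sequenced
clones, and infer the specificity matrix:

```r
library(phagespec)
library(dplyr)

truth <- ground_truth(elastase_truth_matrix("hNE"))
run   <- run_biopanning(panning_params(), truth, seed = 42)
tidy(run)
#> # A tibble: 5 × 5
#>   round  bound released_protease released_control enrichment
#>   <int>  <dbl>             <int>            <int>      <dbl>
#> 1     1 100000              2786               93       30.0
#> 2     2 100000              4032              100       40.3
#> 3     3 100000              5389               96       56.1
#> 4     4 100000              6864              108       63.6
#> 5     5 100000              8641              131       66.0
```

Enrichment (protease released / PBS-control released) grows round over
round into the tens-to-hundreds-fold range this protocol reports.

```r
block <- align_nonamers(rename(run$sequenced, peptide = "nonamer"),
                        align_params(anchors = primary_specificity("hNE")))
pfm   <- build_pfm(block, alpha = 1)
glance(pfm)
#> # A tibble: 1 × 5
#>   alpha total_ic_bits max_ic_bits max_ic_subsite consensus
#>   <dbl>         <dbl>       <dbl> <chr>          <chr>
#> 1     1          8.74        3.34 P1             AVVAVSALI

round(class_collapse(pfm)["P1", ], 2)
#>         aromatic         negative         positive  small_aliphatic
#>             0.00             0.00             0.00             0.00
#> larger_aliphatic      hydrophilic
#>             0.99             0.00

cor(as.vector(pfm$freq), as.vector(truth$pwm$freq))
#> [1] 0.891
```

The most informative subsite is P1 (3.3 bits), its mass sits almost
entirely on the larger-aliphatic class, the P1′ consensus is Ser — and
the inferred matrix correlates 0.89 with the simulation's ground truth.
`autoplot(pfm)` draws the logo-style class-colored profile.

Reporter substrates reproduce the characteristic gel logic — a central
Val insert is cleaved in the middle of the linker, while the Ala variant
is refractory and falls back to the Val encoded by the SalI cloning
site:

```r
m <- elastase_truth_matrix("hNE")
predict_cleavage(build_construct("GRGGVGGRG"), m)
#>   p1_pos residue kind   score frag_n_kda frag_c_kda
#> 1    116 V       insert 0.225       12.4       13.0

predict_cleavage(build_construct("GRGGAGGRG"), m)
#>   p1_pos residue kind         score frag_n_kda frag_c_kda
#> 1    121 V       sal_fallback 0.225       12.8       12.6

cons <- build_construct("VLLVSEVL")
construct_mass(cons)                          # 25.5 kDa uncleaved
fragment_masses(cons, cons$insert_start + 3)  # 12.38 / 13.14 kDa bands
```

A one-call pipeline (`run_pipeline(list(seed = 1), "out/")`) chains
simulate → align → build-matrix (→ design → scan) and writes
provenance-stamped TSV/JSON/FASTA artifacts; see the vignette in
`vignettes/specificity-profiling.Rmd` for the model, parameter
rationale, and limitations.

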