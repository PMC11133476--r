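---
title: "Identifying tissue-targeting peptides from biopanning NGS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tissue-targeting peptides from biopanning NGS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopanr)
```

## The experiment this package models

In vivo phage display couples a random peptide to the pIII coat protein
of M13 phage, so that each virion's DNA encodes the peptide it displays.
A library of ~10^9–10^13 such clones is injected into an animal; phages
recovered from a target tissue are amplified and re-injected for further
rounds, enriching clones whose peptides bind that tissue. Sequencing the
insert region of the recovered phages from the target and from control
organs yields per-tissue, per-round peptide count tables.

biopanr implements the downstream analysis: decoding peptides from raw
reads, cleaning them, grouping near-identical peptides, and deciding
which peptide families are genuinely target-specific. The bundled
library presets describe two widely used naive libraries: a 12-mer with
an `S…GGGS` linker and a 20-mer with an `S…S` linker, sharing the
amplicon flanks `CCTTTCTATTCTCAC` / `GCCGAAACTGTTGAA` and a tolerance of
2 mismatches per flank.

## From reads to peptides

Reads are scanned directly for the two flanks at the exact spacing the
insert length dictates; the read's reverse complement is scanned too,
since amplicons ligate in both orientations. Among qualifying placements
the minimal total flank mismatch count wins, ties resolved to the
leftmost placement and the forward strand, so extraction is
deterministic. We deliberately scan reads directly instead of aligning
them to the phage genome first: for a fixed amplicon the flank match
itself decides whether the read is usable, and a mean-phred read filter
(default threshold 20, configurable) covers quality control without an
external aligner.

Translation uses the standard code in frame 0; stop codons become `*`
and any codon containing an ambiguous base becomes `X`. The filtration
cascade then has a fixed order — (1) drop translations containing `*` or
`X`, (2) keep only translations matching the library's
`prefix + peptide + suffix` layout at the exact length, (3) merge
synonymous DNA variants per (peptide, tissue, round, library) — because
the per-stage report is only interpretable when stages nest. Merging
never crosses tissue, round or library boundaries, and it conserves read
mass; the report exposes both unique-sequence and read totals so either
convention of "peptide count" can be compared.

## Clustering model

Biopanning data are full of near-identical peptides: mutation during
amplification, sequencing errors, and genuinely related binders produce
families differing at one or two positions. We compare equal-length
peptides with the normalized Hamming distance (mismatch fraction). No
multiple alignment is needed — all peptides of a library have the same
length — which removes the one heavyweight dependency such pipelines
typically carry. A substitution-matrix distance (e.g. BLOSUM-weighted)
would treat conservative substitutions as closer; we keep the unweighted
distance because cluster membership here is about read-level identity
drift, not biochemical similarity, and because it makes the distance an
exact metric with rational values.

Clustering is WPGMA (weighted pair-group method with arithmetic mean):
merge the closest pair at height equal to its distance, and set
`d(k, i∪j) = (d(k,i) + d(k,j))/2`. WPGMA is monotone, so merge heights
never decrease and cutting at a height `h` gives a well-defined
partition: two peptides share a cluster iff they merge at height ≤ h.
Hamming distances are massively tied (all values are multiples of 1/L),
and standard library implementations leave tie order unspecified, so we
fixed it: among equally close pairs, the smallest (row, column) position
pair in the current matrix ordering merges first, and consensus residue
ties resolve alphabetically. Every result is thereby reproducible to the
byte.

The implementation is a C++ kernel that keeps cached per-row minima,
invalidating them to stale lower bounds and re-verifying lazily during
the selection scan, so the selected pair is always identical to a full
rescan at near-O(n²) typical cost. Pair distances live in the row of the
younger cluster only, which makes the per-merge update a contiguous
memory sweep. We hold the distance matrix densely in memory rather than
streaming it in blocks: clustering 10,000 peptides needs ~0.8 GB
transiently and a few seconds, which covers this problem class (the
largest single clustering such screens report is on the order of 8,000
round-3 peptides); the buffer is reused across calls so repeated
simulation sweeps do not refault it. Two independent checks guard the
kernel: a brute-force O(n³) rescan reference (exact, including ties) and
`stats::hclust(method = "mcquitty")` on tie-free matrices.

Default cut heights map the stated working range to the two library
lengths: 0.3 for 12-mers and 0.7 for 20-mers (`default_cut_height()`),
both overridable. At 0.3 a 12-mer cluster tolerates roughly 3–4 total
substitutions between members through average linkage; planted families
with radius 1 always hold together, while heavily error-inflated
families can split into a dominant core plus satellite clusters — the
hit ranking is robust to this because counts concentrate in the core.

The consensus of a cluster weights every residue occurrence by its
peptide's read count and takes the per-position argmax; the consensus
count is the members' summed count. If one member carries more than half
the cluster's mass the consensus equals that member exactly.

## Hit selection

`TOPIC20` and `TOPIC` share a specificity filter: a peptide present in
any control tissue above 0.01% of that tissue's final-round reads is
considered non-specific and dropped (absence passes; the threshold is
monotone: raising it never shrinks the survivor set). TOPIC20 clusters
only the top 20 surviving peptides by target count; TOPIC clusters all
survivors and ranks clusters by summed count, which is what lets a
30-member family of count-2 variants outrank a lone count-50 clone.

`SPEC` inverts the logic: cluster first, with no specificity pre-filter,
then judge whole clusters by their tissue profile. Category A clusters
are target-exclusive — off-target count fraction at most ε, with ε = 0
by default, so a single control-tissue read disqualifies. Category B
clusters put at least φ = 0.9 of their reads in the whole heart (target
plus remote heart). Category C reports the single best
remote-heart-dominant cluster. ε and φ are exposed because "exclusive"
and "high number of reads" are qualitative in practice; the defaults are
the strictest reading. Whether the remote heart counts as off-target for
category A is genuinely ambiguous — tissue atlases of such screens mark
LV-only and LV+remote clusters separately — so the off-target tissue set
is a parameter (`offtarget_tissues`), with the strict reading (remote
counts as off-target) as default.

Round-over-round enrichment uses `log2(count + 1)` so that a zero count
and an unobserved cluster coincide at 0 (a bare log2 would send zeros to
−∞ before any NA handling). A cluster is "enriched" when its entries
increase strictly in every target tissue and never increase in any
depleting tissue; the depleting condition is non-strict because
log-scale counts plateau easily and a flat control trajectory carries no
evidence of off-target enrichment.

## The simulator and what passing tests mean

The generator emulates the experiment end to end: a naive library of
distinct random peptides with log-normal abundances; planted families
(seed peptide, substitution radius, per-tissue fitness); three rounds in
which every collected tissue is an independent multinomial sample of
`depth` reads with probability ∝ pool composition × tissue fitness; and
FASTQ emission with uniform synonymous codon choice, random read
placement and context, independent per-base substitution errors, a
reverse-complemented read fraction, and phred scores from a clamped
discretized normal. One seed makes all outputs byte-identical.

Parameter defaults, chosen once as the simulated study conditions:

| parameter | default | why |
|---|---|---|
| `n_naive_clones` | 1,000 | desk-scale stand-in for library diversity |
| `naive_meanlog`, `naive_sdlog` | 0, 0.3 | naive libraries are near-equimolar; ±35% clonal variation |
| `depth` | 10,000 reads/tissue/round | typical per-sample amplicon yield at desk scale |
| `rounds` | 3 | standard panning design |
| `error_rate` | 0.001/base | Illumina-class substitution rate (tests also exercise 0.01) |
| `phred_mean`, `phred_sd` | 35, 3 | realistic quality profile, clamped to [2, 40] |
| `revcomp_fraction` | 0.5 | unoriented amplicon ligation |
| `read_length` | 150 | one mate of a 2×150 run holds flank+insert+flank |
| LV-exclusive fitness | 10 target / 1e-8 elsewhere | strong binder with no off-target binding (fitness must stay positive) |

Between rounds the pool composition updates deterministically —
proportional carryover of the target-bound clones, i.e. weights multiply
by target fitness. The recovered pool is amplified to ~10^13 virions
before reinjection, so the 10^4-read sequencing sample is a readout of
the pool, not a bottleneck on it. Modelling the carryover through the
sampled counts instead would add multinomial drift that manufactures
spuriously "exclusive" singleton clusters in a large fraction of neutral
runs; with proportional carryover, a neutral screen (all fitness 1)
essentially never yields a category-A cluster, which is the correct null
behaviour for the strict ε = 0 reading. Amplification bias per clone is
a config hook left at 1 — real screens do exhibit propagation bias, and
the package deliberately does not attempt to correct for it.

What the simulator does **not** emulate: PCR chimeras and indels
(substitution errors only), quality-dependent error placement, clone
dropout during tissue recovery, paired-end mate structure (single-end
emission; a 150-nt read holds the whole amplicon), and any real binding
chemistry — fitness multipliers are phenomenological. Passing the
planted-truth tests therefore demonstrates that the pipeline's inference
is correct under its own generative assumptions, not that those
assumptions capture every artifact of real screens.

Problem sizes used by the test-suite checks were picked to exercise the
pipeline at realistic scale while keeping a full run on one CPU within a
coffee break: the round-trip check simulates 5,000 reads per tissue and
round for both presets; recovery and null checks run 100 seeded
replicates at depth 10,000 with ~1,000-clone libraries (a 1%-error
replicate clusters ~8,000 unique round-3 peptides, matching the scale of
a real final-round clustering); the clustering kernel is verified
against the brute-force reference on 1,000 random metric matrices.

## Numerical and degenerate-input choices

- Cut comparisons use `height ≤ h + 1e-9` to absorb floating-point noise
  in averaged Hamming distances.
- A single peptide clusters trivially; an empty survivor set yields an
  empty hit list; TOPIC20 proceeds with a warning when fewer than
  `top_n` peptides survive.
- `N` bases count as flank mismatches and translate to `X`, so they are
  removed by the cascade rather than silently recoded.
- Reads shorter than flank5 + insert + flank3 extract nothing (not an
  error); a motif longer than its sequence likewise scans to "no match".
- The titer helper rejects `A269 < A320` (background exceeding signal
  indicates a failed measurement) and non-positive genome sizes.
- Rank ties anywhere resolve alphabetically by sequence.

## Known limitations

- Hamming-based clustering near the cut height can split or merge
  differently from alignment-based distances; the cut heights are
  per-library conventions, not fitted quantities.
- SPEC's ε = 0 is brittle by construction: one stray control read
  disqualifies a cluster. That is the intended strictest reading; loosen
  ε when control samples are deep or noisy.
- The enrichment criterion requires strict increase in the target across
  all rounds and is therefore conservative; real screens lose clones to
  recovery and amplification noise that the criterion does not forgive.
- Dense distance matrices bound practical clustering to roughly 2×10^4
  peptides in 8 GB; beyond that, pre-collapse singletons or raise the
  abundance floor before clustering.
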