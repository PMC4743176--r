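# tagcapture

Simulation and evaluation toolkit for transposase-based chromatin
accessibility assays. `tagcapture` models how the *same* Tn5 insertion
events become very different sequencing libraries under two capture
chemistries, and implements the full peak-set comparison stack used to
quantify the difference.

**Who it is for:** method developers and analysts studying capture bias in
tagmentation assays — why PCR-based fragment capture (ATAC-style) loses
small accessible regions and over-represents long ones, and how every-end
linear capture (THS-style) avoids that loss — plus anyone needing
transparent, oracle-tested implementations of standard peak-set statistics
(base-pair overlap, ≥1-bp peak sharing, length-stratified overlap,
three-way Venn sharing, TSS distances, FRiP-style fractions, mean±SEM per
peak-length bin, larger-30 %/smaller-70 % splits).

## The model in brief

Insertions on one chromosomal molecule are Poisson with rate
`rate_closed` per bp in closed chromatin and `rate_open · weight` inside
accessible regions (~1 % of the genome, lengths log-uniform on
100–3,000 bp by default); each insertion's transposon orientation is an
independent fair draw. Capture then differs by chemistry:

* **THS model** — every cut yields up to two end templates, one per flank,
  running to the neighbouring cut; a template is captured iff its runoff
  length ∈ [400, 2000] bp, then linearly amplified into `amp_factor`
  duplicates of one molecular end. Orientation never gates capture.
* **ATAC model** — each pair of adjacent cuts defines a candidate fragment;
  it amplifies iff the adaptors are heteroadapter-configured (probability
  1/2 under random orientation) **and** its length ∈ [200, 800] bp; PCR
  copies follow a geometric law, two reads per copy on opposite strands.

Downstream: clonal removal on the (contig, 5′ position, strand) key,
seed-reproducible down-sampling to matched unique-alignment depth, binned
coverage, a Poisson/Benjamini–Hochberg stand-in peak caller (imported BED
peak sets are analysed identically), and every comparison statistic above.

## Worked example

A matched comparison on one synthetic 2-Mb genome (plus a high-copy
mitochondrial contig), 100 cells:

```r
library(tagcapture)

cfg <- sim_config(seed = 7, accessible_fraction = 0.01)
m <- generate_landscape(cfg, genome_size = 2e6, mito_size = 16500)
m
#> GenomeModel: 2 contig(s), 2,016,500 bp total
#>   accessible: 21 region(s), 20,437 bp (1.013% of genome)
#>   mitochondrial contig: chrM (copy factor 50)

ex <- run_comparative_experiment(seed = 7)   # simulate, capture, dedup,
ex$depth                                     # depth-match, call peaks
#> [1] 4947

ex$peaks_ths
#> PeakSet 'THS': 58 peak(s), 27,600 bp total
ex$peaks_atac
#> PeakSet 'ATAC': 33 peak(s), 21,800 bp total

# recall of small (<= 400 bp) truth regions at matched depth
truth_recall_by_length(ex$truth, ex$peaks_ths, max_len = 400)$recall
#> [1] 0.75
truth_recall_by_length(ex$truth, ex$peaks_atac, max_len = 400)$recall
#> [1] 0.375

# capture efficiency and the capture-bias split for the THS library
tab <- count_alignments_in_peaks(ex$aln_ths, ex$peaks_ths)
tab
#> PeakCountTable: 58 peak(s); 3,262 of 4,947 alignments in peaks (65.9%)
rank_split(tab)
#> RankSplitResult: larger class (18 peaks) holds 60.66% of alignments;
#> smaller class holds 5.28%
```

Read: at the same unique-alignment depth, every-end capture recovers twice
as many small accessible regions as PCR capture (0.75 vs 0.375 here), calls
more peaks (58 vs 33), and 65.9 % of its alignments fall inside called
peaks — the FRiP-style capture-efficiency statistic. The rank split shows
how alignments distribute between the longest 30 % of peaks and the rest.

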