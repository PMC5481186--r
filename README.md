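# pirkit

Simulation and analysis of PIWI-slicer-triggered piRNA biogenesis from
small RNA sequencing libraries.

## What this is for

PIWI-clade Argonautes cleave piRNA-complementary target RNAs 10 nt
downstream of the guide's 5' end. The cut yields two fragments with
distinct fates: the downstream fragment becomes a **pre-piRNA
intermediate** (sequenced as a maximum-length 51-nt read when
processing stalls) that matures into a **secondary piRNA** followed by
**phased trail piRNAs**, while the upstream fragment is trimmed into a
protected **16-nt by-product** whose 3' end marks the cleavage site.
These products are studied on an artificial reporter precursor carrying
35 perfectly complementary binding sites for 26-nt guide piRNAs.

`pirkit` is for computational biologists working on small RNA silencing
pathways. It provides:

* a seeded **generator** for reporter sequences, biogenesis products with
  ground-truth labels, and sequencing-ready FASTQ libraries (barcodes,
  3' adapters, 51-nt truncation, contaminating 21-23-nt miRNAs, and a
  conversion-efficiency knob for wild-type-like versus helicase-mutant-like
  genotypes);
* the **analysis statistics** for such libraries: demultiplexing, exact
  adapter clipping, Hamming-distance alignment with an optional protected
  seed (no mismatches at read positions 2-10), 5'/3'-end distance
  profiles around target sites, product classification, relative
  16-mer/51-mer ratios, the ping-pong score, rpm and
  divide-by-23-nt-count normalisations, sense/antisense annotation,
  0.25-rpm/3-fold 5'-end sharing classes, PCC×100 profile correlation,
  1st/10th-nucleotide composition and signed consensus coverage.

The core statistic is the end-distance score between two position-weight
vectors M (plus-strand ends) and N (minus-strand 5' ends, in plus
coordinates):

    score(Δ) = Σ_i M(i) · N(i + Δ)

Δ = 0 means shared 5'-end nucleotides and Δ = 9 corresponds to the 10-nt
5' overlap — the ping-pong signature of slicer-generated 5' ends. All
coordinates are 0-based half-open with one-past-last 3' ends, which makes
the secondary piRNA 5' end and the by-product 3' end both register at
distance −10 from a target-site origin.

## Worked example

```r
library(pirkit)

cfg <- default_config(seed = 1)      # control (0.9) and mutant (0.15)
sim <- run_simulate(cfg)             # 35-site reporter, 50,000 reads/library
res <- run_analyze(sim, cfg)
str(res$report$control)
#> List of 10
#>  $ n_reads                 : int 50000
#>  $ n_mapped                : int 40000
#>  $ modal_length_pirna      : int 26
#>  $ modal_length_contaminant: int 22
#>  $ modal_length_byproduct  : int 16
#>  $ argmax_d5_pirna         : int -10
#>  $ argmax_d3_byproduct     : int -10
#>  $ pingpong_argmax         : int 9
#>  $ byproduct_ratio         : num 0.538
#>  $ intermediate_ratio      : num 0.053
```

Reading the report: piRNA-sized reads (24-30 nt, modal 26 nt) have their
5'-end histogram peaking at −10 — their 5' ends were created by slicing.
The 16-nt class peaks at −10 with its 3' ends — the discarded by-product.
The ping-pong score between the targeting guides and the produced piRNAs
peaks at Δ = 9 (10-nt overlap). In the mutant library
(`res$report$mutant`) the same geometry holds but piRNAs collapse while
slicer products persist, so the relative ratios rise
(`intermediate_ratio` 0.053 → 2.72 in this run) — the signature of
cleavage without conversion.

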