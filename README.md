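# long16s

Reconstruction of near full-length 16S rRNA gene sequences from paired-end
Illumina reads of dual molecularly-tagged amplicons.

Short-read 16S surveys cover one hypervariable region (~250–600 bp of the
~1,500 bp gene) and lose taxonomic resolution outside it. One way around this
is to tag each template molecule before amplification with a random 10-nt
molecular tag (UMI) on *both* ends, sequence a mixed pool of full-length
("end+end") amplicon fragments and tagmented ("end+internal") fragments on a
standard 2×250 MiSeq run, and then reassemble each progenitor molecule from
the reads that carry — or are linked through — its tag pair. `long16s`
implements the computational half of that protocol for microbiome
researchers, plus a wet-lab protocol simulator with full ground truth so
every stage can be validated without sequencing data.

## What the pipeline does

Each tagged amplicon end reads, 5'→3':

```
[phaser 0–3 nt][sample barcode 8 nt][random tag 10 nt][primer site][gene ...]
```

1. **Demultiplexing** (`classify_pairs`) — each mate is scanned over the
   allowed phaser lengths; the 8-nt barcode must match a known barcode with
   ≤ 1 mismatch *and* the 27F/1391R annealing sequence must follow the tag
   (IUPAC-aware, ≤ 2 mismatches). Pairs with both ends decoded are end+end;
   exactly one decoded end means end+internal; barcode pairings never
   assigned to a sample are counted as in-vitro recombination evidence
   (`invalid_combination_rate`).
2. **Dual-tag clustering** (`greedy_cluster`) — every end+end pair yields a
   64-nt signature: tag_f(10) + tag_r(10) + barcode_f(8) + barcode_r(8) +
   the first 14 nt of gene sequence from each end. Signatures are clustered
   greedily at > 89 % Hamming identity in abundance-sorted order with one
   consensus-refinement pass, giving one cluster per progenitor molecule.
3. **Chimera elimination** (`filter_recombinants`) — a PCR template-switch
   chimera inherits tag_f from one parent and tag_r from another, so its
   cluster shares a consensus tag with each parent while being less
   abundant. Any cluster sharing a tag (either end) with a strictly more
   abundant cluster is discarded; `recombination_stats` reports the
   read-level recombination rate and the parent:chimera abundance ratio.
4. **Binning** (`assign_read_pairs`) — all reads, end+end and end+internal,
   are matched to the kept clusters' consensus tags (unique best match,
   ≤ 1 mismatch) and grouped into per-template bins.
5. **Assembly** (`assemble_template`) — per bin: synthetic-sequence and
   BWA-style Q20 quality trimming, k-mer spectrum error correction, de
   Bruijn assembly at k = 31, and removal of contigs whose mean coverage is
   more than 10-fold below the bin maximum (chimera-derived debris).
6. **Consensus quality** (`map_reads`, `call_consensus`) — bin reads are
   mapped back to the kept contigs (15-mer anchor, gapless, ≥ 90 %
   identity) and a per-base consensus PHRED score is called as
   `min(93, max(0, Σq_agree − Σq_disagree))`.
7. **Run statistics** (`length_summary`, `bias_estimate`) — sequence length
   distribution, fraction > 1,300 nt, and PCR amplification bias as the
   coefficient of variation of cluster abundances (sample SD / mean).

The simulator (`sim_config`, `simulate_run`) emulates the protocol:
per-template dual tagging, lognormally biased amplification, single-breakpoint
template-switch chimeras with tag inheritance, tagmentation into 400–1,500 bp
fragments pooled ~7:1 with full-length amplicons, and 2×250 reads with
substitution errors and position-decaying qualities — with truth tables
linking every read to its source molecule.

## Worked example

```r
library(long16s)

sc <- sim_config(n_templates = 40, n_samples = 4, depth = 8,
                 bias_sigma = 1.27, chimera_rate = 0.10,
                 tagmented_ratio = 7, error_rate = 0.005, seed = 7)
sim <- simulate_run(sc)
sim
#> <sim_run> 3752 read pairs from 469 molecules (40 templates, 40 chimeric molecules)

res <- run_pipeline(sim)
res
#> <long16s_run>
#>   3752 pairs: 469 end+end / 3280 end+internal / 3 unassigned
#>   80 clusters, 40 kept after chimera filter (recombination 8.5%)
#>   40 assemblies, 24 (60.0%) > 1300 nt
#>   amplification bias (relative mean error): 1.22

res$consensus[["C00016"]]
#> <consensus_seq C00016> 1328 nt, median Q93, median coverage 14

res$stats$bias
#> <bias_estimate> 40 clusters: mean 10.72, sd 13.10, relative mean error 1.22
#>   relative abundance spread: 0.09-5.97 x mean
```

Reading the output: of 3,752 simulated read pairs, 469 are end+end and form
80 dual-tag clusters; the 40 chimeric clusters are removed by the abundance
rule (a measured read-level recombination rate of 8.5 % against the
generative 10 %). All 40 templates assemble; 60 % reach full length at this
shallow 7:1 tagmentation ratio — interior coverage, not tag logic, is the
limiting factor, which is why the end-anchored positions show higher
coverage in `res$stats$profile`. The relative mean error of 1.22 says the
amplification spread across templates has an SD slightly above the mean.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/longamp.R simulate --out-dir run1 --seed 7 --n-templates 40
Rscript inst/scripts/longamp.R run-all  --out-dir run1 --seed 7
```

`run-all` writes per-stage TSV/FASTQ/JSON outputs plus checksum manifests
under `run1/` and skips unchanged stages on rerun.

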