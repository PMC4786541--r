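# codonmotif

Quantitative analysis of short DNA motif distributions on bacterial
chromosomes, using the redundancy of the genetic code as the null model.

## Who this is for

Microbiologists and bioinformaticians asking whether a motif — Dam
methylation sites (GATC), FtsK orienting polar sequences (KOPS, GGGNAGGG),
or any IUPAC motif — is over- or under-represented in particular genes, gene
sets, chromosomal regions, or chromosome arms, *beyond* what the encoded
proteins already force. Classical Markov-chain nulls conflate protein-level
selection with motif-level selection; this package conditions on the protein
and treats synonymous codon choice as the randomness.

## The statistic

Within a coding sequence, a **potential site** is a (position, frame offset)
pair where the encoded peptide window could spell the motif through some
synonymous re-encoding (a motif of length *l* at codon offset *p* spans
⌈(p+l)/3⌉ codons). Its realization probability is estimated from genome-wide
in-frame codon n-gram counts conditioned on the peptide:

    P_mot(pep) = Σ f(cod_mot | pep) / Σ f(cod | pep)

Assuming independence of potential sites, the observed count *m* over a
gene's (or gene set's, or window's) sites follows a Poisson-binomial
distribution with

    m̄ = Σ P_mot,   s = sqrt( Σ P_mot (1 − P_mot) ),   z = (m − m̄) / s

with |z| ≥ 2 as the significance convention. Chromosome-scale asymmetries
(leading/lagging strand, coding/template strand, ori/ter half, replichore,
gene subset) are tested by Monte-Carlo randomization of gene orientations or
labels (10,000 replicates by default), giving a bias z-score.

A structural consequence of the raw-count estimator: merged over *all* genes
of the replicon that the table was built from, m̄ equals m exactly, so the
genome-wide z is 0 — every genome is its own null, and only deviations of
parts (genes, sets, windows, strands) from the whole are signals.

## Worked example

Real runs start from FASTA + GFF3 (`read_genome()`); here a synthetic genome
with known GATC content stands in, so every number is checkable:

```r
library(codonmotif)

genome <- synthetic_genome(12, 900, "GATC", n_potential = 8, n_real = 2, seed = 101)
genome
#> <replicon> synthetic_replicon - 11196 bp, circular, ori = 0 , ter = 5598
#>    12 validated CDS, 0 excluded

tab <- build_codon_table(genome, max_span = 2)
gp  <- genome_profiles(genome, "GATC", tab)
head(gp$table[, c("gene_id","strand","n_windows","m","m_bar","s","z")], 5)
#>   gene_id strand n_windows m     m_bar         s          z
#> 1   sg001      +         6 2 1.5357143 1.0282986  0.4515087
#> 2   sg002      +         5 2 1.7500000 0.9682458  0.2581989
#> 3   sg003      -         5 2 1.3095238 0.9340498  0.7392285
#> 4   sg004      +         3 2 0.8571429 0.7775550  1.4698087
#> 5   sg005      -         8 2 2.6071429 1.2822374 -0.4735027
```

Each row: `n_windows` usable potential GATC sites, `m` realized sites, `m_bar`
and `s` the Poisson-binomial expectation and standard deviation, `z` the
per-gene deviation. Merging all genes reproduces the genome-is-its-own-null
identity:

```r
merge_profiles(gp$profiles$coding, scope_id = "all genes")
#> <motif_profile> all genes [coding]: 71 windows, m = 24, m_bar = 24.000, s = 3.718, z = 0.000
```

The textbook single-window check — Arg-Ser admits GATC at codon offset 1
(A**GA TC**C), and 8 of the 36 codon pairs realize it:

```r
motif_probability("RS", 1, "GATC", uniform_codon_table(2))
#> [1] 0.2222222
```

A chromosome-half bias test (this genome has none planted):

```r
gz <- gene_z_table(genome, "GATC", tab)
bias_test(gz, "ori_ter", n_replicates = 10000, seed = 1)
#> <bias_result> ori_ter: observed = -0.0385, null = 0.0041 +/- 0.3712, z_bias = -0.11 (10000 replicates, 12 genes)
```

`sliding_window_rings()` / `render_rings()` draw the classic 50–500 kb
ring plots, `scale_and_average()` builds ori-anchored 1000-bin cross-genome
profiles with SEM, and `kmer_sweep()` scores all 4^k k-mers over a gene set.
A command-line wrapper with `scan`, `bias`, `profile` and `simulate`
subcommands ships in `inst/scripts/codonmotif`.

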