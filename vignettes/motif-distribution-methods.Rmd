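---
title: "Scoring DNA motif distributions with a codon-redundancy null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring DNA motif distributions with a codon-redundancy null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonmotif)
```

## The problem

Short DNA motifs — Dam methylation sites (GATC), FtsK orienting polar
sequences (KOPS, GGGNAGGG), chromosome-organization signals — are often
distributed non-randomly along bacterial chromosomes, and the distribution is
part of how the corresponding system works. Whether a motif is locally over-
or under-represented is always a statement relative to a null model. The
common choice, Markov chains over the raw nucleotide sequence, mixes coding
and non-coding constraints and cannot separate "selected for the motif" from
"selected for the encoded protein".

`codonmotif` instead takes the protein-coding information itself as the null.
Within coding sequence, the amino acid chain is treated as fixed and the
synonymous codon choice as the random variable. Every position where some
synonymous re-encoding could spell the motif is a *potential site*; the null
asks how often codon usage would realize it by chance.

## The model

**Potential sites and the codon span.** A motif of length $l$ starting at
offset $p \in \{0, 1, 2\}$ within its first codon covers
$\lceil (p + l)/3 \rceil$ codons. Over the three offsets this gives spans
$\{l/3, l/3 + 1\}$ when $3 \mid l$, $\{\lfloor l/3\rfloor + 1\}$ when
$l \equiv 1$, and $\{\lfloor l/3\rfloor + 1, \lfloor l/3\rfloor + 2\}$ when
$l \equiv 2 \pmod 3$. A (position, offset) pair is a potential site when the
encoded peptide window admits the motif through some synonymous encoding.
For example, the dipeptide Arg-Ser admits GATC at $p = 1$ because it can be
encoded as A**GA TC**C.

**Realization probability.** For a peptide window $pep$ the probability that
the motif is realized is

$$P_{mot}(pep) = \frac{\sum f(cod_{mot} \mid pep)}{\sum f(cod \mid pep)},$$

the table-weighted fraction of synonymous codon strings for $pep$ that spell
the motif at the required offset. The frequencies $f$ are raw genome-wide
counts of in-frame codon $n$-grams over all retained coding sequences of the
analyzed replicon — no smoothing, no pseudocounts. A window whose peptide
$n$-gram was never observed has an undefined probability and is excluded
from both the expectation *and* the observed count, keeping numerator and
null on one event space. Degenerate IUPAC motifs are expanded to their
concrete set; an encoding counts if it matches any expansion (union, no
double counting within a window).

**The z-score.** Assuming independence of potential sites, the motif count
over a gene's windows follows a Poisson-binomial distribution with

$$\bar m = \sum P_{mot}, \qquad
  s = \sqrt{\textstyle\sum P_{mot}(1 - P_{mot})}, \qquad
  z = \frac{m - \bar m}{s}.$$

(We take $s$ as the standard deviation, i.e. the square root of the summed
Bernoulli variances; $|z| \ge 2$ is used as the significance convention
throughout.) Gene sets and sliding windows are scored by concatenating the
probability lists and summing the observed counts — $\bar m$ and $s^2$ are
additive, so set scores are exact, not averaged. A gene with no usable
window has a *missing* z, never 0: a zero would fake "exactly as expected".

## Indexed proteome scan

Potential sites are found by enumerating, once per motif and offset, the set
of peptide windows that admit the motif (at most $4^{3 \cdot span - l}$
expansions per offset), and then looking up every length-$span$ substring of
every protein in that hash set. This is the indexed-search equivalent of a
suffix-tree scan — linear in proteome length for fixed motif length — and is
verified in the test suite to return exactly the windows of a naive
per-position scan.

## Strand modes and bias tests

Each gene can be scored on its **coding** strand, its **template** strand
(the reverse-complement motif searched on the coding sequence), or its
**leading**/**lagging** strand, which resolve to coding or template through
the gene's replication context: on the right replichore (the arc from ori to
ter in ascending coordinates) the `+` strand is leading, on the left
replichore the `-` strand. For palindromic motifs such as GATC, coding and
template scores coincide and strand biases are undefined by construction.

Five chromosome-scale biases are tested by Monte Carlo (default 10,000
replicates): leading/lagging, coding/template, ori-half/ter-half, left/right
replichore, and subset-vs-rest. The observed statistic is the mean z
difference between the two classes (for strand biases, the per-gene
difference averaged over genes). The null randomizes at the gene level:
orientations are flipped for strand biases (each flip negates that gene's
contribution), class labels are permuted for positional biases, and
size-matched random subsets are drawn for the subset bias. The bias z-score
is the observed statistic standardized by the null's Monte-Carlo mean and
standard deviation. Genes lacking a finite z in either class are dropped
(complete-case); classes with fewer than two genes are refused. Where the
randomization scheme was genuinely open (positions vs labels for positional
biases), label permutation was chosen: it conditions on the gene layout and
tests only the quantity of interest.

## Chromosome profiles

Sliding-window rings use the standard layout of 50–500 kb windows in 50 kb
steps (10 rings); the step within a ring defaults to a tenth of the window.
A gene belongs to a window when its (circular) midpoint falls inside it, so
each gene contributes to exactly one window per ring position and merging
stays additive. For cross-species averaging, per-gene z values are mapped to
$\lfloor 1000 \cdot d_{ori}/L \rfloor$ bins, where $d_{ori}$ is the circular
distance from the origin in the direction of ascending coordinates; the
origin sits at bin 0/1000, bins are averaged within a genome and then across
genomes with the SEM taken across genomes (species are the replication
unit, not genes). No smoothing beyond the binning is applied. The profile is
invariant to rotating the genome's coordinate start, which the tests check.

## Synthetic study conditions

The generator builds random in-frame coding sequences with *exact* numbers
of potential and realized sites: motif-admitting peptide windows (chosen so
they admit the motif at exactly one offset, with both motif-spelling and
motif-free encodings available) are planted at non-overlapping positions
separated by at least one codon; the remaining codons are drawn uniformly
over synonymous codons (optionally from an empirical table) with
redraw-on-violation so no accidental admitting window survives; a final
structural rescan enforces the exact targets and the construction is retried
on failure. Sequences start with ATG, contain no internal stop, and pass the
package's own CDS validation; generation is deterministic per seed.

Default study conditions mirror the published evaluation settings: 3000 bp
sequences for single-gene enrichment landscapes (up to ~40 potential sites),
tetramer sweeps over all 256 motifs, an interdependence panel in which one
focal motif varies from depletion to enrichment while everything else is
random, and a null-calibration run of 2000 codon-resampling replicates.
Scaled-down sizes used in the test suite (12–48 genes of 600–900 bp per
genome) were chosen as the smallest sets at which the statistics stabilize.

What the generator does *not* emulate: intergenic DNA and its regulatory
constraints, operon structure, amino-acid composition bias, GC skew, or
horizontal transfer. Passing tests therefore demonstrate the correctness and
calibration of the statistic under its own model assumptions — independence
of potential sites given the peptide — not that real genomes satisfy those
assumptions. On real data, weak dependence between overlapping windows and
table-estimation noise in rare peptide $n$-grams add (small) extra variance.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 input is converted on
  read. Genes wrapping the circular coordinate origin get midpoints modulo
  the replicon length.
* The terminus defaults to the point diametrically opposite the origin and
  is configurable; genes exactly equidistant from ori and ter are assigned
  to the ori half (deterministic tie-break).
* Terminal stop codons are trimmed before analysis; windows touching the
  stop are dropped with it. CDSs failing validation (length, ambiguity
  codes, internal stops) are excluded and reported, never silently fixed.
* Alternative start codons (GTG, TTG) are kept as their literal codons in
  the frequency table and in window peptides, so realized codons always
  encode the window peptide; only the reported protein sequence shows Met.
* `s = 0` with `m = m_bar` gives z = 0; `s = 0` with a deviation reports a
  signed infinity rather than masking it.
* The codon n-gram table is built per genome (each replicon is its own
  null); pooling across genomes is possible but not the default.
* Overlapping genes are retained independently — the method scores genes,
  not genomic positions.

## Limitations

Monte-Carlo bias z-scores have resolution limited by the replicate count;
with 10,000 replicates the null moments are stable to ~1–2%. Motifs whose
admitting-peptide dictionary is astronomically large (very short or very
degenerate motifs) make the *generator* (not the scanner) refuse, since
background sequence free of accidental sites cannot be constructed. The
method is designed for bacterial-style genomes that are mostly coding; it
says nothing about motif occurrences in intergenic DNA.
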