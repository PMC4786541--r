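# Shared synthetic fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small circular genome: 12 genes, 600 bp each, GATC at moderate density.
fixture_genome <- function() {
  cached("genome12", synthetic_genome(12, 600, "GATC", 6, 2, seed = 101))
}

fixture_table <- function() {
  cached("table12", build_codon_table(fixture_genome(), max_span = 2))
}

# Genome with leading-strand-only enrichment of a non-palindromic motif:
# all genes on '+', first half on the right replichore (leading), second half
# on the left (lagging); motif realized almost fully in leading genes only.
fixture_planted_bias <- function() {
  cached("planted", {
    n <- 30L
    ref <- data.frame(gene_id = sprintf("g%02d", 1:n), n_potential = 8L,
                      n_real = c(rep(7L, n / 2), rep(1L, n / 2)),
                      length = 600L, stringsAsFactors = FALSE)
    resample_genome_like(ref, "GGAT", seed = 99, strands = rep("+", n))
  })
}

fixture_planted_gz <- function() {
  cached("planted_gz", {
    gen <- fixture_planted_bias()
    tab <- build_codon_table(gen, max_span = 2)
    gene_z_table(gen, "GGAT", tab)
  })
}

# Hand-written 6-gene toy genome (3 plus, 3 minus strand) for IO tests.
toy_genome_files <- function(dir = tempfile("toy")) {
  dir.create(dir)
  set.seed(7)
  gene <- function() paste0(
    "ATG", paste(sample(c("GAA", "GCT", "CGT", "TTC", "AAA", "GGT"), 8,
                        replace = TRUE), collapse = ""), "TAA")
  genes <- replicate(6, gene())
  spacers <- replicate(7, paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                                collapse = ""))
  strands <- c("+", "-", "+", "-", "+", "-")
  seq <- spacers[1]
  start0 <- integer(6); end0 <- integer(6)
  for (i in 1:6) {
    start0[i] <- nchar(seq)
    body <- if (strands[i] == "+") genes[i]
            else as.character(Biostrings::reverseComplement(Biostrings::DNAString(genes[i])))
    seq <- paste0(seq, body, spacers[i + 1])
    end0[i] <- start0[i] + nchar(genes[i])
  }
  fa <- file.path(dir, "toy.fasta"); gff <- file.path(dir, "toy.gff3")
  writeLines(c(">toy", seq), fa)
  writeLines(c("##gff-version 3",
               sprintf("toy\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=t%d;locus_tag=TOY_%04d",
                       start0 + 1L, end0, strands, 1:6, 1:6)), gff)
  list(fasta = fa, gff = gff, genes = genes, strands = strands,
       start0 = start0, end0 = end0, length = nchar(seq))
}
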