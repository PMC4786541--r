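# Independent oracles used across the suite. These re-derive expected values
# by brute force (exhaustive enumeration / naive scans) without reusing the
# package's own computational paths.

# Exact Poisson-binomial mean and sd by exhaustive enumeration of all 2^n
# outcomes of independent Bernoulli trials.
pb_enumerate <- function(probs) {
  n <- length(probs)
  if (n == 0L) return(c(mean = 0, sd = 0))
  X <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  M <- sweep(X, 2, probs, "*") + sweep(1 - X, 2, 1 - probs, "*")
  pr <- exp(rowSums(log(M)))   # log(0) -> -Inf -> exp gives 0, no NaN
  counts <- rowSums(X)
  mu <- sum(pr * counts)
  v <- sum(pr * counts^2) - mu^2
  c(mean = mu, sd = sqrt(max(v, 0)))
}

# Independent inversion of genetic code table 11 (not via codons_for()).
oracle_codons_by_aa <- local({
  gc <- Biostrings::getGeneticCode("11")
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
})

# All codon strings encoding a peptide, by direct expansion.
oracle_encodings <- function(pep) {
  aas <- strsplit(pep, "")[[1]]
  sets <- oracle_codons_by_aa[aas]
  if (any(vapply(sets, is.null, logical(1)))) return(character(0))
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# Does `seqs` contain any concrete expansion of `motif` starting at 1-based
# position `at`? Checked by literal string comparison, no regex.
oracle_has_motif_at <- function(seqs, motif, at) {
  exps <- codonmotif::iupac_expand(motif)
  sub <- substr(seqs, at, at + nchar(motif) - 1L)
  sub %in% exps
}

# Brute-force realization probability: table-weighted fraction of encodings
# spelling the motif at codon offset p. NA when the peptide was never observed.
oracle_pmot <- function(pep, p, motif, table) {
  enc <- oracle_encodings(pep)
  if (!length(enc)) return(NA_real_)
  k <- nchar(pep)
  w <- if (table$type == "uniform") rep(1, length(enc)) else {
    ww <- unname(table$counts[[k]][enc]); ww[is.na(ww)] <- 0; ww
  }
  den <- sum(w)
  if (den == 0) return(NA_real_)
  sum(w[oracle_has_motif_at(enc, motif, p + 1L)]) / den
}

# Naive per-position window scan of one coding sequence: every (codon index,
# offset) pair, peptide identity from a literal translation, probability from
# oracle_pmot. Returns the same columns as potential_windows().
oracle_window_scan <- function(nt, motif, table) {
  gc <- Biostrings::getGeneticCode("11")
  n <- nchar(nt) %/% 3L
  starts <- seq(1L, 3L * n, by = 3L)
  cods <- substring(nt, starts, starts + 2L)
  aa <- unname(gc[cods])
  l <- nchar(motif)
  rows <- list()
  for (p in 0:2) {
    span <- as.integer(ceiling((p + l) / 3))
    if (n < span) next
    for (i in seq_len(n - span + 1L)) {
      pep <- paste(aa[i:(i + span - 1L)], collapse = "")
      pr <- oracle_pmot(pep, p, motif, table)
      if (is.na(pr) || pr == 0) next
      off <- 3L * (i - 1L) + p
      rows[[length(rows) + 1L]] <- data.frame(
        nt_offset = off, p = p, span = span, peptide_window = pep,
        probability = pr,
        realized = oracle_has_motif_at(nt, motif, off + 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(nt_offset = integer(0), p = integer(0),
                      span = integer(0), peptide_window = character(0),
                      probability = numeric(0), realized = logical(0))
  out[order(out$nt_offset, out$p), , drop = FALSE]
}
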