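# The codon-redundancy null model: in-frame codon n-gram frequency tables,
# the codon-span rule, realization probabilities for peptide windows, and
# enumeration of potential motif windows over a proteome.

#' Number of codons a motif spans at a given codon offset
#'
#' A motif of length `l` whose first base sits at offset `p` (0, 1 or 2) within
#' its first codon covers `ceiling((p + l)/3)` codons. Over the three offsets
#' this reproduces the span set `{floor(l/3), floor(l/3)+1}` for `l %% 3 == 0`,
#' `{floor(l/3)+1}` for `l %% 3 == 1` and `{floor(l/3)+1, floor(l/3)+2}` for
#' `l %% 3 == 2`.
#'
#' @param l Motif length in bp (>= 1).
#' @param p Codon offset of the motif's first base: 0, 1 or 2.
#' @return Integer number of codons covered.
#' @export
codon_span <- function(l, p) {
  stopifnot(all(l >= 1), all(p %in% 0:2))
  as.integer(ceiling((p + l) / 3))
}

#' Build the genome-wide in-frame codon n-gram table
#'
#' Counts every in-frame run of `k` consecutive codons (k = 1 .. `max_span`)
#' within single coding sequences, summed over all retained CDSs. Runs never
#' cross gene boundaries. These raw counts are the frequencies `f(cod)` from
#' which motif realization probabilities are estimated.
#'
#' @param x A `motif_genome`, a CDS data.frame with a `nucleotides` column, or
#'   a character vector of in-frame coding sequences.
#' @param max_span Largest n-gram size needed (>= the largest codon span of
#'   the motifs to be analyzed).
#' @return An object of class `codon_table` with `counts` (list of named
#'   numeric vectors, one per k) and `max_span`.
#' @export
build_codon_table <- function(x, max_span = 3L) {
  nts <- if (inherits(x, "motif_genome")) x$cds$nucleotides
         else if (is.data.frame(x)) x$nucleotides
         else as.character(x)
  if (length(nts) == 0L) stop("empty CDS list")
  codlist <- lapply(nts, codon_split)
  counts <- vector("list", max_span)
  for (k in seq_len(max_span)) {
    grams <- unlist(lapply(codlist, kgrams, k = k), use.names = FALSE)
    tab <- table(grams)
    counts[[k]] <- setNames(as.numeric(tab), names(tab))
  }
  structure(list(counts = counts, max_span = as.integer(max_span),
                 type = "empirical"), class = "codon_table")
}

# rolling k-grams of a codon vector, pasted into 3k-nt strings
kgrams <- function(cods, k) {
  n <- length(cods)
  if (n < k) return(character(0))
  if (k == 1L) return(cods)
  do.call(paste0, lapply(0:(k - 1L), function(j) cods[(1L + j):(n - k + 1L + j)]))
}

#' Uniform codon table
#'
#' A `codon_table` in which every codon n-gram of sense codons has weight 1,
#' so realization probabilities reduce to the fraction of synonymous encodings
#' spelling the motif. Used for theoretical calculations and as the reference
#' model for uniformly generated synthetic sequences.
#'
#' @param max_span Largest n-gram size the table will be queried for.
#' @return A `codon_table` of type `"uniform"`.
#' @export
uniform_codon_table <- function(max_span = 4L) {
  structure(list(counts = NULL, max_span = as.integer(max_span),
                 type = "uniform"), class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  if (x$type == "uniform") {
    cat("<codon_table> uniform, max span", x$max_span, "\n")
  } else {
    cat("<codon_table> empirical, max span", x$max_span, ";",
        sum(x$counts[[1]]), "codons in", length(x$counts[[1]]), "distinct codons\n")
  }
  invisible(x)
}

# weights of codon k-gram strings under a table (0 for unobserved)
table_weights <- function(table, strings, k) {
  if (table$type == "uniform") return(rep(1, length(strings)))
  if (k > table$max_span) stop("codon table built with max_span ", table$max_span,
                               " but span ", k, " requested")
  w <- unname(table$counts[[k]][strings])
  w[is.na(w)] <- 0
  w
}

#' Probability that a potential motif window is realized
#'
#' For a peptide window `pep` of `codon_span(l, p)` amino acids, the
#' realization probability is the table-weighted fraction of synonymous codon
#' strings for `pep` that spell the motif starting at offset `p` of the first
#' codon:
#' `P = sum(f(cod_mot | pep)) / sum(f(cod | pep))`,
#' where the numerator sums frequencies of encodings matching any concrete
#' expansion of the (possibly degenerate IUPAC) motif at that offset.
#'
#' @param peptide_window Amino-acid string of length `codon_span(nchar(motif), p)`.
#' @param p Codon offset (0, 1 or 2) of the motif's first base.
#' @param motif IUPAC nucleotide motif.
#' @param table A [codon_table][build_codon_table].
#' @param table_id NCBI translation table, default `"11"`.
#' @return The probability in \[0, 1\], or `NA_real_` when no encoding of the
#'   peptide window was ever observed (denominator zero) — such windows are
#'   unusable and are excluded from profiles.
#' @export
motif_probability <- function(peptide_window, p, motif, table, table_id = "11") {
  motif <- toupper(motif)
  l <- nchar(motif)
  span <- codon_span(l, p)
  if (nchar(peptide_window) != span)
    stop("peptide window has ", nchar(peptide_window), " residues; span for (l=",
         l, ", p=", p, ") is ", span)
  enc <- peptide_encodings(peptide_window, table_id)
  if (length(enc) == 0L) return(NA_real_)
  w <- table_weights(table, enc, span)
  den <- sum(w)
  if (den == 0) return(NA_real_)
  rx <- paste0("^", iupac_regex(motif), "$")
  hit <- grepl(rx, substr(enc, p + 1L, p + l))
  sum(w[hit]) / den
}

# all codon strings encoding a peptide (empty if it contains stop/unknown)
peptide_encodings <- function(pep, table_id = "11") {
  aas <- strsplit(pep, "", fixed = TRUE)[[1]]
  sets <- codons_for(table_id)[aas]
  if (any(vapply(sets, is.null, logical(1)))) return(character(0))
  if (length(sets) == 1L) return(sets[[1]])
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' Precompute the peptide-window dictionary for a motif
#'
#' For each codon offset `p` the set of peptide windows that *admit* the motif
#' (some synonymous encoding spells it at that offset) is enumerated once.
#' Scanning a proteome then reduces to hash lookups of its length-`span`
#' peptide substrings in these sets — the indexed-search equivalent of a
#' suffix-tree scan, sub-quadratic in total proteome length and identical in
#' output to a naive per-position scan.
#'
#' @inheritParams motif_probability
#' @return An object of class `motif_index` holding, per offset, the span, the
#'   admitting peptide set, and a memoization cache for probabilities.
#' @export
motif_index <- function(motif, table, table_id = "11") {
  motif <- toupper(motif)
  l <- nchar(motif)
  expansions <- iupac_expand(motif)
  gc <- genetic_code(table_id)
  pep_sets <- vector("list", 3L)
  spans <- integer(3L)
  for (p in 0:2) {
    span <- codon_span(l, p)
    spans[p + 1L] <- span
    nfree_pre <- p
    nfree_post <- 3L * span - p - l
    pre <- all_nt_strings(nfree_pre)
    post <- all_nt_strings(nfree_post)
    full <- as.vector(outer(pre, as.vector(outer(expansions, post, paste0)), paste0))
    peps <- unique(vapply(full, function(s) {
      paste(gc[codon_split(s)], collapse = "")
    }, character(1), USE.NAMES = FALSE))
    pep_sets[[p + 1L]] <- peps[!grepl("*", peps, fixed = TRUE)]
  }
  structure(list(motif = motif, l = l, spans = spans, pep_sets = pep_sets,
                 regex = paste0("^", iupac_regex(motif), "$"),
                 table = table, table_id = table_id,
                 cache = new.env(parent = emptyenv())),
            class = "motif_index")
}

all_nt_strings <- function(n) {
  if (n == 0L) return("")
  sets <- rep(list(c("A", "C", "G", "T")), n)
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

# memoized probability lookup through a motif_index
index_probability <- function(index, pep, p) {
  key <- paste0(p, "|", pep)
  val <- index$cache[[key]]
  if (is.null(val)) {
    val <- motif_probability(pep, p, index$motif, index$table, index$table_id)
    index$cache[[key]] <- val
  }
  val
}

#' Enumerate the potential motif windows of a coding sequence
#'
#' A potential window is a (position, codon offset) pair whose encoded peptide
#' admits the motif through synonymous codon choice with realization
#' probability > 0 under the table; it must lie fully within the stop-trimmed
#' coding sequence. Windows whose peptide n-gram was never observed in the
#' table (denominator zero) are unusable and returned in the `skipped`
#' attribute instead.
#'
#' @param nucleotides In-frame, stop-trimmed coding-strand sequence.
#' @param motif IUPAC motif, or a prebuilt [motif_index()] via `index`.
#' @param table A [codon_table][build_codon_table] (ignored when `index` given).
#' @param index Optional prebuilt [motif_index()]; build one per genome scan
#'   to share the dictionary and probability cache across genes.
#' @param gene_id Identifier copied into the result.
#' @param table_id NCBI translation table.
#' @return data.frame: gene_id, nt_offset (0-based, on the coding sequence),
#'   p, span, peptide_window, probability, realized (does the realized DNA
#'   spell the motif here). Attribute `skipped` lists excluded windows.
#' @export
potential_windows <- function(nucleotides, motif = NULL, table = NULL,
                              index = NULL, gene_id = NA_character_,
                              table_id = "11") {
  if (is.null(index)) {
    if (is.null(motif) || is.null(table))
      stop("give either a motif_index or motif + table")
    index <- motif_index(motif, table, table_id)
  }
  gc <- genetic_code(index$table_id)
  cods <- codon_split(nucleotides)
  pep <- paste(gc[cods], collapse = "")
  n <- length(cods)
  out <- vector("list", 3L)
  skip <- vector("list", 3L)
  for (p in 0:2) {
    span <- index$spans[p + 1L]
    if (n < span) next
    i <- seq_len(n - span + 1L)
    wpep <- substring(pep, i, i + span - 1L)
    hit <- which(wpep %in% index$pep_sets[[p + 1L]])
    if (!length(hit)) next
    probs <- vapply(wpep[hit], function(pp) index_probability(index, pp, p),
                    numeric(1), USE.NAMES = FALSE)
    nt_off <- 3L * (hit - 1L) + p
    realized <- grepl(index$regex,
                      substr(rep(nucleotides, length(hit)),
                             nt_off + 1L, nt_off + index$l))
    df <- data.frame(gene_id = gene_id, nt_offset = nt_off, p = p,
                     span = span, peptide_window = wpep[hit],
                     probability = probs, realized = realized,
                     stringsAsFactors = FALSE)
    skip[[p + 1L]] <- df[is.na(df$probability), , drop = FALSE]
    out[[p + 1L]] <- df[!is.na(df$probability) & df$probability > 0, , drop = FALSE]
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(gene_id = character(0), nt_offset = integer(0),
                      p = integer(0), span = integer(0),
                      peptide_window = character(0), probability = numeric(0),
                      realized = logical(0), stringsAsFactors = FALSE)
  res <- res[order(res$nt_offset, res$p), , drop = FALSE]
  rownames(res) <- NULL
  skipped <- do.call(rbind, skip[!vapply(skip, is.null, logical(1))])
  attr(res, "skipped") <- skipped
  res
}
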