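# Genetic-code and IUPAC utilities shared by the model and the generators.
# Translation defaults to NCBI table 11 (bacterial); codons are always handled
# as literal trinucleotide strings so that alternative start codons keep their
# own identity in the frequency tables.

.codon_env <- new.env(parent = emptyenv())

#' Forward genetic code as a named character vector
#'
#' @param table_id NCBI genetic code identifier (character), default `"11"`.
#' @return Named character vector mapping the 64 codons to one-letter amino
#'   acids (`*` for stop).
#' @export
genetic_code <- function(table_id = "11") {
  key <- paste0("fwd_", table_id)
  if (is.null(.codon_env[[key]])) {
    .codon_env[[key]] <- Biostrings::getGeneticCode(table_id)
  }
  .codon_env[[key]]
}

#' Synonymous codons per amino acid
#'
#' Inverts the genetic code: for each amino acid the set of codons encoding it.
#' Stop codons are excluded (key `*` is absent).
#'
#' @inheritParams genetic_code
#' @return Named list, one character vector of codons per amino acid.
#' @export
codons_for <- function(table_id = "11") {
  key <- paste0("rev_", table_id)
  if (is.null(.codon_env[[key]])) {
    gc <- genetic_code(table_id)
    gc <- gc[gc != "*"]
    .codon_env[[key]] <- split(names(gc), unname(gc))
  }
  .codon_env[[key]]
}

#' Translate an in-frame nucleotide string codon by codon
#'
#' Literal translation: alternative start codons (GTG, TTG) are translated as
#' their table-11 amino acid (Val, Leu), not as Met. Used internally wherever
#' peptide identity must agree with the realized codons.
#'
#' @param nt In-frame nucleotide string (length a multiple of 3, A/C/G/T).
#' @inheritParams genetic_code
#' @return One-letter amino-acid string; stops appear as `*`.
#' @export
translate_literal <- function(nt, table_id = "11") {
  stopifnot(nchar(nt) %% 3L == 0L)
  if (nchar(nt) == 0L) return("")
  cods <- codon_split(nt)
  paste(genetic_code(table_id)[cods], collapse = "")
}

#' Split an in-frame nucleotide string into codons
#' @inheritParams translate_literal
#' @return Character vector of codons.
#' @export
codon_split <- function(nt) {
  n <- nchar(nt)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(nt, starts, starts + 2L)
}

#' Expand an IUPAC nucleotide motif to its concrete sequences
#'
#' @param motif IUPAC nucleotide string, case-insensitive.
#' @return Character vector of all concrete A/C/G/T expansions.
#' @export
iupac_expand <- function(motif) {
  motif <- toupper(motif)
  letters <- strsplit(motif, "", fixed = TRUE)[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(letters, names(map))
  if (length(bad)) stop("invalid IUPAC letters in motif: ", paste(bad, collapse = ", "))
  sets <- lapply(letters, function(x) strsplit(map[[x]], "", fixed = TRUE)[[1]])
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' IUPAC motif as a fixed-position regular expression
#' @inheritParams iupac_expand
#' @return Regex matching exactly the motif's expansions (unanchored).
#' @export
iupac_regex <- function(motif) {
  motif <- toupper(motif)
  letters <- strsplit(motif, "", fixed = TRUE)[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(letters, names(map))
  if (length(bad)) stop("invalid IUPAC letters in motif: ", paste(bad, collapse = ", "))
  paste(vapply(letters, function(x) {
    s <- map[[x]]
    if (nchar(s) == 1L) s else paste0("[", s, "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of an IUPAC motif
#' @inheritParams iupac_expand
#' @return IUPAC string of the reverse complement.
#' @export
revcomp_motif <- function(motif) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(motif))))
}

# Reverse complement for plain A/C/G/T(/N) strings, vectorized.
revcomp_nt <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
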