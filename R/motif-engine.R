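# Per-gene and per-set motif profiles: observed counts over potential windows,
# Poisson-binomial moments and z-scores, on the requested strand.

#' Construct a motif profile from a probability list and an observed count
#'
#' @param probabilities Realization probabilities of the potential windows.
#' @param m Observed motif count over those windows.
#' @param scope_id Gene id, set name or window id.
#' @param strand_mode One of `"coding"`, `"template"`, `"leading"`, `"lagging"`.
#' @return Object of class `motif_profile` with fields `probabilities`, `m`,
#'   `m_bar` (= sum of probabilities), `s` (= sqrt(sum P(1-P))) and `z`.
#'   `z` is `NA` for window-less scopes (missing, never 0).
#' @export
motif_profile <- function(probabilities, m, scope_id = NA_character_,
                          strand_mode = "coding") {
  mom <- poisson_binomial_summary(probabilities)
  z <- if (length(probabilities) == 0L) NA_real_ else zscore(m, mom[[1]], mom[[2]])
  structure(list(scope_id = scope_id, strand_mode = strand_mode,
                 probabilities = probabilities, m = as.integer(m),
                 m_bar = mom[[1]], s = mom[[2]], z = z),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> %s [%s]: %d windows, m = %d, m_bar = %.3f, s = %.3f, z = %s\n",
              x$scope_id, x$strand_mode, length(x$probabilities), x$m,
              x$m_bar, x$s, ifelse(is.na(x$z), "NA", sprintf("%.3f", x$z))))
  invisible(x)
}

# resolve strand mode to the motif actually searched on the coding sequence:
# template = reverse complement of the motif on the coding strand;
# leading/lagging resolve to coding/template through the gene's strand class.
resolve_strand_motif <- function(motif, strand_mode, strand_class = NULL) {
  if (strand_mode %in% c("leading", "lagging")) {
    if (is.null(strand_class))
      stop("leading/lagging strand mode needs the gene's replication context")
    coding_is_it <- (strand_class == "leading") == (strand_mode == "leading")
    strand_mode <- if (coding_is_it) "coding" else "template"
  }
  if (strand_mode == "template") revcomp_motif(motif) else toupper(motif)
}

#' Observed motif count in one coding sequence
#'
#' Counts potential windows whose realized nucleotides spell the motif (any
#' IUPAC expansion) at the window's offset. Occurrences falling outside usable
#' windows are not counted, keeping the observed count and the null model on
#' the same event space.
#'
#' @param nucleotides In-frame, stop-trimmed coding-strand sequence.
#' @param motif IUPAC motif.
#' @param table A [codon_table][build_codon_table].
#' @param strand_mode `"coding"` (default) or `"template"`; for
#'   `"leading"`/`"lagging"` supply `strand_class`.
#' @param strand_class The gene's `"leading"`/`"lagging"` label (only needed
#'   for those modes).
#' @param table_id NCBI translation table.
#' @return Integer count m.
#' @export
observed_count <- function(nucleotides, motif, table, strand_mode = "coding",
                           strand_class = NULL, table_id = "11") {
  m <- resolve_strand_motif(motif, strand_mode, strand_class)
  w <- potential_windows(nucleotides, m, table, table_id = table_id)
  sum(w$realized)
}

#' Motif profile of a single gene
#'
#' @inheritParams observed_count
#' @param gene_id Identifier for the profile.
#' @param index Optional prebuilt [motif_index()] for the *resolved* motif
#'   (coding-strand search string); pass one when scanning many genes.
#' @return A [motif_profile()].
#' @export
gene_profile <- function(nucleotides, motif, table, strand_mode = "coding",
                         strand_class = NULL, gene_id = NA_character_,
                         index = NULL, table_id = "11") {
  mres <- resolve_strand_motif(motif, strand_mode, strand_class)
  if (is.null(index)) index <- motif_index(mres, table, table_id)
  else if (index$motif != mres)
    stop("index built for motif ", index$motif, " but ", mres, " required")
  w <- potential_windows(nucleotides, index = index, gene_id = gene_id)
  motif_profile(w$probability, sum(w$realized), scope_id = gene_id,
                strand_mode = strand_mode)
}

#' Merge motif profiles into a gene-set profile
#'
#' Probability lists are concatenated, observed counts summed, and the
#' Poisson-binomial moments and z recomputed on the merged list. All profiles
#' must share the strand mode.
#'
#' @param profiles List of [motif_profile()] objects.
#' @param scope_id Name for the merged scope.
#' @return A [motif_profile()].
#' @export
merge_profiles <- function(profiles, scope_id = "set") {
  if (length(profiles) == 0L) stop("no profiles to merge")
  modes <- unique(vapply(profiles, `[[`, character(1), "strand_mode"))
  if (length(modes) != 1L)
    stop("profiles mix strand modes: ", paste(modes, collapse = ", "))
  probs <- unlist(lapply(profiles, `[[`, "probabilities"), use.names = FALSE)
  m <- sum(vapply(profiles, `[[`, integer(1), "m"))
  motif_profile(probs, m, scope_id = scope_id, strand_mode = modes)
}

#' Per-gene motif profiles for a whole genome
#'
#' Runs the indexed window scan once per strand mode over all retained genes.
#'
#' @param genome A `motif_genome`.
#' @param motif IUPAC motif.
#' @param table A [codon_table][build_codon_table] (typically built from the
#'   same genome).
#' @param strand_modes Subset of `c("coding", "template", "leading",
#'   "lagging")`. Leading/lagging require a circular replicon with ori.
#' @param context Optional precomputed [assign_replication_context()] result.
#' @param table_id NCBI translation table.
#' @return List with `profiles` (list per strand mode of per-gene
#'   [motif_profile()]s) and `table` (tidy data.frame: gene_id, start, end,
#'   strand, strand_class, strand_mode, n_windows, m, m_bar, s, z).
#' @export
genome_profiles <- function(genome, motif, table,
                            strand_modes = "coding", context = NULL,
                            table_id = "11") {
  cds <- genome$cds
  needs_ctx <- any(strand_modes %in% c("leading", "lagging"))
  if (needs_ctx && is.null(context)) context <- assign_replication_context(genome)
  strand_class <- if (!is.null(context)) context$strand_class[match(cds$gene_id, context$gene_id)]
                  else rep(NA_character_, nrow(cds))

  idx_coding <- motif_index(toupper(motif), table, table_id)
  rc <- revcomp_motif(motif)
  idx_template <- if (identical(rc, toupper(motif))) idx_coding
                  else motif_index(rc, table, table_id)

  base <- lapply(seq_len(nrow(cds)), function(i) {
    list(coding = potential_windows(cds$nucleotides[i], index = idx_coding,
                                    gene_id = cds$gene_id[i]),
         template = potential_windows(cds$nucleotides[i], index = idx_template,
                                      gene_id = cds$gene_id[i]))
  })

  profiles <- list()
  rows <- list()
  for (mode in strand_modes) {
    plist <- lapply(seq_len(nrow(cds)), function(i) {
      use <- if (mode %in% c("coding", "template")) mode
             else if ((strand_class[i] == "leading") == (mode == "leading")) "coding"
             else "template"
      w <- base[[i]][[use]]
      motif_profile(w$probability, sum(w$realized),
                    scope_id = cds$gene_id[i], strand_mode = mode)
    })
    names(plist) <- cds$gene_id
    profiles[[mode]] <- plist
    rows[[mode]] <- data.frame(
      gene_id = cds$gene_id, start = cds$start, end = cds$end,
      strand = cds$strand, strand_class = strand_class, strand_mode = mode,
      n_windows = vapply(plist, function(p) length(p$probabilities), integer(1)),
      m = vapply(plist, `[[`, integer(1), "m"),
      m_bar = vapply(plist, `[[`, numeric(1), "m_bar"),
      s = vapply(plist, `[[`, numeric(1), "s"),
      z = vapply(plist, `[[`, numeric(1), "z"),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(profiles = profiles, table = tab)
}

#' z-scores of all k-mers over a gene set
#'
#' Merged-set profile z for every concrete k-mer, e.g. all 256 tetramers of a
#' functional gene group.
#'
#' @param cds CDS data.frame (rows of a `motif_genome` `cds` table) holding
#'   the gene set.
#' @param k k-mer size (k = 4 gives 256 motifs).
#' @param table A [codon_table][build_codon_table] built from the whole genome.
#' @param table_id NCBI translation table.
#' @return data.frame: motif, n_windows, m, m_bar, s, z — sorted by decreasing z.
#' @export
kmer_sweep <- function(cds, k, table, table_id = "11") {
  kmers <- all_nt_strings(k)
  rows <- lapply(kmers, function(km) {
    idx <- motif_index(km, table, table_id)
    wl <- lapply(seq_len(nrow(cds)), function(i)
      potential_windows(cds$nucleotides[i], index = idx, gene_id = cds$gene_id[i]))
    probs <- unlist(lapply(wl, `[[`, "probability"), use.names = FALSE)
    m <- sum(vapply(wl, function(w) sum(w$realized), numeric(1)))
    prof <- motif_profile(probs, m, scope_id = km)
    data.frame(motif = km, n_windows = length(probs), m = prof$m,
               m_bar = prof$m_bar, s = prof$s, z = prof$z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$z), ]
}
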