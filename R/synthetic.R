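# Generators for synthetic coding sequences and genomes with exactly
# controlled numbers of potential and realized motif sites, plus the motif
# interdependence experiment they support.
#
# Construction outline: planted windows are placed at non-overlapping codon
# ranges and given encodings from a precomputed catalog (peptides admitting
# the motif at exactly the chosen offset, with both motif-spelling and
# motif-free encodings available); background codons are then drawn
# left-to-right with redraw-on-violation so no accidental admitting window
# survives; a final structural rescan enforces the exact target counts.

# catalog of plantable peptides for (motif, p): peptides admitting the motif
# at offset p and nowhere else within their own span, with at least one
# encoding realizing the motif only at p and one realizing it nowhere.
plant_catalog <- function(motif, table_id = "11") {
  motif <- toupper(motif)
  l <- nchar(motif)
  idx <- motif_index(motif, uniform_codon_table(max(codon_span(l, 0:2))),
                     table_id)
  rx <- iupac_regex(motif)
  lapply(0:2, function(p) {
    span <- codon_span(l, p)
    peps <- idx$pep_sets[[p + 1L]]
    entries <- lapply(peps, function(pep) {
      enc <- peptide_encodings(pep, table_id)
      occ <- gregexpr(paste0("(?=", rx, ")"), enc, perl = TRUE)
      offsets <- lapply(occ, function(o) {
        o <- as.integer(o); o <- o[o > 0] - 1L   # 0-based
        o[o + l <= 3L * span]
      })
      all_off <- sort(unique(unlist(offsets)))
      if (!identical(all_off, p)) return(NULL)   # admits elsewhere too
      real_enc <- enc[vapply(offsets, function(o) identical(o, p), logical(1))]
      free_enc <- enc[vapply(offsets, length, integer(1)) == 0L]
      if (!length(real_enc) || !length(free_enc)) return(NULL)
      list(pep = pep, realized = real_enc, unrealized = free_enc)
    })
    entries[!vapply(entries, is.null, logical(1))]
  })
}

# does any window of `index` that covers codon j and lies fully in the filled
# region admit the motif, excluding exact planted keys? peptide given as a
# character vector of amino acids; filled = logical vector.
violates_at <- function(aa, filled, j, index, planted_keys) {
  n <- length(aa)
  for (p in 0:2) {
    span <- index$spans[p + 1L]
    lo <- max(1L, j - span + 1L)
    hi <- min(j, n - span + 1L)
    if (lo > hi) next
    for (i in lo:hi) {
      rng <- i:(i + span - 1L)
      if (!all(filled[rng])) next
      if (paste0(i, "_", p) %in% planted_keys) next
      pep <- paste(aa[rng], collapse = "")
      if (pep %in% index$pep_sets[[p + 1L]]) return(TRUE)
    }
  }
  FALSE
}

#' Generate a random coding sequence with exact motif-site counts
#'
#' Produces an in-frame coding sequence (ATG start, no internal stops, stop
#' codon excluded) of the requested length containing exactly `n_potential`
#' positions where synonymous codon choice admits the motif, of which exactly
#' `n_real` spell the motif in the realized DNA. All other codons are drawn at
#' random (uniformly over synonymous codons, or following a supplied codon
#' table) under the constraint that they create no further admitting window.
#'
#' @param length Coding length in bp (multiple of 3; the stop codon is not
#'   included). Default 3000.
#' @param motif IUPAC motif.
#' @param n_potential Target number of potential windows (>= `n_real`).
#' @param n_real Target number of realized motifs.
#' @param codon_source `"uniform"` (default) or `"table"`; `"table"` draws
#'   background codons from the 1-gram frequencies of `table`.
#' @param table Codon table for `codon_source = "table"`.
#' @param seed Integer seed; identical spec + seed gives an identical sequence.
#' @param gene_id Identifier for the returned record.
#' @param max_attempts Bound on whole-sequence construction retries before the
#'   targets are declared infeasible.
#' @param table_id NCBI translation table.
#' @return One-row CDS data.frame (gene_id, start, end, strand, nucleotides,
#'   peptide, midpoint) with attribute `planted` (data.frame: codon_start
#'   (1-based), p, nt_offset, peptide, realized).
#' @export
random_coding_sequence <- function(length = 3000L, motif = "GATC",
                                   n_potential = 10L, n_real = 5L,
                                   codon_source = c("uniform", "table"),
                                   table = NULL, seed = NULL,
                                   gene_id = "synth", max_attempts = 50L,
                                   table_id = "11") {
  codon_source <- match.arg(codon_source)
  if (length %% 3L != 0L) stop("length must be a multiple of 3")
  if (n_real > n_potential) stop("n_real must be <= n_potential")
  if (!is.null(seed)) set.seed(seed)
  n_codons <- length %/% 3L
  motif <- toupper(motif)
  l <- nchar(motif)
  max_span <- max(codon_span(l, 0:2))
  idx <- motif_index(motif, uniform_codon_table(max_span), table_id)
  catalog <- plant_catalog(motif, table_id)
  usable_p <- which(vapply(catalog, length, integer(1)) > 0L) - 1L
  if (n_potential > 0L && !length(usable_p))
    stop("no plantable peptide windows exist for motif ", motif)

  # background codon pool and weights
  gc <- genetic_code(table_id)
  sense <- names(gc)[gc != "*"]
  bg_w <- if (codon_source == "table") {
    if (is.null(table) || table$type != "empirical")
      stop("codon_source = 'table' needs an empirical codon table")
    w <- table$counts[[1]][sense]; w[is.na(w)] <- 0; w / sum(w)
  } else rep(1 / length(sense), length(sense))

  # feasibility: ATG + plants with >= 1 codon gaps
  need <- 1L + n_potential * max_span + max(0L, n_potential - 1L)
  if (need > n_codons)
    stop("infeasible targets: ", n_potential, " windows of span <= ", max_span,
         " do not fit in ", n_codons, " codons")

  for (attempt in seq_len(max_attempts)) {
    ps <- if (n_potential > 0L)
      usable_p[sample.int(length(usable_p), n_potential, replace = TRUE)]
      else integer(0)
    spans <- codon_span(l, ps)
    # place plants left to right with random gaps (never at codon 1)
    slack <- n_codons - 1L - sum(spans) - n_potential
    if (slack < 0) stop("infeasible targets: windows do not fit in ",
                        n_codons, " codons")
    gaps <- if (n_potential > 0L) {
      extra <- if (slack > 0) tabulate(sample.int(n_potential + 1L, slack,
                                                  replace = TRUE),
                                       nbins = n_potential + 1L)
               else integer(n_potential + 1L)
      extra + c(1L, rep(1L, max(0L, n_potential - 1L)), 0L)[seq_len(n_potential + 1L)]
    } else integer(0)

    cods <- rep(NA_character_, n_codons)
    cods[1] <- "ATG"
    planted <- data.frame(codon_start = integer(0), p = integer(0),
                          peptide = character(0), realized = logical(0))
    pos <- 1L
    realized_flags <- if (n_potential > 0L)
      sample(rep(c(TRUE, FALSE), c(n_real, n_potential - n_real))) else logical(0)
    ok_place <- TRUE
    for (i in seq_len(n_potential)) {
      pos <- pos + gaps[i]
      entry <- catalog[[ps[i] + 1L]][[sample.int(length(catalog[[ps[i] + 1L]]), 1L)]]
      enc <- if (realized_flags[i]) sample(entry$realized, 1L)
             else sample(entry$unrealized, 1L)
      rng <- pos:(pos + spans[i] - 1L)
      if (max(rng) > n_codons) { ok_place <- FALSE; break }
      cods[rng] <- codon_split(enc)
      planted <- rbind(planted, data.frame(
        codon_start = pos, p = ps[i], peptide = entry$pep,
        realized = realized_flags[i], stringsAsFactors = FALSE))
      pos <- pos + spans[i]
    }
    if (!ok_place) next
    planted_keys <- paste0(planted$codon_start, "_", planted$p)

    # fill background left-to-right with redraw-on-violation
    aa <- rep(NA_character_, n_codons)
    filled <- !is.na(cods)
    aa[filled] <- gc[cods[filled]]
    ok_fill <- TRUE
    for (j in which(!filled)) {
      placed <- FALSE
      for (try in 1:60) {
        cand <- sample(sense, 1L, prob = bg_w)
        cods[j] <- cand; aa[j] <- gc[[cand]]; filled[j] <- TRUE
        if (!violates_at(aa, filled, j, idx, planted_keys)) { placed <- TRUE; break }
        filled[j] <- FALSE
      }
      if (!placed) { ok_fill <- FALSE; break }
    }
    if (!ok_fill) next

    nt <- paste(cods, collapse = "")
    w <- potential_windows(nt, index = idx, gene_id = gene_id)
    if (nrow(w) != n_potential || sum(w$realized) != n_real) next

    pep <- paste(aa, collapse = "")
    out <- data.frame(gene_id = gene_id, start = 0L, end = length,
                      strand = "+", nucleotides = nt, peptide = pep,
                      midpoint = length %/% 2L, stringsAsFactors = FALSE)
    planted$nt_offset <- 3L * (planted$codon_start - 1L) + planted$p
    attr(out, "planted") <- planted
    return(out)
  }
  stop("could not realize targets (n_potential = ", n_potential, ", n_real = ",
       n_real, ") within ", max_attempts, " attempts; targets likely infeasible")
}

#' Build a synthetic genome whose per-gene motif counts match a reference table
#'
#' One synthetic coding sequence is generated per reference gene with the
#' matched (potential, realized) counts; the genes are laid head-to-tail (with
#' terminal stop codons and short random intergenic spacers, strands drawn at
#' random) into a circular replicon that round-trips through [write_genome()]
#' and [read_genome()].
#'
#' @param reference_counts data.frame with columns `gene_id`, `n_potential`,
#'   `n_real` and optionally `length` (coding bp, default 3000).
#' @param motif IUPAC motif.
#' @param seed Integer seed for the whole genome.
#' @param ori_position Origin placed on the assembled replicon (default 0).
#' @param spacer_bp Intergenic spacer length (default 30).
#' @param codon_source,table Passed to [random_coding_sequence()].
#' @param replicon_id Sequence id of the assembled replicon.
#' @param strands Optional character vector of `+`/`-` per gene; default
#'   random.
#' @param table_id NCBI translation table.
#' @return A `motif_genome`; genes with infeasible targets are skipped and
#'   listed in its `excluded` report (reason `"infeasible targets"`).
#' @export
resample_genome_like <- function(reference_counts, motif, seed = NULL,
                                 ori_position = 0L, spacer_bp = 30L,
                                 codon_source = "uniform", table = NULL,
                                 replicon_id = "synthetic_replicon",
                                 strands = NULL, table_id = "11") {
  stopifnot(all(c("gene_id", "n_potential", "n_real") %in% names(reference_counts)))
  if (!is.null(seed)) set.seed(seed)
  lens <- if ("length" %in% names(reference_counts)) reference_counts$length
          else rep(3000L, nrow(reference_counts))
  genes <- vector("list", nrow(reference_counts))
  skipped <- character(0)
  for (i in seq_len(nrow(reference_counts))) {
    g <- tryCatch(
      random_coding_sequence(length = lens[i], motif = motif,
                             n_potential = reference_counts$n_potential[i],
                             n_real = reference_counts$n_real[i],
                             codon_source = codon_source, table = table,
                             gene_id = reference_counts$gene_id[i],
                             table_id = table_id),
      error = function(e) NULL)
    if (is.null(g)) skipped <- c(skipped, reference_counts$gene_id[i])
    genes[[i]] <- g
  }
  keep <- !vapply(genes, is.null, logical(1))
  if (!any(keep)) stop("no gene satisfied its targets")
  if (is.null(strands)) {
    strands <- sample(c("+", "-"), nrow(reference_counts), replace = TRUE)
  } else {
    stopifnot(length(strands) == nrow(reference_counts),
              all(strands %in% c("+", "-")))
  }
  genes <- genes[keep]
  strands <- strands[keep]
  pieces <- character(0)
  start0 <- integer(length(genes)); end0 <- integer(length(genes))
  cursor <- 0L
  for (i in seq_along(genes)) {
    spacer <- paste(sample(c("A", "C", "G", "T"), spacer_bp, replace = TRUE),
                    collapse = "")
    cursor <- cursor + spacer_bp
    coding <- paste0(genes[[i]]$nucleotides, "TAA")
    start0[i] <- cursor
    end0[i] <- cursor + nchar(coding)
    pieces <- c(pieces, spacer,
                if (strands[i] == "+") coding else revcomp_nt(coding))
    cursor <- end0[i]
  }
  seq <- paste(pieces, collapse = "")
  rep_obj <- replicon(replicon_id, seq, topology = "circular",
                      ori_position = ori_position)
  genome <- build_cds_set(rep_obj, vapply(genes, `[[`, character(1), "gene_id"),
                          start0, end0, strands, table_id = table_id)
  if (length(skipped))
    genome$excluded <- rbind(genome$excluded,
                             data.frame(gene_id = skipped,
                                        reason = "infeasible targets",
                                        stringsAsFactors = FALSE))
  genome
}

#' Convenience wrapper: random synthetic genome
#'
#' @param n_genes Number of genes.
#' @param gene_length Coding length per gene in bp (recycled).
#' @param motif IUPAC motif.
#' @param n_potential,n_real Per-gene targets (recycled across genes).
#' @param seed Integer seed.
#' @param ... Passed to [resample_genome_like()].
#' @return A `motif_genome`.
#' @export
synthetic_genome <- function(n_genes, gene_length = 900L, motif = "GATC",
                             n_potential = 8L, n_real = 2L, seed = NULL, ...) {
  ref <- data.frame(gene_id = sprintf("sg%03d", seq_len(n_genes)),
                    n_potential = rep_len(n_potential, n_genes),
                    n_real = rep_len(n_real, n_genes),
                    length = rep_len(gene_length, n_genes),
                    stringsAsFactors = FALSE)
  resample_genome_like(ref, motif, seed = seed, ...)
}

#' Redraw the codons of a gene under the table's conditional frequencies
#'
#' Each codon is redrawn from `f(codon | amino acid)` (literal translation),
#' giving one draw from the codon-redundancy null for that gene.
#'
#' @param nucleotides In-frame coding sequence.
#' @param table Codon table supplying the conditional frequencies (uniform
#'   table gives uniform synonymous draws).
#' @param table_id NCBI translation table.
#' @return Resampled nucleotide string of the same length and peptide.
#' @export
resample_gene_codons <- function(nucleotides, table, table_id = "11") {
  gc <- genetic_code(table_id)
  cods <- codon_split(nucleotides)
  aas <- gc[cods]
  rev_code <- codons_for(table_id)
  new_cods <- vapply(aas, function(a) {
    opts <- rev_code[[a]]
    if (length(opts) == 1L) return(opts)
    w <- table_weights(table, opts, 1L)
    if (sum(w) == 0) w <- rep(1, length(opts))
    sample(opts, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  paste(new_cods, collapse = "")
}

#' Null distribution of the merged z under codon resampling
#'
#' Repeatedly redraws the codons of a gene set under the table's conditional
#' frequencies, recounts realized motifs over the (unchanged) potential
#' windows, and returns the merged z per replicate. Used to check that z is
#' calibrated (mean ~ 0, variance ~ 1) under the null.
#'
#' @param cds CDS data.frame (gene set).
#' @param motif IUPAC motif.
#' @param table Codon table used both for window probabilities and resampling.
#' @param n_replicates Number of resampling replicates.
#' @param seed Integer seed.
#' @param table_id NCBI translation table.
#' @return Numeric vector of `n_replicates` merged z values.
#' @export
null_z_distribution <- function(cds, motif, table, n_replicates = 2000L,
                                seed = NULL, table_id = "11") {
  if (!is.null(seed)) set.seed(seed)
  motif <- toupper(motif)
  idx <- motif_index(motif, table, table_id)
  wl <- lapply(cds$nucleotides, potential_windows, index = idx)
  probs <- unlist(lapply(wl, `[[`, "probability"), use.names = FALSE)
  mom <- poisson_binomial_summary(probs)
  l <- nchar(motif)
  rx <- paste0("^", iupac_regex(motif), "$")
  gc <- genetic_code(table_id)
  rev_code <- codons_for(table_id)
  m_rep <- integer(n_replicates)
  for (i in seq_along(wl)) {
    w <- wl[[i]]
    if (!nrow(w)) next
    cods <- codon_split(cds$nucleotides[i])
    aas <- gc[cods]
    n <- length(cods)
    # draw all replicate codons at once, grouped by amino acid
    mat <- matrix(NA_character_, nrow = n, ncol = n_replicates)
    for (a in unique(aas)) {
      pos <- which(aas == a)
      opts <- rev_code[[a]]
      if (length(opts) == 1L) { mat[pos, ] <- opts; next }
      wt <- table_weights(table, opts, 1L)
      if (sum(wt) == 0) wt <- rep(1, length(opts))
      mat[pos, ] <- sample(opts, length(pos) * n_replicates,
                           replace = TRUE, prob = wt)
    }
    for (j in seq_len(nrow(w))) {
      cstart <- w$nt_offset[j] %/% 3L + 1L
      p <- w$nt_offset[j] %% 3L
      rng <- cstart:(cstart + w$span[j] - 1L)
      enc <- peptide_encodings(w$peptide_window[j], table_id)
      realizing <- enc[grepl(rx, substr(enc, p + 1L, p + l))]
      strs <- if (length(rng) == 1L) mat[rng, ]
              else do.call(paste0, lapply(rng, function(r) mat[r, ]))
      m_rep <- m_rep + (strs %in% realizing)
    }
  }
  vapply(m_rep, zscore, numeric(1), mean = mom[[1]], sd = mom[[2]])
}

#' Motif interdependence experiment on synthetic genomes
#'
#' Scaled-down reproduction of the tetramer interdependence study: synthetic
#' genomes carry one focal motif whose per-gene realization level varies over
#' a biologically plausible range while everything else is random. Every gene
#' is then scanned for all `4^k` k-mers, giving per-gene z-score pairs (focal
#' motif vs every other motif). The experiment compares the probability that
#' another motif is significant (|z| >= 2) conditional on the focal motif
#' being significantly enriched or depleted in that gene against the marginal
#' probability; under independence the two agree.
#'
#' @param motif1 Focal motif (default GATC).
#' @param k k-mer size for the sweep (default 4).
#' @param n_genomes Number of independent synthetic genomes.
#' @param genes_per_genome,gene_length Genome geometry.
#' @param n_potential Per-gene potential-site target for the focal motif.
#' @param enrichment_range Range of per-gene realization fractions
#'   `n_real/n_potential`, spread linearly across each genome's genes so the
#'   focal z spans depletion to enrichment within the biological range.
#' @param seed Integer seed.
#' @param table_id NCBI translation table.
#' @return List with `pairs` (data.frame genome, gene_id, motif2, z1, z2),
#'   `p_cond`, `p_marg`, their binomial standard errors, and pair counts
#'   `n_cond`, `n_marg`.
#' @export
interdependence_experiment <- function(motif1 = "GATC", k = 4L,
                                       n_genomes = 2L, genes_per_genome = 24L,
                                       gene_length = 600L, n_potential = 8L,
                                       enrichment_range = c(0, 1),
                                       seed = NULL, table_id = "11") {
  if (!is.null(seed)) set.seed(seed)
  motif1 <- toupper(motif1)
  fracs <- seq(enrichment_range[1], enrichment_range[2],
               length.out = genes_per_genome)
  kmers <- all_nt_strings(k)
  pair_rows <- vector("list", n_genomes)
  for (g in seq_len(n_genomes)) {
    n_real <- round(fracs * n_potential)
    ref <- data.frame(gene_id = sprintf("g%02d_%02d", g, seq_len(genes_per_genome)),
                      n_potential = n_potential, n_real = n_real,
                      length = gene_length, stringsAsFactors = FALSE)
    genome <- resample_genome_like(ref, motif1, replicon_id = sprintf("ig%02d", g))
    tab <- build_codon_table(genome, max_span = max(codon_span(k, 0:2)))
    zmat <- vapply(kmers, function(km) {
      idx <- motif_index(km, tab, table_id)
      vapply(genome$cds$nucleotides, function(nt) {
        w <- potential_windows(nt, index = idx)
        motif_profile(w$probability, sum(w$realized))$z
      }, numeric(1), USE.NAMES = FALSE)
    }, numeric(nrow(genome$cds)))
    z1 <- zmat[, motif1]
    others <- setdiff(kmers, motif1)
    pair_rows[[g]] <- data.frame(
      genome = g,
      gene_id = rep(genome$cds$gene_id, times = length(others)),
      motif2 = rep(others, each = nrow(genome$cds)),
      z1 = rep(z1, times = length(others)),
      z2 = as.vector(zmat[, others]),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  pairs <- pairs[is.finite(pairs$z1) & is.finite(pairs$z2), ]
  sig1 <- abs(pairs$z1) >= 2
  sig2 <- abs(pairs$z2) >= 2
  n_cond <- sum(sig1); n_marg <- nrow(pairs)
  p_cond <- if (n_cond) mean(sig2[sig1]) else NA_real_
  p_marg <- mean(sig2)
  se <- function(p, n) if (n > 0 && !is.na(p)) sqrt(max(p * (1 - p), 1e-12) / n) else NA_real_
  list(pairs = pairs, p_cond = p_cond, p_marg = p_marg,
       se_cond = se(p_cond, n_cond), se_marg = se(p_marg, n_marg),
       n_cond = n_cond, n_marg = n_marg)
}

#' Coupling of overlapping and competing motifs at extreme enrichment
#'
#' Generates a background genome with the focal motif at a natural
#' realization level and a set of extreme genes in which every potential site
#' is realized, then scores partner motifs over the extreme genes against the
#' background-derived codon table. Partner motifs overlapping the focal motif
#' (e.g. AGAT vs GATC) gain occurrences with it and couple positively;
#' partners competing for shared potential sites (e.g. AATC vs GATC) are
#' displaced and couple negatively.
#'
#' @param motif1 Focal motif.
#' @param partners Character vector of partner motifs to score.
#' @param n_background,n_extreme Gene counts for the two sets.
#' @param gene_length Coding length per gene (bp).
#' @param n_potential Potential sites per gene for `motif1`.
#' @param background_frac Realization fraction in the background set.
#' @param seed Integer seed.
#' @param table_id NCBI translation table.
#' @return data.frame: motif, n_windows, m, m_bar, z — merged over the
#'   extreme genes, `motif1` first.
#' @export
motif_coupling <- function(motif1 = "GATC", partners = c("AGAT", "AATC"),
                           n_background = 24L, n_extreme = 12L,
                           gene_length = 3000L, n_potential = 40L,
                           background_frac = 0.2, seed = NULL,
                           table_id = "11") {
  if (!is.null(seed)) set.seed(seed)
  motif1 <- toupper(motif1); partners <- toupper(partners)
  bg_ref <- data.frame(gene_id = sprintf("bg%03d", seq_len(n_background)),
                       n_potential = n_potential,
                       n_real = rbinom(n_background, n_potential, background_frac),
                       length = gene_length, stringsAsFactors = FALSE)
  bg <- resample_genome_like(bg_ref, motif1, replicon_id = "bg")
  ex_ref <- data.frame(gene_id = sprintf("ex%03d", seq_len(n_extreme)),
                       n_potential = n_potential, n_real = n_potential,
                       length = gene_length, stringsAsFactors = FALSE)
  ex <- resample_genome_like(ex_ref, motif1, replicon_id = "ex")
  max_span <- max(codon_span(max(nchar(c(motif1, partners))), 0:2))
  tab <- build_codon_table(bg, max_span = max_span)
  rows <- lapply(c(motif1, partners), function(mm) {
    idx <- motif_index(mm, tab, table_id)
    wl <- lapply(ex$cds$nucleotides, potential_windows, index = idx)
    probs <- unlist(lapply(wl, `[[`, "probability"), use.names = FALSE)
    m <- sum(vapply(wl, function(w) sum(w$realized), numeric(1)))
    prof <- motif_profile(probs, m, scope_id = mm)
    data.frame(motif = mm, n_windows = length(probs), m = prof$m,
               m_bar = prof$m_bar, z = prof$z, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
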