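# Reading FASTA + GFF3 genomes, CDS extraction and validation, and
# replication-context labelling (replichore, leading/lagging, ori/ter half).

#' Construct a replicon descriptor
#'
#' @param id Sequence identifier (must match the GFF3 seqid).
#' @param sequence Nucleotide string (uppercased internally).
#' @param topology `"circular"` or `"linear"`. Positional analyses (replichore,
#'   leading/lagging, ori/ter) require a circular replicon.
#' @param ori_position 0-based coordinate of the replication origin.
#' @param ter_position 0-based coordinate of the terminus; defaults to the
#'   point diametrically opposite the origin on circular replicons.
#' @return An object of class `replicon`.
#' @export
replicon <- function(id, sequence, topology = c("circular", "linear"),
                     ori_position = NULL, ter_position = NULL) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (!is.null(ori_position)) {
    if (ori_position < 0 || ori_position >= len)
      stop("ori_position outside sequence [0, ", len, ")")
    if (is.null(ter_position) && topology == "circular")
      ter_position <- (ori_position + len %/% 2L) %% len
  }
  structure(
    list(id = id, sequence = sequence, length = len, topology = topology,
         ori_position = ori_position, ter_position = ter_position),
    class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat("<replicon>", x$id, "-", x$length, "bp,", x$topology)
  if (!is.null(x$ori_position))
    cat(", ori =", x$ori_position, ", ter =", x$ter_position)
  cat("\n")
  invisible(x)
}

# circular distance between coordinates on a replicon of length L
circ_dist <- function(a, b, L) {
  d <- (a - b) %% L
  pmin(d, L - d)
}

#' Read a genome from FASTA + GFF3 and extract validated coding sequences
#'
#' CDS features are pulled from the GFF3, minus-strand features are
#' reverse-complemented so that `nucleotides` always reads 5'->3' on the coding
#' strand, and a terminal stop codon (if present) is trimmed before analysis.
#' CDSs failing validation (length not a multiple of 3, ambiguous nucleotides,
#' internal stop codons) are excluded and listed in the `excluded` report.
#'
#' Gene identifiers come from the `locus_tag` attribute, falling back to `ID`.
#' Coordinates are converted from GFF3 1-based closed to 0-based half-open.
#'
#' @param fasta_path Path to a nucleotide FASTA file.
#' @param gff_path Path to a GFF3 file with CDS features for that record.
#' @param ori_position,ter_position Replication origin/terminus (0-based bp);
#'   `ter_position` defaults to the point opposite `ori_position`.
#' @param replicon_id Which FASTA record to analyze when the file holds several
#'   replicons; default requires exactly one record.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param table_id NCBI translation table, default `"11"`.
#' @return A list of class `motif_genome` with elements `replicon`, `cds`
#'   (data.frame: gene_id, start, end, strand, nucleotides, peptide, midpoint)
#'   and `excluded` (data.frame: gene_id, reason).
#' @export
read_genome <- function(fasta_path, gff_path, ori_position = NULL,
                        ter_position = NULL, replicon_id = NULL,
                        topology = "circular", table_id = "11") {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(replicon_id)) {
    if (length(seqs) != 1L)
      stop("FASTA holds ", length(seqs), " records; give replicon_id")
    replicon_id <- names(seqs)[1]
  }
  if (!replicon_id %in% names(seqs))
    stop("replicon '", replicon_id, "' not in FASTA")
  seq <- toupper(as.character(seqs[[replicon_id]]))

  gff <- rtracklayer::import(gff_path)
  gff <- gff[gff$type == "CDS" & as.character(GenomicRanges::seqnames(gff)) == replicon_id]
  if (length(gff) == 0L)
    stop("no CDS features for seqid '", replicon_id, "' in ", gff_path)

  ids <- if (!is.null(gff$locus_tag)) as.character(gff$locus_tag) else rep(NA_character_, length(gff))
  fallback <- if (!is.null(gff$ID)) as.character(gff$ID) else rep(NA_character_, length(gff))
  ids[is.na(ids)] <- fallback[is.na(ids)]
  ids[is.na(ids)] <- paste0("cds_", seq_along(gff))[is.na(ids)]

  rep_obj <- replicon(replicon_id, seq, topology = topology,
                      ori_position = ori_position, ter_position = ter_position)
  start0 <- GenomicRanges::start(gff) - 1L
  end0 <- GenomicRanges::end(gff)
  strand <- as.character(GenomicRanges::strand(gff))
  strand[!strand %in% c("+", "-")] <- "+"
  build_cds_set(rep_obj, ids, start0, end0, strand, table_id = table_id)
}

# Core CDS extraction + validation shared by read_genome() and the synthetic
# genome assembler. start/end are 0-based half-open on the forward strand;
# end may exceed the replicon length for genes wrapping the coordinate origin
# of a circular replicon.
build_cds_set <- function(rep_obj, ids, start0, end0, strand, table_id = "11") {
  L <- rep_obj$length
  ord <- order(start0, end0)
  ids <- ids[ord]; start0 <- start0[ord]; end0 <- end0[ord]; strand <- strand[ord]

  keep <- logical(length(ids))
  reason <- character(length(ids))
  nts <- peps <- character(length(ids))
  gc <- genetic_code(table_id)
  stops <- names(gc)[gc == "*"]

  for (i in seq_along(ids)) {
    s <- start0[i]; e <- end0[i]
    if (s < 0 || e <= s || (rep_obj$topology == "linear" && e > L) || e > 2L * L) {
      reason[i] <- "coordinates outside replicon"; next
    }
    nt <- if (e <= L) substr(rep_obj$sequence, s + 1L, e) else
      paste0(substr(rep_obj$sequence, s + 1L, L), substr(rep_obj$sequence, 1L, e - L))
    if (strand[i] == "-") nt <- revcomp_nt(nt)
    if (nchar(nt) %% 3L != 0L) { reason[i] <- "length not multiple of 3"; next }
    if (grepl("[^ACGT]", nt)) { reason[i] <- "ambiguous nucleotide"; next }
    cods <- codon_split(nt)
    if (cods[length(cods)] %in% stops) cods <- cods[-length(cods)]
    if (length(cods) == 0L) { reason[i] <- "empty after stop trimming"; next }
    aa <- gc[cods]
    if (any(aa == "*")) { reason[i] <- "internal stop codon"; next }
    if (cods[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
    keep[i] <- TRUE
    nts[i] <- paste(cods, collapse = "")
    peps[i] <- paste(aa, collapse = "")
  }

  mid <- ((start0 + end0) %/% 2L) %% L
  cds <- data.frame(
    gene_id = ids[keep], start = start0[keep], end = end0[keep],
    strand = strand[keep], nucleotides = nts[keep], peptide = peps[keep],
    midpoint = mid[keep], stringsAsFactors = FALSE)
  excluded <- data.frame(gene_id = ids[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  structure(list(replicon = rep_obj, cds = cds, excluded = excluded),
            class = "motif_genome")
}

#' @export
print.motif_genome <- function(x, ...) {
  print(x$replicon)
  cat("  ", nrow(x$cds), "validated CDS,", nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Assign replication context to every retained gene
#'
#' Each gene (by midpoint) is labelled with its replichore (`right` = the arc
#' from ori to ter in ascending circular coordinates, `left` = the other arm),
#' its strand class (`leading` iff coding strand is `+` on the right replichore
#' or `-` on the left), and its chromosome half (`ori` if the circular distance
#' of the midpoint to ori is <= its distance to ter, else `ter`).
#'
#' @param genome A `motif_genome` from [read_genome()] (circular, with ori set).
#' @return data.frame: gene_id, replichore, strand_class, half.
#' @export
assign_replication_context <- function(genome) {
  rep_obj <- genome$replicon
  if (rep_obj$topology != "circular")
    stop("replication context requires a circular replicon; '", rep_obj$id,
         "' is linear (leading/lagging, replichore and ori/ter analyses are undefined)")
  if (is.null(rep_obj$ori_position))
    stop("replication context requires an ori_position on replicon '", rep_obj$id, "'")
  L <- rep_obj$length
  ori <- rep_obj$ori_position
  ter <- rep_obj$ter_position
  mid <- genome$cds$midpoint
  right_len <- (ter - ori) %% L
  replichore <- ifelse((mid - ori) %% L < right_len, "right", "left")
  strand_class <- ifelse(
    (replichore == "right" & genome$cds$strand == "+") |
      (replichore == "left" & genome$cds$strand == "-"),
    "leading", "lagging")
  half <- ifelse(circ_dist(mid, ori, L) <= circ_dist(mid, ter, L), "ori", "ter")
  data.frame(gene_id = genome$cds$gene_id, replichore = replichore,
             strand_class = strand_class, half = half, stringsAsFactors = FALSE)
}

#' Write a genome back to FASTA + GFF3
#'
#' Inverse of [read_genome()] for synthetic genomes: coordinates are converted
#' to GFF3 1-based closed, gene ids stored as `locus_tag` and `ID`.
#'
#' @param genome A `motif_genome`.
#' @param fasta_path,gff_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(genome$replicon$sequence)
  names(seqs) <- genome$replicon$id
  Biostrings::writeXStringSet(seqs, fasta_path)
  cds <- genome$cds
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$replicon$id, genome$replicon$length),
             sprintf("%s\tcodonmotif\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
                     genome$replicon$id, cds$start + 1L, cds$end, cds$strand,
                     cds$gene_id, cds$gene_id))
  writeLines(lines, gff_path)
  invisible(c(fasta = fasta_path, gff = gff_path))
}

#' Write the CDS validation report as TSV
#'
#' @param genome A `motif_genome`.
#' @param path Output TSV path (columns gene_id, reason).
#' @export
write_validation_report <- function(genome, path) {
  write.table(genome$excluded, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
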