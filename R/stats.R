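# Poisson-binomial moments, the z statistic, and the five Monte-Carlo bias
# tests (leading/lagging, coding/template, ori/ter, replichore, subset).

#' Mean and standard deviation of a Poisson-binomial count
#'
#' The motif count over potential windows is a sum of independent Bernoulli
#' trials with unequal probabilities: mean = sum(P), sd = sqrt(sum(P * (1-P))).
#'
#' @param probabilities Numeric vector of probabilities in \[0, 1\].
#' @return Numeric vector `c(mean, sd)`; `c(0, 0)` for an empty list.
#' @export
poisson_binomial_summary <- function(probabilities) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  c(mean = sum(probabilities),
    sd = sqrt(sum(probabilities * (1 - probabilities))))
}

#' Motif z-score
#'
#' `z = (m - mean) / sd`. When `sd == 0`: 0 if the observation equals the
#' expectation, otherwise a signed infinity (an undefined-extreme deviation,
#' kept distinguishable from a genuine 0).
#'
#' @param m Observed count.
#' @param mean,sd Poisson-binomial moments.
#' @return The z-score.
#' @export
zscore <- function(m, mean, sd) {
  stopifnot(sd >= 0)
  if (sd == 0) {
    if (m == mean) return(0)
    return(sign(m - mean) * Inf)
  }
  (m - mean) / sd
}

#' Per-gene z table for bias testing
#'
#' Computes coding- and template-strand z per gene plus the replication
#' context, the input shape the bias tests consume.
#'
#' @inheritParams genome_profiles
#' @return data.frame: gene_id, strand, replichore, strand_class, half,
#'   z_coding, z_template, midpoint.
#' @export
gene_z_table <- function(genome, motif, table, context = NULL, table_id = "11") {
  if (is.null(context)) context <- assign_replication_context(genome)
  gp <- genome_profiles(genome, motif, table,
                        strand_modes = c("coding", "template"),
                        context = context, table_id = table_id)
  tab <- gp$table
  zc <- tab$z[tab$strand_mode == "coding"]
  zt <- tab$z[tab$strand_mode == "template"]
  cds <- genome$cds
  data.frame(gene_id = cds$gene_id, strand = cds$strand,
             replichore = context$replichore, strand_class = context$strand_class,
             half = context$half, z_coding = zc, z_template = zt,
             midpoint = cds$midpoint, stringsAsFactors = FALSE)
}

#' Monte-Carlo bias test for chromosome-scale motif asymmetries
#'
#' The observed statistic is the mean z difference between two gene classes:
#' * `leading_lagging` — per-gene difference between the z on the gene's
#'   leading strand and on its lagging strand, averaged over genes; the null
#'   randomizes gene orientations (each flip swaps the two values).
#' * `coding_template` — as above with coding vs template strand.
#' * `ori_ter` — mean coding-strand z of ori-half genes minus ter-half genes;
#'   null permutes the half labels.
#' * `replichore` — left minus right replichore, label permutation null.
#' * `subset` — genes in a supplied subset minus all other genes; null draws
#'   random size-matched subsets without replacement.
#'
#' The bias z-score is `(observed - null_mean) / null_sd` over `n_replicates`
#' randomizations. Genes lacking a finite z in either quantity are dropped
#' (complete-case).
#'
#' @param gene_z A [gene_z_table()] data.frame.
#' @param bias_kind One of `"leading_lagging"`, `"coding_template"`,
#'   `"ori_ter"`, `"replichore"`, `"subset"`.
#' @param n_replicates Number of Monte-Carlo randomizations (default 10000).
#' @param seed Integer seed recorded in the result; `NULL` leaves the RNG state
#'   untouched.
#' @param subset_ids Gene ids of the subset (for `bias_kind = "subset"`).
#' @return Object of class `bias_result`: bias_kind, observed, null_mean,
#'   null_sd, z_bias, n_replicates, seed, n_genes.
#' @export
bias_test <- function(gene_z, bias_kind = c("leading_lagging", "coding_template",
                                            "ori_ter", "replichore", "subset"),
                      n_replicates = 10000L, seed = NULL, subset_ids = NULL) {
  bias_kind <- match.arg(bias_kind)
  if (!is.null(seed)) set.seed(seed)

  if (bias_kind %in% c("leading_lagging", "coding_template")) {
    d <- if (bias_kind == "coding_template") {
      gene_z$z_coding - gene_z$z_template
    } else {
      ifelse(gene_z$strand_class == "leading",
             gene_z$z_coding - gene_z$z_template,
             gene_z$z_template - gene_z$z_coding)
    }
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2L) stop("fewer than 2 genes with finite z for ", bias_kind)
    observed <- mean(d)
    # orientation flip negates each gene's contribution
    signs <- matrix(sample(c(-1, 1), n * n_replicates, replace = TRUE),
                    nrow = n)
    null_stats <- as.vector(crossprod(d, signs)) / n
  } else {
    if (bias_kind == "ori_ter") {
      lab <- gene_z$half == "ori"
    } else if (bias_kind == "replichore") {
      lab <- gene_z$replichore == "left"
    } else {
      if (is.null(subset_ids)) stop("subset bias needs subset_ids")
      lab <- gene_z$gene_id %in% subset_ids
    }
    z <- gene_z$z_coding
    ok <- is.finite(z)
    z <- z[ok]; lab <- lab[ok]
    n <- length(z); nA <- sum(lab)
    if (nA < 2L || n - nA < 2L)
      stop("fewer than 2 genes in a class for ", bias_kind)
    observed <- mean(z[lab]) - mean(z[!lab])
    S <- sum(z)
    sumA <- vapply(seq_len(n_replicates),
                   function(r) sum(z[sample.int(n, nA)]), numeric(1))
    null_stats <- sumA / nA - (S - sumA) / (n - nA)
  }

  null_mean <- mean(null_stats)
  null_sd <- sd(null_stats)
  structure(list(bias_kind = bias_kind, observed = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 z_bias = (observed - null_mean) / null_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 n_genes = n),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result> %s: observed = %.4f, null = %.4f +/- %.4f, z_bias = %.2f (%d replicates, %d genes)\n",
              x$bias_kind, x$observed, x$null_mean, x$null_sd, x$z_bias,
              x$n_replicates, x$n_genes))
  invisible(x)
}

#' Bias report for several bias kinds
#'
#' @inheritParams bias_test
#' @param bias_kinds Character vector of bias kinds to run.
#' @return data.frame: bias_kind, observed, null_mean, null_sd, z_bias,
#'   n_replicates, seed.
#' @export
bias_report <- function(gene_z, bias_kinds = c("leading_lagging", "coding_template",
                                               "ori_ter", "replichore"),
                        n_replicates = 10000L, seed = NULL, subset_ids = NULL) {
  rows <- lapply(seq_along(bias_kinds), function(i) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    b <- bias_test(gene_z, bias_kinds[i], n_replicates = n_replicates,
                   seed = s, subset_ids = subset_ids)
    data.frame(bias_kind = b$bias_kind, observed = b$observed,
               null_mean = b$null_mean, null_sd = b$null_sd,
               z_bias = b$z_bias, n_replicates = b$n_replicates,
               seed = b$seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
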