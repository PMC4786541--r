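# Chromosome-wide sliding-window z-score rings, multi-genome scaled averaging,
# and their plots.

#' Sliding-window z-score rings over a circular replicon
#'
#' For each window size a ring of overlapping circular windows is laid out;
#' each window's z is the merged-set z over all genes whose midpoint falls in
#' it (merging is additive in m, sum(P) and sum(P(1-P))). Default ring sizes
#' follow the standard layout of 50 to 500 kb in 50 kb steps (10 rings,
#' outside-in by decreasing granularity).
#'
#' @param genome A `motif_genome` with a circular replicon.
#' @param profiles List of per-gene [motif_profile()]s in `genome$cds` order
#'   (one strand mode), e.g. `genome_profiles(...)$profiles$coding`.
#' @param window_sizes Window sizes in bp; each must not exceed the replicon.
#' @param step Center spacing in bp; default `window_size / 10` per ring.
#' @return data.frame of class `window_rings`: window_size, center, n_genes,
#'   m, m_bar, z.
#' @export
sliding_window_rings <- function(genome, profiles,
                                 window_sizes = seq(50e3, 500e3, by = 50e3),
                                 step = NULL) {
  L <- genome$replicon$length
  if (genome$replicon$topology != "circular")
    stop("sliding-window rings require a circular replicon")
  if (any(window_sizes > L))
    stop("window size exceeds replicon length (", L, " bp)")
  mid <- genome$cds$midpoint
  m_g <- vapply(profiles, `[[`, integer(1), "m")
  mb_g <- vapply(profiles, `[[`, numeric(1), "m_bar")
  v_g <- vapply(profiles, function(p) sum(p$probabilities * (1 - p$probabilities)),
                numeric(1))
  nw_g <- vapply(profiles, function(p) length(p$probabilities), integer(1))

  rings <- lapply(window_sizes, function(w) {
    st <- if (is.null(step)) max(1, round(w / 10)) else step
    centers <- seq(0, L - 1, by = st)
    rows <- lapply(centers, function(ctr) {
      inw <- circ_dist(mid, ctr, L) <= w / 2
      m <- sum(m_g[inw]); mb <- sum(mb_g[inw]); v <- sum(v_g[inw])
      z <- if (sum(nw_g[inw]) == 0L) NA_real_ else zscore(m, mb, sqrt(v))
      data.frame(window_size = w, center = ctr, n_genes = sum(inw),
                 m = m, m_bar = mb, z = z)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, rings)
  rownames(out) <- NULL
  class(out) <- c("window_rings", "data.frame")
  out
}

#' Scale per-gene z profiles of several genomes onto a common ori-anchored axis
#'
#' Gene positions are mapped to `floor(n_bins * ((midpoint - ori) %% L) / L)`,
#' so the replication origin sits at bin 0/`n_bins` regardless of chromosome
#' size or the arbitrary coordinate start. Per genome each bin is averaged,
#' then the mean and SEM across genomes are reported per bin.
#'
#' @param gene_z_tables List of per-genome data.frames with columns `midpoint`
#'   and `z` (e.g. subsets of [gene_z_table()] output).
#' @param ori_positions,lengths Numeric vectors, one ori (bp) and one
#'   chromosome length (bp) per genome.
#' @param n_bins Number of scaled bins (default 1000).
#' @return data.frame of class `scaled_profile`: bin (0-based), mean_z, sem,
#'   n_genomes (genomes contributing to the bin).
#' @export
scale_and_average <- function(gene_z_tables, ori_positions, lengths,
                              n_bins = 1000L) {
  stopifnot(length(gene_z_tables) == length(ori_positions),
            length(gene_z_tables) == length(lengths),
            length(gene_z_tables) >= 1L)
  per_genome <- lapply(seq_along(gene_z_tables), function(g) {
    tab <- gene_z_tables[[g]]
    L <- lengths[g]; ori <- ori_positions[g]
    z <- tab$z
    ok <- is.finite(z)
    bin <- floor(n_bins * ((tab$midpoint[ok] - ori) %% L) / L)
    bin[bin == n_bins] <- n_bins - 1L
    vapply(0:(n_bins - 1L), function(b) {
      zz <- z[ok][bin == b]
      if (length(zz)) mean(zz) else NA_real_
    }, numeric(1))
  })
  mat <- do.call(cbind, per_genome)
  n_gen <- rowSums(!is.na(mat))
  mean_z <- ifelse(n_gen > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_len(n_bins), function(i) {
    v <- mat[i, !is.na(mat[i, ])]
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  }, numeric(1))
  sem[n_gen == 0] <- NA_real_
  out <- data.frame(bin = 0:(n_bins - 1L), mean_z = mean_z, sem = sem,
                    n_genomes = n_gen)
  class(out) <- c("scaled_profile", "data.frame")
  out
}

#' Render sliding-window rings as a circular plot
#'
#' Rings are drawn outside-in by decreasing window granularity, z color-coded
#' on a diverging scale saturating red at `z >= highlight_threshold` and blue
#' at `z <= -highlight_threshold`.
#'
#' @param rings A [sliding_window_rings()] result.
#' @param highlight_threshold Saturation threshold (default 2, the usual
#'   significance convention).
#' @param gene_positions Optional numeric vector of gene midpoints to overlay
#'   as ticks on the outermost ring.
#' @return A ggplot object.
#' @export
render_rings <- function(rings, highlight_threshold = 2, gene_positions = NULL) {
  df <- as.data.frame(rings)
  sizes <- sort(unique(df$window_size))
  # smallest window outermost (highest granularity outside)
  df$ring <- length(sizes) - match(df$window_size, sizes) + 1L
  thr <- highlight_threshold
  df$z_clip <- pmax(pmin(df$z, thr), -thr)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$ring,
                                        fill = .data$z_clip)) +
    ggplot2::geom_tile(height = 0.9) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95", high = "red",
                                  midpoint = 0, limits = c(-thr, thr),
                                  name = "z") +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::ylim(0, length(sizes) + 1) +
    ggplot2::theme_void()
  if (!is.null(gene_positions)) {
    gp <- data.frame(x = gene_positions, y = length(sizes) + 0.7)
    p <- p + ggplot2::geom_point(data = gp,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE, size = 0.3)
  }
  p
}

#' Plot a scaled multi-genome profile with its SEM band
#'
#' @param x A [scale_and_average()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.scaled_profile <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$mean_z), , drop = FALSE]   # bins without genes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_z)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_z - .data$sem,
                                      ymax = .data$mean_z + .data$sem),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "scaled position (ori at 0/max)", y = "mean z") +
    ggplot2::theme_minimal()
}
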