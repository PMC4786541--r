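test_that("a window covering the whole replicon reproduces the genome-wide z", {
  gen <- fixture_genome()
  tab <- fixture_table()
  gp <- genome_profiles(gen, "GATC", tab)
  L <- gen$replicon$length
  rings <- sliding_window_rings(gen, gp$profiles$coding,
                                window_sizes = L, step = L)
  whole <- merge_profiles(gp$profiles$coding)
  expect_equal(rings$z[1], whole$z)
  expect_equal(rings$n_genes[1], nrow(gen$cds))
})

test_that("default ring layout has 10 rings from 50 to 500 kb", {
  gen <- fixture_genome()
  gp <- genome_profiles(gen, "GATC", fixture_table())
  # same gene content embedded on a replicon large enough for the default layout
  big <- gen
  big$replicon$length <- 600000L
  rings <- sliding_window_rings(big, gp$profiles$coding)
  expect_equal(sort(unique(rings$window_size)), seq(50e3, 500e3, by = 50e3))
  expect_equal(length(unique(rings$window_size)), 10)
  # oversized window on the true replicon is refused
  expect_error(sliding_window_rings(gen, gp$profiles$coding,
                                    window_sizes = 10 * gen$replicon$length),
               "exceeds")
})

test_that("the max-|z| window centers on a planted enriched arc", {
  gen <- fixture_planted_bias()          # first half of the replicon enriched
  tab <- build_codon_table(gen, max_span = 2)
  gp <- genome_profiles(gen, "GGAT", tab)
  L <- gen$replicon$length
  rings <- sliding_window_rings(gen, gp$profiles$coding,
                                window_sizes = round(L / 4), step = 200)
  best <- rings$center[which.max(rings$z)]
  # enriched genes occupy the first half: the hottest window sits inside it
  expect_true(best < L / 2 || best > L - L / 8)
  expect_gt(max(rings$z, na.rm = TRUE), 2)
})

test_that("window z values are invariant to gene ordering", {
  gen <- fixture_genome()
  gp <- genome_profiles(gen, "GATC", fixture_table())
  L <- gen$replicon$length
  r1 <- sliding_window_rings(gen, gp$profiles$coding,
                             window_sizes = round(L / 3), step = 500)
  set.seed(4)
  perm <- sample(nrow(gen$cds))
  gen2 <- gen
  gen2$cds <- gen$cds[perm, ]
  r2 <- sliding_window_rings(gen2, gp$profiles$coding[perm],
                             window_sizes = round(L / 3), step = 500)
  expect_equal(r1$z, r2$z)
})

test_that("scaled averaging anchors at ori and averages across genomes", {
  # single genome: scaled copy of itself with zero SEM
  t1 <- data.frame(midpoint = c(1000, 30000, 60000), z = c(1, -2, 0.5))
  p1 <- scale_and_average(list(t1), ori_positions = 0, lengths = 100000)
  expect_equal(p1$mean_z[p1$bin == 10], 1)
  expect_equal(p1$mean_z[p1$bin == 300], -2)
  expect_true(all(p1$sem[p1$n_genomes > 0] == 0))
  # two identical genomes: mean unchanged, SEM 0
  p2 <- scale_and_average(list(t1, t1), c(0, 0), c(100000, 100000))
  expect_equal(p2$mean_z, p1$mean_z)
  expect_true(all(p2$sem[p2$n_genomes > 0] == 0))
})

test_that("rotating genome coordinates leaves the ori-anchored profile unchanged", {
  set.seed(12)
  L <- 200000
  mids <- sort(sample(0:(L - 1), 80))
  z <- rnorm(80)
  shift <- 73211
  t1 <- data.frame(midpoint = mids, z = z)
  t2 <- data.frame(midpoint = (mids + shift) %% L, z = z)
  p1 <- scale_and_average(list(t1), 10000, L)
  p2 <- scale_and_average(list(t2), (10000 + shift) %% L, L)
  expect_equal(p1$mean_z, p2$mean_z)
})

test_that("bumps planted at one third of each replichore average to bins ~333/667", {
  L <- 1e6
  mk <- function(noise_seed) {
    set.seed(noise_seed)
    mids <- seq(0, L - 1, by = 1000)
    d <- pmin(abs(mids - L / 3), abs(mids - 2 * L / 3))
    z <- 3 * exp(-(d / 40000)^2) + rnorm(length(mids), sd = 0.3)
    data.frame(midpoint = mids, z = z)
  }
  prof <- scale_and_average(list(mk(1), mk(2), mk(3)),
                            ori_positions = c(0, 0, 0), lengths = rep(L, 3))
  peaks <- order(prof$mean_z, decreasing = TRUE)[1:40]
  expect_true(any(abs(prof$bin[peaks] - 333) < 30))
  expect_true(any(abs(prof$bin[peaks] - 667) < 30))
  expect_true(all(abs(prof$bin[peaks] - 333) < 60 |
                  abs(prof$bin[peaks] - 667) < 60))
})

test_that("ring and profile plots build", {
  gen <- fixture_genome()
  gp <- genome_profiles(gen, "GATC", fixture_table())
  L <- gen$replicon$length
  rings <- sliding_window_rings(gen, gp$profiles$coding,
                                window_sizes = c(round(L / 4), round(L / 2)),
                                step = 1000)
  p <- render_rings(rings, gene_positions = gen$cds$midpoint)
  expect_s3_class(p, "ggplot")
  t1 <- data.frame(midpoint = c(1000, 30000), z = c(1, -1))
  prof <- scale_and_average(list(t1), 0, 100000)
  expect_s3_class(plot(prof), "ggplot")
})
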