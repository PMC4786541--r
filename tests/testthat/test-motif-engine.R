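test_that("observed counts match the worked example and a naive scan", {
  u <- uniform_codon_table(2)
  nt <- "ATGAGATCCAAA"   # M R S K
  expect_equal(observed_count(nt, "GATC", u), 1)
  # GATC is palindromic: template search finds the same occurrence
  expect_equal(observed_count(nt, "GATC", u, strand_mode = "template"), 1)
  # tandem overlapping occurrences, counted once per (position, offset) window
  gen <- fixture_genome()
  tab <- fixture_table()
  for (i in seq_len(nrow(gen$cds))) {
    nt <- gen$cds$nucleotides[i]
    expect_equal(observed_count(nt, "GATC", tab),
                 sum(oracle_window_scan(nt, "GATC", tab)$realized))
  }
})

test_that("gene profiles carry Poisson-binomial moments and guard degenerate cases", {
  u <- uniform_codon_table(2)
  # all windows certain and realized: s = 0 and m = m_bar, z reported as 0
  prof <- gene_profile("ATGTGGTGG", "TGG", u, gene_id = "w")
  expect_equal(prof$m_bar, prof$m)
  expect_equal(prof$s, 0)
  expect_equal(prof$z, 0)
  # window-less gene: z is missing, never 0
  prof0 <- gene_profile(paste0("ATG", strrep("AAA", 10)), "GATC", u)
  expect_equal(length(prof0$probabilities), 0)
  expect_true(is.na(prof0$z))
  # moments equal spreadsheet arithmetic on the window list
  gen <- fixture_genome()
  tab <- fixture_table()
  w <- potential_windows(gen$cds$nucleotides[1], "GATC", tab)
  prof1 <- gene_profile(gen$cds$nucleotides[1], "GATC", tab)
  expect_equal(prof1$m_bar, sum(w$probability))
  expect_equal(prof1$s, sqrt(sum(w$probability * (1 - w$probability))))
  expect_equal(prof1$z, (sum(w$realized) - prof1$m_bar) / prof1$s)
})

test_that("palindromic motifs give identical coding and template z per gene", {
  gen <- fixture_genome()
  tab <- fixture_table()
  gp <- genome_profiles(gen, "GATC", tab,
                        strand_modes = c("coding", "template"))
  zc <- gp$table$z[gp$table$strand_mode == "coding"]
  zt <- gp$table$z[gp$table$strand_mode == "template"]
  expect_equal(zc, zt)
})

test_that("template z of a motif equals coding z of its reverse complement", {
  gen <- fixture_genome()
  tab <- fixture_table()
  for (m in c("GGAT", "GACT")) {
    for (i in 1:5) {
      nt <- gen$cds$nucleotides[i]
      p_t <- gene_profile(nt, m, tab, strand_mode = "template")
      p_c <- gene_profile(nt, revcomp_motif(m), tab, strand_mode = "coding")
      expect_equal(p_t$z, p_c$z)
      expect_equal(p_t$m, p_c$m)
    }
  }
})

test_that("merging profiles is additive and equals recomputation from scratch", {
  gen <- fixture_genome()
  tab <- fixture_table()
  idx <- motif_index("GATC", tab)
  profs <- lapply(seq_len(nrow(gen$cds)), function(i)
    gene_profile(gen$cds$nucleotides[i], "GATC", tab, index = idx,
                 gene_id = gen$cds$gene_id[i]))
  # identity
  one <- merge_profiles(profs[1])
  expect_equal(one$z, profs[[1]]$z)
  # additivity of m_bar and s^2
  two <- merge_profiles(profs[1:2])
  expect_equal(two$m_bar, profs[[1]]$m_bar + profs[[2]]$m_bar)
  expect_equal(two$s^2, profs[[1]]$s^2 + profs[[2]]$s^2)
  # merged z equals z computed on the concatenated window list
  all10 <- merge_profiles(profs[1:10])
  wl <- lapply(1:10, function(i)
    potential_windows(gen$cds$nucleotides[i], index = idx))
  probs <- unlist(lapply(wl, `[[`, "probability"))
  m <- sum(unlist(lapply(wl, `[[`, "realized")))
  expect_equal(all10$m, m)
  expect_equal(all10$z,
               (m - sum(probs)) / sqrt(sum(probs * (1 - probs))))
  # mixing strand modes is refused
  tmpl <- gene_profile(gen$cds$nucleotides[1], "GGAT", tab,
                       strand_mode = "template")
  expect_error(merge_profiles(list(profs[[1]], tmpl)), "strand modes")
})

test_that("k-mer sweep covers the space and recovers a planted enrichment", {
  gen <- fixture_genome()
  tab <- fixture_table()
  s1 <- kmer_sweep(gen$cds[1:3, ], 1, tab)
  expect_equal(nrow(s1), 4)
  expect_setequal(s1$motif, c("A", "C", "G", "T"))
  # gene set with GATC saturated: GATC must rank first of the 256 tetramers
  enr <- resample_genome_like(
    data.frame(gene_id = sprintf("e%02d", 1:6), n_potential = 10L,
               n_real = 10L, length = 600L),
    "GATC", seed = 55)
  combined <- rbind(gen$cds, enr$cds)
  tab2 <- build_codon_table(combined, max_span = 2)
  sw <- kmer_sweep(enr$cds, 4, tab2)
  expect_equal(sw$motif[1], "GATC")
})
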