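test_that("codon span follows the motif-length rule at every offset", {
  # l mod 3 == 1: single span floor(l/3)+1
  expect_equal(codon_span(4, 0:2), c(2, 2, 2))
  expect_equal(codon_span(1, 0:2), c(1, 1, 1))
  # l mod 3 == 0: spans {floor(l/3), floor(l/3)+1}
  expect_equal(codon_span(3, 0:2), c(1, 2, 2))
  expect_equal(sort(unique(codon_span(6, 0:2))), c(2, 3))
  # l mod 3 == 2: spans {floor(l/3)+1, floor(l/3)+2}
  expect_equal(codon_span(8, 0), 3)
  expect_equal(codon_span(8, 2), 4)
  expect_equal(sort(unique(codon_span(8, 0:2))), c(3, 4))
  # general rule check across lengths: observed span set matches the branch
  for (l in 1:9) {
    spans <- unique(codon_span(l, 0:2))
    expected <- switch(as.character(l %% 3),
                       "0" = c(l %/% 3, l %/% 3 + 1),
                       "1" = l %/% 3 + 1,
                       "2" = c(l %/% 3 + 1, l %/% 3 + 2))
    expect_setequal(spans, expected)
  }
})

test_that("codon n-gram table counts in-frame grams within genes only", {
  # single CDS ATG GAT (stop already trimmed upstream)
  tab <- build_codon_table("ATGGAT", max_span = 2)
  expect_equal(tab$counts[[1]], c(ATG = 1, GAT = 1))
  expect_equal(tab$counts[[2]], c(ATGGAT = 1))
  # two identical CDSs double every count
  tab2 <- build_codon_table(c("ATGGAT", "ATGGAT"), max_span = 2)
  expect_equal(tab2$counts[[1]], 2 * tab$counts[[1]])
  expect_equal(tab2$counts[[2]], 2 * tab$counts[[2]])
  # totals across a random fixture equal sum(len_i/3 - k + 1)
  gen <- fixture_genome()
  tabg <- build_codon_table(gen, max_span = 2)
  ncod <- nchar(gen$cds$nucleotides) / 3
  expect_equal(sum(tabg$counts[[1]]), sum(ncod))
  expect_equal(sum(tabg$counts[[2]]), sum(ncod - 1))
})

test_that("uniform-table realization probabilities match hand enumeration", {
  u <- uniform_codon_table(2)
  # Trp has the single codon TGG: motif TGG is forced
  expect_equal(motif_probability("W", 0, "TGG", u), 1)
  # Arg-Ser admits GATC at p=1 through 2 x 4 of the 36 codon pairs
  expect_equal(motif_probability("RS", 1, "GATC", u), 8 / 36)
  # Lys-Lys can never spell GATC
  expect_equal(motif_probability("KK", 0, "GATC", u), 0)
  expect_equal(motif_probability("KK", 1, "GATC", u), 0)
  expect_equal(motif_probability("KK", 2, "GATC", u), 0)
})

test_that("probabilities are invariant under scaling all table counts", {
  gen <- fixture_genome()
  tab <- fixture_table()
  tab10 <- tab
  tab10$counts <- lapply(tab$counts, function(x) 10 * x)
  for (pep in c("RS", "DA", "GS")) {
    for (p in 0:2) {
      expect_equal(motif_probability(pep, p, "GATC", tab10),
                   motif_probability(pep, p, "GATC", tab))
    }
  }
})

test_that("degenerate IUPAC motifs dominate any concrete expansion", {
  u <- uniform_codon_table(3)
  for (pep in c("RS", "GR", "WG")) {
    pr_deg <- motif_probability(pep, 1, "GAKC", u)   # K = G or T
    for (m in c("GAGC", "GATC")) {
      expect_gte(pr_deg, motif_probability(pep, 1, m, u))
    }
  }
})

test_that("unobserved peptide n-grams are flagged, not scored", {
  # empirical table from a tiny CDS cannot have seen W-W pairs
  tab <- build_codon_table("ATGGAT", max_span = 2)
  expect_true(is.na(motif_probability("WW", 0, "GATC", tab)))
  # the window lands in the skipped report of the scan
  nt <- "ATGTGGTGGGAT"   # M W W D
  w <- potential_windows(nt, "TGGT", tab)
  skipped <- attr(w, "skipped")
  expect_true(!is.null(skipped) && nrow(skipped) >= 1)
  expect_true(all(is.na(skipped$probability)))
})

test_that("window enumeration matches the worked GATC example", {
  u <- uniform_codon_table(2)
  nt <- "ATGAGATCCAAA"   # M R S K via ATG AGA TCC AAA
  w <- potential_windows(nt, "GATC", u)
  expect_equal(nrow(w), 1)
  expect_equal(w$nt_offset, 4)
  expect_equal(w$p, 1)
  expect_equal(w$peptide_window, "RS")
  expect_true(w$realized)
  # poly-Lys gene admits no GATC anywhere
  polyk <- paste0("ATG", paste(rep("AAA", 20), collapse = ""))
  expect_equal(nrow(potential_windows(polyk, "GATC", u)), 0)
})

test_that("indexed scan equals the naive per-position scan (incl. 1-mers)", {
  gen <- fixture_genome()
  tab <- fixture_table()
  idx <- motif_index("GATC", tab)
  for (i in 1:4) {
    nt <- gen$cds$nucleotides[i]
    got <- potential_windows(nt, index = idx)
    want <- oracle_window_scan(nt, "GATC", tab)
    expect_equal(got[c("nt_offset", "p", "span", "peptide_window",
                       "probability", "realized")],
                 want, ignore_attr = TRUE)
  }
  # single-base motif: windows at every G-permitting codon position
  u <- uniform_codon_table(1)
  nt <- "ATGAGATCCAAA"
  got <- potential_windows(nt, "G", u)
  want <- oracle_window_scan(nt, "G", u)
  expect_equal(got$nt_offset, want$nt_offset)
  expect_equal(got$probability, want$probability)
})

test_that("every realized occurrence is covered by a positive-probability window", {
  gen <- fixture_genome()
  tab <- fixture_table()
  idx <- motif_index("GATC", tab)
  for (i in seq_len(nrow(gen$cds))) {
    nt <- gen$cds$nucleotides[i]
    hits <- gregexpr("(?=GATC)", nt, perl = TRUE)[[1]]
    hits <- hits[hits > 0] - 1L
    w <- potential_windows(nt, index = idx)
    for (q in hits) {
      cover <- w[w$nt_offset == q & w$p == q %% 3, ]
      expect_equal(nrow(cover), 1)
      expect_gt(cover$probability, 0)
      expect_true(cover$realized)
    }
  }
})
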