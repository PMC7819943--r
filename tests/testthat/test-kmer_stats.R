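test_that("a 40-nt probe yields 40 - k + 1 occurrences, homopolymer case", {
  probe <- data.frame(probe_id = "g_1", core_seq = strrep("A", 40),
                      intensity = 1234)
  kt <- kmer_decompose(probe, 9)
  expect_equal(nrow(kt), 1L)
  expect_equal(kt$kmer, strrep("A", 9))
  expect_equal(kt$occurrence_total, 32L)
  expect_equal(kt$distinct_positions, 32L)
  expect_equal(kt$intensity_ave, 1234)
  expect_equal(attr(kt, "total_occurrence"), 32L)
})

test_that("occurrence totals and averages match a brute-force enumeration", {
  set.seed(31)
  shared <- "GATTGACAG"
  probes <- data.frame(
    probe_id = paste0("g", 1:3, "_1"),
    core_seq = c(paste0(shared, random_dna(1, 31)),
                 paste0(random_dna(1, 5), shared, random_dna(1, 26)),
                 paste0(random_dna(1, 10), shared, random_dna(1, 21))),
    intensity = c(100, 200, 700))
  kt <- kmer_decompose(probes, 9)
  # independent enumeration
  occ <- list()
  for (i in 1:3) {
    for (p in 1:32) {
      w <- substr(probes$core_seq[i], p, p + 8)
      occ[[w]] <- rbind(occ[[w]], c(probes$intensity[i], p))
    }
  }
  expect_equal(nrow(kt), length(occ))
  expect_equal(sum(kt$occurrence_total), 3 * 32)
  for (w in c(shared, sample(names(occ), 10))) {
    row <- kt[kt$kmer == w, ]
    expect_equal(row$occurrence_total, nrow(occ[[w]]))
    expect_equal(row$intensity_ave, mean(occ[[w]][, 1]))
    expect_equal(row$distinct_positions, length(unique(occ[[w]][, 2])))
    expect_equal(row$score_product, row$intensity_ave * row$occurrence_total)
  }
})

test_that("decomposition is invariant to probe order and honours k bounds", {
  set.seed(32)
  probes <- data.frame(probe_id = paste0("g", 1:20, "_1"),
                       core_seq = random_dna(20, 40),
                       intensity = runif(20, 50, 5000))
  a <- kmer_decompose(probes, 7)
  b <- kmer_decompose(probes[sample(20), ], 7)
  expect_equal(a, b, ignore_attr = TRUE)
  expect_error(kmer_decompose(probes, 0), "k")
  expect_error(kmer_decompose(probes, 41), "k")
  # k = probe length: each probe contributes its own core exactly once
  full <- kmer_decompose(probes, 40)
  expect_equal(sum(full$occurrence_total), 20L)
  expect_setequal(full$kmer, probes$core_seq)
  expect_error(kmer_decompose(transform(probes, core_seq = substr(core_seq, 1, 39))[1:2, ] |>
                                rbind(probes[3, ]), 9), "same length")
})

test_that("k-mers containing N are skipped and counted", {
  probes <- data.frame(probe_id = "g_1",
                       core_seq = paste0(strrep("A", 20), "N", strrep("C", 19)),
                       intensity = 10)
  kt <- kmer_decompose(probes, 9)
  expect_false(any(grepl("N", kt$kmer)))
  expect_equal(attr(kt, "n_skipped_n"), 9L)
  expect_equal(attr(kt, "total_occurrence"), 32L - 9L)
})

test_that("G/C run filter equals the regex oracle", {
  expect_equal(nrow(gc_run_filter(data.frame(kmer = "GGGGACGTA"))), 0L)
  expect_equal(nrow(gc_run_filter(data.frame(kmer = "GCGCGCGCG"))), 1L)
  set.seed(33)
  kmers <- data.frame(kmer = unique(random_dna(1000, 9)))
  filt <- gc_run_filter(kmers)
  oracle_keep <- !grepl("G{4,}|C{4,}", kmers$kmer)
  expect_equal(filt$kmer, kmers$kmer[oracle_keep])
  expect_equal(attr(filt, "n_discarded"), sum(!oracle_keep))
  # run length is configurable
  expect_equal(nrow(gc_run_filter(data.frame(kmer = "GGGAAAAAA"), min_run = 3)), 0L)
})

test_that("ranking matches a comparison-sort oracle in both modes", {
  set.seed(34)
  tab <- data.frame(kmer = unique(random_dna(40, 9))[1:20],
                    intensity_ave = round(runif(20, 100, 900)),
                    occurrence_total = sample(1:50, 20, replace = TRUE))
  tab$score_product <- tab$intensity_ave * tab$occurrence_total
  tab$distinct_positions <- pmin(tab$occurrence_total, 32L)
  by_int <- rank_kmers(tab, "intensity")
  expect_equal(by_int$kmer,
               tab$kmer[order(-tab$intensity_ave, tab$kmer)])
  by_prod <- rank_kmers(tab, "product")
  expect_equal(by_prod$kmer,
               tab$kmer[order(-tab$score_product, tab$kmer)])
  expect_equal(by_prod$rank, 1:20)
  expect_error(rank_kmers(tab, "zzz"))
  # single-entry table is its own top in either mode
  single <- rank_kmers(tab[1, ], "intensity")
  expect_equal(single$kmer, tab$kmer[1])
})

test_that("the auto4x occurrence floor is four times the mean occurrence", {
  tab <- data.frame(kmer = c("AAAAAAAAA", "CCCCCCCCC", "GATCGATCG",
                             "TTTTTTTTT", "ACACACACA"),
                    intensity_ave = c(10, 20, 30, 40, 50),
                    occurrence_total = c(1L, 1L, 1L, 1L, 20L))
  tab$score_product <- tab$intensity_ave * tab$occurrence_total
  tab$distinct_positions <- 1L
  # mean occurrence 4.8 -> floor ceil(19.2) = 20: only the 20-occurrence k-mer
  rk <- rank_kmers(tab, "intensity", min_occurrence = "auto4x")
  expect_equal(rk$kmer, "ACACACACA")
  expect_equal(attr(rk, "min_occurrence"), 20)
  # floor excluding everything is a named error, not an empty table
  tab$occurrence_total <- rep(1L, 5)
  tab$score_product <- tab$intensity_ave
  expect_error(rank_kmers(tab, "intensity", min_occurrence = 5), "occurrence floor")
})

test_that("occurrence conservation holds on random probe sets", {
  set.seed(35)
  for (k in c(5, 9, 11)) {
    probes <- data.frame(probe_id = paste0("g", 1:50, "_1"),
                         core_seq = random_dna(50, 40),
                         intensity = runif(50, 10, 100))
    kt <- kmer_decompose(probes, k)
    expect_equal(sum(kt$occurrence_total), 50 * (40 - k + 1))
    expect_true(all(kt$distinct_positions <=
                    pmin(kt$occurrence_total, 40 - k + 1)))
  }
})
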