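# k-mer table holding every k-mer seen in a probe set, built directly
flat_table <- function(kmers, intensities) {
  tab <- data.frame(kmer = kmers, intensity_ave = intensities,
                    occurrence_total = 1L, distinct_positions = 1L)
  tab$score_product <- tab$intensity_ave
  attr(tab, "k") <- nchar(kmers[1])
  class(tab) <- c("kmer_table", "data.frame")
  tab
}

all_point_mutants <- function(motif) {
  k <- nchar(motif)
  out <- character(0)
  for (i in seq_len(k)) for (b in c("A", "C", "G", "T")) {
    out <- c(out, paste0(substr(motif, 1, i - 1), b, substr(motif, i + 1, k)))
  }
  unique(out)
}

test_that("constant-intensity tables give zero positional deltas", {
  motif <- "ATTGATTG"
  tab <- flat_table(all_point_mutants(motif), 100)
  mp <- mutation_scan(motif, tab)
  expect_equal(mp$position_delta, rep(0, 8))
  expect_equal(mp$wt_intensity, 100)
})

test_that("mutation deltas equal a hand computation and locate the hot base", {
  motif <- "ATTGA"
  muts <- all_point_mutants(motif)
  # wild type bright; mutants at position 4 (the G) dark; others mid
  val <- ifelse(muts == motif, 1000,
                ifelse(substr(muts, 4, 4) != "G", 100, 600))
  tab <- flat_table(muts, val)
  mp <- mutation_scan(motif, tab)
  expect_equal(mp$position_delta[4], 1000 - 100)
  expect_equal(mp$position_delta[1], 1000 - 600)
  expect_equal(mp$max_pos, 4L)
  expect_equal(mp$min_pos, 1L)
  # sum-based variant
  mps <- mutation_scan(motif, tab, aggregate = "sum")
  expect_equal(mps$position_delta[4], 1000 - 300)
})

test_that("missing mutants are excluded with a warning, absent motif errors", {
  motif <- "ATTGA"
  muts <- setdiff(all_point_mutants(motif), c("CTTGA", "GTTGA", "TTTGA"))
  tab <- flat_table(c(motif, setdiff(muts, motif)), c(900, rep(300, length(muts) - 1)))
  expect_warning(mp <- mutation_scan(motif, tab), "absent")
  expect_true(is.na(mp$position_delta[1]))  # all three mutants missing
  expect_equal(mp$position_delta[2], 600)
  expect_error(suppressWarnings(mutation_scan("CCCCC", tab)), "absent")
})

test_that("mutation scan is invariant to probe relabelling upstream", {
  set.seed(51)
  probes <- data.frame(probe_id = paste0("g", 1:30, "_1"),
                       core_seq = random_dna(30, 40),
                       intensity = runif(30, 100, 1000))
  probes$core_seq[1] <- paste0("ATTGATTGA", substr(probes$core_seq[1], 10, 40))
  k1 <- kmer_decompose(probes, 9)
  relabel <- transform(probes, probe_id = paste0("x", probe_id))
  k2 <- kmer_decompose(relabel, 9)
  m1 <- suppressWarnings(mutation_scan("ATTGATTGA", k1))
  m2 <- suppressWarnings(mutation_scan("ATTGATTGA", k2))
  expect_equal(m1$position_delta, m2$position_delta)
})

test_that("greedy extension follows the highest-intensity window per side", {
  motif <- "ATTGATTG"
  # 5' chain: GATTGATT then TGATTGAT; 3' chain: TTGATTGG then TGATTGGT
  kmers <- c(motif,
             "AATTGATT", "TATTGATT", "CATTGATT", "GATTGATT",
             "AGATTGAT", "TGATTGAT", "CGATTGAT", "GGATTGAT",
             "TTGATTGA", "TTGATTGC", "TTGATTGG", "TTGATTGT",
             "TGATTGGA", "TGATTGGC", "TGATTGGG", "TGATTGGT")
  val <- c(1000,
           100, 200, 150, 900,      # 5' step 1 -> G
           100, 800, 200, 300,      # 5' step 2 -> T
           100, 200, 700, 300,      # 3' step 1 -> G
           100, 200, 250, 600)      # 3' step 2 -> T
  tab <- flat_table(kmers, val)
  tr <- extend_motif(motif, tab)
  expect_equal(tr$final_motif, "TGATTGATTGGT")
  expect_equal(tr$steps$base, c("G", "G", "T", "T"))
  expect_equal(tr$steps$direction, c("5p", "3p", "5p", "3p"))
  # determinism: identical rerun gives an identical trace
  expect_identical(extend_motif(motif, tab), tr)
})

test_that("extension tie-break picks the alphabetically first base", {
  motif <- "ATTGA"
  kmers <- c(motif, paste0(c("A", "C", "G", "T"), "ATTG"),
             paste0("TTGA", c("A", "C", "G", "T")))
  tab <- flat_table(kmers, c(500, rep(300, 8)))
  tr <- extend_motif(motif, tab, max_steps_each_side = 1)
  expect_equal(tr$final_motif, "AATTGAA")
})

test_that("extension truncates when no candidate window exists", {
  tab <- flat_table(c("ATTGA", "TTGAC"), c(500, 400))  # only one 3' window
  tr <- extend_motif("ATTGA", tab)
  expect_equal(tr$final_motif, "ATTGAC")
  expect_true("5p" %in% tr$truncated)
})

test_that("flanking preference tallies hand-countable contexts", {
  prom <- data.frame(gene_id = "g1", sequence = "AAATTGATTGTT")
  m <- flanking_preference(prom, "ATTGATTG", window = 3)
  expect_equal(unname(m["-1", "A"]), 1L)
  expect_equal(unname(m["+1", "T"]), 1L)
  expect_equal(sum(m["-3", ]), 0L)  # truncated at the 5' edge (only 2 left bases)
  expect_equal(attr(m, "n_occurrences"), 1L)

  # absent motif: all-zero matrix
  m0 <- flanking_preference(prom, "CCCCCC")
  expect_true(all(m0 == 0L))

  # planted bias: -1 fixed to G across 100 promoters; the left flank is kept
  # T-free so no overlapping occurrence can form across the insertion point
  set.seed(52)
  left <- chartr("T", "C", random_dna(100, 20))
  proms <- data.frame(gene_id = paste0("g", 1:100),
                      sequence = paste0(left, "G", "ATTGATTG",
                                        random_dna(100, 20)))
  mg <- flanking_preference(proms, "ATTGATTG")
  expect_gte(mg["-1", "G"], 100L)
  # per-position totals never exceed the occurrence count
  expect_true(all(rowSums(mg) <= attr(mg, "n_occurrences")))
})

test_that("reverse-complement occurrences contribute minus-strand flanks", {
  # plus strand: C CAATCAAT G  -> minus strand reads C ATTGATTG G
  prom <- data.frame(gene_id = "g", sequence = "TTCCAATCAATGTT")
  m <- flanking_preference(prom, "ATTGATTG", window = 1, include_rc = TRUE)
  expect_equal(unname(m["-1", "C"]), 1L)
  expect_equal(unname(m["+1", "G"]), 1L)
})
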