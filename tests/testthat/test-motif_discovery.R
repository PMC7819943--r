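test_that("cluster membership handles identity, shifts, and rejections", {
  m <- is_cluster_member("GATTGATTG", "GATTGATTG")
  expect_true(m$member)
  expect_equal(m$offset, 0L)
  expect_equal(m$mismatches, 0L)

  # pure 1-nt shift of the seed: 8-nt overlap, 0 mismatches
  m <- is_cluster_member("ATTGATTGA", "GATTGATTG")
  expect_true(m$member)
  expect_equal(m$offset, 1L)
  expect_equal(m$mismatches, 0L)

  # 3 mismatches at every admissible offset is out
  expect_false(is_cluster_member("GCACGCACG", "GATTGATTG")$member)
  expect_error(is_cluster_member("ACGT", "GATTGATTG"), "equal length")
})

test_that("membership agrees with the exhaustive sliding-window oracle", {
  seed <- "GATTG"
  words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 5),
                                       stringsAsFactors = FALSE))
  got <- vapply(words, function(w) is_cluster_member(w, seed)$member, logical(1))
  want <- vapply(words, function(w) oracle_member(w, seed), logical(1))
  expect_equal(unname(got), unname(want))

  # and on random 9-mers against a 9-mer seed
  set.seed(41)
  seed9 <- "GATTGATTG"
  for (w in random_dna(200, 9)) {
    expect_equal(is_cluster_member(w, seed9)$member, oracle_member(w, seed9),
                 info = w)
  }
})

test_that("mismatch counts are symmetric between candidate and seed", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_dna(1, 9); b <- random_dna(1, 9)
    ma <- is_cluster_member(a, b)
    mb <- is_cluster_member(b, a)
    expect_equal(ma$member, mb$member)
    if (ma$member) {
      expect_equal(ma$mismatches, mb$mismatches)
      expect_equal(abs(ma$offset), abs(mb$offset))
    }
  }
})

test_that("build_cluster collects planted variants of the seed", {
  set.seed(43)
  seed <- "GATTGATTG"
  mutate1 <- function(s) {
    i <- sample(6:9, 1)  # keep the 5' GATTG core intact
    b <- sample(setdiff(c("A", "C", "G", "T"), substr(s, i, i)), 1)
    paste0(substr(s, 1, i - 1), b, substr(s, i + 1, 9))
  }
  planted <- unique(vapply(1:60, function(i) mutate1(seed), character(1)))
  random_bg <- setdiff(unique(random_dna(40, 9)), c(seed, planted))
  ranked <- data.frame(kmer = c(seed, planted, random_bg))
  cl <- build_cluster(ranked)
  expect_equal(cl$seed, seed)
  expect_true(all(planted %in% cl$members$kmer))
  # chance passes among the random background must agree with the oracle
  for (w in random_bg) {
    expect_equal(w %in% cl$members$kmer, oracle_member(w, seed), info = w)
  }
  expect_error(build_cluster(ranked[0, , drop = FALSE]), "empty")
  # a seed-only list gives a singleton cluster
  expect_equal(build_cluster(data.frame(kmer = seed))$n_members, 1L)
})

test_that("cluster_all partitions k-mers greedily in seed-rank order", {
  # mutually non-matching k-mers -> singletons
  lonely <- data.frame(kmer = c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG"))
  cls <- cluster_all(lonely, max_clusters = 10)
  expect_equal(length(cls), 3L)
  expect_true(all(vapply(cls, `[[`, integer(1), "n_members") == 1L))

  # two planted families separate into two clusters with the right consensus
  fam <- function(seed, n, keep) {
    v <- vapply(seq_len(n), function(i) {
      i2 <- sample(setdiff(1:9, keep), 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), substr(seed, i2, i2)), 1)
      paste0(substr(seed, 1, i2 - 1), b, substr(seed, i2 + 1, 9))
    }, character(1))
    unique(c(seed, v))
  }
  set.seed(44)
  f1 <- fam("GATTGATTG", 30, 1:5)
  f2 <- fam("GCCACGTCA", 30, 3:7)
  f2 <- setdiff(f2, f1)
  ranked <- data.frame(kmer = c(f1, f2))
  cls <- cluster_all(ranked, max_clusters = 5)
  expect_gte(length(cls), 2L)
  expect_true(grepl("GATTG", cls[[1]]$consensus, fixed = TRUE))
  # partition: no k-mer in two clusters
  all_members <- unlist(lapply(cls, function(cl) cl$members$kmer))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("PWM counts, normalisation, and consensus follow the member stack", {
  # identical members: unit columns, consensus = the k-mer
  cl <- build_cluster(data.frame(kmer = rep("GATTGATTG", 1)))
  cl$members <- data.frame(kmer = rep("GATTGATTG", 4),
                           offset = 0L, mismatches = 0L)
  cl$n_members <- 4L
  cl <- build_pwm(cl)
  expect_true(all(colSums(cl$pwm_probs) - 1 < 1e-9))
  expect_true(all(apply(cl$pwm_probs, 2, max) == 1))
  expect_equal(cl$consensus, "GATTGATTG")

  # hand tally at offsets {0, 0, +1}
  cl2 <- structure(list(seed = "GATTG",
                        members = data.frame(
                          kmer = c("GATTG", "GCTTG", "ATTGA"),
                          offset = c(0L, 0L, 1L), mismatches = c(0L, 1L, 0L)),
                        n_members = 3L),
                   class = "motif_cluster")
  cl2 <- build_pwm(cl2, trim_support = 0)
  # seed coordinates 1..6; column 1 covered by two members: G,G
  expect_equal(unname(cl2$pwm_counts["G", 1]), 2)
  expect_equal(unname(cl2$pwm_counts["A", 2]), 2)  # A,C,A -> A=2
  expect_equal(unname(cl2$pwm_counts["C", 2]), 1)
  expect_equal(unname(cl2$pwm_counts["A", 6]), 1)  # only member 3 reaches col 6
  expect_equal(nchar(cl2$consensus), ncol(cl2$pwm_probs))

  # low-support end columns are trimmed at 25%
  cl3 <- structure(list(seed = "GATTG",
                        members = data.frame(
                          kmer = c(rep("GATTG", 5), "ATTGA"),
                          offset = c(rep(0L, 5), 1L), mismatches = 0L),
                        n_members = 6L),
                   class = "motif_cluster")
  cl3 <- build_pwm(cl3)  # col 6 supported by 1/6 < 25% -> trimmed
  expect_equal(ncol(cl3$pwm_probs), 5L)
  expect_equal(cl3$consensus, "GATTG")
})

test_that("intensity-weighted PWM uses member intensities as votes", {
  cl <- structure(list(seed = "GAT",
                       members = data.frame(
                         kmer = c("GAT", "CAT"), offset = 0L, mismatches = c(0L, 1L),
                         intensity_ave = c(300, 100)),
                       n_members = 2L),
                  class = "motif_cluster")
  cl <- build_pwm(cl, intensity_weighted = TRUE)
  expect_equal(unname(cl$pwm_probs["G", 1]), 0.75)
  expect_equal(unname(cl$pwm_probs["C", 1]), 0.25)
})
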