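# Independent oracles and fixture builders used across the suite.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Brute-force two-segment fit: lm() at every admissible breakpoint.
brute_segment_fit <- function(y, min_segment = 50L, break_range = c(0.001, 0.5)) {
  n <- length(y)
  y <- sort(y, decreasing = TRUE)
  r <- seq_len(n)
  lo <- max(min_segment, ceiling(break_range[1] * n))
  hi <- min(n - min_segment, floor(break_range[2] * n))
  best <- NULL
  best_sse <- Inf
  for (b in lo:hi) {
    f1 <- lm(y[1:b] ~ r[1:b])
    f2 <- lm(y[(b + 1):n] ~ r[(b + 1):n])
    sse <- sum(resid(f1)^2) + sum(resid(f2)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(b = b,
                   steep = c(slope = unname(coef(f1)[2]), intercept = unname(coef(f1)[1])),
                   tail = c(slope = unname(coef(f2)[2]), intercept = unname(coef(f2)[1])))
    }
  }
  best
}

# Exhaustive membership oracle: slide candidate over seed at every offset,
# implemented with plain string ops, no shared code with the package.
oracle_member <- function(candidate, seed, max_mismatch = 2L, core_len = 5L) {
  k <- nchar(seed)
  for (o in -(k - core_len):(k - core_len)) {
    i <- max(1, 1 - o):min(k, k - o)
    cb <- substring(candidate, i, i)
    sb <- substring(seed, i + o, i + o)
    eq <- cb == sb
    mm <- sum(!eq)
    run <- 0L; best <- 0L
    for (e in eq) {
      run <- if (e) run + 1L else 0L
      best <- max(best, run)
    }
    if (mm <= max_mismatch && best >= core_len) return(TRUE)
  }
  FALSE
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mwu_p <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  all_v <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(all_v), n1)
  us <- apply(idx, 2, function(i) u_stat(all_v[i], all_v[-i]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Enumerate the reverse-complement classes of all k-mers by brute force.
oracle_rc_classes <- function(k) {
  rc1 <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                           collapse = "")
  words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                       stringsAsFactors = FALSE))
  length(unique(vapply(words, function(w) min(w, rc1(w)), character(1))))
}

# Small synthetic probe set with known intensities for hand-checkable stats.
toy_probes <- function() {
  data.frame(
    probe_id = paste0("G", rep(1:3, each = 2), "_", rep(1:2, 3)),
    core_seq = c(
      paste0("ATTGATTGA", strrep("C", 31)),
      paste0(strrep("T", 10), "ATTGATTGA", strrep("C", 21)),
      strrep("A", 40),
      paste0(strrep("G", 3), strrep("AT", 17), "CGA"),
      paste0("CAATCAATC", strrep("A", 31)),
      strrep("GT", 20)
    ),
    intensity = c(5000, 4000, 100, 80, 3000, 50),
    stringsAsFactors = FALSE
  )
}
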