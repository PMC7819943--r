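# Enumerate candidate offsets ordered 0, -1, +1, -2, +2, ...
.offsets_for <- function(k, core_len) {
  m <- k - core_len
  if (m < 0) stop("'core_len' may not exceed k", call. = FALSE)
  o <- seq.int(-m, m)
  o[order(abs(o), o)]
}

# Align candidate against seed at a fixed ungapped offset o (candidate base i
# sits over seed base i + o). Overhanging bases are neither matches nor
# mismatches. Returns c(mismatches, longest_exact_run) over the overlap.
.align_at <- function(cand, seed, o) {
  k <- length(seed)
  i <- seq.int(max(1L, 1L - o), min(k, k - o))  # candidate positions in overlap
  eq <- cand[i] == seed[i + o]
  runs <- rle(eq)
  best_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  c(mismatches = sum(!eq), run = best_run)
}

#' Test whether a k-mer belongs to a seed's motif cluster
#'
#' A candidate joins the cluster of a seed template when some ungapped
#' alignment offset gives an overlap containing an exact match of at least
#' `core_len` consecutive nt with at most `max_mismatch` mismatches.
#' Among admissible offsets the best is the one with fewest mismatches,
#' then smallest absolute offset, then negative (5'-shift) before positive.
#'
#' @param candidate,seed k-mers of equal length.
#' @param max_mismatch maximum mismatches within the aligned overlap
#'   (default 2).
#' @param core_len required length of an exact consecutive match (default 5).
#' @return list with `member` (logical), `offset` (candidate shift relative
#'   to the seed; NA when not a member) and `mismatches` (NA likewise).
#' @export
is_cluster_member <- function(candidate, seed, max_mismatch = 2L, core_len = 5L) {
  if (nchar(candidate) != nchar(seed)) {
    stop(sprintf("candidate (%d nt) and seed (%d nt) must have equal length",
                 nchar(candidate), nchar(seed)), call. = FALSE)
  }
  k <- nchar(seed)
  cv <- strsplit(candidate, "", fixed = TRUE)[[1]]
  sv <- strsplit(seed, "", fixed = TRUE)[[1]]
  best <- NULL
  for (o in .offsets_for(k, core_len)) {
    a <- .align_at(cv, sv, o)
    if (a[["run"]] >= core_len && a[["mismatches"]] <= max_mismatch) {
      if (is.null(best) ||
          a[["mismatches"]] < best$mismatches ||
          (a[["mismatches"]] == best$mismatches &&
           (abs(o) < abs(best$offset) ||
            (abs(o) == abs(best$offset) && o < best$offset)))) {
        best <- list(offset = o, mismatches = a[["mismatches"]])
      }
    }
  }
  if (is.null(best)) {
    list(member = FALSE, offset = NA_integer_, mismatches = NA_integer_)
  } else {
    list(member = TRUE, offset = best$offset, mismatches = best$mismatches)
  }
}

#' Build a motif cluster around a seed template
#'
#' Takes the highest-ranked k-mer as the seed and collects, in one greedy
#' pass over the ranked list, every k-mer passing [is_cluster_member()].
#'
#' @param ranked a ranked `kmer_table` (see [rank_kmers()]), or any
#'   data.frame with a `kmer` column ordered best-first.
#' @param max_mismatch,core_len membership parameters, see
#'   [is_cluster_member()].
#' @param seed optional explicit seed k-mer (default: first row of `ranked`).
#' @return an object of class `motif_cluster`: list with `seed`, `members`
#'   (data.frame `kmer`, `offset`, `mismatches` plus any ranking columns),
#'   `n_members`. Use [build_pwm()] to add the position weight matrix and
#'   consensus.
#' @export
build_cluster <- function(ranked, max_mismatch = 2L, core_len = 5L, seed = NULL) {
  stopifnot(is.data.frame(ranked), "kmer" %in% names(ranked))
  if (nrow(ranked) == 0L) stop("empty ranked k-mer list", call. = FALSE)
  if (is.null(seed)) seed <- ranked$kmer[1]
  hits <- lapply(ranked$kmer, is_cluster_member, seed = seed,
                 max_mismatch = max_mismatch, core_len = core_len)
  member <- vapply(hits, `[[`, logical(1), "member")
  members <- ranked[member, , drop = FALSE]
  members$offset <- vapply(hits[member], `[[`, integer(1), "offset")
  members$mismatches <- vapply(hits[member], `[[`, integer(1), "mismatches")
  rownames(members) <- NULL
  structure(
    list(seed = seed, members = members, n_members = nrow(members),
         max_mismatch = as.integer(max_mismatch),
         core_len = as.integer(core_len)),
    class = "motif_cluster"
  )
}

#' Greedy partition of ranked k-mers into motif clusters
#'
#' Repeatedly takes the highest-ranked unassigned k-mer as a new seed, builds
#' its cluster from the unassigned k-mers, and removes the members, so every
#' k-mer belongs to at most one cluster. Each cluster gets its PWM and
#' consensus via [build_pwm()].
#'
#' @inheritParams build_cluster
#' @param max_clusters stop after this many clusters (default 10).
#' @param min_cluster_size drop trailing clusters smaller than this
#'   (default 1, i.e. keep all).
#' @param trim_support consensus end-trimming threshold passed to
#'   [build_pwm()].
#' @return list of `motif_cluster` objects in seed-rank order.
#' @export
cluster_all <- function(ranked, max_mismatch = 2L, core_len = 5L,
                        max_clusters = 10L, min_cluster_size = 1L,
                        trim_support = 0.25) {
  stopifnot(is.data.frame(ranked), "kmer" %in% names(ranked))
  if (nrow(ranked) == 0L) stop("empty ranked k-mer list", call. = FALSE)
  clusters <- list()
  remaining <- ranked
  while (nrow(remaining) > 0L && length(clusters) < max_clusters) {
    cl <- build_cluster(remaining, max_mismatch = max_mismatch,
                        core_len = core_len)
    cl <- build_pwm(cl, trim_support = trim_support)
    if (cl$n_members >= min_cluster_size) clusters[[length(clusters) + 1L]] <- cl
    remaining <- remaining[!(remaining$kmer %in% cl$members$kmer), , drop = FALSE]
  }
  clusters
}

#' Position weight matrix and consensus for a motif cluster
#'
#' Stacks the member k-mers at their alignment offsets against the seed,
#' counts the four bases per column (one vote per member by default,
#' optionally weighted by pseudo-intensity), normalises columns to
#' probabilities, and reads off the per-column majority base as the
#' consensus. End columns supported by fewer than `trim_support` of the
#' members are trimmed, so a 9-mer seed cluster can yield a shorter (e.g.
#' 8-nt) consensus.
#'
#' @param cluster a `motif_cluster` from [build_cluster()].
#' @param trim_support minimum fraction of members that must cover an end
#'   column for it to be kept (default 0.25).
#' @param intensity_weighted weight each member's vote by its
#'   `intensity_ave` column (default FALSE: one vote per member).
#' @return the cluster with `pwm_counts` and `pwm_probs` (4 x width matrices,
#'   rows A,C,G,T), `consensus`, and `consensus_ties` (columns whose majority
#'   base was tied and broken alphabetically) filled in.
#' @export
build_pwm <- function(cluster, trim_support = 0.25, intensity_weighted = FALSE) {
  stopifnot(inherits(cluster, "motif_cluster"))
  mem <- cluster$members
  if (nrow(mem) == 0L) stop("cluster has no members", call. = FALSE)
  k <- nchar(cluster$seed)
  off <- mem$offset
  w <- if (intensity_weighted) {
    if (is.null(mem$intensity_ave)) stop("members carry no intensity_ave", call. = FALSE)
    mem$intensity_ave
  } else rep(1, nrow(mem))
  # member i occupies seed coordinates (1 + off[i]) .. (k + off[i])
  lo <- min(1L + off); hi <- max(k + off)
  width <- hi - lo + 1L
  counts <- matrix(0, nrow = 4L, ncol = width,
                   dimnames = list(DNA_BASES, as.character(seq.int(lo, hi))))
  chars <- strsplit(mem$kmer, "", fixed = TRUE)
  for (i in seq_len(nrow(mem))) {
    cols <- (1L + off[i]):(k + off[i]) - lo + 1L
    for (j in seq_len(k)) {
      counts[chars[[i]][j], cols[j]] <- counts[chars[[i]][j], cols[j]] + w[i]
    }
  }
  support <- colSums(counts) / sum(w)
  keep <- which(support >= trim_support)
  # trim from the ends only: keep the contiguous block between the first and
  # last sufficiently supported column
  keep_range <- if (length(keep)) seq.int(min(keep), max(keep)) else seq_len(width)
  counts <- counts[, keep_range, drop = FALSE]
  probs <- sweep(counts, 2L, colSums(counts), "/")
  top <- apply(counts, 2L, which.max)  # ties -> first, i.e. alphabetical
  ties <- vapply(seq_len(ncol(counts)), function(j) {
    sum(counts[, j] == max(counts[, j])) > 1L
  }, logical(1))
  cluster$pwm_counts <- counts
  cluster$pwm_probs <- probs
  cluster$consensus <- paste(DNA_BASES[top], collapse = "")
  cluster$consensus_ties <- which(ties)
  cluster$trim_support <- trim_support
  cluster
}

#' @export
print.motif_cluster <- function(x, ...) {
  cat(sprintf("Motif cluster: seed %s, %d members\n", x$seed, x$n_members))
  if (!is.null(x$consensus)) {
    cat(sprintf("  consensus: %s (width %d)\n", x$consensus, ncol(x$pwm_probs)))
  }
  invisible(x)
}
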