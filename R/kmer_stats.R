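#' Decompose probes into k-mers with pseudo-intensities
#'
#' Splits every probe core into its overlapping k-mers with a 1-nt shift
#' (a 40-nt probe yields 40 - k + 1 of them, e.g. 32 9-mers) and assigns the
#' probe's fluorescence intensity to each occurrence ("pseudo-intensity").
#' Per distinct k-mer the mean pseudo-intensity, total occurrence count,
#' their product, and the number of distinct probe offsets are reported —
#' the columns used to rank candidate binding words.
#'
#' Counting is forward-strand only; a reverse-complement motif is a separate
#' k-mer. k-mers containing N are skipped (their count is reported in the
#' `n_skipped_n` attribute).
#'
#' @param probes data.frame with columns `core_seq` and `intensity`
#'   (and optionally `probe_id`); all cores must share one length.
#' @param k word length. 5–11 is the standard analysis range; any
#'   1 <= k <= probe length is accepted.
#' @param unique_per_probe count at most one occurrence per probe (the
#'   default counts every offset as one occurrence).
#' @return data.frame of class `kmer_table` with columns `kmer`,
#'   `intensity_ave`, `occurrence_total`, `score_product`,
#'   `distinct_positions`, sorted by `kmer`; attributes `k`, `n_probes`,
#'   `probe_length`, `total_occurrence`, `n_skipped_n`, `unique_per_probe`.
#' @export
kmer_decompose <- function(probes, k, unique_per_probe = FALSE) {
  if (!is.data.frame(probes) || !all(c("core_seq", "intensity") %in% names(probes))) {
    stop("expected a data.frame with columns 'core_seq' and 'intensity'",
         call. = FALSE)
  }
  if (nrow(probes) == 0L) stop("empty probe set", call. = FALSE)
  L <- unique(nchar(probes$core_seq))
  if (length(L) != 1L) {
    stop("all probe cores must have the same length; found lengths ",
         paste(L, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > L) {
    stop(sprintf("'k' must be a single integer in 1..%d (probe length)", L),
         call. = FALSE)
  }
  k <- as.integer(k)
  n <- nrow(probes)
  P <- L - k + 1L
  # position-major blocks: rows 1..n are offset 1, next n rows offset 2, ...
  kmer <- unlist(lapply(seq_len(P), function(i) {
    substring(probes$core_seq, i, i + k - 1L)
  }), use.names = FALSE)
  dt <- data.table::data.table(
    kmer = kmer,
    pos = rep(seq_len(P), each = n),
    probe = rep.int(seq_len(n), P),
    intensity = rep.int(probes$intensity, P)
  )
  n_skip <- 0L
  if (anyNA(dt$kmer) || any(grepl("N", probes$core_seq, fixed = TRUE))) {
    has_n <- grepl("N", dt$kmer, fixed = TRUE)
    n_skip <- sum(has_n)
    dt <- dt[!has_n]
  }
  if (unique_per_probe) {
    dt <- unique(dt, by = c("kmer", "probe"))
  }
  total_occ <- nrow(dt)
  pos <- NULL; intensity <- NULL  # appease R CMD check
  agg <- dt[, list(intensity_ave = mean(intensity),
                   occurrence_total = .N),
            by = kmer]
  dp <- unique(dt[, c("kmer", "pos")])[, list(distinct_positions = .N), by = kmer]
  agg <- dp[agg, on = "kmer"]
  data.table::setorder(agg, kmer)
  out <- as.data.frame(agg)
  out$score_product <- out$intensity_ave * out$occurrence_total
  out <- out[, c("kmer", "intensity_ave", "occurrence_total",
                 "score_product", "distinct_positions")]
  structure(out,
            class = c("kmer_table", "data.frame"),
            k = k, n_probes = n, probe_length = L,
            total_occurrence = total_occ, n_skipped_n = n_skip,
            unique_per_probe = unique_per_probe)
}

.keep_kmer_attrs <- function(out, from, ...) {
  keep <- c("k", "n_probes", "probe_length", "total_occurrence",
            "n_skipped_n", "unique_per_probe")
  for (a in keep) attr(out, a) <- attr(from, a)
  extra <- list(...)
  for (a in names(extra)) attr(out, a) <- extra[[a]]
  class(out) <- unique(c("kmer_table", class(out)))
  out
}

#' Discard G/C homopolymer-run k-mers
#'
#' k-mers containing a run of `min_run` or more consecutive G (or consecutive
#' C) bind nonspecifically across transcription factors on this array type
#' and are removed before ranking.
#'
#' @param table a `kmer_table` from [kmer_decompose()].
#' @param min_run minimum homopolymer run length (default 4).
#' @return the filtered `kmer_table`; attribute `n_discarded` holds the
#'   number of removed k-mers.
#' @export
gc_run_filter <- function(table, min_run = 4L) {
  stopifnot(is.data.frame(table), "kmer" %in% names(table))
  pat <- sprintf("G{%d,}|C{%d,}", min_run, min_run)
  drop <- grepl(pat, table$kmer)
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  .keep_kmer_attrs(out, table, n_discarded = sum(drop))
}

#' Rank k-mers by pseudo-intensity or intensity x occurrence
#'
#' Sorts k-mers in decreasing order of either their mean pseudo-intensity
#' (`mode = "intensity"`; suited to factors with one dominant site) or the
#' product of intensity and occurrence (`mode = "product"`; suited to factors
#' with several motifs), optionally after dropping rare k-mers. Ties break
#' lexicographically.
#'
#' @param table a `kmer_table`.
#' @param mode `"intensity"` or `"product"`.
#' @param min_occurrence numeric floor on `occurrence_total`, or the string
#'   `"auto4x"` for `ceiling(4 * mean(occurrence_total))` (k-mers occurring
#'   at least four times the average).
#' @return the table with a leading `rank` column, ordered by rank.
#' @export
rank_kmers <- function(table, mode = c("intensity", "product"),
                       min_occurrence = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(table),
            all(c("kmer", "intensity_ave", "occurrence_total",
                  "score_product") %in% names(table)))
  if (identical(min_occurrence, "auto4x")) {
    min_occurrence <- ceiling(4 * mean(table$occurrence_total))
  } else if (!is.numeric(min_occurrence) || length(min_occurrence) != 1L) {
    stop("'min_occurrence' must be a single number or \"auto4x\"", call. = FALSE)
  }
  out <- table[table$occurrence_total >= min_occurrence, , drop = FALSE]
  if (nrow(out) == 0L) stop("no k-mer passes the occurrence floor", call. = FALSE)
  key <- switch(mode, intensity = out$intensity_ave, product = out$score_product)
  out <- out[order(-key, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  .keep_kmer_attrs(out, table, sort_mode = mode, min_occurrence = min_occurrence)
}
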