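.kmer_lookup <- function(table) {
  stats::setNames(table$intensity_ave, table$kmer)
}

.mutate_at <- function(motif, i, b) {
  paste0(substr(motif, 1, i - 1), b, substr(motif, i + 1, nchar(motif)))
}

#' Per-position mutation effect profile of a motif
#'
#' For every position of the motif, looks up the pseudo-intensities of the
#' three single-base substitution k-mers and compares their mean (or sum)
#' with the wild-type pseudo-intensity. A large positive delta marks a base
#' the binding depends on.
#'
#' @param motif DNA string of the same length as the table's k.
#' @param table a `kmer_table` containing `motif`.
#' @param aggregate `"mean"` (default) or `"sum"` of the mutant intensities.
#' @return object of class `mutation_profile`: list with `motif`,
#'   `wt_intensity`, `mutants` (4 x k matrix of mutant intensities, wild-type
#'   cells NA), `position_delta`, `n_missing` (mutant k-mers absent from the
#'   table), `max_pos`, `min_pos`.
#' @export
mutation_scan <- function(motif, table, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  k <- attr(table, "k")
  if (!is.null(k) && nchar(motif) != k) {
    stop(sprintf("motif length %d does not match table k = %d", nchar(motif), k),
         call. = FALSE)
  }
  look <- .kmer_lookup(table)
  wt <- look[motif]
  if (is.na(wt)) stop(sprintf("motif '%s' is absent from the k-mer table", motif),
                      call. = FALSE)
  kk <- nchar(motif)
  mut <- matrix(NA_real_, nrow = 4L, ncol = kk,
                dimnames = list(DNA_BASES, strsplit(motif, "")[[1]]))
  for (i in seq_len(kk)) {
    wt_base <- substr(motif, i, i)
    for (b in setdiff(DNA_BASES, wt_base)) {
      mut[b, i] <- unname(look[.mutate_at(motif, i, b)])
    }
  }
  n_missing <- sum(is.na(mut)) - kk  # kk wild-type cells are NA by design
  delta <- vapply(seq_len(kk), function(i) {
    v <- mut[, i]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    wt - switch(aggregate, mean = mean(v), sum = sum(v))
  }, numeric(1))
  if (n_missing > 0L) {
    warning(sprintf("%d mutant k-mer(s) absent from the table; excluded from the mutant mean",
                    n_missing), call. = FALSE)
  }
  structure(
    list(motif = motif, wt_intensity = unname(wt), mutants = mut,
         position_delta = delta, aggregate = aggregate, n_missing = n_missing,
         max_pos = if (all(is.na(delta))) NA_integer_ else which.max(delta),
         min_pos = if (all(is.na(delta))) NA_integer_ else which.min(delta)),
    class = "mutation_profile"
  )
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("Mutation profile of %s (wild-type intensity %.1f)\n",
              x$motif, x$wt_intensity))
  cat("  position deltas (wt - ", x$aggregate, " of mutants):\n    ", sep = "")
  cat(paste(sprintf("%s:%0.1f", strsplit(x$motif, "")[[1]], x$position_delta),
            collapse = "  "), "\n")
  if (!is.na(x$max_pos)) {
    cat(sprintf("  max decrease at position %d (%s), min at position %d (%s)\n",
                x$max_pos, substr(x$motif, x$max_pos, x$max_pos),
                x$min_pos, substr(x$motif, x$min_pos, x$min_pos)))
  }
  invisible(x)
}

# One greedy sliding-window step on one side. window: current k-mer window
# for that side; returns list(base, window, intensity) or NULL when no
# candidate window is present in the table.
.extend_step <- function(window, side, look) {
  k <- nchar(window)
  cand <- if (side == "5p") paste0(DNA_BASES, substr(window, 1, k - 1))
          else paste0(substr(window, 2, k), DNA_BASES)
  val <- look[cand]
  if (all(is.na(val))) return(NULL)
  best <- which.max(val)  # NA ignored; ties -> first, i.e. alphabetical base
  list(base = DNA_BASES[best], window = cand[best], intensity = unname(val[best]))
}

#' Greedy base-by-base motif extension
#'
#' Extends a motif in the 5' and 3' directions by sliding a fixed-length
#' window: each step prepends (5') or appends (3') one of the four bases,
#' drops the opposite end, and keeps the window with the highest
#' pseudo-intensity. Each side's chain starts from the input motif; the final
#' motif is the chosen 5' bases + motif + chosen 3' bases (e.g. ATTGATTG
#' extended two steps per side can give TGATTGATTGGT).
#'
#' @param motif DNA string present in the table.
#' @param table a `kmer_table` with k = nchar(motif).
#' @param max_steps_each_side steps per direction (default 2).
#' @param directions trace ordering: `"alternate"` interleaves 5',3',5',3'
#'   (default), `"five_then_three"` finishes the 5' side first.
#' @return object of class `extension_trace`: list with `start_motif`,
#'   `steps` (data.frame `direction`, `step`, `base`, `window`, `intensity`),
#'   `final_motif`, `truncated` (sides stopped early because no candidate
#'   window was in the table).
#' @export
extend_motif <- function(motif, table, max_steps_each_side = 2L,
                         directions = c("alternate", "five_then_three")) {
  directions <- match.arg(directions)
  look <- .kmer_lookup(table)
  if (is.na(look[motif])) {
    stop(sprintf("motif '%s' is absent from the k-mer table", motif), call. = FALSE)
  }
  order5 <- rep("5p", max_steps_each_side)
  order3 <- rep("3p", max_steps_each_side)
  plan <- if (directions == "alternate") {
    as.vector(rbind(order5, order3))
  } else c(order5, order3)
  win <- c("5p" = motif, "3p" = motif)
  done <- c("5p" = FALSE, "3p" = FALSE)
  stepn <- c("5p" = 0L, "3p" = 0L)
  prefix <- character(0); suffix <- character(0)
  steps <- list()
  for (side in plan) {
    if (done[side]) next
    st <- .extend_step(win[side], side, look)
    if (is.null(st)) { done[side] <- TRUE; next }
    stepn[side] <- stepn[side] + 1L
    win[side] <- st$window
    if (side == "5p") prefix <- c(st$base, prefix) else suffix <- c(suffix, st$base)
    steps[[length(steps) + 1L]] <- data.frame(
      direction = side, step = stepn[side], base = st$base,
      window = st$window, intensity = st$intensity, stringsAsFactors = FALSE)
  }
  structure(
    list(start_motif = motif,
         steps = if (length(steps)) do.call(rbind, steps)
                 else data.frame(direction = character(0), step = integer(0),
                                 base = character(0), window = character(0),
                                 intensity = numeric(0)),
         final_motif = paste0(paste(prefix, collapse = ""), motif,
                              paste(suffix, collapse = "")),
         truncated = names(done)[done]),
    class = "extension_trace"
  )
}

#' @export
print.extension_trace <- function(x, ...) {
  cat(sprintf("Motif extension: %s -> %s\n", x$start_motif, x$final_motif))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      s <- x$steps[i, ]
      cat(sprintf("  %s step %d: +%s  (window %s, intensity %.1f)\n",
                  s$direction, s$step, s$base, s$window, s$intensity))
    }
  }
  if (length(x$truncated)) {
    cat("  truncated on side(s):", paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Base preferences flanking a motif in promoter sequences
#'
#' Tallies the bases observed at the `window` positions immediately 5' and 3'
#' of every occurrence of the motif in a promoter set. Occurrences at
#' promoter edges contribute only the positions that exist.
#'
#' @param promoters data.frame with `gene_id` and `sequence`.
#' @param motif literal DNA string.
#' @param window flank width on each side (default 3).
#' @param include_rc also count reverse-complement occurrences (their flanks
#'   are read on the minus strand, i.e. reverse-complemented before
#'   tallying). Default FALSE.
#' @return integer matrix, rows = positions (-window..-1, +1..+window),
#'   columns = A,C,G,T; attribute `n_occurrences` gives the occurrence count.
#' @export
flanking_preference <- function(promoters, motif, window = 3L,
                                include_rc = FALSE) {
  stopifnot(is.data.frame(promoters),
            all(c("gene_id", "sequence") %in% names(promoters)),
            nchar(motif) >= 1L)
  pos_labels <- c(paste0("-", window:1), paste0("+", 1:window))
  counts <- matrix(0L, nrow = 2L * window, ncol = 4L,
                   dimnames = list(pos_labels, DNA_BASES))
  n_occ <- 0L
  tally <- function(seq, m, as_rc) {
    mlen <- nchar(m)
    hits <- gregexpr(m, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return()
    for (h in hits) {
      n_occ <<- n_occ + 1L
      left <- substr(seq, max(1L, h - window), h - 1L)
      right <- substr(seq, h + mlen, min(nchar(seq), h + mlen + window - 1L))
      if (as_rc) {  # read the flanks in the motif's own (minus-strand) frame
        tmp <- left
        left <- reverse_complement(right)
        right <- reverse_complement(tmp)
      }
      lb <- strsplit(left, "")[[1]]
      if (length(lb)) {
        at <- window - length(lb) + seq_along(lb)
        for (j in seq_along(lb)) {
          if (lb[j] %in% DNA_BASES) counts[at[j], lb[j]] <<- counts[at[j], lb[j]] + 1L
        }
      }
      rb <- strsplit(right, "")[[1]]
      for (j in seq_along(rb)) {
        if (rb[j] %in% DNA_BASES) counts[window + j, rb[j]] <<- counts[window + j, rb[j]] + 1L
      }
    }
  }
  rc <- reverse_complement(motif)
  for (s in promoters$sequence) {
    tally(s, motif, FALSE)
    if (include_rc && rc != motif) tally(s, rc, TRUE)
  }
  attr(counts, "n_occurrences") <- n_occ
  counts
}
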