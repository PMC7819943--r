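.gene_from_probe_id <- function(probe_id) {
  bad <- !grepl("_", probe_id, fixed = TRUE)
  if (any(bad)) {
    stop(sprintf("malformed probe_id without gene prefix: '%s'",
                 probe_id[which(bad)[1]]), call. = FALSE)
  }
  sub("_[^_]*$", "", probe_id)
}

.find_hits <- function(ids, seqs, motif, include_rc) {
  out <- list()
  scan_one <- function(pattern, strand) {
    m <- gregexpr(pattern, seqs, fixed = TRUE)
    for (i in seq_along(seqs)) {
      pos <- m[[i]]
      if (pos[1] == -1L) next
      out[[length(out) + 1L]] <<- data.frame(
        id = ids[i], offset = as.integer(pos), strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  scan_one(motif, "+")
  rc <- reverse_complement(motif)
  if (include_rc && rc != motif) scan_one(rc, "-")
  if (length(out) == 0L) {
    return(data.frame(id = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$id, res$offset, res$strand), , drop = FALSE]
}

#' Scan strong-binding probes for a motif and list putative target genes
#'
#' Substring search of the motif (and optionally its reverse complement)
#' over probe core sequences. Gene ids are parsed from probe ids by dropping
#' the final `_<tile>` suffix; because consecutive probes overlap, one
#' genomic site can hit two probes, so genes are deduplicated.
#'
#' @param probes data.frame with `probe_id` and `core_seq` (e.g. strong
#'   probes joined to the design).
#' @param motif literal DNA string (length at most the probe length).
#' @param include_rc also report reverse-complement hits (default FALSE).
#' @return object of class `gene_hits`: list with `motif`, `hits`
#'   (data.frame `probe_id`, `gene_id`, `offset` (1-based within the core),
#'   `strand`), `genes` (sorted unique), `n_probes`, `n_genes`.
#' @export
scan_probes <- function(probes, motif, include_rc = FALSE) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "core_seq") %in% names(probes)))
  hits <- .find_hits(probes$probe_id, probes$core_seq, motif, include_rc)
  names(hits)[1] <- "probe_id"
  hits$gene_id <- if (nrow(hits)) .gene_from_probe_id(hits$probe_id) else character(0)
  hits <- hits[, c("probe_id", "gene_id", "offset", "strand")]
  rownames(hits) <- NULL
  genes <- sort(unique(hits$gene_id))
  structure(list(motif = motif, hits = hits, genes = genes,
                 n_probes = length(unique(hits$probe_id)),
                 n_genes = length(genes), include_rc = include_rc,
                 level = "probe"),
            class = "gene_hits")
}

#' Scan promoter sequences for a motif
#'
#' Like [scan_probes()] but over whole promoters; each gene is counted once
#' however many occurrences it carries.
#'
#' @param promoters data.frame with `gene_id` and `sequence`.
#' @inheritParams scan_probes
#' @return a `gene_hits` object; `n_probes` is the number of promoters hit.
#' @export
scan_promoters <- function(promoters, motif, include_rc = FALSE) {
  stopifnot(is.data.frame(promoters),
            all(c("gene_id", "sequence") %in% names(promoters)))
  hits <- .find_hits(promoters$gene_id, promoters$sequence, motif, include_rc)
  names(hits)[1] <- "gene_id"
  rownames(hits) <- NULL
  genes <- sort(unique(hits$gene_id))
  structure(list(motif = motif, hits = hits, genes = genes,
                 n_probes = length(genes), n_genes = length(genes),
                 include_rc = include_rc, level = "promoter"),
            class = "gene_hits")
}

#' @export
print.gene_hits <- function(x, ...) {
  cat(sprintf("Motif %s: %d hit(s) in %d %s(s), %d unique gene(s)%s\n",
              x$motif, nrow(x$hits), x$n_probes,
              if (x$level == "probe") "probe" else "promoter",
              x$n_genes,
              if (x$include_rc) " (both strands)" else " (forward strand)"))
  invisible(x)
}

#' Representative consensus from a letter-probability matrix
#'
#' Extracts, per position, the base with occupancy strictly above
#' `occupancy_min` (otherwise N), and accepts the motif only when it has at
#' least `min_distinct` non-N positions and no two adjacent Ns. Accepted
#' consensus strings are trimmed of leading/trailing Ns.
#'
#' @param lpm numeric matrix, one row per position, columns A, C, G, T, rows
#'   summing to 1 (a PlantTFDB-style letter-probability matrix; see
#'   [read_lpm()]).
#' @param occupancy_min strict occupancy threshold (default 0.5).
#' @param min_distinct minimum number of determined (non-N) positions
#'   (default 6).
#' @return list with `accepted` (logical), `consensus` (trimmed string, or
#'   NA when rejected), `full` (untrimmed), `reason` (NA when accepted).
#' @export
lpm_to_consensus <- function(lpm, occupancy_min = 0.5, min_distinct = 6L) {
  if (!is.matrix(lpm) || ncol(lpm) != 4L) {
    stop("'lpm' must be a positions x 4 matrix with columns A, C, G, T",
         call. = FALSE)
  }
  if (is.null(colnames(lpm))) colnames(lpm) <- DNA_BASES
  if (!identical(colnames(lpm), DNA_BASES)) lpm <- lpm[, DNA_BASES, drop = FALSE]
  if (any(lpm < 0) || any(lpm > 1) || any(abs(rowSums(lpm) - 1) > 1e-6)) {
    stop("invalid letter-probability matrix: entries must lie in [0,1] and rows sum to 1",
         call. = FALSE)
  }
  ch <- vapply(seq_len(nrow(lpm)), function(i) {
    j <- which.max(lpm[i, ])  # ties resolve alphabetically
    if (lpm[i, j] > occupancy_min) DNA_BASES[j] else "N"
  }, character(1))
  full <- paste(ch, collapse = "")
  n_distinct <- sum(ch != "N")
  if (n_distinct < min_distinct) {
    return(list(accepted = FALSE, consensus = NA_character_, full = full,
                reason = sprintf("only %d determined position(s), need %d",
                                 n_distinct, min_distinct)))
  }
  if (grepl("NN", full, fixed = TRUE)) {
    return(list(accepted = FALSE, consensus = NA_character_, full = full,
                reason = "consecutive undetermined positions"))
  }
  list(accepted = TRUE, consensus = gsub("^N+|N+$", "", full), full = full,
       reason = NA_character_)
}

#' Count probes carrying repeated occurrences of a secondary motif
#'
#' Among the probes containing a primary motif, counts those whose core also
#' carries at least `min_count` occurrences of a secondary element (e.g.
#' probes with a WRKY-bound motif that contain two TGAC W-box cores).
#'
#' @param probes data.frame with `probe_id` and `core_seq`.
#' @param motif primary motif (literal).
#' @param secondary secondary element (literal).
#' @param min_count minimum number of secondary occurrences (default 2).
#' @param include_rc count both strands of the secondary element
#'   (default FALSE).
#' @return list with `n_primary` (probes with the primary motif) and
#'   `n_cooccur` (of those, probes with >= min_count secondary occurrences).
#' @export
count_motif_cooccurrence <- function(probes, motif, secondary, min_count = 2L,
                                     include_rc = FALSE) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "core_seq") %in% names(probes)))
  prim <- grepl(motif, probes$core_seq, fixed = TRUE)
  seqs <- probes$core_seq[prim]
  count_occ <- function(pat) {
    vapply(gregexpr(pat, seqs, fixed = TRUE),
           function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  }
  n_occ <- count_occ(secondary)
  rc <- reverse_complement(secondary)
  if (include_rc && rc != secondary) n_occ <- n_occ + count_occ(rc)
  list(n_primary = sum(prim), n_cooccur = sum(n_occ >= min_count))
}
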