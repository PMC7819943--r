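#' Wilcoxon-Mann-Whitney test of motif-containing vs motif-free probes
#'
#' Compares the intensity ranks of probes whose core sequence contains the
#' motif with those of all other probes. The exact null distribution is used
#' when the smaller group has at most 8 members and there are no ties;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction) is used. Two-sided.
#'
#' @param probes data.frame with `core_seq` and `intensity`.
#' @param motif literal DNA string.
#' @param include_rc also count reverse-complement occurrences as
#'   motif-containing (default FALSE).
#' @return list with `statistic` (the U statistic of the motif group),
#'   `p_value`, `n_motif`, `n_other`, `exact`.
#' @export
mwu_motif_test <- function(probes, motif, include_rc = FALSE) {
  stopifnot(is.data.frame(probes),
            all(c("core_seq", "intensity") %in% names(probes)))
  has <- grepl(motif, probes$core_seq, fixed = TRUE)
  if (include_rc) {
    rc <- reverse_complement(motif)
    if (rc != motif) has <- has | grepl(rc, probes$core_seq, fixed = TRUE)
  }
  if (!any(has)) stop(sprintf("no probe contains motif '%s'", motif), call. = FALSE)
  if (all(has)) stop(sprintf("every probe contains motif '%s'; no comparison group",
                             motif), call. = FALSE)
  x <- probes$intensity[has]
  y <- probes$intensity[!has]
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_motif = length(x), n_other = length(y), exact = exact)
}

#' Motif distribution across the steep/tail intensity partition
#'
#' Classifies every above-background probe as steep (intensity above the
#' fitted cutoff) or tail, assigns it to the forward-motif,
#' reverse-complement, or no-motif group by substring search of its core
#' sequence, and summarises counts, group mean +/- sd intensities, fold
#' changes over the no-motif group, the fraction of motif-bearing probes in
#' the strong-binding zone, and the Wilcoxon-Mann-Whitney test of
#' motif-bearing (forward or reverse) vs motif-free probes.
#'
#' Probes containing both the forward and reverse motif are assigned to the
#' forward group (count reported in `n_both`). For palindromic motifs the
#' forward and reverse groups coincide and the reverse group is empty.
#' p-values below 2.2e-16 are floored at that value and flagged
#' (`p_underflow`), matching the conventional "p < 2.2e-16" report.
#'
#' @param probes data.frame with `probe_id`, `core_seq`, `intensity` for all
#'   above-background probes.
#' @param fit a `segment_fit` or a numeric cutoff.
#' @param motif literal DNA string.
#' @return object of class `motif_enrichment`: list with `motif`, `rc_motif`,
#'   `palindromic`, `counts` (3 x 2 matrix groups x zones), `means`, `sds`,
#'   `fold_forward`, `fold_reverse`, `strong_fraction`, `n_both`, `mwu`
#'   (as [mwu_motif_test()] plus `p_underflow`).
#' @export
enrichment_summary <- function(probes, fit, motif) {
  stopifnot(is.data.frame(probes),
            all(c("core_seq", "intensity") %in% names(probes)))
  cutoff <- if (inherits(fit, "segment_fit")) fit$cutoff else as.numeric(fit)
  rc <- reverse_complement(motif)
  palindromic <- rc == motif
  fwd <- grepl(motif, probes$core_seq, fixed = TRUE)
  rev_ <- if (palindromic) rep(FALSE, nrow(probes))
          else grepl(rc, probes$core_seq, fixed = TRUE)
  n_both <- sum(fwd & rev_)
  group <- ifelse(fwd, "forward", ifelse(rev_, "reverse", "none"))
  zone <- ifelse(probes$intensity > cutoff, "steep", "tail")
  counts <- matrix(0L, nrow = 3L, ncol = 2L,
                   dimnames = list(c("forward", "reverse", "none"),
                                   c("steep", "tail")))
  tab <- table(group, zone)
  counts[rownames(tab), colnames(tab)] <- tab
  gmean <- function(g) if (any(group == g)) mean(probes$intensity[group == g]) else NA_real_
  gsd <- function(g) if (sum(group == g) > 1L) stats::sd(probes$intensity[group == g]) else NA_real_
  means <- c(forward = gmean("forward"), reverse = gmean("reverse"),
             none = gmean("none"))
  sds <- c(forward = gsd("forward"), reverse = gsd("reverse"), none = gsd("none"))
  fold_forward <- if (is.na(means["none"])) NA_real_ else unname(means["forward"] / means["none"])
  fold_reverse <- if (is.na(means["none"])) NA_real_ else unname(means["reverse"] / means["none"])
  with_motif <- group != "none"
  strong_fraction <- if (any(with_motif)) {
    sum(with_motif & zone == "steep") / sum(with_motif)
  } else NA_real_
  mwu <- if (any(with_motif) && !all(with_motif)) {
    wt <- stats::wilcox.test(probes$intensity[with_motif],
                             probes$intensity[!with_motif],
                             alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
    p <- wt$p.value
    list(statistic = unname(wt$statistic),
         p_value = max(p, 2.2e-16), p_underflow = p < 2.2e-16,
         n_motif = sum(with_motif), n_other = sum(!with_motif))
  } else NULL
  structure(
    list(motif = motif, rc_motif = rc, palindromic = palindromic,
         cutoff = cutoff, counts = counts, means = means, sds = sds,
         fold_forward = fold_forward, fold_reverse = fold_reverse,
         strong_fraction = strong_fraction, n_both = n_both, mwu = mwu),
    class = "motif_enrichment"
  )
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("Motif enrichment: %s (reverse complement %s%s)\n",
              x$motif, x$rc_motif, if (x$palindromic) ", palindromic" else ""))
  cat(sprintf("  cutoff %.4g\n", x$cutoff))
  print(x$counts)
  cat(sprintf("  mean intensity: forward %.1f, reverse %.1f, none %.1f\n",
              x$means["forward"], x$means["reverse"], x$means["none"]))
  cat(sprintf("  fold over no-motif: forward %.2f, reverse %.2f\n",
              x$fold_forward, x$fold_reverse))
  if (!is.na(x$strong_fraction)) {
    cat(sprintf("  motif-bearing probes in the strong-binding zone: %.1f%%\n",
                100 * x$strong_fraction))
  }
  if (!is.null(x$mwu)) {
    cat(sprintf("  Wilcoxon-Mann-Whitney: U = %.4g, p %s %.3g\n",
                x$mwu$statistic, if (x$mwu$p_underflow) "<" else "=",
                x$mwu$p_value))
  }
  if (x$n_both > 0L) {
    cat(sprintf("  %d probe(s) contain both strands' motifs (assigned to forward)\n",
                x$n_both))
  }
  invisible(x)
}
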