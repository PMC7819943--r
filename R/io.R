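#' Read promoter sequences from FASTA
#'
#' Record ids become gene ids (up to the first whitespace); sequences are
#' upper-cased. Duplicate ids, empty sequences, and characters outside
#' ACGTN are rejected with named errors.
#'
#' @param path FASTA file.
#' @return data.frame with `gene_id` and `sequence`.
#' @export
read_promoter_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  dup <- duplicated(ids)
  if (any(dup)) stop(sprintf("duplicate FASTA id: '%s'", ids[which(dup)[1]]),
                     call. = FALSE)
  empty <- nchar(seqs) == 0L
  if (any(empty)) stop(sprintf("empty sequence for id '%s'", ids[which(empty)[1]]),
                       call. = FALSE)
  .check_dna(seqs, "FASTA sequences")
  data.frame(gene_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data.frame with `gene_id` and `sequence`.
#' @param path output file.
#' @param width line width (default 70).
#' @export
write_promoter_fasta <- function(x, path, width = 70L) {
  stopifnot(is.data.frame(x), all(c("gene_id", "sequence") %in% names(x)))
  ss <- Biostrings::BStringSet(stats::setNames(x$sequence, x$gene_id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read an intensity table
#'
#' Tab-separated with header `probe_id  intensity [background]`.
#'
#' @param path TSV file.
#' @return data.frame with `probe_id`, `intensity` and, when present,
#'   `background`.
#' @export
read_intensity_tsv <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  .check_intensity_table(x)
  x
}

#' Write an intensity table
#' @param x intensity data.frame.
#' @param path output TSV.
#' @export
write_intensity_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Write an array design to TSV
#'
#' Columns `probe_id  gene_id  tile_index  start  end  core_seq  full_seq`,
#' with 1-based inclusive coordinates (internal coordinates are 0-based
#' half-open).
#'
#' @param design a `pbm_design`.
#' @param path output TSV.
#' @export
write_design_tsv <- function(design, path) {
  stopifnot(inherits(design, "pbm_design"))
  p <- design$probes
  out <- data.frame(probe_id = p$probe_id, gene_id = p$gene_id,
                    tile_index = p$tile_index,
                    start = p$start + 1L, end = p$end,
                    core_seq = p$core_seq, full_seq = p$full_seq,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an array design TSV written by [write_design_tsv()]
#' @param path TSV file.
#' @return data.frame with internal 0-based half-open coordinates restored.
#' @export
read_design_tsv <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  x$start <- x$start - 1L
  x
}

#' Write a ranked k-mer table to TSV
#'
#' Columns `rank  kmer  intensity_ave  occurrence_total  int_ave_x_occur_tot
#' occur_diff_pos`; intensity columns are formatted with two decimals.
#'
#' @param table a ranked `kmer_table` (see [rank_kmers()]).
#' @param path output TSV.
#' @export
write_kmer_tsv <- function(table, path) {
  stopifnot(is.data.frame(table), "kmer" %in% names(table))
  rank <- if ("rank" %in% names(table)) table$rank else seq_len(nrow(table))
  out <- data.frame(rank = rank, kmer = table$kmer,
                    intensity_ave = .fmt2(table$intensity_ave),
                    occurrence_total = table$occurrence_total,
                    int_ave_x_occur_tot = .fmt2(table$score_product),
                    occur_diff_pos = table$distinct_positions,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write a segment fit as JSON
#' @param fit a `segment_fit`.
#' @param path output JSON.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "segment_fit"))
  x <- list(steep_slope = unname(fit$steep[["slope"]]),
            steep_intercept = unname(fit$steep[["intercept"]]),
            tail_slope = unname(fit$tail[["slope"]]),
            tail_intercept = unname(fit$tail[["intercept"]]),
            breakpoint_rank = fit$breakpoint_rank,
            cutoff = fit$cutoff, n = fit$n, sse = fit$sse)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a PWM in MEME minimal motif format
#'
#' @param pwm_probs 4 x width probability matrix (rows A, C, G, T) or a
#'   `motif_cluster` with one.
#' @param name motif name.
#' @param path output file; when NULL the text is returned invisibly-printed.
#' @param nsites number of contributing sites (default 20).
#' @return the text, invisibly when written to a file.
#' @export
write_meme_motif <- function(pwm_probs, name, path = NULL, nsites = 20L) {
  if (inherits(pwm_probs, "motif_cluster")) {
    if (is.null(pwm_probs$pwm_probs)) stop("cluster has no PWM; run build_pwm()",
                                           call. = FALSE)
    nsites <- pwm_probs$n_members
    pwm_probs <- pwm_probs$pwm_probs
  }
  stopifnot(is.matrix(pwm_probs), nrow(pwm_probs) == 4L)
  if (any(abs(colSums(pwm_probs) - 1) > 1e-6)) {
    stop("PWM columns must sum to 1", call. = FALSE)
  }
  w <- ncol(pwm_probs)
  rows <- vapply(seq_len(w), function(j) {
    paste(sprintf("%.6f", pwm_probs[, j]), collapse = " ")
  }, character(1))
  txt <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           "A 0.25 C 0.25 G 0.25 T 0.25", "",
           sprintf("MOTIF %s", name),
           sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                   w, nsites),
           rows, "")
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' Read the first motif from a MEME minimal format file
#' @param path MEME file.
#' @return list with `name` and `pwm_probs` (4 x width, rows A,C,G,T).
#' @export
read_meme_motif <- function(path) {
  lines <- readLines(path)
  mi <- grep("^MOTIF ", lines)
  if (!length(mi)) stop("no MOTIF block found", call. = FALSE)
  name <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[mi[1]])
  hi <- grep("^letter-probability matrix", lines)
  hi <- hi[hi > mi[1]][1]
  if (is.na(hi)) stop("no letter-probability matrix found", call. = FALSE)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
  vals <- lines[(hi + 1):(hi + w)]
  m <- do.call(rbind, lapply(strsplit(trimws(vals), "\\s+"), as.numeric))
  pwm <- t(m)
  rownames(pwm) <- DNA_BASES
  list(name = name, pwm_probs = pwm)
}

#' Read a letter-probability matrix
#'
#' Whitespace-delimited, one row per motif position, four columns in A C G T
#' order, with an optional header row.
#'
#' @param path matrix file.
#' @return positions x 4 matrix with columns A, C, G, T.
#' @export
read_lpm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("[ACGTacgt]", strsplit(trimws(lines[1]), "\\s+")[[1]][1]) &&
      is.na(suppressWarnings(as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]][1])))) {
    lines <- lines[-1]
  }
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 4L) stop("expected 4 columns (A C G T)", call. = FALSE)
  colnames(m) <- DNA_BASES
  m
}

#' Pipeline configuration
#'
#' Validated parameter bundle for [run_pbm_pipeline()]; serialisable to JSON
#' with [write_pbm_config()] / [read_pbm_config()] (unknown keys are
#' rejected on read).
#'
#' @param k k-mer length (default 9).
#' @param sort_mode `"intensity"` or `"product"`.
#' @param min_occurrence occurrence floor for ranking (number or
#'   `"auto4x"`).
#' @param max_mismatch,core_len cluster membership parameters.
#' @param max_clusters cluster count cap.
#' @param trim_support consensus end-trimming support threshold.
#' @param min_run G/C homopolymer filter run length.
#' @param include_rc scan both strands in enrichment/scan stages.
#' @param max_rank cap on the number of ranked k-mers fed to clustering
#'   (default 2000; keeps the greedy pass quadratic-safe).
#' @param seed RNG seed recorded with the run.
#' @return list of class `pbm_config`.
#' @export
pbm_config <- function(k = 9L, sort_mode = c("intensity", "product"),
                       min_occurrence = 1, max_mismatch = 2L, core_len = 5L,
                       max_clusters = 10L, trim_support = 0.25, min_run = 4L,
                       include_rc = FALSE, max_rank = 2000L, seed = 1L) {
  sort_mode <- match.arg(sort_mode)
  structure(list(k = as.integer(k), sort_mode = sort_mode,
                 min_occurrence = min_occurrence,
                 max_mismatch = as.integer(max_mismatch),
                 core_len = as.integer(core_len),
                 max_clusters = as.integer(max_clusters),
                 trim_support = trim_support, min_run = as.integer(min_run),
                 include_rc = include_rc, max_rank = as.integer(max_rank),
                 seed = as.integer(seed)),
            class = "pbm_config")
}

#' @rdname pbm_config
#' @param config a `pbm_config`.
#' @param path JSON file.
#' @export
write_pbm_config <- function(config, path) {
  stopifnot(inherits(config, "pbm_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pbm_config
#' @export
read_pbm_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pbm_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(pbm_config, x)
}
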