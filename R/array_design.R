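#' Tile one promoter into overlapping probes
#'
#' Cuts a promoter sequence (5'→3', ending at its anchor point, e.g. the
#' translation start site) into fixed-length probes advanced by a fixed step,
#' so that consecutive probes overlap by `probe_length - step` nt. With the
#' defaults (40-nt probes, 20-nt step) a 1-kb promoter yields 49 probes.
#'
#' @param sequence one promoter sequence (character scalar, alphabet ACGTN).
#' @param gene_id gene identifier; probe ids are `<gene_id>_<tile_index>`.
#' @param probe_length probe core length in nt (default 40).
#' @param step tiling step in nt (default 20).
#' @return data.frame with columns `probe_id`, `gene_id`, `tile_index`,
#'   `start`, `end` (0-based half-open offsets within the promoter),
#'   `core_seq`, and `has_n` (TRUE when the core contains an N).
#' @examples
#' p <- tile_promoter(strrep("ACGT", 250), "Os00g0000001")
#' nrow(p)  # 49
#' @export
tile_promoter <- function(sequence, gene_id, probe_length = 40L, step = 20L) {
  stopifnot(length(sequence) == 1L, length(gene_id) == 1L,
            probe_length >= 1L, step >= 1L)
  .check_dna(sequence, sprintf("promoter '%s'", gene_id))
  L <- nchar(sequence)
  if (L < probe_length) {
    stop(sprintf("promoter '%s' (%d nt) is shorter than the probe length (%d nt)",
                 gene_id, L, probe_length), call. = FALSE)
  }
  n <- (L - probe_length) %/% step + 1L
  start <- (seq_len(n) - 1L) * as.integer(step)
  core <- substring(sequence, start + 1L, start + probe_length)
  data.frame(
    probe_id = paste0(gene_id, "_", seq_len(n)),
    gene_id = gene_id,
    tile_index = seq_len(n),
    start = start,
    end = start + as.integer(probe_length),
    core_seq = core,
    has_n = grepl("N", core, fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Design a full promoter-tiling array
#'
#' Applies [tile_promoter()] to every promoter and appends the synthesis
#' linker (a PCR primer annealing site) and a poly-T spacer to each probe
#' core, producing the full on-array sequence. Promoters shorter than 1 kb
#' are tiled with proportionally fewer probes rather than rejected.
#'
#' @param promoters data.frame with columns `gene_id` and `sequence`
#'   (optionally `anchor_class`, kept as metadata), e.g. from
#'   [read_promoter_fasta()].
#' @param probe_length,step tiling parameters, see [tile_promoter()].
#' @param linker primer linker appended 3' of the core
#'   (default `"CGGAGTCACCTAGTGCAG"`).
#' @param polyT thymidine spacer appended after the linker (default `"TTTTT"`).
#' @return an object of class `pbm_design`: a list with `probes` (data.frame
#'   as in [tile_promoter()] plus `full_seq`), `n_genes`, `probe_length`,
#'   `step`, `linker`, `polyT`.
#' @export
design_array <- function(promoters, probe_length = 40L, step = 20L,
                         linker = "CGGAGTCACCTAGTGCAG", polyT = "TTTTT") {
  if (!is.data.frame(promoters) || nrow(promoters) == 0L) {
    stop("'promoters' must be a non-empty data.frame with gene_id and sequence",
         call. = FALSE)
  }
  stopifnot(all(c("gene_id", "sequence") %in% names(promoters)))
  dup <- duplicated(promoters$gene_id)
  if (any(dup)) {
    stop(sprintf("duplicate gene_id in promoter set: '%s'",
                 promoters$gene_id[which(dup)[1]]), call. = FALSE)
  }
  .check_dna(promoters$sequence, "promoter sequences")
  L <- nchar(promoters$sequence)
  short <- L < probe_length
  if (any(short)) {
    stop(sprintf("promoter '%s' (%d nt) is shorter than the probe length (%d nt)",
                 promoters$gene_id[which(short)[1]], L[which(short)[1]],
                 probe_length), call. = FALSE)
  }
  n_tiles <- (L - probe_length) %/% as.integer(step) + 1L
  idx <- rep.int(seq_len(nrow(promoters)), n_tiles)
  tile_index <- sequence(n_tiles)
  start <- (tile_index - 1L) * as.integer(step)
  core <- substring(promoters$sequence[idx], start + 1L, start + probe_length)
  probes <- data.frame(
    probe_id = paste0(promoters$gene_id[idx], "_", tile_index),
    gene_id = promoters$gene_id[idx],
    tile_index = tile_index,
    start = start,
    end = start + as.integer(probe_length),
    core_seq = core,
    full_seq = paste0(core, linker, polyT),
    has_n = grepl("N", core, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  structure(
    list(probes = probes, n_genes = nrow(promoters),
         probe_length = as.integer(probe_length), step = as.integer(step),
         linker = linker, polyT = polyT),
    class = "pbm_design"
  )
}

#' @export
print.pbm_design <- function(x, ...) {
  cat(sprintf("Promoter-tiling PBM design: %d probes from %d genes\n",
              nrow(x$probes), x$n_genes))
  cat(sprintf("  probe length %d nt, step %d nt (overlap %d nt)\n",
              x$probe_length, x$step, x$probe_length - x$step))
  cat(sprintf("  linker %s + %s\n", x$linker, x$polyT))
  if (any(x$probes$has_n)) {
    cat(sprintf("  %d probe cores contain N (flagged)\n", sum(x$probes$has_n)))
  }
  invisible(x)
}

#' Size of the k-mer sequence space
#'
#' Number of distinct DNA k-mers, optionally merging each k-mer with its
#' reverse complement into one equivalence class (as done when designing
#' double-stranded universal arrays: 4^9 = 262,144 9-mers collapse to
#' 131,072 classes).
#'
#' @param k word length (1–16).
#' @param collapse_rc merge reverse-complement pairs into one class?
#' @return a count (numeric).
#' @examples
#' kmer_space_size(9)                      # 262144
#' kmer_space_size(9, collapse_rc = TRUE)  # 131072
#' @export
kmer_space_size <- function(k, collapse_rc = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > 16) {
    stop("'k' must be a single integer in 1..16", call. = FALSE)
  }
  total <- 4^k
  if (!collapse_rc) return(total)
  # odd k has no reverse-complement palindromes; even k has 4^(k/2) of them
  if (k %% 2 == 1) total / 2 else (total + 4^(k / 2)) / 2
}
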