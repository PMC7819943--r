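#' Configuration for the synthetic PBM simulator
#'
#' Bundles and validates the parameters of [simulate_pbm()]. The defaults
#' emulate a genome-scale promoter-tiling array: 1-kb promoters tiled into
#' 40-nt probes at a 20-nt step, a heavy-tailed log-normal background
#' intensity (meanlog 7, sdlog 1, i.e. mean ~1800 AU with a long right
#' tail), and multiplicative intensity boosts for probes whose core fully
#' contains a planted motif — which reproduces the steep-head/heavy-tail
#' shape of real rank-ordered PBM intensities.
#'
#' @param n_genes number of promoters to simulate.
#' @param motifs list of planted motifs, each a list with `sequence`
#'   (DNA string), `boost` (multiplier > 1) and `prob` (per-gene planting
#'   probability in `[0,1]`).
#' @param seed RNG seed (mandatory; every stochastic call is reproducible).
#' @param promoter_length promoter length in nt (default 1000).
#' @param probe_length,step tiling parameters (defaults 40/20).
#' @param bg_meanlog,bg_sdlog log-normal background parameters
#'   (defaults 7 and 1).
#' @param baseline additive intensity baseline in AU (default 100).
#' @param bg_quantile quantile of the null intensity distribution used as
#'   the reported background level, so roughly this fraction of unboosted
#'   probes falls at or below background (default 0.05).
#' @return a validated list of class `pbm_sim_config`.
#' @export
pbm_sim_config <- function(n_genes, motifs = list(), seed,
                           promoter_length = 1000L, probe_length = 40L,
                           step = 20L, bg_meanlog = 7, bg_sdlog = 1,
                           baseline = 100, bg_quantile = 0.05) {
  if (missing(seed)) stop("'seed' is mandatory for simulation", call. = FALSE)
  stopifnot(n_genes >= 1L, promoter_length >= probe_length,
            bg_sdlog > 0, baseline >= 0,
            bg_quantile > 0, bg_quantile < 1)
  for (m in motifs) {
    if (!all(c("sequence", "boost", "prob") %in% names(m))) {
      stop("each motif needs 'sequence', 'boost' and 'prob'", call. = FALSE)
    }
    .check_dna(m$sequence, "planted motif", allow_n = FALSE)
    if (nchar(m$sequence) > promoter_length) {
      stop(sprintf("motif '%s' is longer than the promoter", m$sequence),
           call. = FALSE)
    }
    if (m$boost <= 1) stop("motif boost multipliers must be > 1", call. = FALSE)
    if (m$prob < 0 || m$prob > 1) stop("planting probabilities must lie in [0,1]",
                                       call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), motifs = motifs,
                 seed = as.integer(seed),
                 promoter_length = as.integer(promoter_length),
                 probe_length = as.integer(probe_length),
                 step = as.integer(step),
                 bg_meanlog = bg_meanlog, bg_sdlog = bg_sdlog,
                 baseline = baseline, bg_quantile = bg_quantile),
            class = "pbm_sim_config")
}

#' Simulate a promoter-tiling PBM experiment with planted motifs
#'
#' Generates i.i.d. uniform-ACGT promoters, overwrites planted motif copies
#' at random positions with the configured per-gene probability, tiles them
#' with [design_array()], and draws probe intensities as
#' `baseline + lognormal noise x prod(boosts)` where the boost product
#' multiplies one boost factor per planted occurrence fully contained in the
#' probe core. The emitted truth record makes every downstream inference
#' testable against the generator.
#'
#' @param config a `pbm_sim_config`.
#' @return object of class `pbm_sim`: list with `promoters` (data.frame
#'   `gene_id`, `sequence`), `design` (a `pbm_design`), `intensities`
#'   (data.frame `probe_id`, `intensity`, `background`), `truth` (list:
#'   `planted` data.frame of surviving occurrences (`gene_id`, `motif`,
#'   `pos` 1-based), `probe_boost`, `probe_class` ("signal"/"background"),
#'   `background`), and the echoed `config`.
#' @export
simulate_pbm <- function(config) {
  stopifnot(inherits(config, "pbm_sim_config"))
  .with_seed(config$seed, {
    n <- config$n_genes
    L <- config$promoter_length
    chars <- sample(DNA_BASES, n * L, replace = TRUE)
    seqs <- apply(matrix(chars, nrow = L), 2L, paste, collapse = "")
    gene_id <- sprintf("SYN%06dg", seq_len(n))
    planted <- list()
    for (m in config$motifs) {
      mlen <- nchar(m$sequence)
      hit <- stats::runif(n) < m$prob
      pos <- integer(n)
      pos[hit] <- sample.int(L - mlen + 1L, sum(hit), replace = TRUE)
      for (i in which(hit)) {
        substr(seqs[i], pos[i], pos[i] + mlen - 1L) <- m$sequence
      }
      if (any(hit)) {
        planted[[length(planted) + 1L]] <- data.frame(
          gene_id = gene_id[hit], motif = m$sequence, pos = pos[hit],
          boost = m$boost, stringsAsFactors = FALSE)
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted)
               else data.frame(gene_id = character(0), motif = character(0),
                               pos = integer(0), boost = numeric(0))
    # later plantings can overwrite earlier ones: keep only surviving copies
    if (nrow(planted)) {
      seq_of <- stats::setNames(seqs, gene_id)
      ok <- vapply(seq_len(nrow(planted)), function(i) {
        p <- planted[i, ]
        substr(seq_of[[p$gene_id]], p$pos, p$pos + nchar(p$motif) - 1L) == p$motif
      }, logical(1))
      planted <- planted[ok, , drop = FALSE]
      rownames(planted) <- NULL
    }
    promoters <- data.frame(gene_id = gene_id, sequence = seqs,
                            stringsAsFactors = FALSE)
    design <- design_array(promoters, probe_length = config$probe_length,
                           step = config$step)
    pr <- design$probes
    boost <- rep(1, nrow(pr))
    if (nrow(planted)) {
      idx_by_gene <- split(seq_len(nrow(pr)), pr$gene_id)
      for (i in seq_len(nrow(planted))) {
        p <- planted[i, ]
        rows <- idx_by_gene[[p$gene_id]]
        s0 <- p$pos - 1L                       # 0-based occurrence start
        e0 <- s0 + nchar(p$motif)              # 0-based half-open end
        inside <- pr$start[rows] <= s0 & pr$end[rows] >= e0
        boost[rows[inside]] <- boost[rows[inside]] * p$boost
      }
    }
    noise <- stats::rlnorm(nrow(pr), config$bg_meanlog, config$bg_sdlog)
    intensity <- config$baseline + noise * boost
    background <- config$baseline +
      stats::qlnorm(config$bg_quantile, config$bg_meanlog, config$bg_sdlog)
    intensities <- data.frame(probe_id = pr$probe_id, intensity = intensity,
                              background = background,
                              stringsAsFactors = FALSE)
    structure(
      list(promoters = promoters, design = design, intensities = intensities,
           truth = list(planted = planted, probe_boost = boost,
                        probe_class = ifelse(boost > 1, "signal", "background"),
                        background = background),
           config = config),
      class = "pbm_sim")
  })
}

#' @export
print.pbm_sim <- function(x, ...) {
  cat(sprintf("Synthetic PBM: %d genes, %d probes, %d planted motif occurrence(s)\n",
              x$config$n_genes, nrow(x$design$probes), nrow(x$truth$planted)))
  cat(sprintf("  background level %.1f AU; %d probe(s) carry a boost\n",
              x$truth$background, sum(x$truth$probe_boost > 1)))
  invisible(x)
}
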