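#' Reverse complement of a DNA string
#'
#' Vectorised reverse complement for plain character DNA (alphabet ACGTN).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("ATTGATTG")
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

# data.table is used via :: only; declare awareness so [.data.table dispatches
.datatable.aware <- TRUE

# DNA alphabet used throughout; consensus ties break alphabetically on this order
DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s} (first offender: '%s')",
                 what, if (allow_n) ",N" else "",
                 substr(x[which(bad)[1]], 1, 60)), call. = FALSE)
  }
  invisible(TRUE)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so simulation calls do not perturb it.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer 'seed' is required", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable two-sided formatting of intensities in exported tables
.fmt2 <- function(x) formatC(x, format = "f", digits = 2)
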