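#' Drop probes at or below background
#'
#' Keeps only probes whose intensity is strictly greater than background
#' (a scalar, or a per-probe `background` column in `x`). The count and
#' mean +/- sd of the survivors are attached as attributes and shown by
#' `print`.
#'
#' @param x data.frame with columns `probe_id`, `intensity` and optionally
#'   `background`.
#' @param background scalar background intensity; required unless `x` has a
#'   `background` column.
#' @return the filtered data.frame with attributes `n`, `mean`, `sd`.
#' @export
filter_background <- function(x, background = NULL) {
  .check_intensity_table(x)
  bg <- if (!is.null(background)) background else x$background
  if (is.null(bg)) {
    stop("no background available: supply 'background' or include a background column",
         call. = FALSE)
  }
  keep <- x$intensity > bg
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- nrow(out)
  attr(out, "mean") <- mean(out$intensity)
  attr(out, "sd") <- stats::sd(out$intensity)
  out
}

.check_intensity_table <- function(x) {
  if (!is.data.frame(x) || !all(c("probe_id", "intensity") %in% names(x))) {
    stop("expected a data.frame with columns 'probe_id' and 'intensity'",
         call. = FALSE)
  }
  if (anyDuplicated(x$probe_id)) stop("duplicate probe_id", call. = FALSE)
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

# O(1) OLS of y on x over a contiguous rank range using precomputed
# cumulative sums; returns c(slope, intercept, sse)
.ols_range <- function(cs, from, to) {
  m <- to - from + 1
  s <- function(v) v[to + 1L] - v[from]
  sx <- s(cs$x); sy <- s(cs$y); sxx <- s(cs$xx); sxy <- s(cs$xy); syy <- s(cs$yy)
  cxx <- sxx - sx * sx / m
  cxy <- sxy - sx * sy / m
  cyy <- syy - sy * sy / m
  slope <- cxy / cxx
  intercept <- (sy - slope * sx) / m
  sse <- cyy - slope * cxy
  c(slope = slope, intercept = intercept, sse = max(sse, 0))
}

#' Fit a two-segment line to the rank-ordered intensity distribution
#'
#' Rank-ordered PBM intensities typically show a steep left slope (specific
#' binders) followed by a long, nearly flat right tail (background binding).
#' Intensities are sorted in decreasing order, x = rank (1-based), y =
#' intensity, and two independent ordinary-least-squares lines y = a x + b
#' are fitted on either side of a breakpoint chosen by exhaustive grid search
#' minimising the summed squared error. The strong-binding cutoff is the
#' extrapolated y-intercept of the tail line (b2).
#'
#' @param x data.frame with `probe_id` and `intensity` (typically the output
#'   of [filter_background()]).
#' @param min_points minimum number of entries required (default 100).
#' @param min_segment minimum points per segment (default 50).
#' @param break_range admissible breakpoint range as fractions of the number
#'   of ranks (default `c(0.001, 0.5)`).
#' @param max_candidates cap on the number of candidate breakpoints; when the
#'   admissible range holds more ranks than this, every s-th rank is tried
#'   (default 1e4).
#' @param keep_data keep the sorted ranks/intensities in the object so that
#'   `plot()` and `residuals()` work (default TRUE).
#' @return an object of class `segment_fit` with components `steep`
#'   (`slope`, `intercept`), `tail` (`slope`, `intercept`),
#'   `breakpoint_rank`, `cutoff` (= tail intercept), `n`, `sse`.
#' @seealso [select_strong_probes()]
#' @export
fit_rank_segments <- function(x, min_points = 100L, min_segment = 50L,
                              break_range = c(0.001, 0.5),
                              max_candidates = 1e4, keep_data = TRUE) {
  .check_intensity_table(x)
  n <- nrow(x)
  if (n < min_points) {
    stop(sprintf("need at least %d above-background probes, got %d",
                 min_points, n), call. = FALSE)
  }
  ord <- order(-x$intensity, x$probe_id)  # stable: ties by probe_id
  y <- x$intensity[ord]
  if (max(y) == min(y)) {
    stop("degenerate input: all intensities are identical; no rank structure to fit",
         call. = FALSE)
  }
  r <- as.numeric(seq_len(n))
  cs <- list(x = c(0, cumsum(r)), y = c(0, cumsum(y)),
             xx = c(0, cumsum(r * r)), xy = c(0, cumsum(r * y)),
             yy = c(0, cumsum(y * y)))
  lo <- max(min_segment, ceiling(break_range[1] * n))
  hi <- min(n - min_segment, floor(break_range[2] * n))
  if (lo > hi) stop("no admissible breakpoint: input too small for the segment constraints",
                    call. = FALSE)
  stride <- max(1L, ceiling((hi - lo + 1) / max_candidates))
  cand <- seq.int(lo, hi, by = stride)
  best <- NULL
  best_sse <- Inf
  for (b in cand) {
    f1 <- .ols_range(cs, 1L, b)
    f2 <- .ols_range(cs, b + 1L, n)
    sse <- f1[["sse"]] + f2[["sse"]]
    if (sse < best_sse) {  # ties keep the smallest breakpoint
      best_sse <- sse
      best <- list(b = b, f1 = f1, f2 = f2)
    }
  }
  fit <- structure(
    list(
      steep = c(slope = best$f1[["slope"]], intercept = best$f1[["intercept"]]),
      tail = c(slope = best$f2[["slope"]], intercept = best$f2[["intercept"]]),
      breakpoint_rank = best$b,
      cutoff = best$f2[["intercept"]],
      n = n,
      sse = best_sse,
      candidates = length(cand),
      stride = stride
    ),
    class = "segment_fit"
  )
  if (keep_data) {
    fit$data <- data.frame(rank = seq_len(n), intensity = y,
                           probe_id = x$probe_id[ord],
                           stringsAsFactors = FALSE)
  }
  fit
}

#' @export
print.segment_fit <- function(x, ...) {
  cat("Two-segment rank-intensity fit\n")
  cat(sprintf("  steep region: y = %.4g x + %.6g (ranks 1..%d)\n",
              x$steep[["slope"]], x$steep[["intercept"]], x$breakpoint_rank))
  cat(sprintf("  tail region : y = %.4g x + %.6g (ranks %d..%d)\n",
              x$tail[["slope"]], x$tail[["intercept"]],
              x$breakpoint_rank + 1L, x$n))
  cat(sprintf("  strong-binding cutoff (tail intercept): %.6g\n", x$cutoff))
  invisible(x)
}

#' @export
coef.segment_fit <- function(object, ...) {
  c(steep_slope = unname(object$steep[["slope"]]),
    steep_intercept = unname(object$steep[["intercept"]]),
    tail_slope = unname(object$tail[["slope"]]),
    tail_intercept = unname(object$tail[["intercept"]]))
}

#' Predicted intensity at given ranks
#' @param object a `segment_fit`.
#' @param rank ranks (1-based) at which to evaluate the piecewise line.
#' @param ... unused.
#' @export
predict.segment_fit <- function(object, rank, ...) {
  if (missing(rank)) rank <- seq_len(object$n)
  steep <- rank <= object$breakpoint_rank
  ifelse(steep,
         object$steep[["slope"]] * rank + object$steep[["intercept"]],
         object$tail[["slope"]] * rank + object$tail[["intercept"]])
}

#' @export
residuals.segment_fit <- function(object, ...) {
  if (is.null(object$data)) stop("fit was made with keep_data = FALSE", call. = FALSE)
  object$data$intensity - predict(object, object$data$rank)
}

#' @export
summary.segment_fit <- function(object, ...) {
  out <- c(coef(object),
           breakpoint_rank = object$breakpoint_rank,
           cutoff = object$cutoff, n = object$n, sse = object$sse)
  class(out) <- "summary.segment_fit"
  out
}

#' @export
print.summary.segment_fit <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @export
plot.segment_fit <- function(x, log = "", ...) {
  if (is.null(x$data)) stop("fit was made with keep_data = FALSE", call. = FALSE)
  graphics::plot(x$data$rank, x$data$intensity, pch = ".", col = "grey40",
                 xlab = "rank", ylab = "intensity", log = log, ...)
  b <- x$breakpoint_rank
  graphics::lines(1:b, predict(x, 1:b), col = "red3", lwd = 2)
  graphics::lines((b + 1):x$n, predict(x, (b + 1):x$n), col = "blue3", lwd = 2)
  graphics::abline(h = x$cutoff, lty = 2)
  invisible(x)
}

#' Select strong-binding probes above the fitted cutoff
#'
#' @param x intensity data.frame (same table the fit was computed on).
#' @param fit a `segment_fit`, or a numeric cutoff.
#' @return the subset with intensity strictly above the cutoff, ordered by
#'   decreasing intensity (ties by probe_id); attribute `n` carries the count.
#' @export
select_strong_probes <- function(x, fit) {
  .check_intensity_table(x)
  cutoff <- if (inherits(fit, "segment_fit")) fit$cutoff else as.numeric(fit)
  out <- x[x$intensity > cutoff, , drop = FALSE]
  out <- out[order(-out$intensity, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "n") <- nrow(out)
  out
}
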