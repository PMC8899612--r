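#' @importFrom stats median rbinom rlnorm rnorm rpois runif setNames dnorm pnorm
#' @importFrom utils head tail combn
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic region
#'
#' A region is a 0-based half-open interval `[start, end)` on a contig, the
#' internal coordinate convention used throughout the package.  On-disk
#' formats (GFF3, VCF, BED) use their standard dialects; see
#' [coord_to_disk()].
#'
#' @param contig Contig identifier.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param label Optional region label.
#' @return A list of class `"region"`.
#' @export
region <- function(contig, start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || end <= start)
    stop("region must satisfy start < end (0-based half-open); got [",
         start, ", ", end, ")")
  structure(list(contig = contig, start = start, end = end, label = label),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s:[%d, %d) %s (%d bp)\n", x$contig, x$start, x$end,
              if (nzchar(x$label)) x$label else "", x$end - x$start))
  invisible(x)
}

region_length <- function(r) r$end - r$start

#' Convert between internal and on-disk coordinates
#'
#' Internal coordinates are 0-based half-open; GFF3/VCF are 1-based
#' inclusive.  The two functions are inverses of each other.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
coord_to_disk <- function(start, end) list(start = start + 1L, end = end)

#' @rdname coord_to_disk
#' @export
coord_to_memory <- function(start, end) list(start = start - 1L, end = end)

## Derive a per-stage RNG seed from the master seed so each simulation stage
## has its own reproducible stream.  Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 48271 + h) %% 2147483647
}

set_stage_seed <- function(seed, stage) set.seed(stage_seed(seed, stage))

## round() with R's banker's rounding is unsuitable for reproducing printed
## tables; use half-up rounding at reporting time.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
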