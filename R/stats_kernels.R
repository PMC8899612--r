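## Self-contained statistics used across the pipeline: GC skew profiling and
## its scatter statistic, the exact Mann-Whitney U test, and Nei-Gojobori
## (1986-style) dN/dS with Jukes-Cantor correction.

#' GC skew profile of a sequence
#'
#' Computes `(G - C) / (G + C)` in sliding windows.  On a correctly assembled
#' circular bacterial chromosome the skew sign switches exactly twice, at the
#' replication origin and terminus; regions where the sign flips erratically
#' ("scattered" skew) are one diagnostic of scrapyard islands.
#'
#' @param seq A [Biostrings::DNAString], character scalar, or an
#'   [annotated_genome()] (first contig used).
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @param circular If `TRUE`, windows wrap around the origin and every
#'   position starts a window (`L / step` windows); otherwise only complete
#'   windows are used.
#' @return A data frame of class `"skew_profile"` with columns `start`
#'   (0-based window start), `skew` and `sign` (+1/-1/0; 0 also for windows
#'   with no G or C), plus attributes `window`, `step`, `length`.
#' @export
gc_skew_profile <- function(seq, window = 10000L, step = window,
                            circular = TRUE) {
  if (inherits(seq, "annotated_genome")) {
    circular <- unname(seq$circular[1L])
    seq <- seq$seq[[1L]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  L <- length(seq)
  if (L == 0L) stop("empty sequence")
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (window > L) stop("window exceeds sequence length")
  if (circular) {
    starts0 <- seq.int(0L, L - 1L, by = step)
    ext <- Biostrings::xscat(seq, Biostrings::subseq(seq, 1L, window - 1L))
    v <- Biostrings::Views(ext, start = starts0 + 1L, width = window)
  } else {
    starts0 <- seq.int(0L, L - window, by = step)
    v <- Biostrings::Views(seq, start = starts0 + 1L, width = window)
  }
  gc <- Biostrings::letterFrequency(v, c("G", "C"))
  tot <- gc[, 1L] + gc[, 2L]
  skew <- ifelse(tot == 0, 0, (gc[, 1L] - gc[, 2L]) / pmax(tot, 1L))
  out <- data.frame(start = starts0, skew = skew, sign = sign(skew))
  class(out) <- c("skew_profile", "data.frame")
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "length") <- L
  out
}

#' Skew scatter (adjacent sign-flip fraction) of a region
#'
#' Operationalizes "scattered GC skew": among adjacent window pairs whose
#' skew signs are both nonzero, the fraction whose signs differ.  A clean
#' replichore structure gives values near 0 inside a replichore; a region
#' whose flip fraction greatly exceeds the genome-wide background is flagged
#' as scattered.
#'
#' @param profile A `"skew_profile"` from [gc_skew_profile()].
#' @param reg A [region()]; only windows fully inside are used.  Must cover
#'   at least 3 windows.
#' @param scatter_factor Region is flagged scattered when its flip fraction
#'   is at least this multiple of the genome background (default 2).
#' @return List with `flip_fraction` (region), `background` (whole profile),
#'   `scattered` (logical) and `n_windows`.
#' @export
skew_scatter <- function(profile, reg, scatter_factor = 2) {
  window <- attr(profile, "window")
  flip_frac <- function(sgn) {
    a <- sgn[-length(sgn)]; b <- sgn[-1L]
    ok <- a != 0 & b != 0
    if (!any(ok)) return(0)
    mean(a[ok] != b[ok])
  }
  inside <- profile$start >= reg$start & (profile$start + window) <= reg$end
  if (sum(inside) < 3L)
    stop("region covers fewer than 3 complete windows")
  ff <- flip_frac(profile$sign[inside])
  bg <- flip_frac(profile$sign)
  list(flip_fraction = ff, background = bg,
       scattered = bg > 0 && ff >= scatter_factor * bg,
       n_windows = sum(inside))
}

#' Mann-Whitney U test (exact for small untied samples)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test.  When there are no ties
#' and `m + n <= max_exact`, the p-value is exact, by enumeration of all
#' `choose(m + n, m)` group labelings of the pooled sample.  Otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used, matching the conventional default behaviour of
#' rank-sum tests in standard statistical software.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param max_exact Largest pooled size for the enumeration branch.
#' @return List with `U` (statistic for group `a`), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal-approximation"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))$p   # 0.1
#' @export
mann_whitney_exact <- function(a, b, max_exact = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(c(a, b))) stop("missing values not allowed")
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && N <= max_exact) {
    combs <- combn(N, m)
    Us <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(r)
    sigma2 <- (m * n / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal-approximation"
  }
  list(U = U, p = p, method = method)
}

## --- NG86 dN/dS ------------------------------------------------------------

codon_split <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0) stop("coding sequence length not divisible by 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

aa_of <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

## Fraction of the three possible changes at each codon position that are
## synonymous, summed over positions: the number of synonymous sites of the
## codon.  Changes to stop codons count as nonsynonymous.
syn_sites_of_codon <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- aa_of(codon)
  s <- 0
  for (i in 1:3) {
    for (bse in setdiff(bases, substring(codon, i, i))) {
      mut <- codon
      substring(mut, i, i) <- bse
      if (identical(aa_of(mut), aa0) && aa_of(mut) != "*") s <- s + 1 / 3
    }
  }
  s
}

SYN_SITES <- local({
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setNames(vapply(codons, syn_sites_of_codon, numeric(1)), codons)
})

## Average synonymous/nonsynonymous differences between two codons over all
## minimal mutational pathways; pathways passing through a stop codon are
## excluded (unless all do).
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(nd = 0, sd = 0))
  perms <- if (d == 1L) list(pos) else if (d == 2L)
    list(pos, rev(pos)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) pos[o])
  paths <- lapply(perms, function(ord) {
    cur <- c1
    nd <- 0; sd <- 0; valid <- TRUE
    for (i in ord) {
      nxt <- cur
      substring(nxt, i, i) <- substring(c2, i, i)
      if (aa_of(nxt) == "*") valid <- FALSE
      if (aa_of(nxt) == aa_of(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd, valid = as.numeric(valid))
  })
  pm <- do.call(rbind, paths)
  use <- pm[, "valid"] == 1
  if (!any(use)) use <- rep(TRUE, nrow(pm))
  c(nd = mean(pm[use, "nd"]), sd = mean(pm[use, "sd"]))
}

#' Nei-Gojobori dN/dS between two in-frame coding sequences
#'
#' Counting-method dN/dS: synonymous and nonsynonymous site counts are
#' averaged over the two sequences; observed differences in codons that
#' differ at more than one position are averaged over all minimal mutational
#' pathways (pathways through stop codons excluded); the Jukes-Cantor
#' correction `d = -(3/4) log(1 - (4/3) p)` is applied to both proportions.
#' A ratio near or below ~0.3-0.4 indicates purifying selection, the regime
#' reported for conserved diguanylate cyclases disrupted by mobile elements.
#'
#' @param seq_a,seq_b Equal-length, gap-free, in-frame coding sequences
#'   (character or `DNAString`), without internal stop codons.
#' @return List with `N`, `S` (site counts), `Nd`, `Sd` (differences), `pN`,
#'   `pS`, `dN`, `dS` and `dnds` (`NA` when undefined: `dS = 0` or a
#'   saturated correction).
#' @export
dnds_ng86 <- function(seq_a, seq_b) {
  ca <- codon_split(seq_a); cb <- codon_split(seq_b)
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  if (any(!c(ca, cb) %in% names(SYN_SITES)))
    stop("sequences must contain only A/C/G/T")
  internal <- seq_len(length(ca) - 1L)
  if (any(aa_of(ca[internal]) == "*") || any(aa_of(cb[internal]) == "*"))
    stop("internal stop codon")
  drop_stop <- aa_of(ca) == "*" | aa_of(cb) == "*"
  ca <- ca[!drop_stop]; cb <- cb[!drop_stop]
  S <- (sum(SYN_SITES[ca]) + sum(SYN_SITES[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(codon_path_diffs, ca, cb)
  Nd <- sum(diffs["nd", ]); Sd <- sum(diffs["sd", ])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dN <- jc(pN); dS <- jc(pS)
  dnds <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = dN, dS = dS, dnds = dnds)
}
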