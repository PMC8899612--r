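test_that("GC skew follows the direct-count definition", {
  expect_equal(gc_skew_profile("GGGGCC", window = 6, circular = FALSE)$skew,
               (4 - 2) / (4 + 2))
  p <- gc_skew_profile("ATATAT", window = 6, circular = FALSE)
  expect_equal(p$skew, 0)
  expect_equal(p$sign, 0)
  expect_error(gc_skew_profile("", window = 1), "empty")
  expect_error(gc_skew_profile("ACGT", window = 10, circular = FALSE),
               "window")
})

test_that("a constructed two-replichore circular genome has exactly 2 sign changes", {
  set.seed(1)
  half <- function(pG) paste(sample(c("A", "T", "G", "C"), 50000,
                                    replace = TRUE,
                                    prob = c(0.23, 0.23, pG, 0.54 - pG)),
                             collapse = "")
  geno <- paste0(half(0.36), half(0.18))   # G-rich then C-rich
  p <- gc_skew_profile(geno, window = 5000, step = 1000, circular = TRUE)
  expect_equal(nrow(p), 100000 / 1000)
  sgn <- p$sign[p$sign != 0]
  flips <- sum(sgn != c(sgn[-1], sgn[1]))  # circular adjacency
  expect_equal(flips, 2)
})

test_that("reverse complementing a circular sequence negates the skew profile", {
  set.seed(2)
  geno <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  p1 <- gc_skew_profile(geno, window = 2000, step = 2000, circular = TRUE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(geno)))
  p2 <- gc_skew_profile(rc, window = 2000, step = 2000, circular = TRUE)
  expect_equal(sort(p2$skew), sort(-p1$skew), tolerance = 1e-12)
})

test_that("skew scatter is 0 for constant signs, 1 for alternating, ~0.5 for iid", {
  mk_prof <- function(signs, window = 10L) {
    p <- data.frame(start = seq.int(0L, by = window,
                                    length.out = length(signs)),
                    skew = signs * 0.1, sign = signs)
    class(p) <- c("skew_profile", "data.frame")
    attr(p, "window") <- window
    attr(p, "step") <- window
    p
  }
  reg <- function(n, window = 10L) region("x", 0L, n * window)
  const <- mk_prof(rep(1, 50))
  expect_equal(skew_scatter(const, reg(50))$flip_fraction, 0)
  alt <- mk_prof(rep(c(1, -1), 25))
  expect_equal(skew_scatter(alt, reg(50))$flip_fraction, 1)
  set.seed(3)
  iid <- mk_prof(sample(c(-1, 1), 1000, replace = TRUE))
  ff <- skew_scatter(iid, reg(1000))$flip_fraction
  expect_lt(abs(ff - 0.5), 3 * sqrt(0.25 / 999))
  expect_error(skew_scatter(const, region("x", 0L, 15L)), "fewer than 3")
})

test_that("Mann-Whitney exact branch matches full-enumeration results", {
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))$p, 2 / 20)
  r <- mann_whitney_exact(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$p, 1)
  ## symmetry
  a <- c(0.3, 1.2, 5); b <- c(0.7, 2.2, 9, 11)
  expect_equal(mann_whitney_exact(a, b)$p, mann_whitney_exact(b, a)$p)
  ## complete separation minimizes p for fixed sizes
  sep <- mann_whitney_exact(1:4, 11:14)$p
  mixed <- mann_whitney_exact(c(1, 3, 12, 13), c(2, 4, 11, 14))$p
  expect_lt(sep, mixed)
  expect_error(mann_whitney_exact(numeric(), 1:3), "non-empty")
})

test_that("exact branch agrees with the rank-sum reference for all group sizes <= 6", {
  set.seed(7)
  for (m in 1:6) {
    for (n in 1:6) {
      for (rep in 1:3) {
        a <- sample(seq(1, 1000), m)
        b <- sample(setdiff(seq(1, 1000), a), n)
        ours <- mann_whitney_exact(a, b)
        ref <- wilcox.test(a, b, exact = TRUE)
        expect_equal(ours$method, "exact")
        expect_equal(ours$p, ref$p.value, tolerance = 1e-12,
                     label = sprintf("m=%d n=%d", m, n))
      }
    }
  }
})

test_that("tie-corrected normal approximation matches the reference default", {
  set.seed(8)
  for (rep in 1:10) {
    a <- sample(1:8, 12, replace = TRUE)   # ties guaranteed
    b <- sample(1:8, 15, replace = TRUE)
    ours <- mann_whitney_exact(a, b)
    ref <- suppressWarnings(wilcox.test(a, b))
    expect_equal(ours$method, "normal-approximation")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("published island-content contrasts reproduce the reported p-values", {
  sy <- ferrovum_island_counts()
  sc <- sy[sy$region == "scrapyard" & sy$genome != "S2.4alt", ]
  out <- sy[sy$region == "outside", ]
  ## adaptive-function ("rest of ORF") percent: exact test
  p_rest <- mann_whitney_exact(sc$functional_pct_printed,
                               out$functional_pct_printed)
  expect_equal(p_rest$method, "exact")
  expect_equal(round(p_rest$p, 3), 0.008)
  ## HP percent: a tie forces the approximation
  p_hp <- mann_whitney_exact(sc$hp_pct_printed, out$hp_pct_printed)
  expect_equal(p_hp$method, "normal-approximation")
  expect_equal(round(p_hp$p, 3), 0.012)
  ## ME density per 10 kbp: exact test
  p_me <- mann_whitney_exact(sc$me_dens_printed, out$me_dens_printed)
  expect_equal(p_me$method, "exact")
  expect_equal(round(p_me$p, 3), 0.016)
})

test_that("NG86 handles degenerate inputs and validates frames", {
  d <- dnds_ng86("ATGAAA", "ATGAAA")
  expect_equal(d$pN, 0); expect_equal(d$pS, 0)
  expect_true(is.na(d$dnds))
  ## only nonsynonymous differences: dS = 0, ratio undefined
  d2 <- dnds_ng86("ATGATT", "ATGCTT")   # I -> L at a nonsyn site
  expect_gt(d2$Nd, 0); expect_equal(d2$Sd, 0)
  expect_true(is.na(d2$dnds))
  expect_error(dnds_ng86("ATGAA", "ATGAA"), "divisible by 3")
  expect_error(dnds_ng86("ATGAAA", "ATG"), "equal length")
  expect_error(dnds_ng86("ATGTAAAAA", "ATGTAAAAA"), "stop")
})

test_that("NG86 matches the brute-force codon-pathway oracle", {
  set.seed(11)
  for (rep in 1:5) {
    a <- random_cds(200)
    b <- a
    ## plant substitutions, some at synonymous third positions
    idx <- sample(nchar(a), 10)
    for (i in idx) {
      substr(b, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, i, i)), 1)
    }
    if (any(Biostrings::GENETIC_CODE[
      substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))] == "*")) next
    ours <- dnds_ng86(a, b)
    orc <- ng86_oracle(a, b)
    for (f in c("N", "S", "Nd", "Sd", "pN", "pS"))
      expect_equal(ours[[f]], orc[[f]], tolerance = 1e-9, label = f)
    if (!is.na(orc$dN)) expect_equal(ours$dN, orc$dN, tolerance = 1e-9)
    if (!is.na(orc$dS)) expect_equal(ours$dS, orc$dS, tolerance = 1e-9)
  }
})

test_that("NG86 site counts conserve N + S and are order-invariant", {
  set.seed(12)
  a <- random_cds(100)
  b <- random_cds(100)
  d <- dnds_ng86(a, b)
  expect_equal(d$N + d$S, 300)
  ## identical codon permutation applied to both sequences
  ord <- sample(100)
  perm <- function(x) paste(substring(x, (ord - 1) * 3 + 1, ord * 3),
                            collapse = "")
  d2 <- dnds_ng86(perm(a), perm(b))
  expect_equal(d$pN, d2$pN, tolerance = 1e-12)
  expect_equal(d$pS, d2$pS, tolerance = 1e-12)
})
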