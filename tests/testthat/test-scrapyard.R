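## feature table with category counts planted at known start positions
mk_region_features <- function(counts, reg, offset_out = NULL,
                               counts_out = NULL) {
  build <- function(counts, lo, hi, prefix) {
    cats <- rep(names(counts), counts)
    n <- length(cats)
    starts <- as.integer(seq(lo, hi - 200L, length.out = n))
    data.frame(id = paste0(prefix, seq_len(n)), contig = "g",
               start = starts, end = starts + 150L, strand = "+",
               type = "CDS", product = "x", category = cats,
               stringsAsFactors = FALSE)
  }
  f <- build(counts, reg$start, reg$end, "in")
  if (!is.null(counts_out))
    f <- rbind(f, build(counts_out, offset_out[1], offset_out[2], "out"))
  f
}

test_that("region content statistics reproduce the characterized island row", {
  reg <- region("g", 32353L, 226193L, "scrapyard")
  counts <- c(HP = 175L, PHAGE = 9L, ME = 22L, FUNCTIONAL = 38L)
  feats <- mk_region_features(counts, reg,
                              offset_out = c(300000L, 2749106L),
                              counts_out = c(HP = 1026L, PHAGE = 13L,
                                             ME = 116L, FUNCTIONAL = 1592L))
  v <- data.frame(contig = "g",
                  pos = c(as.integer(seq(32400, 226000, length.out = 231)),
                          as.integer(seq(300000, 2749000,
                                         length.out = 452))))
  st <- region_content_stats(feats, v, reg, 2749106L)
  expect_equal(st$inside$orf_total, 244L)
  expect_equal(round(st$inside$hp_pct, 1), 71.7)
  expect_equal(round(st$inside$hp_dens, 2), 9.03)
  expect_equal(round(st$inside$me_pct, 2), 9.02)
  expect_equal(round(st$inside$ssv_dens, 1), 11.9)
  expect_equal(st$inside$functional_count, 38L)
  expect_equal(round(st$outside$ssv_dens, 2), 1.77)
  ## start-position rule at the boundary
  b <- feats[1, ]; b$id <- "edge"; b$start <- reg$start - 1L
  b$end <- b$start + 150L
  st2 <- region_content_stats(rbind(feats, b), v, reg, 2749106L)
  expect_equal(st2$inside$orf_total, 244L)
  expect_equal(st2$outside$orf_total, 2747L + 1L)
  ## empty region
  st3 <- region_content_stats(feats[0, ], v[0, ], reg, 2749106L)
  expect_equal(st3$inside$orf_total, 0L)
  expect_equal(st3$inside$hp_pct, 0)
  expect_equal(st3$inside$hp_dens, 0)
})

test_that("every published percent and density value is reproduced", {
  tab <- ferrovum_island_counts()
  tol_of <- function(x) {
    dp <- nchar(sub("^[^.]*\\.?", "", as.character(x)))
    0.55 * 10^(-dp)
  }
  for (i in seq_len(nrow(tab))) {
    st <- stats_from_row(tab[i, ])
    for (m in c("hp", "phage", "me", "functional")) {
      printed_pct <- tab[i, paste0(m, "_pct_printed")]
      printed_dens <- tab[i, paste0(m, "_dens_printed")]
      lbl <- paste(tab$genome[i], tab$region[i], m)
      expect_lt(abs(st[[paste0(m, "_pct")]] - printed_pct),
                tol_of(printed_pct), label = paste(lbl, "pct"))
      expect_lt(abs(st[[paste0(m, "_dens")]] - printed_dens),
                tol_of(printed_dens), label = paste(lbl, "dens"))
    }
    if (!is.na(tab$ssv_dens_printed[i]))
      expect_lt(abs(st$ssv_dens - tab$ssv_dens_printed[i]),
                tol_of(tab$ssv_dens_printed[i]))
  }
})

test_that("enrichment ratios reproduce the published fold values", {
  folds <- sapply(c("MI1A", "MI1I", "OL2a6", "S2.4"), function(g) {
    er <- enrichment_ratios(stats_from_row(island_row(g, "scrapyard")),
                            stats_from_row(island_row(g, "outside")))
    ssv <- er[er$metric == "SSV", ]
    c(fold = ssv$fold, inside = ssv$direction == "inside")
  })
  expect_equal(round(folds["fold", c("MI1A", "MI1I", "OL2a6")], 1),
               c(MI1A = 6.7, MI1I = 5.2, OL2a6 = 2.8))
  expect_true(all(folds["inside", c("MI1A", "MI1I", "OL2a6")] == 1))
  expect_equal(unname(round(folds["fold", "S2.4"], 1)), 6.1)
  expect_false(unname(folds["inside", "S2.4"]) == 1)
  ## gene-category percent folds span the published ranges
  rng <- sapply(c("MI1A", "MI1I", "MI1III", "S2.4", "OL2a6"), function(g) {
    er <- enrichment_ratios(stats_from_row(island_row(g, "scrapyard")),
                            stats_from_row(island_row(g, "outside")))
    c(hp = er$fold[er$metric == "HP"], me = er$fold[er$metric == "ME"],
      fn = er$fold[er$metric == "FUNCTIONAL"])
  })
  expect_equal(round(range(rng["hp", ]), 1), c(1.8, 1.9))
  expect_equal(round(range(rng["me", ]), 1), c(1.6, 2.5))
  expect_equal(round(range(rng["fn", ]), 1), c(1.8, 3.7))
  ## degenerate cases
  eq <- enrichment_ratios(stats_from_row(island_row("MI1A", "scrapyard")),
                          stats_from_row(island_row("MI1A", "scrapyard")))
  expect_true(all(eq$fold == 1))
  expect_true(all(eq$direction == "none"))
})

test_that("anchor delimitation is exclusive of both anchors and validates inputs", {
  feats <- data.frame(
    id = c("a", "g1", "b"), contig = "g",
    start = c(900L, 2000L, 5000L), end = c(1000L, 2500L, 5085L),
    strand = "+", type = c("tRNA", "CDS", "tRNA"),
    product = c("tRNA-Ser-CGA", "x", "tRNA-Val-CAC"),
    stringsAsFactors = FALSE)
  feats$category <- classify_gene_category(feats$product, feats$type)
  reg <- delimit_by_anchors(feats, "tRNA-Ser-CGA", "tRNA-Val-CAC")
  expect_equal(c(reg$start, reg$end), c(1000L, 5000L))
  expect_equal(region_length(reg), 4000L)
  expect_error(delimit_by_anchors(feats, "tRNA-Leu-TAA", "tRNA-Val-CAC"),
               "tRNA-Leu-TAA")
  ## duplicated right anchor at equal distance: ambiguous
  dup <- feats[3, ]; dup$id <- "b2"
  dup$start <- 1000L + (5000L - 1000L); dup$end <- dup$start + 85L
  f2 <- rbind(feats, dup,
              within(feats[1, ], { id <- "a2"; start <- 8900L; end <- 9000L }))
  expect_error(delimit_by_anchors(f2, "tRNA-Ser-CGA", "tRNA-Val-CAC"),
               "ambiguous|candidate")
})

test_that("inside and outside statistics conserve genome-wide totals", {
  s <- shared_sim()
  feats <- s$pop$genome$features
  v <- s$pop$truth$ssv
  st <- region_content_stats(feats, v, s$pop$truth$scrapyard,
                             s$cfg$genome_length)
  cds <- feats[feats$type == "CDS", ]
  for (m in c("hp", "phage", "me", "functional")) {
    cat <- toupper(sub("functional", "FUNCTIONAL", m))
    expect_equal(st$inside[[paste0(m, "_count")]] +
                   st$outside[[paste0(m, "_count")]],
                 sum(cds$category == cat), label = m)
  }
  expect_equal(st$inside$ssv_count + st$outside$ssv_count, nrow(v))
  expect_equal(st$inside$orf_total + st$outside$orf_total, nrow(cds))
  ## percent/density consistency
  expect_equal(st$inside$hp_count,
               round(st$inside$hp_pct * st$inside$orf_total / 100))
  expect_equal(st$inside$hp_dens * st$inside$length_bp / 1e4,
               st$inside$hp_count)
})

test_that("a planted 150 kbp island is recovered with Jaccard >= 0.9", {
  cfg <- sim_config(seed = 3L, genome_length = 600000L, insertions = NULL)
  pop <- simulate_population(simulate_genome(cfg))
  skew <- gc_skew_profile(pop$genome)
  det <- detect_scrapyards(pop$genome, variants = pop$truth$ssv, skew = skew)
  expect_equal(length(det), 1L)
  expect_gte(jaccard_region(det[[1]], pop$truth$scrapyard), 0.9)
  ## per-island stats attached
  st <- attr(det[[1]], "stats")
  expect_gt(st$inside$hp_pct, st$outside$hp_pct)
})

test_that("a compositionally uniform genome yields no islands", {
  cfg <- sim_config(seed = 4L, genome_length = 300000L, scrapyard = NULL,
                    insertions = NULL)
  pop <- simulate_population(simulate_genome(cfg))
  det <- detect_scrapyards(pop$genome, variants = pop$truth$ssv,
                           skew = gc_skew_profile(pop$genome))
  expect_equal(length(det), 0L)
})

test_that("islands separated by more than the merge gap stay separate", {
  set.seed(41)
  L <- 600000L
  seqs <- Biostrings::DNAStringSet(setNames(paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "g"))
  isl <- list(c(100000L, 200000L), c(340000L, 440000L))
  starts <- seq.int(500L, L - 1500L, by = 700L)
  in_isl <- vapply(starts, function(s)
    any(vapply(isl, function(r) s >= r[1] && s < r[2], logical(1))),
    logical(1))
  cat <- ifelse(in_isl,
                sample(c("HP", "ME", "PHAGE", "FUNCTIONAL"), length(starts),
                       TRUE, prob = c(0.72, 0.12, 0.04, 0.12)),
                sample(c("HP", "FUNCTIONAL"), length(starts), TRUE,
                       prob = c(0.37, 0.63)))
  feats <- data.frame(id = paste0("g", seq_along(starts)), contig = "g",
                      start = starts, end = starts + 600L, strand = "+",
                      type = "CDS", product = "x", category = cat,
                      stringsAsFactors = FALSE)
  genome <- annotated_genome(seqs, feats)
  ## SSVs at the characterized densities: 11.9/10 kbp inside, 1.77 outside
  pos_in <- sort(unlist(lapply(isl, function(r)
    r[1] + sample.int(r[2] - r[1], round(11.9e-4 * (r[2] - r[1]))))))
  pos_out <- sort(sample.int(L, round(1.77e-4 * L)))
  v <- data.frame(contig = "g", pos = as.integer(c(pos_in, pos_out)))
  det <- detect_scrapyards(genome, variants = v)
  expect_equal(length(det), 2L)
  expect_gte(jaccard_region(det[[1]], region("g", isl[[1]][1], isl[[1]][2])),
             0.8)
  expect_gte(jaccard_region(det[[2]], region("g", isl[[2]][1], isl[[2]][2])),
             0.8)
  ## relaxing the HP threshold never shrinks island coverage
  covered <- function(d) sum(vapply(d, region_length, integer(1)))
  det_relaxed <- detect_scrapyards(genome, variants = v, hp_min = 0.45)
  expect_gte(covered(det_relaxed), covered(det))
})
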