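test_that("insertion signals follow CIGAR arithmetic and length gates", {
  aln <- rbind(
    aln_row("a", 500L, "100M900I100M", strrep("A", 1100)),
    aln_row("b", 500L, "100M8I100M", strrep("A", 208)),
    aln_row("c", 700L, "400S60M", strrep("C", 460)),
    aln_row("d", 700L, "60M400S", strrep("G", 460)))
  aln$seq[1] <- paste0(strrep("A", 100), strrep("T", 900), strrep("A", 100))
  sig <- collect_insertion_signals(aln, min_read_len = 100L)
  expect_equal(sig$kind[sig$qname == "a"], "cigar-insertion")
  expect_equal(sig$breakpoint[sig$qname == "a"], 600L)
  expect_equal(sig$length[sig$qname == "a"], 900L)
  expect_equal(sig$seq[sig$qname == "a"], strrep("T", 900))
  expect_false("b" %in% sig$qname)          # 8 bp < min length 10
  expect_equal(sig$kind[sig$qname == "c"], "left-clip")
  expect_equal(sig$breakpoint[sig$qname == "c"], 700L)
  expect_equal(sig$kind[sig$qname == "d"], "right-clip")
  expect_equal(sig$breakpoint[sig$qname == "d"], 760L)
  ## the short-read length gate removes everything
  expect_equal(nrow(collect_insertion_signals(aln, min_read_len = 5000L)), 0L)
})

## build a locus with n_ins insertion-bearing and n_span clean reads
mk_locus <- function(n_ins, n_span, ins_len = 200L) {
  ins_seq <- paste(sample(c("A", "C", "G", "T"), ins_len, replace = TRUE),
                   collapse = "")
  reads <- list()
  for (i in seq_len(n_ins))
    reads[[length(reads) + 1L]] <- aln_row(
      paste0("ins", i), 1000L, sprintf("500M%dI500M", ins_len),
      paste0(strrep("A", 500), ins_seq, strrep("A", 500)))
  for (i in seq_len(n_span))
    reads[[length(reads) + 1L]] <- aln_row(
      paste0("span", i), 1000L, "1000M", strrep("A", 1000))
  do.call(rbind, reads)
}

test_that("clustering applies the two-read minor-variant rule", {
  set.seed(31)
  aln <- mk_locus(4L, 6L)
  calls <- cluster_and_call(collect_insertion_signals(aln), aln)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$supporting, 4L)
  expect_equal(calls$spanning, 6L)
  expect_equal(calls$variability, "variable")
  expect_equal(calls$breakpoint, 1500L)
  ## single supporting read: no call at the default support threshold
  aln1 <- mk_locus(1L, 9L)
  expect_equal(nrow(cluster_and_call(collect_insertion_signals(aln1), aln1)),
               0L)
  ## the minor variant can also be the intact allele
  aln2 <- mk_locus(10L, 1L)
  calls2 <- cluster_and_call(collect_insertion_signals(aln2), aln2)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$variability, "possibly-non-variable")
  ## empty input
  expect_equal(nrow(cluster_and_call(
    collect_insertion_signals(aln1[0, ]), aln1[0, ])), 0L)
})

test_that("local-alignment scoring agrees with a quadratic DP oracle", {
  set.seed(32)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  for (rep in 1:4) {
    a <- rnd(80); b <- rnd(160)
    ## embed a mutated copy of a's middle into b
    core <- substr(a, 21, 60)
    b <- paste0(substr(b, 1, 60), core, substr(b, 61, 160))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    expect_equal(Biostrings::score(al), sw_score(a, b), label = "SW score")
  }
})

test_that("library classification accepts true elements and rejects noise", {
  set.seed(33)
  lib <- Biostrings::DNAStringSet(c(
    ISx = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")))
  exact <- data.frame(contig = "chr", breakpoint = 10L,
                      consensus = as.character(lib[[1]]),
                      stringsAsFactors = FALSE)
  cl <- classify_insertion(exact, lib)
  expect_equal(cl$classification, "ME:ISx")
  ## reverse-complement hit
  rc <- exact
  rc$consensus <- as.character(Biostrings::reverseComplement(lib[[1]]))
  expect_equal(classify_insertion(rc, lib)$classification, "ME:ISx")
  ## random sequence: no hit
  noise <- exact
  noise$consensus <- paste(sample(c("A", "C", "G", "T"), 1000,
                                  replace = TRUE), collapse = "")
  expect_equal(classify_insertion(noise, lib)$classification, "UNKNOWN")
  ## ~85% identity over ~60% of the consensus passes the 0.8/0.5 gates
  frag <- strsplit(substr(as.character(lib[[1]]), 1, 600), "")[[1]]
  mut <- sample(600, 90)
  frag[mut] <- vapply(frag[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  partial <- exact
  partial$consensus <- paste0(paste(frag, collapse = ""),
                              paste(sample(c("A", "C", "G", "T"), 400,
                                           replace = TRUE), collapse = ""))
  cp <- classify_insertion(partial, lib)
  expect_equal(cp$classification, "ME:ISx")
  expect_gte(cp$class_identity, 0.8)
})

test_that("disruption classes follow the inclusion/exclusion rules", {
  feats <- data.frame(
    id = c("dgc", "hyp", "tnp", "phg"),
    contig = "chr",
    start = c(100L, 1000L, 2000L, 3000L),
    end = c(600L, 1500L, 2500L, 3500L),
    strand = "+", type = "CDS",
    product = c("diguanylate cyclase/phosphodiesterase",
                "hypothetical protein", "IS5 family transposase",
                "phage portal protein"),
    stringsAsFactors = FALSE)
  feats$category <- classify_gene_category(feats$product)
  calls <- data.frame(contig = "chr",
                      breakpoint = c(300L, 1200L, 2200L, 3200L, 800L),
                      stringsAsFactors = FALSE)
  out <- assign_disruption(calls, feats)
  expect_equal(out$disruption,
               c("FUNCTIONAL-GENE", "HP", "ME/PHAGE", "ME/PHAGE",
                 "INTERGENIC"))
  expect_equal(out$disrupted_feature, c("dgc", "hyp", "tnp", "phg", NA))
})

test_that("planted insertions are recovered with correct breakpoints and elements", {
  s <- shared_sim()
  calls <- shared_calls()
  sc <- score_insertion_calls(calls, s$pop$truth$insertions, tol = 20L)
  expect_equal(sc$recall, 1)
  expect_equal(sc$false_positives, 0L)
  expect_true(all(sc$correct_class))
})

test_that("insertion-free simulations yield zero calls", {
  cfg <- sim_config(seed = 23L, genome_length = 60000L, insertions = NULL,
                    short_coverage = 1)
  pop <- simulate_population(simulate_genome(cfg))
  reads <- simulate_reads(pop)
  calls <- cluster_and_call(collect_insertion_signals(reads$long),
                            reads$long)
  expect_equal(nrow(calls), 0L)
})

test_that("variability flag matches the carrier/non-carrier predicate on error-free reads", {
  cfg <- sim_config(seed = 24L, genome_length = 80000L,
                    long_error = c(sub = 0, ins = 0, del = 0),
                    short_coverage = 1)
  pop <- simulate_population(simulate_genome(cfg))
  reads <- simulate_reads(pop)
  calls <- cluster_and_call(collect_insertion_signals(reads$long),
                            reads$long)
  truth <- pop$truth$insertions
  H <- cfg$n_haplotypes
  for (i in seq_len(nrow(calls))) {
    j <- which.min(abs(truth$breakpoint - calls$breakpoint[i]))
    expect_equal(calls$variability[i] == "variable",
                 min(calls$supporting[i], calls$spanning[i]) >= 2L)
    ## supporting/spanning counts are consistent with the planted frequency
    est <- calls$supporting[i] /
      (calls$supporting[i] + calls$spanning[i])
    expect_lt(abs(est - truth$freq[j]),
              4 * sqrt(truth$freq[j] * (1 - truth$freq[j]) /
                         (calls$supporting[i] + calls$spanning[i])) + 0.05)
  }
})

test_that("junction genotyping formats and counts follow the report conventions", {
  set.seed(35)
  s <- shared_sim()
  genome <- s$pop$genome
  bp <- 60000L
  elem <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  call <- list(breakpoint = bp, consensus = elem)
  ref <- genome$seq[[1]]
  intact_read <- as.character(Biostrings::subseq(ref, bp - 100L, bp + 100L))
  left_read <- paste0(as.character(Biostrings::subseq(ref, bp - 100L, bp)),
                      substr(elem, 1, 100))
  right_read <- paste0(substr(elem, 201, 300),
                       as.character(Biostrings::subseq(ref, bp + 1L,
                                                       bp + 100L)))
  reads114 <- Biostrings::DNAStringSet(rep(intact_read, 114))
  g <- genotype_junctions(call, reads114, genome)
  expect_equal(g$formatted, "n (0/114)")
  expect_equal(g$y, 0L); expect_equal(g$n, 114L)
  mixed <- Biostrings::DNAStringSet(c(rep(left_read, 32),
                                      rep(right_read, 32),
                                      rep(intact_read, 100)))
  g2 <- genotype_junctions(call, mixed, genome)
  expect_equal(g2$y, 32L); expect_equal(g2$n, 100L)
  expect_equal(c(g2$y_left, g2$y_right), c(32L, 32L))
  expect_equal(g2$ratio, 0.32)
  expect_equal(g2$formatted, "y/n = 0.32")
  ## orientation invariance
  g3 <- genotype_junctions(call, Biostrings::reverseComplement(mixed),
                           genome)
  expect_equal(c(g3$y, g3$n), c(g2$y, g2$n))
  ## no coverage at all
  far <- Biostrings::DNAStringSet(strrep("A", 200))
  expect_error(genotype_junctions(call, far, genome), "coverage")
})

test_that("disruption ratio estimates f/(1-f) from deep short reads", {
  cfg <- sim_config(
    seed = 25L, genome_length = 50000L,
    insertions = data.frame(element = "ISFm1", target = "FUNCTIONAL",
                            frequency = 0.3, stringsAsFactors = FALSE),
    long_coverage = 5, short_coverage = 200)
  pop <- simulate_population(simulate_genome(cfg))
  reads <- simulate_reads(pop)
  truth <- pop$truth$insertions
  call <- list(breakpoint = truth$breakpoint[1], consensus = truth$payload[1])
  g <- genotype_junctions(call, reads$short$aln, pop$genome)
  f_hat <- g$y / (g$y + g$n)
  f <- truth$freq[1]
  expect_lt(abs(f_hat - f), 3 * sqrt(f * (1 - f) / (g$y + g$n)))
})
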