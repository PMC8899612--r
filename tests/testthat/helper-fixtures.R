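## Shared fixtures, built once per test run, and independent oracles used by
## the property tests.

.fixture_env <- new.env(parent = emptyenv())

## default-conditions simulation (scrapyard + 5 planted insertions, 20
## haplotypes, 20x long / 50x short coverage) on a 120 kbp genome
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 42L, genome_length = 120000L)
    s <- simulate_genome(cfg)
    pop <- simulate_population(s)
    reads <- simulate_reads(pop)
    .fixture_env$sim <- list(cfg = cfg, pop = pop, reads = reads)
  }
  .fixture_env$sim
}

## shared insertion calls derived from the shared simulation
shared_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    s <- shared_sim()
    sig <- collect_insertion_signals(s$reads$long)
    cl <- cluster_and_call(sig, s$reads$long)
    cl <- classify_insertion(cl, s$pop$elements)
    .fixture_env$calls <- assign_disruption(cl, s$pop$genome$features)
  }
  .fixture_env$calls
}

## on-disk dataset + pipeline config used by the orchestration tests
pipeline_fixture_dir <- function() {
  if (is.null(.fixture_env$pipe_dir)) {
    d <- file.path(tempdir(), "intrapop_pipe_fixture")
    cfg <- sim_config(seed = 17L, genome_length = 80000L,
                      long_coverage = 15, short_coverage = 25)
    simulate_dataset(cfg, d)
    .fixture_env$pipe_dir <- d
  }
  .fixture_env$pipe_dir
}

pipe_cfg <- function(d, out) {
  pipeline_config(
    genome_fasta = file.path(d, "genome.fasta"),
    annotations_gff3 = file.path(d, "genes.gff3"),
    long_sam = file.path(d, "truth_long.sam"),
    short_sam = file.path(d, "truth_short.sam"),
    me_library_fasta = file.path(d, "elements.fasta"),
    out_dir = out)
}

## published island characterization rows keyed by genome/region
island_row <- function(genome, region_label) {
  tab <- ferrovum_island_counts()
  tab[tab$genome == genome & tab$region == region_label, , drop = FALSE]
}

stats_from_row <- function(r) {
  region_stats_row(r$genome,
                   c(HP = r$hp_count, PHAGE = r$phage_count, ME = r$me_count,
                     FUNCTIONAL = r$functional_count),
                   r$ssv_count, r$length_bp, orf_total = r$orf_total)
}

## all orderings of a vector (for the codon-pathway oracle)
perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  out
}

## Brute-force NG86 oracle: explicit enumeration of codon mutational
## pathways, written independently of the package implementation.
ng86_oracle <- function(a, b) {
  gc_tab <- Biostrings::GENETIC_CODE
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(a); cb <- split3(b)
  syn_sites <- function(cd) {
    s <- 0
    for (i in 1:3) {
      for (nb in setdiff(c("A", "C", "G", "T"), substr(cd, i, i))) {
        m <- cd; substr(m, i, i) <- nb
        if (gc_tab[[m]] != "*" && gc_tab[[m]] == gc_tab[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }
  S <- (sum(vapply(ca, syn_sites, 0)) + sum(vapply(cb, syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  Nd <- 0; Sd <- 0
  for (j in seq_along(ca)) {
    pos <- which(strsplit(ca[j], "")[[1]] != strsplit(cb[j], "")[[1]])
    if (!length(pos)) next
    rows <- NULL
    for (ord in perms_of(pos)) {
      cur <- ca[j]; nd <- 0; sd <- 0; ok <- TRUE
      for (i in ord) {
        nxt <- cur; substr(nxt, i, i) <- substr(cb[j], i, i)
        if (gc_tab[[nxt]] == "*") ok <- FALSE
        if (gc_tab[[nxt]] == gc_tab[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      rows <- rbind(rows, c(nd, sd, ok))
    }
    use <- rows[, 3] == 1
    if (!any(use)) use <- rep(TRUE, nrow(rows))
    Nd <- Nd + mean(rows[use, 1]); Sd <- Sd + mean(rows[use, 2])
  }
  pN <- Nd / N; pS <- Sd / S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = jc(pN), dS = jc(pS))
}

## random stop-free in-frame coding sequence
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  ok <- names(gc_tab)[gc_tab != "*"]
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

## tiny hand-built alignment row
aln_row <- function(qname, pos, cigar, seq, flag = 0L, contig = "chr") {
  data.frame(qname = qname, flag = flag, contig = contig, pos = pos,
             mapq = 60L, cigar = cigar, seq = seq,
             qual = strrep("I", nchar(seq)), stringsAsFactors = FALSE)
}

## Smith-Waterman local alignment score, quadratic DP (oracle for the
## library-classification alignment scoring)
sw_score <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                     gap_ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - gap_open - gap_ext)
      F_[i, j] <- max(F_[i - 1, j] - gap_ext, H[i - 1, j] - gap_open - gap_ext)
      sc <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F_[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}
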