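## Read simulation over the haplotype pool.  Reads are sampled uniformly
## across haplotypes (so a variant's read support is proportional to its
## carrier fraction) and carry simple error models: long reads get
## substitution/1-bp-insertion/1-bp-deletion errors folded into their truth
## CIGAR, short paired reads get substitution errors only.  The truth
## alignment of every read to the *reference* is emitted SAM-style, with
## planted element insertions exposed as I operations (or soft clips for
## boundary-overlapping reads).

BASES <- c("A", "C", "G", "T")

## substitute bases at rate e; replacement always differs from the original
inject_substitutions <- function(seqs, e) {
  if (e <= 0 || !length(seqs)) return(seqs)
  big <- paste(seqs, collapse = "")
  chars <- strsplit(big, "")[[1L]]
  idx <- which(runif(length(chars)) < e)
  if (length(idx)) {
    old <- match(chars[idx], BASES)
    new <- ((old - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
    ok <- !is.na(old)
    chars[idx[ok]] <- BASES[new[ok]]
  }
  big <- paste(chars, collapse = "")
  ends <- cumsum(nchar(seqs))
  substring(big, c(1L, head(ends, -1L) + 1L), ends)
}

## Fold per-base substitution/insertion/deletion errors into one read and
## its CIGAR, keeping the CIGAR/SEQ length contract intact.
apply_long_errors <- function(seq_chr, cigar, rates) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  cols <- rep(ops, lens)
  qcols <- which(cols %in% c("S", "M", "I"))
  qchars <- strsplit(seq_chr, "")[[1L]]
  stopifnot(length(qchars) == length(qcols))
  nq <- length(qcols)
  ## substitutions
  sub_i <- which(runif(nq) < rates[["sub"]])
  if (length(sub_i)) {
    old <- match(qchars[sub_i], BASES)
    new <- ((old - 1L + sample.int(3L, length(sub_i), replace = TRUE)) %% 4L) + 1L
    qchars[sub_i[!is.na(old)]] <- BASES[new[!is.na(old)]]
  }
  ## 1 bp deletion errors on interior M columns
  m_q <- which(cols[qcols] == "M")
  m_q <- m_q[m_q > 1L & m_q < nq]
  del_i <- m_q[runif(length(m_q)) < rates[["del"]]]
  ## 1 bp insertion errors after interior M columns
  ins_after <- m_q[runif(length(m_q)) < rates[["ins"]]]
  base_by_col <- rep(NA_character_, length(cols))
  base_by_col[qcols] <- qchars
  op_new <- cols
  if (length(del_i)) {
    op_new[qcols[del_i]] <- "D"
    base_by_col[qcols[del_i]] <- NA_character_
  }
  key <- as.numeric(seq_along(cols))
  if (length(ins_after)) {
    key <- c(key, qcols[ins_after] + 0.5)
    op_new <- c(op_new, rep("I", length(ins_after)))
    base_by_col <- c(base_by_col, sample(BASES, length(ins_after),
                                         replace = TRUE))
  }
  o <- order(key)
  op_new <- op_new[o]; base_by_col <- base_by_col[o]
  r <- rle(op_new)
  list(seq = paste(base_by_col[!is.na(base_by_col)], collapse = ""),
       cigar = paste0(r$lengths, r$values, collapse = ""))
}

#' Simulate long and short reads from a haplotype population
#'
#' @param pop A `"sim_population"` from [simulate_population()].
#' @param config A [sim_config()] (defaults to the one inside `pop`).
#' @return List of class `"sim_reads"` with
#'   \describe{
#'     \item{long}{alignment data frame (truth SAM columns: `qname`, `flag`,
#'       `contig`, `pos`, `mapq`, `cigar`, `seq`, `qual`) plus provenance
#'       columns `hap`, `hap_start`.}
#'     \item{short}{list with `aln` (both mates, truth SAM columns) and
#'       `r1`/`r2` (`DNAStringSet` of physical reads, reverse-strand mates
#'       reverse-complemented as a sequencer would emit them).}
#'     \item{contig_lengths}{named vector for SAM headers.}
#'   }
#' @export
simulate_reads <- function(pop, config = pop$config) {
  L <- genome_length(pop$genome)
  contig <- names(pop$genome$seq)[1L]
  H <- length(pop$haplotypes)
  hap_len <- Biostrings::width(pop$haplotypes)

  hap_chr <- vapply(seq_len(H), function(h)
    as.character(pop$haplotypes[[h]]), character(1L))

  ## ---- long reads ----
  set_stage_seed(config$seed, "reads_long")
  target <- config$long_coverage * L
  mu <- log(config$long_mean_length) - config$long_sdlog^2 / 2
  n_guess <- ceiling(target / config$long_mean_length * 1.5) + 10L
  rl <- pmax(config$long_min_length,
             as.integer(round(rlnorm(n_guess, mu, config$long_sdlog))))
  n_long <- which(cumsum(rl) >= target)[1L]
  if (is.na(n_long)) n_long <- n_guess
  rl <- rl[seq_len(n_long)]
  hap <- sample.int(H, n_long, replace = TRUE)
  rl <- pmin(rl, hap_len[hap])
  start <- as.integer(floor(runif(n_long) * (hap_len[hap] - rl + 1)))
  flag <- ifelse(runif(n_long) < 0.5, 0L, 16L)
  raw_seq <- substring(hap_chr[hap], start + 1L, start + rl)
  pos <- integer(n_long); cig <- character(n_long)
  seqs <- character(n_long); ok <- logical(n_long)
  for (i in seq_len(n_long)) {
    proj <- project_read(pop$hap_maps[[hap[i]]], start[i], start[i] + rl[i])
    if (is.null(proj)) next
    err <- apply_long_errors(raw_seq[i], proj$cigar, config$long_error)
    pos[i] <- proj$pos; cig[i] <- err$cigar; seqs[i] <- err$seq
    ok[i] <- TRUE
  }
  long_aln <- data.frame(
    qname = sprintf("long_%06d", which(ok)), flag = flag[ok],
    contig = contig, pos = pos[ok], mapq = 60L, cigar = cig[ok],
    seq = seqs[ok], qual = strrep("I", nchar(seqs[ok])),
    hap = hap[ok], hap_start = start[ok], stringsAsFactors = FALSE)

  ## ---- short paired reads ----
  set_stage_seed(config$seed, "reads_short")
  len <- config$short_length
  n_frag <- ceiling(config$short_coverage * L / (2 * len))
  hap <- sample.int(H, n_frag, replace = TRUE)
  isize <- pmax(len, as.integer(round(rnorm(n_frag, config$short_insert_mean,
                                            config$short_insert_sd))))
  isize <- pmin(isize, hap_len[hap])
  fstart <- as.integer(floor(runif(n_frag) * (hap_len[hap] - isize + 1)))
  s1 <- fstart; e1 <- pmin(s1 + len, s1 + isize)
  e2 <- fstart + isize; s2 <- pmax(s1, e2 - len)
  r1_seq <- inject_substitutions(substring(hap_chr[hap], s1 + 1L, e1),
                                 config$short_error)
  r2_seq <- inject_substitutions(substring(hap_chr[hap], s2 + 1L, e2),
                                 config$short_error)
  project_batch <- function(sv, ev) {
    pos <- integer(n_frag); cig <- character(n_frag); ok <- logical(n_frag)
    for (i in seq_len(n_frag)) {
      p <- project_read(pop$hap_maps[[hap[i]]], sv[i], ev[i])
      if (is.null(p)) next
      pos[i] <- p$pos; cig[i] <- p$cigar; ok[i] <- TRUE
    }
    list(pos = pos, cigar = cig, ok = ok)
  }
  p1 <- project_batch(s1, e1)
  p2 <- project_batch(s2, e2)
  a1 <- data.frame(qname = sprintf("frag_%06d/1", which(p1$ok)), flag = 0L,
                   contig = contig, pos = p1$pos[p1$ok], mapq = 60L,
                   cigar = p1$cigar[p1$ok], seq = r1_seq[p1$ok],
                   stringsAsFactors = FALSE)
  a2 <- data.frame(qname = sprintf("frag_%06d/2", which(p2$ok)), flag = 16L,
                   contig = contig, pos = p2$pos[p2$ok], mapq = 60L,
                   cigar = p2$cigar[p2$ok], seq = r2_seq[p2$ok],
                   stringsAsFactors = FALSE)
  short_aln <- rbind(a1, a2)
  short_aln$qual <- strrep("I", nchar(short_aln$seq))
  ## physical reads: reverse-strand mate is emitted reverse-complemented
  r1 <- Biostrings::DNAStringSet(r1_seq)
  names(r1) <- sprintf("frag_%06d/1", seq_len(n_frag))
  r2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(r2_seq))
  names(r2) <- sprintf("frag_%06d/2", seq_len(n_frag))

  structure(list(long = long_aln,
                 short = list(aln = short_aln, r1 = r1, r2 = r2),
                 contig_lengths = setNames(L, contig)),
            class = "sim_reads")
}

#' Simulate a complete dataset and write it to disk
#'
#' Runs [simulate_genome()], [simulate_population()] and [simulate_reads()]
#' and writes the standard file bundle: `genome.fasta`, `genes.gff3`,
#' `elements.fasta`, `haplotypes.fasta`, `long.fastq`,
#' `short_R1.fastq`/`short_R2.fastq`, `truth_long.sam`, `truth_short.sam`,
#' `truth_ssv.vcf`, `truth_insertions.tsv` and `truth_regions.bed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `pop`, `reads` and the file `paths`.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  pop <- simulate_population(sim)
  reads <- simulate_reads(pop)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(pop$genome$seq, p("genome.fasta"))
  write_features(pop$genome$features, p("genes.gff3"))
  Biostrings::writeXStringSet(pop$elements, p("elements.fasta"))
  Biostrings::writeXStringSet(pop$haplotypes, p("haplotypes.fasta"))
  write_fastq_df(reads$long, p("long.fastq"))
  write_fastq_set(reads$short$r1, p("short_R1.fastq"))
  write_fastq_set(reads$short$r2, p("short_R2.fastq"))
  write_alignments(reads$long, p("truth_long.sam"), reads$contig_lengths)
  write_alignments(reads$short$aln, p("truth_short.sam"),
                   reads$contig_lengths)
  write_truth_ssv_vcf(pop$truth$ssv, p("truth_ssv.vcf"))
  utils::write.table(pop$truth$insertions[, setdiff(
    names(pop$truth$insertions), "payload")], p("truth_insertions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  regs <- list()
  if (!is.null(pop$truth$scrapyard)) regs <- list(pop$truth$scrapyard)
  write_regions_bed(regs, p("truth_regions.bed"))
  invisible(list(pop = pop, reads = reads,
                 paths = vapply(c("genome.fasta", "genes.gff3",
                                  "elements.fasta", "haplotypes.fasta",
                                  "long.fastq", "short_R1.fastq",
                                  "short_R2.fastq", "truth_long.sam",
                                  "truth_short.sam", "truth_ssv.vcf",
                                  "truth_insertions.tsv",
                                  "truth_regions.bed"), p, character(1L))))
}

## FASTQ writers: flag-16 truth records are emitted reverse-complemented, as
## the sequencer would have produced them.
write_fastq_df <- function(aln, path) {
  seqs <- Biostrings::DNAStringSet(aln$seq)
  rev <- bitwAnd(aln$flag, 16L) > 0L
  seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
  names(seqs) <- aln$qname
  write_fastq_set(seqs, path)
}

write_fastq_set <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(seqs), "\n", as.character(seqs), "\n+\n",
                    strrep("I", Biostrings::width(seqs))), con)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ file.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

write_truth_ssv_vcf <- function(ssv, path) {
  write_vcf_variants(
    data.frame(contig = ssv$contig, pos = ssv$pos, ref = ssv$ref,
               alt = ssv$alt, depth = NA_integer_, alt_support = NA_integer_,
               alt_fraction = ssv$freq, stringsAsFactors = FALSE),
    path)
}
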