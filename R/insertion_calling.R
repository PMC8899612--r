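## Polymorphic mobile-element insertion calling from long reads: extract
## per-read insertion signals (long CIGAR I operations and large soft
## clips), cluster them into candidate insertion sites, count supporting vs
## spanning reads, classify the inserted consensus against an IS element
## library, assign gene-disruption status, and genotype disruption ratios
## from short reads via junction-spanning matches.

#' Collect per-read insertion signals from long-read alignments
#'
#' Every CIGAR insertion of at least `min_len` bp yields a signal at its
#' reference anchor (the base before which the insertion occurs); soft clips
#' of at least `min_clip` bp yield clip signals at the aligned end, since an
#' insertion near a read boundary manifests as a clip rather than an I
#' operation.  Reads shorter than `min_read_len` are ignored.
#'
#' @param aln Long-read alignment data frame.
#' @param min_len Minimum CIGAR insertion length (default 10).
#' @param min_clip Minimum soft-clip length (default 100).
#' @param min_read_len Minimum read length (default 1000).
#' @return Data frame with `qname`, `contig`, `breakpoint` (0-based), `kind`
#'   (`cigar-insertion`, `left-clip`, `right-clip`), `seq`, `length`.
#' @export
collect_insertion_signals <- function(aln, min_len = 10L, min_clip = 100L,
                                      min_read_len = 1000L) {
  empty <- data.frame(qname = character(), contig = character(),
                      breakpoint = integer(), kind = character(),
                      seq = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(aln)) return(empty)
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    aln$cigar, after.soft.clipping = FALSE)
  aln <- aln[qlen >= min_read_len, , drop = FALSE]
  if (!nrow(aln)) return(empty)
  reads <- Biostrings::DNAStringSet(aln$seq)
  out <- list()

  rr_i <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos + 1L, ops = "I")
  qr_i <- GenomicAlignments::cigarRangesAlongQuerySpace(aln$cigar, ops = "I")
  n_i <- S4Vectors::elementNROWS(rr_i)
  if (sum(n_i)) {
    ridx <- rep(seq_len(nrow(aln)), n_i)
    rri <- unlist(rr_i, use.names = FALSE)
    qri <- unlist(qr_i, use.names = FALSE)
    big <- IRanges::width(qri) >= min_len
    if (any(big)) {
      out$ins <- data.frame(
        qname = aln$qname[ridx][big], contig = aln$contig[ridx][big],
        breakpoint = IRanges::start(rri)[big] - 1L,
        kind = "cigar-insertion",
        seq = as.character(Biostrings::subseq(
          reads[ridx][big], start = IRanges::start(qri)[big],
          end = IRanges::end(qri)[big])),
        length = IRanges::width(qri)[big], stringsAsFactors = FALSE)
    }
  }

  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  first_op <- vapply(ops, `[`, "", 1L)
  first_len <- vapply(lens, `[`, 0L, 1L)
  last_op <- vapply(ops, function(x) x[length(x)], "")
  last_len <- vapply(lens, function(x) x[length(x)], 0L)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  lc <- first_op == "S" & first_len >= min_clip
  if (any(lc)) {
    out$left <- data.frame(
      qname = aln$qname[lc], contig = aln$contig[lc],
      breakpoint = aln$pos[lc], kind = "left-clip",
      seq = as.character(Biostrings::subseq(reads[lc], 1L, first_len[lc])),
      length = first_len[lc], stringsAsFactors = FALSE)
  }
  rc <- last_op == "S" & last_len >= min_clip
  if (any(rc)) {
    qw <- nchar(aln$seq[rc])
    out$right <- data.frame(
      qname = aln$qname[rc], contig = aln$contig[rc],
      breakpoint = aln$pos[rc] + refw[rc], kind = "right-clip",
      seq = as.character(Biostrings::subseq(reads[rc], qw - last_len[rc] + 1L,
                                            qw)),
      length = last_len[rc], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res <- res[order(res$contig, res$breakpoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## medoid of a set of sequences under edit distance
medoid_seq <- function(seqs, cap = 30L) {
  if (!length(seqs)) return("")
  if (length(seqs) == 1L) return(seqs)
  if (length(seqs) > cap) seqs <- seqs[seq_len(cap)]
  d <- utils::adist(seqs)
  seqs[which.min(rowSums(d))]
}

#' Cluster insertion signals into insertion calls
#'
#' Signals are clustered by breakpoint proximity (single linkage, gap
#' threshold `cluster_window`).  For each cluster: supporting reads are the
#' distinct reads contributing signals; spanning reads are the distinct
#' reads that cover `breakpoint +/- margin` on the reference without any
#' signal there (the intact-allele evidence); the consensus inserted
#' sequence is the medoid by edit distance of the insertion-bearing
#' segments.  A call is variable when at least two reads support each of the
#' two alleles, i.e. `min(supporting, spanning) >= 2`; calls with fewer than
#' `min_support` supporting reads are not emitted.
#'
#' @param signals Output of [collect_insertion_signals()].
#' @param aln The long-read alignment data frame the signals came from.
#' @param cluster_window Breakpoint clustering gap in bp (default 100).
#' @param margin Spanning-read margin around the breakpoint (default 50).
#' @param min_support Minimum supporting reads (default 2).
#' @return Data frame of calls sorted by contig and breakpoint: `contig`,
#'   `breakpoint`, `consensus`, `length`, `supporting`, `spanning`,
#'   `variability` (`variable` / `possibly-non-variable`).
#' @export
cluster_and_call <- function(signals, aln, cluster_window = 100L,
                             margin = 50L, min_support = 2L) {
  empty <- data.frame(contig = character(), breakpoint = integer(),
                      consensus = character(), length = integer(),
                      supporting = integer(), spanning = integer(),
                      variability = character(), stringsAsFactors = FALSE)
  if (!nrow(signals)) return(empty)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  calls <- list()
  for (ct in unique(signals$contig)) {
    sg <- signals[signals$contig == ct, , drop = FALSE]
    sg <- sg[order(sg$breakpoint), , drop = FALSE]
    cl <- cumsum(c(1L, as.integer(diff(sg$breakpoint) > cluster_window)))
    ct_aln <- aln$contig == ct
    for (k in unique(cl)) {
      s <- sg[cl == k, , drop = FALSE]
      bp <- as.integer(round(median(s$breakpoint)))
      supp_reads <- unique(s$qname)
      covers <- ct_aln & aln$pos <= max(0L, bp - margin) &
        (aln$pos + refw) >= bp + margin
      span_reads <- setdiff(unique(aln$qname[covers]), supp_reads)
      ins_seqs <- s$seq[s$kind == "cigar-insertion"]
      if (!length(ins_seqs)) ins_seqs <- s$seq
      consensus <- medoid_seq(ins_seqs)
      supporting <- length(supp_reads); spanning <- length(span_reads)
      if (supporting < min_support) next
      calls[[length(calls) + 1L]] <- data.frame(
        contig = ct, breakpoint = bp, consensus = consensus,
        length = nchar(consensus), supporting = supporting,
        spanning = spanning,
        variability = if (min(supporting, spanning) >= 2L) "variable" else
          "possibly-non-variable",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  res <- do.call(rbind, calls)
  res <- res[order(res$contig, res$breakpoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## identity/coverage of the best local alignment of x against one subject
local_hit <- function(x, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), subject, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  nm <- Biostrings::nmatch(al); nmm <- Biostrings::nmismatch(al)
  cols <- nm + nmm
  list(score = Biostrings::score(al),
       identity = if (cols > 0) nm / cols else 0,
       coverage = cols / nchar(x))
}

#' Classify inserted consensus sequences against an element library
#'
#' Best local alignment of each call's consensus against every library
#' element (both strands).  A call is classified `ME:<element>` when the
#' best hit reaches `min_identity` over aligned columns and covers at least
#' `min_cov` of the consensus length; otherwise `UNKNOWN`.
#'
#' @param calls Data frame from [cluster_and_call()].
#' @param library A named [Biostrings::DNAStringSet] of element sequences.
#' @param min_identity Minimum identity over aligned columns (default 0.8).
#' @param min_cov Minimum consensus coverage (default 0.5).
#' @return `calls` with added columns `classification` and `class_identity`.
#' @export
classify_insertion <- function(calls, library, min_identity = 0.8,
                               min_cov = 0.5) {
  if (!length(library)) stop("empty element library")
  lib2 <- c(library, Biostrings::reverseComplement(library))
  names(lib2) <- c(names(library), names(library))
  cls <- character(nrow(calls)); idn <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    x <- calls$consensus[i]
    if (!nzchar(x)) {
      warning("call at ", calls$breakpoint[i], " has empty consensus")
      cls[i] <- "UNKNOWN"; idn[i] <- NA_real_
      next
    }
    best <- NULL; best_name <- NA_character_
    for (j in seq_along(lib2)) {
      h <- local_hit(x, lib2[[j]])
      if (is.null(best) || h$score > best$score) {
        best <- h; best_name <- names(lib2)[j]
      }
    }
    ok <- best$identity >= min_identity && best$coverage >= min_cov
    cls[i] <- if (ok) paste0("ME:", best_name) else "UNKNOWN"
    idn[i] <- best$identity
  }
  calls$classification <- cls
  calls$class_identity <- idn
  calls
}

#' Assign gene-disruption status to insertion calls
#'
#' A breakpoint inside a functionally annotated protein-coding gene is a
#' `FUNCTIONAL-GENE` disruption (counted in headline disruption totals); one
#' inside a hypothetical protein is `HP` (reported separately); one inside a
#' mobile-element or phage ORF is `ME/PHAGE` (excluded from totals, as
#' disruptions of selfish elements); anything else is `INTERGENIC`
#' (excluded).
#'
#' @param calls Data frame of insertion calls.
#' @param features Feature data frame with categories.
#' @return `calls` with added `disrupted_feature` and `disruption` columns.
#' @export
assign_disruption <- function(calls, features) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  feat <- rep(NA_character_, nrow(calls))
  cls <- rep("INTERGENIC", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hit <- which(cds$contig == calls$contig[i] &
                   cds$start <= calls$breakpoint[i] &
                   cds$end > calls$breakpoint[i])
    if (!length(hit)) next
    hit <- hit[1L]
    feat[i] <- cds$id[hit]
    cls[i] <- switch(cds$category[hit],
                     FUNCTIONAL = "FUNCTIONAL-GENE",
                     HP = "HP",
                     ME = "ME/PHAGE", PHAGE = "ME/PHAGE",
                     "INTERGENIC")
  }
  calls$disrupted_feature <- feat
  calls$disruption <- cls
  calls
}

#' Genotype an insertion's disruption ratio from short reads
#'
#' Builds three diagnostic junction sequences — left flank + element start,
#' element end + right flank, and the intact flank-through-flank sequence —
#' and counts distinct short reads containing a junction-spanning exact
#' match (either orientation) with at least `min_overlap` bases on each side
#' of the junction point.  The disrupted allele presents two assay points
#' (element start and element end) against the intact allele's one, so `y`
#' is the average of the two disrupted-junction read counts (each read
#' counted once, at one junction); `n` is the number of reads supporting the
#' intact allele.  The disruption ratio `y/n` then estimates `f/(1-f)` for
#' an insertion at population frequency `f`.
#'
#' @param call One-row data frame (or list) with `breakpoint` and
#'   `consensus`.
#' @param reads A [Biostrings::DNAStringSet] of short reads (any
#'   orientation), or an alignment data frame with a `seq` column.
#' @param genome An [annotated_genome()].
#' @param flank Flank length for the reported diagnostic sequences
#'   (default 50).
#' @param min_overlap Required overlap on each side of the junction
#'   (default 20).
#' @param max_mismatch Edit distance allowed when matching a probe inside a
#'   read (default 4).  The element half of a disrupted-junction probe is
#'   taken from the long-read consensus, which at nanopore-scale error
#'   rates carries ~2 errors per 20 bp; exact matching would silently zero
#'   out such assays.  Set to 0 for exact matching.
#' @return List with `y`, `n`, `y_left`, `y_right`, `ratio` (`NA` when
#'   `n == 0`), `fixed`
#'   (`TRUE` when only the disrupted allele was seen), `formatted`
#'   (Table-style report string: `"y/n = R"`, or `"n (0/N)"` when `y = 0`)
#'   and the three diagnostic sequences.
#' @export
genotype_junctions <- function(call, reads, genome, flank = 50L,
                               min_overlap = 20L, max_mismatch = 4L) {
  if (is.data.frame(call)) call <- as.list(call[1L, ])
  if (is.data.frame(reads)) reads <- Biostrings::DNAStringSet(reads$seq)
  refseq <- genome$seq[[1L]]
  bp <- call$breakpoint
  elem <- call$consensus
  if (nchar(elem) < min_overlap) stop("consensus shorter than min_overlap")
  ref_left <- as.character(Biostrings::subseq(refseq, bp - flank + 1L, bp))
  ref_right <- as.character(Biostrings::subseq(refseq, bp + 1L, bp + flank))
  diag_left <- paste0(ref_left, substr(elem, 1L, flank))
  diag_right <- paste0(substr(elem, nchar(elem) - flank + 1L, nchar(elem)),
                       ref_right)
  diag_intact <- paste0(ref_left, ref_right)
  probe <- function(left, right)
    paste0(substr(left, nchar(left) - min_overlap + 1L, nchar(left)),
           substr(right, 1L, min_overlap))
  p_left <- probe(ref_left, elem)
  p_right <- probe(elem, ref_right)
  p_intact <- probe(ref_left, ref_right)
  hits <- function(p) {
    pd <- Biostrings::DNAString(p)
    wi <- max_mismatch > 0L
    Biostrings::vcountPattern(pd, reads, max.mismatch = max_mismatch,
                              with.indels = wi, fixed = TRUE) > 0L |
      Biostrings::vcountPattern(Biostrings::reverseComplement(pd), reads,
                                max.mismatch = max_mismatch,
                                with.indels = wi, fixed = TRUE) > 0L
  }
  hl <- hits(p_left); hr <- hits(p_right)
  y_left <- sum(hl); y_right <- sum(hr & !hl)
  y <- as.integer(round_half_up((y_left + y_right) / 2))
  n <- sum(hits(p_intact))
  if (y_left == 0L && y_right == 0L && n == 0L)
    stop("no junction-spanning coverage at breakpoint ", bp)
  ratio <- if (n > 0L) y / n else NA_real_
  formatted <- if (y == 0L && n > 0L) sprintf("n (0/%d)", n) else
    if (n == 0L) sprintf("fixed (%d/0)", y) else
      sprintf("y/n = %s", format(round_half_up(ratio, 2)))
  list(y = y, n = n, y_left = y_left, y_right = y_right, ratio = ratio,
       fixed = n == 0L && y > 0L, formatted = formatted,
       junction_left = diag_left, junction_right = diag_right,
       junction_intact = diag_intact)
}

#' Score insertion calls against a simulator truth table
#'
#' @param calls Calls (optionally classified).
#' @param truth Truth insertion table from [simulate_population()].
#' @param tol Breakpoint tolerance in bp (default 20).
#' @return List with `recall`, `n_true`, `n_called`, `matched` (per-truth
#'   logical), `correct_class` (per-truth logical, `NA` when unclassified),
#'   and `false_positives` (calls matching no truth breakpoint).
#' @export
score_insertion_calls <- function(calls, truth, tol = 20L) {
  matched <- logical(nrow(truth))
  correct_class <- rep(NA, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- which(abs(calls$breakpoint - truth$breakpoint[i]) <= tol &
                   calls$contig == truth$contig[i])
    matched[i] <- length(hit) > 0L
    if (length(hit) && !is.null(calls$classification))
      correct_class[i] <- any(calls$classification[hit] ==
                                paste0("ME:", truth$element[i]))
  }
  fp <- vapply(seq_len(nrow(calls)), function(j)
    !any(abs(calls$breakpoint[j] - truth$breakpoint) <= tol), logical(1L))
  list(recall = if (nrow(truth)) mean(matched) else NA_real_,
       n_true = nrow(truth), n_called = nrow(calls), matched = matched,
       correct_class = correct_class, false_positives = sum(fp))
}
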