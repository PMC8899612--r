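## Intrapopulation short-sequence-variant (SSV) calling: a transparent
## per-column pileup caller over short-read alignments.  Variants are
## population polymorphisms (no diploid genotype model); the alt fraction is
## the population frequency estimate.  Indels are reported VCF-style,
## left-anchored on the base before the event.

empty_variants <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), class = character(), depth = integer(),
             alt_support = integer(), alt_fraction = numeric(),
             stringsAsFactors = FALSE)
}

#' Call short sequence variants from short-read alignments
#'
#' Per-position allele counting: substitutions are collected from M/=/X
#' alignment columns (optionally filtered on base quality), insertions and
#' deletions from I/D CIGAR operations keyed by their left-anchored
#' position.  One variant is emitted per alternative allele passing the
#' depth, support and fraction thresholds.
#'
#' @param aln Alignment data frame from [read_alignments()] or
#'   [simulate_reads()].
#' @param genome An [annotated_genome()] (the mapping reference).
#' @param min_depth Minimum total depth at the site (default 10).
#' @param min_alt Minimum reads supporting the alternative allele (default 2).
#' @param min_frac Minimum alternative-allele fraction (default 0.1).
#' @param min_baseq Minimum base quality for substitution evidence
#'   (default 10; applied when quality strings are present).
#' @param max_indel Maximum reported indel length in bp (default 200).
#' @return Data frame of variants: `contig`, `pos` (0-based), `ref`, `alt`,
#'   `class` (`SNV`/`INS`/`DEL`/`MNV`), `depth`, `alt_support`,
#'   `alt_fraction`, sorted by contig and position.
#' @export
call_ssv <- function(aln, genome, min_depth = 10L, min_alt = 2L,
                     min_frac = 0.1, min_baseq = 10L, max_indel = 200L) {
  if (!nrow(aln)) {
    warning("no aligned reads; returning empty variant list")
    return(empty_variants())
  }
  unknown <- setdiff(unique(aln$contig), names(genome$seq))
  if (length(unknown))
    stop("alignments reference contigs absent from the genome: ",
         paste(unknown, collapse = ", "))
  out <- lapply(intersect(names(genome$seq), unique(aln$contig)), function(ct)
    call_ssv_contig(aln[aln$contig == ct, , drop = FALSE],
                    genome$seq[[ct]], ct, min_depth, min_alt, min_frac,
                    min_baseq, max_indel))
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty_variants())
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

call_ssv_contig <- function(aln, refseq, contig, min_depth, min_alt,
                            min_frac, min_baseq, max_indel) {
  L <- length(refseq)
  cig <- aln$cigar
  pos1 <- aln$pos + 1L
  rr_m <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos1, ops = "M")
  qr_m <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "M")
  nseg <- S4Vectors::elementNROWS(rr_m)
  read_of <- rep(seq_along(cig), nseg)
  rr <- unlist(rr_m, use.names = FALSE)
  qr <- unlist(qr_m, use.names = FALSE)

  ## depth from M-op coverage
  cov <- as.integer(IRanges::coverage(rr, width = L))

  ## mismatch extraction: concatenate all aligned segments of reads and of
  ## the reference, compare byte-wise
  reads <- Biostrings::DNAStringSet(aln$seq)
  seg_q <- Biostrings::subseq(reads[read_of], start = IRanges::start(qr),
                              end = IRanges::end(qr))
  seg_r <- Biostrings::extractAt(refseq, rr)
  qraw <- charToRaw(as.character(unlist(seg_q)))
  rraw <- charToRaw(as.character(unlist(seg_r)))
  mism <- which(qraw != rraw)

  snv <- NULL
  if (length(mism)) {
    w <- IRanges::width(rr)
    cumw <- cumsum(w)
    seg_idx <- findInterval(mism - 0.5, cumw) + 1L
    off <- mism - c(0L, head(cumw, -1L))[seg_idx]   # 1-based within segment
    refpos0 <- IRanges::start(rr)[seg_idx] - 1L + off - 1L
    altb <- rawToChar(qraw[mism], multiple = TRUE)
    keep <- altb %in% BASES
    ## base-quality filter
    has_q <- !is.null(aln$qual) && all(nzchar(aln$qual)) &&
      !all(aln$qual == "*")
    if (has_q && length(mism)) {
      qual_seg <- substring(aln$qual[read_of], IRanges::start(qr),
                            IRanges::end(qr))
      qual_all <- paste(qual_seg, collapse = "")
      qv <- utf8ToInt(qual_all)[mism] - 33L
      keep <- keep & qv >= min_baseq
    }
    refpos0 <- refpos0[keep]; altb <- altb[keep]
    if (length(refpos0)) {
      key <- paste(refpos0, altb, sep = ":")
      tab <- table(key)
      parts <- strsplit(names(tab), ":", fixed = TRUE)
      p0 <- as.integer(vapply(parts, `[`, "", 1L))
      snv <- data.frame(
        pos = p0,
        ref = as.character(Biostrings::extractAt(
          refseq, IRanges::IRanges(p0 + 1L, width = 1L))),
        alt = vapply(parts, `[`, "", 2L),
        class = "SNV", alt_support = as.integer(tab),
        stringsAsFactors = FALSE)
    }
  }

  ## insertions: left-anchored on the base before the inserted sequence
  rr_i <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos1, ops = "I")
  qr_i <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "I")
  n_i <- S4Vectors::elementNROWS(rr_i)
  ins <- NULL
  if (sum(n_i)) {
    read_i <- rep(seq_along(cig), n_i)
    rri <- unlist(rr_i, use.names = FALSE)
    qri <- unlist(qr_i, use.names = FALSE)
    anchor0 <- IRanges::start(rri) - 2L       # base before the insertion
    iseq <- as.character(Biostrings::subseq(reads[read_i],
                                            start = IRanges::start(qri),
                                            end = IRanges::end(qri)))
    ok <- anchor0 >= 0L & nchar(iseq) <= max_indel
    if (any(ok)) {
      anchor0 <- anchor0[ok]; iseq <- iseq[ok]
      refb <- as.character(Biostrings::extractAt(
        refseq, IRanges::IRanges(anchor0 + 1L, width = 1L)))
      key <- paste(anchor0, paste0(refb, iseq), sep = ":")
      tab <- table(key)
      parts <- strsplit(names(tab), ":", fixed = TRUE)
      p0 <- as.integer(vapply(parts, `[`, "", 1L))
      alt <- vapply(parts, `[`, "", 2L)
      ins <- data.frame(pos = p0, ref = substr(alt, 1L, 1L), alt = alt,
                        class = "INS", alt_support = as.integer(tab),
                        stringsAsFactors = FALSE)
    }
  }

  ## deletions: REF carries the anchor base plus the deleted bases
  rr_d <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos1, ops = "D")
  n_d <- S4Vectors::elementNROWS(rr_d)
  del <- NULL
  if (sum(n_d)) {
    rrd <- unlist(rr_d, use.names = FALSE)
    anchor0 <- IRanges::start(rrd) - 2L
    dlen <- IRanges::width(rrd)
    ok <- anchor0 >= 0L & dlen <= max_indel
    if (any(ok)) {
      rrd <- rrd[ok]; anchor0 <- anchor0[ok]; dlen <- dlen[ok]
      refal <- as.character(Biostrings::extractAt(
        refseq, IRanges::IRanges(anchor0 + 1L, width = dlen + 1L)))
      key <- paste(anchor0, refal, sep = ":")
      tab <- table(key)
      parts <- strsplit(names(tab), ":", fixed = TRUE)
      p0 <- as.integer(vapply(parts, `[`, "", 1L))
      refa <- vapply(parts, `[`, "", 2L)
      del <- data.frame(pos = p0, ref = refa, alt = substr(refa, 1L, 1L),
                        class = "DEL", alt_support = as.integer(tab),
                        stringsAsFactors = FALSE)
    }
  }

  vars <- rbind(snv, ins, del)
  if (is.null(vars) || !nrow(vars)) return(NULL)
  vars$depth <- cov[vars$pos + 1L]
  vars$alt_fraction <- vars$alt_support / pmax(vars$depth, 1L)
  vars <- vars[vars$depth >= min_depth & vars$alt_support >= min_alt &
                 vars$alt_fraction >= min_frac & vars$alt != vars$ref, ,
               drop = FALSE]
  if (!nrow(vars)) return(NULL)
  data.frame(contig = contig, vars[, c("pos", "ref", "alt", "class", "depth",
                                       "alt_support", "alt_fraction")],
             stringsAsFactors = FALSE)
}

#' SSV density of a region, per 10 kbp
#'
#' @param variants Variant data frame ([call_ssv()] output or truth table
#'   with `contig`/`pos`).
#' @param reg A [region()].
#' @return Variants per 10 kbp (unrounded; round to 2 decimals at reporting
#'   time).
#' @export
ssv_region_density <- function(variants, reg) {
  len <- region_length(reg)
  if (len <= 0) stop("zero-length region")
  n <- sum(variants$contig == reg$contig & variants$pos >= reg$start &
             variants$pos < reg$end)
  n * 1e4 / len
}

#' Fraction of variants lying inside protein-coding ORFs
#'
#' @param variants Variant data frame (needs `contig`, `pos`).
#' @param features Feature data frame; only `type == "CDS"` intervals count.
#' @return Fraction in `[0, 1]`.
#' @export
ssv_orf_fraction <- function(variants, features) {
  if (!nrow(variants)) stop("empty variant list")
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(0)
  hits <- IRanges::countOverlaps(
    IRanges::IRanges(variants$pos + 1L, width = 1L),
    IRanges::IRanges(cds$start + 1L, cds$end))
  ## (single-contig convenience: intervals are compared per contig)
  if (length(unique(c(variants$contig, cds$contig))) > 1L) {
    inside <- logical(nrow(variants))
    for (ct in unique(variants$contig)) {
      vi <- variants$contig == ct
      ci <- cds$contig == ct
      inside[vi] <- IRanges::countOverlaps(
        IRanges::IRanges(variants$pos[vi] + 1L, width = 1L),
        IRanges::IRanges(cds$start[ci] + 1L, cds$end[ci])) > 0L
    }
    return(mean(inside))
  }
  mean(hits > 0L)
}

#' Write variants to a VCF (v4.2 subset)
#'
#' Emits `DP`, `AO` and `AF` INFO fields; positions are converted to the
#' 1-based convention.
#'
#' @param variants Variant data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_vcf_variants <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternative allele observations\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    f <- c(if (!is.na(variants$depth[i])) sprintf("DP=%d", variants$depth[i]),
           if (!is.null(variants$alt_support) &&
               !is.na(variants$alt_support[i]))
             sprintf("AO=%d", variants$alt_support[i]),
           if (!is.na(variants$alt_fraction[i]))
             sprintf("AF=%.6g", variants$alt_fraction[i]))
    if (length(f)) paste(f, collapse = ";") else "."
  }, character(1L))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", variants$contig,
                  variants$pos + 1L, variants$ref, variants$alt, info)
  writeLines(c(hdr, if (nrow(variants)) body), path)
  invisible(path)
}

#' Read variants from a VCF (v4.2 subset)
#'
#' Ingest path for externally called variants.  Uses `vcfR` when available,
#' otherwise a plain-text parser for the same column subset.  Multi-allelic
#' records are split into one variant per alternative allele.
#'
#' @param path VCF file (uncompressed).
#' @return Variant data frame in the [call_ssv()] layout.
#' @export
read_vcf_variants <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) return(empty_variants())
    m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    fix <- data.frame(CHROM = m[, 1L], POS = m[, 2L], REF = m[, 4L],
                      ALT = m[, 5L], INFO = m[, 8L],
                      stringsAsFactors = FALSE)
  }
  if (!nrow(fix)) return(empty_variants())
  get_info <- function(info, key) {
    val <- rep(NA_character_, length(info))
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    m <- regmatches(info, regexec(pat, info))
    has <- lengths(m) == 2L
    val[has] <- vapply(m[has], `[`, "", 2L)
    val
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    data.frame(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]) - 1L,
               ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  info <- fix$INFO[rep(seq_len(nrow(fix)),
                       vapply(rows, nrow, integer(1L)))]
  out$class <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L, "SNV",
                      ifelse(nchar(out$ref) < nchar(out$alt), "INS",
                             ifelse(nchar(out$ref) > nchar(out$alt), "DEL",
                                    "MNV")))
  out$depth <- suppressWarnings(as.integer(get_info(info, "DP")))
  out$alt_support <- suppressWarnings(as.integer(get_info(info, "AO")))
  out$alt_fraction <- suppressWarnings(as.numeric(get_info(info, "AF")))
  out
}
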