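## Domain containers and readers/writers for the plain-text formats the
## pipeline touches: FASTA/FASTQ (via Biostrings), GFF3, SAM (text subset),
## VCF (subset), BED and TSV reports.

GENE_CATEGORIES <- c("HP", "ME", "PHAGE", "FUNCTIONAL", "TRNA", "RRNA")

#' Default keyword lexicon for gene functional categories
#'
#' Case-insensitive substring keywords used to map free-text product
#' annotations to the content classes used in scrapyard analysis.  Priority
#' order on matching is ME > PHAGE > HP > FUNCTIONAL; structural RNA genes
#' (tRNA/rRNA) are recognized from the feature type, never from the product.
#' The lexicon is an approximation of typical annotation wording and can be
#' overridden wherever a classification is made.
#'
#' @return Named list with `ME`, `PHAGE` and `HP` keyword vectors and
#'   `ME_regex`, a regular expression for IS-family tokens.
#' @export
default_category_lexicon <- function() {
  list(
    ME = c("transposase", "insertion sequence", "integrase", "resolvase",
           "mobile element", "recombinase", "transposon"),
    ME_regex = "\\bIS[0-9]+\\b",
    PHAGE = c("phage", "capsid", "tail", "terminase", "portal"),
    HP = c("hypothetical protein")
  )
}

#' Classify a gene product string into a content category
#'
#' Deterministic, case-insensitive keyword classification into the classes
#' used for genome-island content analysis: mobile-element proteins (`ME`),
#' phage proteins (`PHAGE`), hypothetical proteins (`HP`), and everything
#' else (`FUNCTIONAL`, i.e. ORFs with an annotated biological function).
#' Keywords are tried in priority order ME > PHAGE > HP so that, e.g.,
#' "phage integrase" classifies as ME.  tRNA/rRNA features are classified
#' from `type`, not from the product text.
#'
#' @param product Character vector of product annotations.
#' @param type Feature type(s): `"CDS"`, `"tRNA"` or `"rRNA"` (recycled).
#' @param lexicon Keyword lexicon, see [default_category_lexicon()].
#' @return Character vector of categories.
#' @examples
#' classify_gene_category("hypothetical protein")        # "HP"
#' classify_gene_category("IS5 family transposase")      # "ME"
#' classify_gene_category("ribulose bisphosphate carboxylase large chain")
#' @export
classify_gene_category <- function(product, type = "CDS",
                                   lexicon = default_category_lexicon()) {
  stopifnot(is.character(product))
  type <- rep_len(type, length(product))
  p <- tolower(product)
  has_any <- function(keys) {
    hit <- rep(FALSE, length(p))
    for (k in keys) hit <- hit | grepl(k, p, fixed = TRUE)
    hit
  }
  cat <- rep("FUNCTIONAL", length(p))
  cat[has_any(lexicon$HP)] <- "HP"
  cat[has_any(lexicon$PHAGE)] <- "PHAGE"
  me <- has_any(lexicon$ME)
  if (!is.null(lexicon$ME_regex))
    me <- me | grepl(lexicon$ME_regex, product, perl = TRUE)
  cat[me] <- "ME"
  cat[tolower(type) == "trna"] <- "TRNA"
  cat[tolower(type) == "rrna"] <- "RRNA"
  cat
}

empty_features <- function() {
  data.frame(id = character(), contig = character(), start = integer(),
              end = integer(), strand = character(), type = character(),
              product = character(), category = character(),
              stringsAsFactors = FALSE)
}

validate_features <- function(features, contig_lengths = NULL) {
  req <- c("id", "contig", "start", "end", "strand", "type", "product",
           "category")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("feature table misses columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(features)) {
    if (any(features$end <= features$start))
      stop("feature intervals must satisfy start < end")
    if (anyDuplicated(features$id))
      stop("feature ids must be unique: ",
           paste(unique(features$id[duplicated(features$id)]), collapse = ", "))
    if (!is.null(contig_lengths)) {
      len <- contig_lengths[features$contig]
      if (anyNA(len)) stop("features reference unknown contigs")
      if (any(features$end > len))
        stop("feature interval exceeds contig length")
    }
  }
  invisible(features)
}

#' Construct an annotated genome
#'
#' Bundles contig sequences with a gene feature table.  Internally all
#' coordinates are 0-based half-open; circular contigs are linearized at
#' position 0 for analysis.
#'
#' @param seq A [Biostrings::DNAStringSet] of contig sequences (named).
#' @param features Feature data frame as returned by [read_features()].
#' @param circular Logical vector (recycled) flagging circular contigs.
#' @return An object of class `"annotated_genome"` with elements `seq`,
#'   `features` and `circular`.
#' @export
annotated_genome <- function(seq, features = empty_features(),
                             circular = TRUE) {
  stopifnot(methods::is(seq, "DNAStringSet"))
  if (is.null(names(seq)) || any(!nzchar(names(seq))))
    stop("contigs must be named")
  circular <- setNames(rep_len(circular, length(seq)), names(seq))
  validate_features(features, setNames(Biostrings::width(seq), names(seq)))
  structure(list(seq = seq, features = features, circular = circular),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %d contig(s), %s bp, %d features\n",
              length(x$seq), format(sum(Biostrings::width(x$seq)), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

genome_length <- function(genome) sum(Biostrings::width(genome$seq))

#' Read gene features from a GFF3 file
#'
#' Parses the 9-column GFF3 subset used by the pipeline (CDS, tRNA and rRNA
#' features with `ID` and `product` attributes).  On-disk 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention and
#' content categories are assigned with [classify_gene_category()].
#'
#' @param path GFF3 file.
#' @param lexicon Category keyword lexicon.
#' @return Feature data frame (one row per feature) with columns `id`,
#'   `contig`, `start`, `end`, `strand`, `type`, `product`, `category`.
#' @export
read_features <- function(path, lexicon = default_category_lexicon()) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) return(empty_features())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 9L)) {
    bad <- idx[which(nfield != 9L)[1L]]
    stop("malformed GFF3 line ", bad, ": expected 9 tab-separated columns, ",
         "found ", nfield[which(nfield != 9L)[1L]])
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1))
    stop("malformed GFF3 line ", idx[which(is.na(start1) | is.na(end1))[1L]],
         ": non-numeric coordinates")
  if (any(end1 < start1))
    stop("GFF3 validation error at line ", idx[which(end1 < start1)[1L]],
         ": end < start")
  attr_field <- m[, 9L]
  get_attr <- function(key) {
    val <- sub(paste0(".*(?:^|;)\\s*", key, "="), "", attr_field, perl = TRUE)
    val <- sub(";.*$", "", val)
    val[!grepl(paste0("(^|;)\\s*", key, "="), attr_field, perl = TRUE)] <- ""
    gsub("%3B", ";", gsub("%3D", "=", gsub("%25", "%", val, fixed = TRUE),
                          fixed = TRUE), fixed = TRUE)
  }
  id <- get_attr("ID")
  id[!nzchar(id)] <- paste0("feature_", which(!nzchar(id)))
  product <- get_attr("product")
  mem <- coord_to_memory(start1, end1)
  feats <- data.frame(id = id, contig = m[, 1L], start = mem$start,
                       end = mem$end, strand = m[, 7L], type = m[, 3L],
                       product = product,
                       category = classify_gene_category(product, m[, 3L],
                                                         lexicon),
                       stringsAsFactors = FALSE)
  validate_features(feats)
}

#' Write gene features to a GFF3 file
#'
#' Inverse of [read_features()]: internal 0-based half-open intervals are
#' emitted 1-based inclusive with `ID` and `product` attributes, so that a
#' read/write round trip is lossless.
#'
#' @param features Feature data frame.
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path, source = "intrapop") {
  validate_features(features)
  esc <- function(x) gsub(";", "%3B", gsub("=", "%3D",
                          gsub("%", "%25", x, fixed = TRUE), fixed = TRUE),
                          fixed = TRUE)
  disk <- coord_to_disk(features$start, features$end)
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
                     features$contig, source, features$type,
                     disk$start, disk$end, features$strand,
                     esc(features$id), esc(features$product)))
  if (!nrow(features)) lines <- lines[1L]
  writeLines(lines, path)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Text SAM reader for the column subset the pipeline consumes (QNAME, FLAG,
#' RNAME, POS, MAPQ, CIGAR, SEQ, QUAL).  Unmapped and secondary/supplementary
#' records are skipped and counted; records whose CIGAR query length
#' disagrees with the sequence length are rejected with a warning counter.
#' Positions are converted to 0-based.
#'
#' @param path SAM file.
#' @return A data frame with columns `qname`, `flag`, `contig`, `pos`
#'   (0-based leftmost reference position), `mapq`, `cigar`, `seq`, `qual`,
#'   plus attributes `skipped` (unmapped/secondary) and `rejected`
#'   (CIGAR/SEQ length mismatches) and `header` (the raw header lines).
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  out <- data.frame(qname = character(), flag = integer(), contig = character(),
                    pos = integer(), mapq = integer(), cigar = character(),
                    seq = character(), qual = character(),
                    stringsAsFactors = FALSE)
  skipped <- 0L; rejected <- 0L
  if (length(rec)) {
    parts <- strsplit(rec, "\t", fixed = TRUE)
    if (any(lengths(parts) < 11L))
      stop("malformed SAM record at line ",
           which(lengths(parts) < 11L)[1L] + length(hdr))
    m <- t(vapply(parts, function(p) p[1:11], character(11L)))
    flag <- as.integer(m[, 2L])
    drop <- bitwAnd(flag, 4L) > 0L | bitwAnd(flag, 256L) > 0L |
      bitwAnd(flag, 2048L) > 0L
    skipped <- sum(drop)
    m <- m[!drop, , drop = FALSE]; flag <- flag[!drop]
    if (nrow(m)) {
      qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
        m[, 6L], after.soft.clipping = FALSE)
      has_seq <- m[, 10L] != "*"
      bad <- has_seq & nchar(m[, 10L]) != qlen
      if (any(bad)) {
        rejected <- sum(bad)
        warning(rejected, " SAM record(s) rejected: CIGAR/SEQ length mismatch")
        m <- m[!bad, , drop = FALSE]; flag <- flag[!bad]
      }
      out <- data.frame(qname = m[, 1L], flag = flag, contig = m[, 3L],
                        pos = as.integer(m[, 4L]) - 1L,
                        mapq = suppressWarnings(as.integer(m[, 5L])),
                        cigar = m[, 6L], seq = m[, 10L], qual = m[, 11L],
                        stringsAsFactors = FALSE)
    }
  }
  attr(out, "skipped") <- skipped
  attr(out, "rejected") <- rejected
  attr(out, "header") <- hdr
  out
}

#' Write alignments to a SAM file
#'
#' @param aln Alignment data frame (see [read_alignments()]).
#' @param path Output file.
#' @param contig_lengths Named integer vector for the `@SQ` header lines.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(aln, path, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  aln$qname, aln$flag, aln$contig, aln$pos + 1L,
                  ifelse(is.na(aln$mapq), 60L, aln$mapq), aln$cigar,
                  aln$seq, ifelse(is.na(aln$qual) | aln$qual == "", "*",
                                  aln$qual))
  writeLines(c(hdr, if (nrow(aln)) body), path)
  invisible(path)
}

#' Strand-aware read of a genome FASTA
#'
#' @param path FASTA file.
#' @param circular Logical, are the contigs circular.
#' @param features Optional feature table to attach.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(path, circular = TRUE, features = empty_features()) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  annotated_genome(seq, features, circular)
}

#' Which features start inside a region
#'
#' Features are counted "in" a region by their start position, the convention
#' used for all content statistics.
#'
#' @param features Feature data frame.
#' @param reg A [region()].
#' @return Logical vector along `features` rows.
#' @export
feature_starts_in <- function(features, reg) {
  features$contig == reg$contig & features$start >= reg$start &
    features$start < reg$end
}

#' Write regions to a BED file
#'
#' @param regions List of [region()] objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- vapply(regions, function(r)
    sprintf("%s\t%d\t%d\t%s", r$contig, r$start, r$end,
            if (nzchar(r$label)) r$label else "."), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read regions from a BED file
#'
#' @param path BED file (first four columns used).
#' @return List of [region()] objects.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(strsplit(lines, "\t", fixed = TRUE), function(p)
    region(p[1L], as.integer(p[2L]), as.integer(p[3L]),
           if (length(p) >= 4L && p[4L] != ".") p[4L] else ""))
}
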