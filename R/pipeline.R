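## End-to-end orchestration: skew -> SSV -> insertion calling ->
## classification -> disruption assignment -> junction genotyping -> region
## statistics, with a machine-readable summary.  All outputs are written
## atomically (temp file + rename) and the run is deterministic for a given
## config and inputs.

#' Build and validate a pipeline configuration
#'
#' @param genome_fasta Reference genome FASTA.
#' @param annotations_gff3 Gene annotations (GFF3 with product attributes).
#' @param long_sam Long-read alignments (SAM).
#' @param short_sam Short-read alignments (SAM); required for the internal
#'   SSV caller and junction genotyping unless `ssv_vcf` is given.
#' @param me_library_fasta Mobile-element library FASTA.
#' @param ssv_vcf Optional externally called variants (VCF) used instead of
#'   the internal caller.
#' @param out_dir Output directory.
#' @param anchors Optional character vector of two anchor names delimiting
#'   the scrapyard (e.g. `c("tRNA-Ser-CGA", "tRNA-Val-CAC")`).
#' @param params Optional named list of stage parameter overrides, blocks
#'   `skew`, `ssv`, `insertion`, `junction`, `scrapyard`.
#' @param seed Seed recorded in the summary (the pipeline itself is
#'   deterministic).
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(genome_fasta, annotations_gff3, long_sam,
                            short_sam = NULL, me_library_fasta = NULL,
                            ssv_vcf = NULL, out_dir = "intrapop_out",
                            anchors = c("tRNA-Ser-CGA", "tRNA-Val-CAC"),
                            params = list(), seed = 1L) {
  cfg <- list(genome_fasta = genome_fasta,
              annotations_gff3 = annotations_gff3,
              long_sam = long_sam, short_sam = short_sam,
              me_library_fasta = me_library_fasta, ssv_vcf = ssv_vcf,
              out_dir = out_dir, anchors = anchors, params = params,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  need <- c("genome_fasta", "annotations_gff3", "long_sam")
  for (f in need)
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("pipeline config: missing input file for '", f, "': ",
           cfg[[f]] %||% "<unset>")
  for (f in c("short_sam", "me_library_fasta", "ssv_vcf"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("pipeline config: '", f, "' does not exist: ", cfg[[f]])
  if (is.null(cfg$short_sam) && is.null(cfg$ssv_vcf))
    stop("pipeline config: need short_sam or ssv_vcf for SSV input")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

## merge user overrides over defaults
merge_params <- function(defaults, over) {
  if (is.null(over)) return(defaults)
  defaults[names(over)] <- over
  defaults
}

#' Run the full analysis pipeline
#'
#' Executes GC-skew profiling, SSV calling (or VCF ingest), insertion
#' calling with classification and disruption assignment, junction
#' genotyping of every call from the short reads, anchor-based scrapyard
#' delimitation (falling back to de novo detection when anchors are absent)
#' with content statistics and enrichment ratios, and writes the report
#' bundle: `summary.json`, `table_regions.tsv`, `table_junctions.tsv`,
#' `insertions.vcf`, `ssv.vcf`, `regions.bed`, `skew.tsv`.
#'
#' @param cfg A `"pipeline_config"` (or path to a YAML config).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[intrapop] stage %-12s ...", name))
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[intrapop] stage %-12s done (%.1fs)", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  features <- stage("load", read_features(cfg$annotations_gff3))
  genome <- read_genome(cfg$genome_fasta, features = features)
  L <- genome_length(genome)

  p_skew <- merge_params(list(window = 10000L, step = 2000L), cfg$params$skew)
  skew <- stage("skew", gc_skew_profile(genome, p_skew$window, p_skew$step))

  p_ssv <- merge_params(list(min_depth = 10L, min_alt = 2L, min_frac = 0.1,
                             min_baseq = 10L), cfg$params$ssv)
  short_aln <- if (!is.null(cfg$short_sam)) read_alignments(cfg$short_sam)
  variants <- stage("ssv", {
    if (!is.null(cfg$ssv_vcf)) read_vcf_variants(cfg$ssv_vcf) else
      call_ssv(short_aln, genome, p_ssv$min_depth, p_ssv$min_alt,
               p_ssv$min_frac, p_ssv$min_baseq)
  })

  p_ins <- merge_params(list(min_len = 10L, min_clip = 100L,
                             min_read_len = 1000L, cluster_window = 100L,
                             margin = 50L, min_support = 2L,
                             min_identity = 0.8, min_cov = 0.5),
                        cfg$params$insertion)
  long_aln <- read_alignments(cfg$long_sam)
  calls <- stage("insertions", {
    sig <- collect_insertion_signals(long_aln, p_ins$min_len, p_ins$min_clip,
                                     p_ins$min_read_len)
    cl <- cluster_and_call(sig, long_aln, p_ins$cluster_window, p_ins$margin,
                           p_ins$min_support)
    if (nrow(cl) && !is.null(cfg$me_library_fasta)) {
      lib <- Biostrings::readDNAStringSet(cfg$me_library_fasta)
      names(lib) <- sub("\\s.*$", "", names(lib))
      cl <- classify_insertion(cl, lib, p_ins$min_identity, p_ins$min_cov)
    } else if (nrow(cl)) cl$classification <- NA_character_
    assign_disruption(cl, features)
  })

  p_jx <- merge_params(list(flank = 50L, min_overlap = 20L),
                       cfg$params$junction)
  junctions <- stage("junctions", {
    if (is.null(short_aln) || !nrow(calls)) NULL else {
      reads <- Biostrings::DNAStringSet(short_aln$seq)
      rows <- lapply(seq_len(nrow(calls)), function(i) {
        g <- tryCatch(genotype_junctions(calls[i, ], reads, genome,
                                         p_jx$flank, p_jx$min_overlap),
                      error = function(e) NULL)
        if (is.null(g)) return(NULL)
        data.frame(breakpoint = calls$breakpoint[i],
                   disrupted_feature = calls$disrupted_feature[i],
                   disruption = calls$disruption[i],
                   y = g$y, n = g$n, ratio = g$ratio,
                   formatted = g$formatted, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    }
  })

  p_sy <- merge_params(list(window = 10000L, step = 2000L, hp_min = 0.55,
                            mob_density_min = 1.0, ssv_factor = 3,
                            merge_gap = 20000L, min_len = 50000L),
                       cfg$params$scrapyard)
  regions <- stage("scrapyard", {
    anchored <- tryCatch(
      if (!is.null(cfg$anchors))
        delimit_by_anchors(features, cfg$anchors[1L], cfg$anchors[2L])
      else NULL, error = function(e) NULL)
    if (!is.null(anchored)) {
      attr(anchored, "stats") <-
        region_content_stats(features, variants, anchored, L)
      list(anchored)
    } else
      detect_scrapyards(genome, features, variants, skew,
                        window = p_sy$window, step = p_sy$step,
                        hp_min = p_sy$hp_min,
                        mob_density_min = p_sy$mob_density_min,
                        ssv_factor = p_sy$ssv_factor,
                        merge_gap = p_sy$merge_gap, min_len = p_sy$min_len)
  })

  ## ---- report bundle ----
  out <- function(f) file.path(cfg$out_dir, f)
  write_atomic(function(p) write_skew_tsv(skew, p), out("skew.tsv"))
  write_atomic(function(p) write_vcf_variants(variants, p), out("ssv.vcf"))
  write_atomic(function(p) write_insertions_vcf(calls, genome, p),
               out("insertions.vcf"))
  write_atomic(function(p) write_regions_bed(regions, p), out("regions.bed"))
  region_tab <- do.call(rbind, lapply(regions, function(r) {
    st <- attr(r, "stats")
    rbind(st$inside, st$outside)
  }))
  write_atomic(function(p) utils::write.table(
    region_tab %||% data.frame(), p, sep = "\t", quote = FALSE,
    row.names = FALSE), out("table_regions.tsv"))
  write_atomic(function(p) utils::write.table(
    junctions %||% data.frame(), p, sep = "\t", quote = FALSE,
    row.names = FALSE), out("table_junctions.tsv"))

  variable <- calls[calls$variability == "variable", , drop = FALSE]
  by_class <- table(factor(variable$disruption,
                           levels = c("FUNCTIONAL-GENE", "HP", "ME/PHAGE",
                                      "INTERGENIC")))
  enrich <- if (length(regions)) {
    st <- attr(regions[[1L]], "stats")
    er <- enrichment_ratios(st$inside, st$outside)
    setNames(as.list(er$fold), paste0("fold_", tolower(er$metric)))
  } else NULL
  summary <- list(
    genome_length = L,
    n_features = nrow(features),
    ssv_total = nrow(variants),
    insertion_calls = nrow(calls),
    variable_me_total = nrow(variable),
    variable_disruptions = as.list(setNames(as.integer(by_class),
                                            names(by_class))),
    islands = lapply(regions, function(r)
      list(label = r$label, from = r$start, to = r$end,
           length = r$end - r$start)),
    enrichment = enrich,
    parameters = list(skew = p_skew, ssv = p_ssv, insertion = p_ins,
                      junction = p_jx, scrapyard = p_sy),
    seed = cfg$seed)
  write_atomic(function(p) jsonlite::write_json(
    summary, p, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    out("summary.json"))
  invisible(summary)
}

write_skew_tsv <- function(skew, path) {
  utils::write.table(as.data.frame(skew), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_insertions_vcf <- function(calls, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insertion length\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Reads supporting the insertion\">",
           "##INFO=<ID=SPANNING,Number=1,Type=Integer,Description=\"Reads spanning the intact allele\">",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Element classification\">",
           "##INFO=<ID=DISRUPT,Number=1,Type=String,Description=\"Disruption class\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0L)
  if (nrow(calls)) {
    refb <- vapply(seq_len(nrow(calls)), function(i)
      as.character(Biostrings::subseq(genome$seq[[calls$contig[i]]],
                                      calls$breakpoint[i],
                                      calls$breakpoint[i])), character(1L))
    body <- sprintf(
      "%s\t%d\t.\t%s\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=%d;SUPPORT=%d;SPANNING=%d;CLASS=%s;DISRUPT=%s",
      calls$contig, calls$breakpoint, refb, calls$length, calls$supporting,
      calls$spanning, calls$classification %||% ".",
      gsub(";", ",", calls$disruption))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
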