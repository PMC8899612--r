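## Synthetic population-genome generator.  Emulates a single-species
## metagenome population: a circular chemolithotroph-like chromosome with a
## planted "scrapyard" island (elevated hypothetical-protein / mobile-element
## / phage gene density, elevated short-variant density, scattered GC skew),
## a pool of haplotypes carrying short variants and IS-element insertions at
## set population frequencies, and long + short reads with simple error
## models.  Every random choice is recorded in truth tables so downstream
## callers can be scored without external data.

HP_PRODUCTS <- "hypothetical protein"
ME_PRODUCTS <- c("IS5 family transposase", "IS30 family transposase",
                 "IS110 family transposase", "site-specific integrase",
                 "resolvase family site-specific recombinase",
                 "mobile element protein")
PHAGE_PRODUCTS <- c("phage tail fiber protein", "phage major capsid protein",
                    "phage terminase large subunit", "phage portal protein")
FUNCTIONAL_PRODUCTS <- c(
  "diguanylate cyclase/phosphodiesterase",
  "acetate kinase", "aerotaxis sensor receptor",
  "cellulose biosynthesis regulation protein BcsB",
  "type II/IV secretion system secretin RcpA",
  "uptake [NiFe] hydrogenase small subunit",
  "5-methyltetrahydrofolate--homocysteine methyltransferase",
  "ribulose bisphosphate carboxylase large chain",
  "circadian clock protein KaiC", "heavy metal efflux pump CusA",
  "assimilatory nitrate reductase large subunit",
  "ABC transporter ATP-binding protein", "elongation factor Tu",
  "DNA polymerase III subunit alpha", "50S ribosomal protein L2",
  "cytochrome c oxidase subunit I", "two-component sensor histidine kinase")

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a circular
#' genome at GC 54.1%, a scrapyard island whose gene-category proportions and
#' short-variant density follow the characterized island of a complete
#' population genome (HP ~72%, ME ~9%, phage ~3.7% of ORFs; 11.9 SSVs per 10
#' kbp inside vs 1.77 outside), a pool of 20 haplotypes, nanopore-like long
#' reads (2%/3%/4% substitution/insertion/deletion errors) and 2 x 250 bp
#' short reads at 0.3% substitution error.
#'
#' @param seed Master seed; each stage derives its own stream from it.
#' @param genome_length Genome length in bp.
#' @param gc Target GC fraction.
#' @param skew_amplitude GC skew amplitude (fraction of G+C bases biased
#'   toward G on the leading strand).
#' @param scrapyard Planted scrapyard [region()], `NULL` for none, or
#'   `"auto"` (default) for a 150 kbp island (capped at a quarter of the
#'   genome) starting at 20% of the genome.
#' @param scrapyard_props,outside_props Named gene-category proportions
#'   (`HP`, `ME`, `PHAGE`, `FUNCTIONAL`), each summing to 1.
#' @param ssv_rate_scrapyard,ssv_rate_outside Planted short-variant rates,
#'   variants per bp.
#' @param freq_range Allele-frequency law for planted SSVs: uniform bounds.
#' @param insertions Data frame with columns `element`, `target` (a gene
#'   category, or `"INTERGENIC"`) and `frequency`, or `NULL` for none.
#' @param n_haplotypes Haplotype pool size.
#' @param n_elements Number of distinct IS elements in the simulated library.
#' @param long_mean_length,long_sdlog Long-read lognormal length law.
#' @param long_min_length Minimum emitted long-read length.
#' @param long_error Named vector `c(sub=, ins=, del=)` of long-read error
#'   rates per base.
#' @param long_coverage Long-read coverage (total bases / genome length).
#' @param short_length Short-read length (bp).
#' @param short_insert_mean,short_insert_sd Fragment-size law for pairs.
#' @param short_error Short-read substitution error rate per base.
#' @param short_coverage Short-read coverage.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 300000L,
                       gc = 0.541,
                       skew_amplitude = 0.25,
                       scrapyard = "auto",
                       scrapyard_props = c(HP = 0.717, ME = 0.090,
                                           PHAGE = 0.037, FUNCTIONAL = 0.156),
                       outside_props = c(HP = 0.374, ME = 0.042,
                                         PHAGE = 0.005, FUNCTIONAL = 0.579),
                       ssv_rate_scrapyard = 11.9 / 1e4,
                       ssv_rate_outside = 1.77 / 1e4,
                       freq_range = c(0.05, 0.95),
                       insertions = default_insertion_specs(),
                       n_haplotypes = 20L,
                       n_elements = 3L,
                       long_mean_length = 8000,
                       long_sdlog = 0.4,
                       long_min_length = 1000L,
                       long_error = c(sub = 0.02, ins = 0.03, del = 0.04),
                       long_coverage = 20,
                       short_length = 250L,
                       short_insert_mean = 600,
                       short_insert_sd = 60,
                       short_error = 0.003,
                       short_coverage = 50) {
  genome_length <- as.integer(genome_length)
  if (identical(scrapyard, "auto")) {
    sy_len <- min(150000L, genome_length %/% 4L)
    sy_start <- as.integer(genome_length * 0.2)
    scrapyard <- region("sim_contig", sy_start, sy_start + sy_len,
                        "scrapyard")
  }
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              gc = gc, skew_amplitude = skew_amplitude,
              scrapyard = scrapyard,
              scrapyard_props = scrapyard_props,
              outside_props = outside_props,
              ssv_rate_scrapyard = ssv_rate_scrapyard,
              ssv_rate_outside = ssv_rate_outside,
              freq_range = freq_range, insertions = insertions,
              n_haplotypes = as.integer(n_haplotypes),
              n_elements = as.integer(n_elements),
              long_mean_length = long_mean_length, long_sdlog = long_sdlog,
              long_min_length = as.integer(long_min_length),
              long_error = long_error, long_coverage = long_coverage,
              short_length = as.integer(short_length),
              short_insert_mean = short_insert_mean,
              short_insert_sd = short_insert_sd,
              short_error = short_error, short_coverage = short_coverage)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_insertion_specs <- function() {
  data.frame(element = paste0("ISFm", 1:5),
             target = c("FUNCTIONAL", "FUNCTIONAL", "FUNCTIONAL",
                        "HP", "INTERGENIC"),
             frequency = c(0.3, 0.5, 0.7, 0.4, 0.6),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg)
  chk(cfg$genome_length >= 1000L, "genome_length too small")
  chk(cfg$gc > 0 && cfg$gc < 1, "gc must be in (0,1)")
  for (p in list(cfg$scrapyard_props, cfg$outside_props)) {
    chk(all(c("HP", "ME", "PHAGE", "FUNCTIONAL") %in% names(p)),
        "proportions must name HP/ME/PHAGE/FUNCTIONAL")
    chk(abs(sum(p) - 1) < 1e-6, "category proportions must sum to 1")
  }
  chk(cfg$ssv_rate_scrapyard >= 0 && cfg$ssv_rate_outside >= 0,
      "SSV rates must be >= 0")
  if (!is.null(cfg$scrapyard)) {
    chk(inherits(cfg$scrapyard, "region"), "scrapyard must be a region")
    chk(cfg$scrapyard$start >= 0 &&
          cfg$scrapyard$end <= cfg$genome_length,
        "scrapyard interval outside genome")
  }
  if (!is.null(cfg$insertions) && nrow(cfg$insertions)) {
    chk(all(cfg$insertions$frequency >= 0 & cfg$insertions$frequency <= 1),
        "insertion frequencies must be in [0,1]")
  }
  chk(cfg$n_haplotypes >= 1L, "need at least one haplotype")
  cfg
}

## ---- genome ---------------------------------------------------------------

#' Simulate an annotated population genome
#'
#' Generates a circular chromosome with two-replichore GC skew (G-rich
#' leading strand, origin at 0, terminus at L/2) whose per-window skew signs
#' are randomized inside the planted scrapyard; places non-overlapping genes
#' (lognormal length law, median ~900 bp) with region-specific category
#' proportions; and anchors the scrapyard between tRNA-Ser-CGA and
#' tRNA-Val-CAC genes so anchor-based delimitation can recover it.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (an [annotated_genome()]), `truth` (list with
#'   the planted `scrapyard` region or `NULL`) and `config`.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set_stage_seed(config$seed, "genome")
  L <- config$genome_length
  contig <- "sim_contig"
  sy <- config$scrapyard

  ## per-window skew signs: clean replichores, randomized in the scrapyard
  win <- 1000L
  wstart <- seq.int(0L, L - 1L, by = win)
  wsign <- ifelse(wstart < L / 2, 1, -1)
  if (!is.null(sy)) {
    in_sy <- wstart >= sy$start & wstart < sy$end
    wsign[in_sy] <- sample(c(-1, 1), sum(in_sy), replace = TRUE)
  }
  base_sign <- rep(wsign, times = pmin(win, L - wstart))
  gc <- config$gc; amp <- config$skew_amplitude
  bases <- character(L)
  for (s in c(1, -1)) {
    mask <- base_sign == s
    if (!any(mask)) next
    pG <- gc / 2 * (1 + amp * s)
    pC <- gc - pG
    bases[mask] <- sample(c("A", "C", "G", "T"), sum(mask), replace = TRUE,
                          prob = c((1 - gc) / 2, pC, pG, (1 - gc) / 2))
  }
  dna <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(dna) <- contig

  ## gene placement: bulk-draw lengths and intergenic gaps, then cumsum
  n_guess <- ceiling(L / 700)
  lens <- pmax(150L, as.integer(round(rlnorm(n_guess, log(900), 0.45))))
  gaps <- 20L + rpois(n_guess, 80)
  starts <- cumsum(gaps + c(0L, head(lens, -1L)))
  keep <- starts + lens <= L
  starts <- starts[keep]; lens <- lens[keep]
  feats <- data.frame(start = starts, end = starts + lens,
                      stringsAsFactors = FALSE)

  ## tRNA anchors delimiting the scrapyard (end of left == island start,
  ## start of right == island end), plus a couple of background tRNAs
  trna <- NULL
  if (!is.null(sy)) {
    trna <- data.frame(
      start = c(sy$start - 85L, sy$end),
      end = c(sy$start, sy$end + 85L),
      product = c("tRNA-Ser-CGA", "tRNA-Val-CAC"),
      stringsAsFactors = FALSE)
  }
  extra_pos <- as.integer(L * c(0.55, 0.9))
  trna <- rbind(trna, data.frame(start = extra_pos, end = extra_pos + 85L,
                                 product = c("tRNA-Met-CAT", "tRNA-Gly-GCC"),
                                 stringsAsFactors = FALSE))
  overlaps_trna <- vapply(seq_len(nrow(feats)), function(i)
    any(feats$start[i] < trna$end & feats$end[i] > trna$start),
    logical(1L))
  feats <- feats[!overlaps_trna, , drop = FALSE]

  in_sy <- if (is.null(sy)) rep(FALSE, nrow(feats)) else
    feats$start >= sy$start & feats$start < sy$end
  pick_products <- function(n, props) {
    cat <- sample(names(props), n, replace = TRUE, prob = props)
    prod <- character(n)
    prod[cat == "HP"] <- HP_PRODUCTS
    prod[cat == "ME"] <- sample(ME_PRODUCTS, sum(cat == "ME"), replace = TRUE)
    prod[cat == "PHAGE"] <- sample(PHAGE_PRODUCTS, sum(cat == "PHAGE"),
                                   replace = TRUE)
    prod[cat == "FUNCTIONAL"] <- sample(FUNCTIONAL_PRODUCTS,
                                        sum(cat == "FUNCTIONAL"),
                                        replace = TRUE)
    prod
  }
  feats$product <- NA_character_
  feats$product[in_sy] <- pick_products(sum(in_sy), config$scrapyard_props)
  feats$product[!in_sy] <- pick_products(sum(!in_sy), config$outside_props)
  feats$type <- "CDS"
  trna$type <- "tRNA"
  all_feats <- rbind(feats[, c("start", "end", "product", "type")],
                     trna[, c("start", "end", "product", "type")])
  all_feats <- all_feats[order(all_feats$start), ]
  n <- nrow(all_feats)
  features <- data.frame(
    id = sprintf("gene_%05d", seq_len(n)),
    contig = contig,
    start = as.integer(all_feats$start), end = as.integer(all_feats$end),
    strand = sample(c("+", "-"), n, replace = TRUE),
    type = all_feats$type, product = all_feats$product,
    category = classify_gene_category(all_feats$product, all_feats$type),
    stringsAsFactors = FALSE)

  genome <- annotated_genome(dna, features, circular = TRUE)
  list(genome = genome,
       truth = list(scrapyard = sy),
       config = config)
}

## ---- population -----------------------------------------------------------

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## IS-like element: terminal inverted repeats flanking a random core
make_element <- function(len, tir_len) {
  tir <- random_dna(tir_len, 0.5)
  core <- random_dna(len - 2L * tir_len, 0.55)
  paste0(tir, core,
         as.character(Biostrings::reverseComplement(
           Biostrings::DNAString(tir))))
}

#' Simulate a haplotype population over a genome
#'
#' Plants short sequence variants (mostly 1 bp substitutions, some short
#' indels) as a Poisson process with region-specific rates, and IS-element
#' insertions (with terminal inverted repeats and a 4-8 bp target-site
#' duplication) at the configured population frequencies.  Each variant is
#' materialized on a random subset of the haplotype pool whose size is the
#' nearest realizable count for its drawn frequency, so linked variants
#' co-occur within haplotypes as in a clonal population.
#'
#' @param sim Output of [simulate_genome()].
#' @param config A [sim_config()] (defaults to the one inside `sim`).
#' @return List of class `"sim_population"` with `genome`, `haplotypes`
#'   (DNAStringSet), `hap_maps` (per-haplotype alignment maps to the
#'   reference), `elements` (DNAStringSet IS library) and `truth` (list with
#'   `scrapyard`, `ssv` and `insertions` data frames).
#' @export
simulate_population <- function(sim, config = sim$config) {
  set_stage_seed(config$seed, "population")
  genome <- sim$genome
  L <- genome_length(genome)
  contig <- names(genome$seq)[1L]
  refseq <- genome$seq[[1L]]
  H <- config$n_haplotypes
  sy <- config$scrapyard

  ## SSV loci: Poisson per region, uniform positions, min 10 bp spacing
  draw_positions <- function(start, end, rate) {
    n <- rpois(1L, rate * (end - start))
    sort(sample.int(end - start, min(n, max(0L, (end - start) %/% 12L))) - 1L
         + start)
  }
  if (is.null(sy)) {
    pos <- draw_positions(0L, L, config$ssv_rate_outside)
    in_sy <- rep(FALSE, length(pos))
  } else {
    p1 <- draw_positions(0L, sy$start, config$ssv_rate_outside)
    p2 <- draw_positions(sy$start, sy$end, config$ssv_rate_scrapyard)
    p3 <- draw_positions(sy$end, L, config$ssv_rate_outside)
    pos <- c(p1, p2, p3)
    in_sy <- pos >= sy$start & pos < sy$end
  }
  ord <- order(pos)
  pos <- pos[ord]; in_sy <- in_sy[ord]
  keep <- c(TRUE, diff(pos) >= 10L) & pos >= 10L & pos < L - 10L
  pos <- pos[keep]; in_sy <- in_sy[keep]
  n_ssv <- length(pos)

  kind <- sample(c("SNV", "INS", "DEL"), n_ssv, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  indel_len <- sample(1:3, n_ssv, replace = TRUE)
  ref_base <- as.character(Biostrings::extractAt(
    refseq, IRanges::IRanges(pos + 1L, width = 1L)))
  other <- function(b) vapply(b, function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
  freqs <- runif(n_ssv, config$freq_range[1L], config$freq_range[2L])
  carriers <- pmin(H, pmax(1L, as.integer(round(freqs * H))))

  ## VCF-style left-anchored representation
  ssv <- data.frame(contig = rep(contig, n_ssv), pos = pos, kind = kind,
                    freq = carriers / H, carriers = carriers,
                    in_scrapyard = in_sy, stringsAsFactors = FALSE)
  ssv$ref <- ref_base
  ssv$alt <- ref_base
  is_snv <- kind == "SNV"
  ssv$alt[is_snv] <- other(ref_base[is_snv])
  ins_seq <- vapply(indel_len, random_dna, character(1L), gc = config$gc)
  is_ins <- kind == "INS"
  ssv$alt[is_ins] <- paste0(ref_base[is_ins],
                            substr(ins_seq[is_ins], 1L, indel_len[is_ins]))
  is_del <- kind == "DEL"
  if (any(is_del)) {
    del_ref <- as.character(Biostrings::extractAt(
      refseq, IRanges::IRanges(pos[is_del] + 1L,
                               width = 1L + indel_len[is_del])))
    ssv$ref[is_del] <- del_ref
  }

  ## IS element library
  elem_ids <- unique(c(if (!is.null(config$insertions))
    config$insertions$element, paste0("ISFm", seq_len(config$n_elements))))
  elem_len <- sample(900:1500, length(elem_ids), replace = TRUE)
  tir_len <- sample(15:25, length(elem_ids), replace = TRUE)
  elements <- Biostrings::DNAStringSet(
    vapply(seq_along(elem_ids), function(i)
      make_element(elem_len[i], tir_len[i]), character(1L)))
  names(elements) <- elem_ids

  ## ME insertions: pick a target feature (or intergenic gap), duplicate a
  ## 4-8 bp target site
  specs <- config$insertions
  feats <- genome$features
  cds <- feats[feats$type == "CDS", ]
  ins_rows <- list()
  if (!is.null(specs) && nrow(specs)) {
    for (i in seq_len(nrow(specs))) {
      f <- specs$frequency[i]
      carr <- if (f <= 0) 0L else pmin(H, pmax(1L, as.integer(round(f * H))))
      tgt <- specs$target[i]
      if (tgt == "INTERGENIC") {
        gaps_start <- head(cds$end, -1L)
        gaps_end <- cds$start[-1L]
        ok <- which(gaps_end - gaps_start >= 100L)
        g <- sample(ok, 1L)
        bp <- as.integer(round((gaps_start[g] + gaps_end[g]) / 2))
        gene_id <- NA_character_
      } else {
        cand <- cds[cds$category == tgt & (cds$end - cds$start) >= 300L, ]
        if (!nrow(cand)) stop("no simulated gene of category ", tgt,
                              " available as insertion target")
        j <- sample(nrow(cand), 1L)
        bp <- as.integer(round((cand$start[j] + cand$end[j]) / 2))
        gene_id <- cand$id[j]
      }
      tsd <- sample(4:8, 1L)
      tsd_seq <- as.character(Biostrings::extractAt(
        refseq, IRanges::IRanges(bp + 1L, width = tsd)))
      payload <- paste0(as.character(elements[[specs$element[i]]]), tsd_seq)
      ins_rows[[i]] <- data.frame(
        contig = contig, breakpoint = bp, element = specs$element[i],
        length = nchar(payload), tsd = tsd, freq = carr / H,
        carriers = carr, target = tgt, disrupted_gene = gene_id,
        payload = payload, stringsAsFactors = FALSE)
    }
  }
  insertions <- if (length(ins_rows)) do.call(rbind, ins_rows) else
    data.frame(contig = character(), breakpoint = integer(),
               element = character(), length = integer(), tsd = integer(),
               freq = numeric(), carriers = integer(), target = character(),
               disrupted_gene = character(), payload = character(),
               stringsAsFactors = FALSE)

  ## drop SSVs colliding with insertion breakpoints
  if (nrow(insertions)) {
    near <- vapply(ssv$pos, function(p)
      any(abs(p - insertions$breakpoint) < 25L), logical(1L))
    ssv <- ssv[!near, , drop = FALSE]
  }
  rownames(ssv) <- NULL

  ## assign carriers
  ssv_carriers <- lapply(ssv$carriers, function(k) sample.int(H, k))
  ins_carriers <- lapply(insertions$carriers, function(k)
    if (k > 0L) sample.int(H, k) else integer())

  ## materialize haplotypes
  hap_seqs <- vector("list", H)
  hap_maps <- vector("list", H)
  for (h in seq_len(H)) {
    has_ssv <- vapply(ssv_carriers, function(x) h %in% x, logical(1L))
    has_ins <- vapply(ins_carriers, function(x) h %in% x, logical(1L))
    edits <- build_edit_table(ssv[has_ssv, , drop = FALSE],
                              insertions[has_ins, , drop = FALSE])
    hap_seqs[[h]] <- apply_edits(refseq, edits)
    hap_maps[[h]] <- build_hap_map(L, edits)
  }
  haplotypes <- Biostrings::DNAStringSet(hap_seqs)
  names(haplotypes) <- sprintf("hap_%02d", seq_len(H))

  structure(list(genome = genome, haplotypes = haplotypes,
                 hap_maps = hap_maps, elements = elements,
                 truth = list(scrapyard = sim$truth$scrapyard,
                              ssv = ssv, insertions = insertions),
                 config = config),
            class = "sim_population")
}

## Edit table: one row per non-identity edit, in reference coordinates.
## ref_pos is 0-based; for indels it is the anchor base (VCF-style), and the
## edited reference span is [ref_pos, ref_pos + ref_len).
build_edit_table <- function(ssv, insertions) {
  rows <- list()
  if (nrow(ssv)) {
    rows[[1L]] <- data.frame(
      ref_pos = ssv$pos,
      ref_len = nchar(ssv$ref),
      alt = ssv$alt, stringsAsFactors = FALSE)
  }
  if (nrow(insertions)) {
    ## payload inserted after the breakpoint base: anchor the edit at the
    ## breakpoint with ref_len 0 (pure insertion between bp-1 and bp)
    rows[[length(rows) + 1L]] <- data.frame(
      ref_pos = insertions$breakpoint,
      ref_len = 0L,
      alt = insertions$payload, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(ref_pos = integer(), ref_len = integer(),
                      alt = character(), stringsAsFactors = FALSE))
  ed <- do.call(rbind, rows)
  ed[order(ed$ref_pos), , drop = FALSE]
}

apply_edits <- function(refseq, edits) {
  if (!nrow(edits)) return(refseq)
  Biostrings::replaceAt(
    refseq,
    IRanges::IRanges(start = edits$ref_pos + 1L, width = edits$ref_len),
    as.character(edits$alt))
}

## Piecewise alignment map of a haplotype to the reference: rows of type M
## (match/mismatch), I (bases present only in the haplotype) and D (bases
## present only in the reference), with half-open coordinates in both frames.
build_hap_map <- function(L, edits) {
  type <- character(); hs <- integer(); he <- integer()
  rs <- integer(); re <- integer()
  rp <- 0L; hp <- 0L
  add <- function(t, h1, h2, r1, r2) {
    type[length(type) + 1L] <<- t
    hs[length(hs) + 1L] <<- h1; he[length(he) + 1L] <<- h2
    rs[length(rs) + 1L] <<- r1; re[length(re) + 1L] <<- r2
  }
  for (i in seq_len(nrow(edits))) {
    e_pos <- edits$ref_pos[i]; e_rlen <- edits$ref_len[i]
    alt_len <- nchar(edits$alt[i])
    ## SNV (ref_len == alt_len): leave inside the M block
    if (e_rlen == nchar(edits$alt[i])) next
    ## indel anchored at ref_pos: the anchor base stays M, the event starts
    ## one base later (for pure insertions ref_len == 0, event at ref_pos)
    if (e_rlen == 0L) {
      ev_ref <- e_pos; ins_len <- alt_len; del_len <- 0L
    } else {
      ev_ref <- e_pos + 1L
      ins_len <- alt_len - 1L
      del_len <- e_rlen - 1L
    }
    if (ev_ref > rp) {
      w <- ev_ref - rp
      add("M", hp, hp + w, rp, rp + w); hp <- hp + w; rp <- rp + w
    }
    if (ins_len > 0L) { add("I", hp, hp + ins_len, rp, rp); hp <- hp + ins_len }
    if (del_len > 0L) { add("D", hp, hp, rp, rp + del_len); rp <- rp + del_len }
  }
  if (rp < L) add("M", hp, hp + (L - rp), rp, L)
  ## plain list of parallel vectors: hot path for read projection
  list(type = type, hap_start = hs, hap_end = he,
       ref_start = rs, ref_end = re, n = length(type))
}

## Project a haplotype interval [s, e) onto the reference: returns the
## 0-based reference start and a CIGAR whose query length is e - s.
## Haplotype-only bases at the read edges become soft clips.
project_read <- function(map, s, e) {
  ops <- character(); lens <- integer()
  ref_start <- NA_integer_
  ## rows are sorted by hap_start; restrict the scan to the overlap window
  i_lo <- max(1L, findInterval(s, map$hap_start))
  while (i_lo > 1L && map$hap_end[i_lo - 1L] > s) i_lo <- i_lo - 1L
  i_hi <- min(map$n, findInterval(e, map$hap_start) + 1L)
  for (i in i_lo:i_hi) {
    t <- map$type[i]
    if (t == "D") {
      b <- map$hap_start[i]
      if (b > s && b < e) { ops <- c(ops, "D"); lens <- c(lens,
        map$ref_end[i] - map$ref_start[i]) }
      next
    }
    lo <- max(s, map$hap_start[i]); hi <- min(e, map$hap_end[i])
    if (hi <= lo) next
    if (t == "M" && is.na(ref_start))
      ref_start <- map$ref_start[i] + (lo - map$hap_start[i])
    ops <- c(ops, t); lens <- c(lens, hi - lo)
  }
  ## leading/trailing I -> S; drop edge D ops
  while (length(ops) && ops[1L] == "D") { ops <- ops[-1L]; lens <- lens[-1L] }
  while (length(ops) && ops[length(ops)] == "D") {
    ops <- head(ops, -1L); lens <- head(lens, -1L)
  }
  if (!length(ops) || !any(ops == "M"))
    return(NULL)  # read falls entirely inside haplotype-only sequence
  first_m <- which(ops == "M")[1L]; last_m <- tail(which(ops == "M"), 1L)
  ops[seq_len(first_m - 1L)][ops[seq_len(first_m - 1L)] == "I"] <- "S"
  if (last_m < length(ops)) {
    idx <- (last_m + 1L):length(ops)
    ops[idx][ops[idx] == "I"] <- "S"
  }
  ## drop D ops stranded outside the clipped core
  keep <- rep(TRUE, length(ops))
  keep[seq_len(first_m - 1L)] <- ops[seq_len(first_m - 1L)] != "D"
  if (last_m < length(ops))
    keep[(last_m + 1L):length(ops)] <- ops[(last_m + 1L):length(ops)] != "D"
  ops <- ops[keep]; lens <- lens[keep]
  ## merge adjacent identical ops
  r <- rle(paste0(ops))
  grp <- rep(seq_along(r$lengths), r$lengths)
  lens <- as.integer(tapply(lens, grp, sum))
  ops <- r$values
  list(pos = ref_start, cigar = paste0(lens, ops, collapse = ""))
}
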