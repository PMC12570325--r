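# Seeded synthetic-cohort generator. Emits a complete toy dataset -- gene
# models, junction counts, outlier p-values, annotated VCF, genotypes,
# phenotypes, frequency/TPM/blacklist side tables -- with planted crsQTL
# structure, so every pipeline stage can be exercised without external data.
#
# Defaults mirror the cohorts the framework was designed around: a WGS
# case-control cohort of 6,625 cases / 2,472 controls and an RNA-seq
# reference cohort of 294 patient / 76 control donors profiled in 1-4 CNS
# tissues. Outlier p-values are generated directly (uniform under the null,
# near-zero for planted carriers); the upstream outlier model itself is out
# of scope and consumed as input.

#' Simulation configuration
#'
#' @param seed Master seed. Each output stream derives its own seed from it
#'   (seed + a fixed offset), so adding an output never perturbs existing
#'   ones. Identical config + seed gives byte-identical output files.
#' @param n_genes,exons_per_gene,exon_len,intron_len Toy genome shape.
#' @param n_cases,n_controls WGS cohort sizes.
#' @param n_rna_cases,n_rna_controls RNA reference cohort donor counts.
#' @param tissues Tissue names; donors are profiled in 1 to
#'   `length(tissues)` of them.
#' @param planted List of planted crsQTLs, each a list with `gene_index`,
#'   `skip_exon`, `n_pathogenic`, `odds_ratio`, `carrier_freq` (per-set
#'   control carrier frequency), `n_rna_carriers` (RNA donors expressing the
#'   junction).
#' @param n_benign,benign_carrier_freq Benign splice-scored variants:
#'   qualifying delta scores but sites matching no reference junction,
#'   carried equally in cases and controls.
#' @param pathogenic_delta,benign_delta Delta-score ranges.
#' @return Object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 6L, exons_per_gene = 5L,
                       exon_len = 120L, intron_len = 300L,
                       n_cases = 6625L, n_controls = 2472L,
                       n_rna_cases = 294L, n_rna_controls = 76L,
                       tissues = c("frontal_cortex", "motor_cortex",
                                   "cervical_cord", "lumbar_cord"),
                       planted = list(list(gene_index = 1L, skip_exon = 3L,
                                           n_pathogenic = 3L, odds_ratio = 20,
                                           carrier_freq = 1e-4,
                                           n_rna_carriers = 3L)),
                       n_benign = 23L, benign_carrier_freq = 6e-4,
                       pathogenic_delta = c(0.5, 0.95),
                       benign_delta = c(0.25, 0.8)) {
  cfg <- as.list(environment())
  for (nm in c("n_genes", "exons_per_gene", "exon_len", "intron_len",
               "n_cases", "n_controls", "n_rna_cases", "n_rna_controls")) {
    if (cfg[[nm]] != as.integer(cfg[[nm]])) stop(nm, " must be an integer")
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  for (pl in cfg$planted) {
    stopifnot(pl$carrier_freq > 0, pl$carrier_freq < 1, pl$odds_ratio > 0,
              pl$skip_exon > 1L, pl$skip_exon < exons_per_gene,
              pl$gene_index >= 1L, pl$gene_index <= n_genes)
    if (pl$n_rna_carriers > n_rna_cases) {
      stop("infeasible config: n_rna_carriers exceeds RNA case donors")
    }
    p_case <- .carrier_prob_case(pl$carrier_freq, pl$odds_ratio)
    if (p_case * n_cases < 1) {
      stop("infeasible config: expected planted case carriers < 1")
    }
  }
  stopifnot(benign_carrier_freq > 0, benign_carrier_freq < 1)
  structure(cfg, class = "SimConfig")
}

.carrier_prob_case <- function(f_ctrl, odds_ratio) {
  odds <- odds_ratio * f_ctrl / (1 - f_ctrl)
  odds / (1 + odds)
}

# deterministic toy genome layout (no randomness)
.gene_layout <- function(cfg) {
  lapply(seq_len(cfg$n_genes), function(g) {
    chrom <- as.character(1L + (g - 1L) %% 2L)
    strand <- if (g %% 2L == 1L) "+" else "-"
    off <- 100000L * g
    starts <- off + (seq_len(cfg$exons_per_gene) - 1L) *
      (cfg$exon_len + cfg$intron_len)
    list(gene_id = sprintf("G%02d", g), symbol = sprintf("GENE%d", g),
         chrom = chrom, strand = strand,
         exons = data.table::data.table(start = starts,
                                        end = starts + cfg$exon_len - 1L))
  })
}

.gtf_lines <- function(layout) {
  unlist(lapply(layout, function(g) {
    span <- c(min(g$exons$start), max(g$exons$end))
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$symbol)
    tx <- paste0(g$gene_id, ".t1")
    attr_t <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s"; tag "basic";',
                      g$gene_id, g$symbol, tx)
    c(
      sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, span[1], span[2], g$strand, attr_g),
      sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, span[1], span[2], g$strand, attr_t),
      sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
              g$chrom, g$exons$start, g$exons$end, g$strand, attr_t,
              seq_len(nrow(g$exons)))
    )
  }))
}

.annotated_introns <- function(g) {
  n <- nrow(g$exons)
  data.table::data.table(
    chrom = g$chrom,
    start = g$exons$end[-n] + 1L,
    end = g$exons$start[-1L] - 1L,
    strand = g$strand
  )
}

# junction skipping exon k, plus the acceptor site of the skipped exon
# (strictly interior to the junction interval)
.planted_junction <- function(g, k) {
  s <- g$exons$end[k - 1L] + 1L
  e <- g$exons$start[k + 1L] - 1L
  acc <- if (g$strand == "+") g$exons$start[k] - 1L else g$exons$end[k] + 1L
  list(chrom = g$chrom, start = s, end = e, strand = g$strand,
       junction_id = junction_id(g$chrom, s, e, g$strand),
       skipped_acceptor = acc, gene = g)
}

# pathogenic variants: qualifying acceptor-loss predictions pointing at the
# skipped exon's annotated acceptor site
.pathogenic_variants <- function(pj, n, delta_range) {
  g <- pj$gene
  sgn <- if (g$strand == "+") -1L else 1L
  pos <- pj$skipped_acceptor + sgn * (50L + seq_len(n) - 1L)
  delta <- round(stats::runif(n, delta_range[1], delta_range[2]), 2)
  dp <- pj$skipped_acceptor - pos
  data.table::data.table(
    chrom = g$chrom, pos = pos, ref = "A", alt = "C",
    gene = g$symbol, role = "pathogenic",
    ds_ag = 0, ds_al = delta, ds_dg = 0, ds_dl = 0,
    dp_ag = 0L, dp_al = dp, dp_dg = 0L, dp_dl = 0L
  )
}

# benign variants: qualifying donor-gain scores at unannotated mid-exon
# sites that coincide with no reference junction boundary
.benign_variants <- function(g, n, delta_range, avoid = integer()) {
  ex <- g$exons
  pos <- integer(0)
  i <- 0L
  while (length(pos) < n) {
    k <- (i %% nrow(ex)) + 1L
    cand <- ex$start[k] + 20L + 2L * (i %/% nrow(ex))
    if (cand <= ex$end[k] - 30L && !cand %in% c(pos, avoid)) {
      pos <- c(pos, cand)
    }
    i <- i + 1L
    if (i > 10000L) stop("could not place benign variants in gene ", g$gene_id)
  }
  delta <- round(stats::runif(n, delta_range[1], delta_range[2]), 2)
  data.table::data.table(
    chrom = g$chrom, pos = pos, ref = "G", alt = "T",
    gene = g$symbol, role = "benign",
    ds_ag = 0, ds_al = 0, ds_dg = delta, ds_dl = 0,
    dp_ag = 0L, dp_al = 0L, dp_dg = 7L, dp_dl = 0L
  )
}

.variant_ids <- function(vt) sprintf("%s:%d:%s:%s", vt$chrom, vt$pos, vt$ref, vt$alt)

# carrier draws for one planted set: Bernoulli per sample with
# case/control-specific probabilities implied by the odds ratio
.draw_planted_genotypes <- function(status, variant_ids, f_ctrl, odds_ratio) {
  n <- length(status)
  p <- ifelse(status == 1, .carrier_prob_case(f_ctrl, odds_ratio), f_ctrl)
  carrier <- stats::rbinom(n, 1L, p) == 1L
  geno <- matrix(0L, nrow = length(variant_ids), ncol = n,
                 dimnames = list(variant_ids, NULL))
  if (any(carrier)) {
    which_v <- sample.int(length(variant_ids), sum(carrier), replace = TRUE)
    geno[cbind(which_v, which(carrier))] <- 1L
  }
  geno
}

.draw_benign_genotypes <- function(n_samples, variant_ids, freq) {
  geno <- matrix(stats::rbinom(length(variant_ids) * n_samples, 1L, freq),
                 nrow = length(variant_ids),
                 dimnames = list(variant_ids, NULL))
  storage.mode(geno) <- "integer"
  geno
}

.spliceai_entry <- function(vt) {
  vapply(seq_len(nrow(vt)), function(i) {
    format_spliceai_info(vt$alt[i], vt$gene[i],
                         c(vt$ds_ag[i], vt$ds_al[i], vt$ds_dg[i], vt$ds_dl[i]),
                         c(vt$dp_ag[i], vt$dp_al[i], vt$dp_dg[i], vt$dp_dl[i]))
  }, "")
}

.pangolin_entry <- function(vt) {
  vapply(seq_len(nrow(vt)), function(i) {
    if (vt$role[i] == "pathogenic") {
      sprintf("%s|0:0.00|%d:%s|", vt$gene[i], vt$dp_al[i],
              formatC(-vt$ds_al[i], format = "f", digits = 2))
    } else {
      sprintf("%s|%d:%s|0:0.00|", vt$gene[i], vt$dp_dg[i],
              formatC(vt$ds_dg[i], format = "f", digits = 2))
    }
  }, "")
}

.predictions_from_spec <- function(vt) {
  vid <- .variant_ids(vt)
  data.table::rbindlist(lapply(seq_len(nrow(vt)), function(i) {
    data.table::data.table(
      variant_id = vid[i], source = "spliceai", gene = vt$gene[i],
      event = c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss"),
      delta_score = c(vt$ds_ag[i], vt$ds_al[i], vt$ds_dg[i], vt$ds_dl[i]),
      site_pos = vt$pos[i] + c(vt$dp_ag[i], vt$dp_al[i], vt$dp_dg[i], vt$dp_dl[i])
    )
  }))
}

.write_vcf <- function(path, vt, geno, sample_names) {
  ord <- order(vt$chrom, vt$pos)
  vt <- vt[ord, ]
  geno <- geno[ord, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(vt$chrom), ">"),
    paste0("##INFO=<ID=SpliceAI,Number=.,Type=String,Description=\"SpliceAI",
           " format: ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL\">"),
    paste0("##INFO=<ID=Pangolin,Number=.,Type=String,Description=\"Pangolin",
           " format: GENE|POS:LARGEST_INCREASE|POS:LARGEST_DECREASE|WARNINGS\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  info <- sprintf("SpliceAI=%s;Pangolin=%s", .spliceai_entry(vt), .pangolin_entry(vt))
  body <- vapply(seq_len(nrow(vt)), function(i) {
    paste(c(vt$chrom[i], vt$pos[i], ".", vt$ref[i], vt$alt[i], ".", ".",
            info[i], "GT", gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

#' Simulate a complete synthetic cohort bundle
#'
#' Writes, under `out_dir`: `genes.gtf`, `known_junctions.tsv`,
#' `junction_counts.tsv`, `outlier_pvalues.tsv`, `sample_sheet.tsv`,
#' `cohort.vcf`, `phenotypes.tsv`, `gnomad_freq.tsv`, `tpm.tsv`,
#' `blacklist.bed`. Planted crsQTL junctions are expressed (tiny outlier
#' p-values, non-zero counts) in `n_rna_carriers` case donors across at
#' least two tissues; planted pathogenic variants carry the configured odds
#' ratio in the WGS cohort genotypes.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Output directory (created if absent).
#' @return Invisible list with `paths`, `config`, and `truth` (planted
#'   junction ids, pathogenic/benign variant ids, WGS status vector).
#' @export
simulate_cohort <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "SimConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  layout <- .gene_layout(cfg)

  # --- gene annotation (deterministic) ---
  writeLines(.gtf_lines(layout), pth("genes.gtf"))
  introns <- data.table::rbindlist(lapply(layout, .annotated_introns))
  known <- data.table::data.table(chrom = introns$chrom, start = introns$start,
                                  end = introns$end, strand = introns$strand)
  data.table::fwrite(known, pth("known_junctions.tsv"), sep = "\t")

  # --- planted junctions & variants (stream: seed + 7) ---
  set.seed(cfg$seed + 7L)
  planted <- lapply(cfg$planted, function(pl) {
    pj <- .planted_junction(layout[[pl$gene_index]], pl$skip_exon)
    pj$spec <- pl
    pj$variants <- .pathogenic_variants(pj, pl$n_pathogenic, cfg$pathogenic_delta)
    pj
  })
  path_vt <- data.table::rbindlist(lapply(planted, `[[`, "variants"))
  benign_vt <- if (cfg$n_benign > 0L) {
    g1 <- layout[[cfg$planted[[1L]]$gene_index]]
    .benign_variants(g1, cfg$n_benign, cfg$benign_delta, avoid = path_vt$pos)
  } else NULL
  vt <- data.table::rbindlist(list(path_vt, benign_vt), use.names = TRUE)

  # --- WGS cohort: phenotypes & genotypes (streams: seed + 1, + 2) ---
  n_wgs <- cfg$n_cases + cfg$n_controls
  wgs_samples <- sprintf("S%05d", seq_len(n_wgs))
  status <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
  set.seed(cfg$seed + 2L)
  sex <- stats::rbinom(n_wgs, 1L, 0.5)
  data.table::fwrite(
    data.table::data.table(sample = wgs_samples, status = status, sex = sex),
    pth("phenotypes.tsv"), sep = "\t")

  set.seed(cfg$seed + 1L)
  geno_blocks <- lapply(seq_along(planted), function(i) {
    pj <- planted[[i]]
    .draw_planted_genotypes(status, .variant_ids(pj$variants),
                            pj$spec$carrier_freq, pj$spec$odds_ratio)
  })
  if (!is.null(benign_vt)) {
    geno_blocks <- c(geno_blocks, list(
      .draw_benign_genotypes(n_wgs, .variant_ids(benign_vt),
                             cfg$benign_carrier_freq)))
  }
  geno <- do.call(rbind, geno_blocks)
  colnames(geno) <- wgs_samples
  .write_vcf(pth("cohort.vcf"), vt, geno[.variant_ids(vt), , drop = FALSE],
             wgs_samples)

  # --- population frequencies: everything rare ---
  data.table::fwrite(
    data.table::data.table(chrom = vt$chrom, pos = vt$pos, ref = vt$ref,
                           alt = vt$alt, af_nonneuro = 1e-5, nhomalt_freq = 0),
    pth("gnomad_freq.tsv"), sep = "\t")

  # --- RNA reference cohort design (stream: seed + 6) ---
  set.seed(cfg$seed + 6L)
  n_rna <- cfg$n_rna_cases + cfg$n_rna_controls
  donors <- sprintf("D%04d", seq_len(n_rna))
  rna_status <- c(rep(1L, cfg$n_rna_cases), rep(0L, cfg$n_rna_controls))
  n_tis <- sample.int(length(cfg$tissues), n_rna, replace = TRUE)
  carrier_donors <- lapply(planted, function(pj) {
    sample(donors[rna_status == 1L], pj$spec$n_rna_carriers)
  })
  # expression in >= 2 tissues is required for replication; force it for carriers
  for (cd in carrier_donors) n_tis[match(cd, donors)] <- pmax(n_tis[match(cd, donors)], 2L)
  tissue_of <- lapply(seq_len(n_rna), function(i) {
    sort(sample(cfg$tissues, n_tis[i]))
  })
  ss <- data.table::rbindlist(lapply(seq_len(n_rna), function(i) {
    data.table::data.table(sample = paste(donors[i], tissue_of[[i]], sep = "_"),
                           donor = donors[i], tissue = tissue_of[[i]],
                           phenotype = rna_status[i])
  }))
  data.table::fwrite(ss, pth("sample_sheet.tsv"), sep = "\t")

  # --- outlier p-values (stream: seed + 3) ---
  set.seed(cfg$seed + 3L)
  null_jx <- junction_id(introns$chrom, introns$start, introns$end, introns$strand)
  ot_null <- data.table::data.table(
    junction_id = rep(null_jx, each = nrow(ss)),
    sample = rep(ss$sample, length(null_jx)),
    tissue = rep(ss$tissue, length(null_jx)),
    pvalue = stats::runif(length(null_jx) * nrow(ss))
  )
  ot_planted <- data.table::rbindlist(lapply(seq_along(planted), function(i) {
    cd <- carrier_donors[[i]]
    rows <- ss[ss$donor %in% cd, ]
    data.table::data.table(
      junction_id = planted[[i]]$junction_id,
      sample = rows$sample, tissue = rows$tissue,
      pvalue = 10^(-stats::runif(nrow(rows), 3.5, 6))
    )
  }))
  data.table::fwrite(data.table::rbindlist(list(ot_null, ot_planted)),
                     pth("outlier_pvalues.tsv"), sep = "\t")

  # --- junction counts (stream: seed + 4) ---
  set.seed(cfg$seed + 4L)
  all_jx <- c(null_jx, vapply(planted, `[[`, "", "junction_id"))
  cnt <- matrix(0L, nrow = length(all_jx), ncol = nrow(ss),
                dimnames = list(all_jx, ss$sample))
  cnt[seq_along(null_jx), ] <- stats::rpois(length(null_jx) * nrow(ss), 30)
  for (i in seq_along(planted)) {
    carrier_samples <- ss$sample[ss$donor %in% carrier_donors[[i]]]
    cnt[length(null_jx) + i, carrier_samples] <-
      stats::rpois(length(carrier_samples), 15) + 1L
  }
  ctdt <- data.table::data.table(junction_id = all_jx)
  ctdt <- cbind(ctdt, data.table::as.data.table(cnt))
  data.table::fwrite(ctdt, pth("junction_counts.tsv"), sep = "\t")

  # --- gene expression & blacklist (stream: seed + 5) ---
  set.seed(cfg$seed + 5L)
  data.table::fwrite(
    data.table::data.table(gene_id = vapply(layout, `[[`, "", "gene_id"),
                           median_tpm = round(stats::runif(cfg$n_genes, 5, 100), 2)),
    pth("tpm.tsv"), sep = "\t")
  writeLines("1\t5000\t6000\tblacklisted_region", pth("blacklist.bed"))

  files <- c("genes.gtf", "known_junctions.tsv", "junction_counts.tsv",
             "outlier_pvalues.tsv", "sample_sheet.tsv", "cohort.vcf",
             "phenotypes.tsv", "gnomad_freq.tsv", "tpm.tsv", "blacklist.bed")
  invisible(list(
    paths = stats::setNames(file.path(out_dir, files), files),
    config = cfg,
    truth = list(
      planted_junctions = vapply(planted, `[[`, "", "junction_id"),
      pathogenic_variants = .variant_ids(path_vt),
      benign_variants = if (is.null(benign_vt)) character() else .variant_ids(benign_vt),
      carrier_donors = carrier_donors,
      status = stats::setNames(status, wgs_samples)
    )
  ))
}

#' In-memory dilution scenario (pathogenic signal masked by benign variants)
#'
#' Builds the single-gene scenario in which a few pathogenic variants, all
#' matched to one planted exon-skipping reference junction, are diluted
#' among benign variants that carry qualifying splice scores but match no
#' junction. The crsQTL test collapses only the matched variants; the
#' gene burden test collapses everything with `max_delta >=` the threshold.
#'
#' @param n_pathogenic,n_benign Variant counts (default 3 and 23).
#' @param odds_ratio Planted effect for the pathogenic set, default 20.
#' @param carrier_freq Control carrier frequency of the pathogenic set,
#'   default 1e-4 (about 10 expected case carriers at the defaults).
#' @param benign_carrier_freq Per-benign-variant carrier frequency,
#'   default 6e-4, identical in cases and controls.
#' @param n_cases,n_controls Cohort sizes, default 5000/5000.
#' @param seed Optional seed; `NULL` uses the current RNG state (useful for
#'   replicate loops).
#' @param gm Optional pre-built single-gene `GeneModel` to reuse across
#'   replicates (saves re-parsing the toy GTF).
#' @return List with `gm`, `db` (one-junction reference table), `variants`,
#'   `predictions`, `genotypes`, `status`, `pathogenic_ids`, `benign_ids`,
#'   `gene` (symbol).
#' @export
make_fig1a_scenario <- function(n_pathogenic = 3L, n_benign = 23L,
                                odds_ratio = 20, carrier_freq = 1e-4,
                                benign_carrier_freq = 6e-4,
                                n_cases = 5000L, n_controls = 5000L,
                                seed = NULL, gm = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(seed = 0L, n_genes = 1L,
                    n_cases = n_cases, n_controls = n_controls,
                    planted = list(list(gene_index = 1L, skip_exon = 3L,
                                        n_pathogenic = max(n_pathogenic, 1L),
                                        odds_ratio = odds_ratio,
                                        carrier_freq = carrier_freq,
                                        n_rna_carriers = 1L)),
                    n_benign = n_benign)
  layout <- .gene_layout(cfg)
  g <- layout[[1L]]
  if (is.null(gm)) {
    gtf <- tempfile(fileext = ".gtf")
    writeLines(.gtf_lines(layout), gtf)
    gm <- load_gene_model(gtf, basic_only = TRUE)
    unlink(gtf)
  }
  pj <- .planted_junction(g, 3L)

  path_vt <- if (n_pathogenic > 0L) {
    .pathogenic_variants(pj, n_pathogenic, cfg$pathogenic_delta)
  } else NULL
  benign_vt <- if (n_benign > 0L) {
    .benign_variants(g, n_benign, cfg$benign_delta,
                     avoid = if (is.null(path_vt)) integer() else path_vt$pos)
  } else NULL
  vt <- data.table::rbindlist(list(path_vt, benign_vt), use.names = TRUE)
  if (nrow(vt) == 0L) stop("scenario needs at least one variant")
  vid <- .variant_ids(vt)

  status <- c(rep(1L, n_cases), rep(0L, n_controls))
  samples <- sprintf("S%05d", seq_along(status))
  blocks <- list()
  if (!is.null(path_vt)) {
    blocks <- c(blocks, list(.draw_planted_genotypes(
      status, .variant_ids(path_vt), carrier_freq, odds_ratio)))
  }
  if (!is.null(benign_vt)) {
    blocks <- c(blocks, list(.draw_benign_genotypes(
      length(status), .variant_ids(benign_vt), benign_carrier_freq)))
  }
  geno <- do.call(rbind, blocks)
  colnames(geno) <- samples

  preds <- .predictions_from_spec(vt)
  cat_ <- classify_junctions(pj$junction_id, gm)
  db <- data.table::data.table(
    junction_id = pj$junction_id, chrom = pj$chrom, start = pj$start,
    end = pj$end, strand = pj$strand,
    gene_id = attr(cat_, "gene_id"), category = as.character(cat_),
    meta_p = NA_real_, n_donors = NA_integer_, donors = NA_character_,
    provenance = "synthetic"
  )
  variants <- data.table::data.table(
    variant_id = vid, chrom = vt$chrom, pos = vt$pos, ref = vt$ref,
    alt = vt$alt,
    max_delta = pmax(vt$ds_ag, vt$ds_al, vt$ds_dg, vt$ds_dl),
    carrier_freq = rowMeans(geno >= 1L),
    hom_freq = rowMeans(geno == 2L),
    missing_rate = 0
  )
  list(gm = gm, db = db, variants = variants, predictions = preds,
       genotypes = geno, status = status, gene = g$symbol,
       pathogenic_ids = if (is.null(path_vt)) character() else .variant_ids(path_vt),
       benign_ids = if (is.null(benign_vt)) character() else .variant_ids(benign_vt))
}
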