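# Splice-altering prediction parsing (SpliceAI / Pangolin VCF INFO),
# per-variant maximum delta scores, cohort genotypes and rarity filters.

.spliceai_events <- c(DS_AG = "acceptor_gain", DS_AL = "acceptor_loss",
                      DS_DG = "donor_gain", DS_DL = "donor_loss")

# GT columns are read with a light text pass rather than readVcf's genotype
# parser: the latter pre-allocates several GiB on cohort-width (thousands of
# samples) plain VCFs, which does not fit the memory budget here.
.read_gt_dosage <- function(path) {
  dt <- data.table::fread(path, skip = "#CHROM", header = TRUE, sep = "\t",
                          colClasses = "character")
  cols <- names(dt)
  fmt <- match("FORMAT", cols)
  if (is.na(fmt) || fmt == length(cols)) return(NULL)
  samples <- cols[(fmt + 1L):length(cols)]
  gt <- as.matrix(dt[, samples, with = FALSE])
  gt <- sub(":.*", "", gt)              # GT is the first FORMAT field
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = list(NULL, samples))
  dos[gt == "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt == "1/1"] <- 2L
  dos
}

.read_cohort_vcf <- function(vcf) {
  geno <- NULL
  if (is.character(vcf)) {
    path <- vcf
    vcf <- VariantAnnotation::readVcf(
      path, param = VariantAnnotation::ScanVcfParam(geno = NA))
    geno <- .read_gt_dosage(path)
  } else {
    gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (!is.null(gt)) {
      clean <- gsub("|", "/", gt, fixed = TRUE)
      geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
      geno[clean == "0/0"] <- 0L
      geno[clean %in% c("0/1", "1/0")] <- 1L
      geno[clean == "1/1"] <- 2L
    }
  }
  alt <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt) != 1L)) {
    stop("multi-allelic records must be pre-split to one ALT per record")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  vid <- sprintf("%s:%d:%s:%s",
                 as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr),
                 as.character(VariantAnnotation::ref(vcf)),
                 as.character(unlist(alt)))
  if (!is.null(geno)) {
    if (nrow(geno) != length(vid)) {
      stop("genotype rows do not match VCF records")
    }
    rownames(geno) <- vid
  }
  list(vcf = vcf, variant_id = vid,
       chrom = as.character(GenomicRanges::seqnames(rr)),
       pos = GenomicRanges::start(rr),
       ref = as.character(VariantAnnotation::ref(vcf)),
       alt = as.character(unlist(alt)),
       genotypes = geno)
}

.variant_table <- function(v, preds) {
  dt <- data.table::data.table(
    variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
    ref = v$ref, alt = v$alt
  )
  if (nrow(preds) > 0L) {
    mx <- preds[, list(max_delta = max(delta_score)), by = "variant_id"]
    dt$max_delta <- mx$max_delta[match(dt$variant_id, mx$variant_id)]
  } else {
    dt$max_delta <- NA_real_
  }
  dt$max_delta[is.na(dt$max_delta)] <- 0
  if (!is.null(v$genotypes)) {
    g <- v$genotypes
    n <- ncol(g)
    dt$carrier_freq <- rowSums(g >= 1L, na.rm = TRUE) / n
    dt$hom_freq <- rowSums(g == 2L, na.rm = TRUE) / n
    dt$missing_rate <- rowSums(is.na(g)) / n
  } else {
    dt$carrier_freq <- dt$hom_freq <- dt$missing_rate <- NA_real_
  }
  dt
}

#' Parse SpliceAI predictions from an annotated VCF
#'
#' The `SpliceAI` INFO field follows the standard pipe-delimited layout
#' `ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`, with one
#' comma-separated entry per gene annotation. Each entry yields four
#' predictions (acceptor/donor x gain/loss); the predicted splice-site
#' genomic position is `POS + DP_event`, and the final per-variant score
#' (`max_delta`) is the maximum delta across all events and entries.
#'
#' @param vcf Path to a VCF 4.2 file (one ALT per record), or a `VCF` object.
#' @return List with components `variants` (one row per variant:
#'   `variant_id, chrom, pos, ref, alt, max_delta, carrier_freq, hom_freq,
#'   missing_rate`), `predictions` (one row per event:
#'   `variant_id, source, gene, event, delta_score, site_pos`), and
#'   `genotypes` (integer dosage matrix variants x samples, `NA` = missing),
#'   `NULL` when the VCF has no genotype columns.
#' @export
parse_spliceai <- function(vcf) {
  v <- .read_cohort_vcf(vcf)
  info <- VariantAnnotation::info(v$vcf)
  ann <- if ("SpliceAI" %in% names(info)) info$SpliceAI else NULL
  preds <- .empty_predictions()
  if (!is.null(ann)) {
    rows <- vector("list", length(v$variant_id))
    for (i in seq_along(v$variant_id)) {
      entries <- ann[[i]]
      entries <- entries[!is.na(entries) & nzchar(entries)]
      if (length(entries) == 0L) next
      per <- lapply(entries, function(ent) {
        f <- strsplit(ent, "|", fixed = TRUE)[[1L]]
        if (length(f) != 10L) {
          stop("malformed SpliceAI entry for variant ", v$variant_id[i], ": ", ent)
        }
        ds <- suppressWarnings(as.numeric(f[3:6]))
        dp <- suppressWarnings(as.integer(f[7:10]))
        if (anyNA(ds) || anyNA(dp)) {
          stop("non-numeric SpliceAI scores for variant ", v$variant_id[i])
        }
        data.table::data.table(
          variant_id = v$variant_id[i], source = "spliceai", gene = f[2L],
          event = unname(.spliceai_events), delta_score = ds,
          site_pos = v$pos[i] + dp
        )
      })
      rows[[i]] <- data.table::rbindlist(per)
    }
    got <- !vapply(rows, is.null, logical(1))
    if (any(got)) preds <- data.table::rbindlist(rows[got])
  }
  list(variants = .variant_table(v, preds), predictions = preds,
       genotypes = v$genotypes)
}

#' Parse Pangolin predictions from an annotated VCF
#'
#' The `Pangolin` INFO layout is
#' `GENE|pos:largest_increase|pos:largest_decrease|WARNINGS` (one entry per
#' gene, comma-separated). Scores are stored as absolute values with the
#' sign retained in `score_sign`; positive scores become `usage_increase`
#' events, negative `usage_decrease`.
#'
#' @inheritParams parse_spliceai
#' @return Same structure as [parse_spliceai()], with `source = "pangolin"`.
#' @export
parse_pangolin <- function(vcf) {
  v <- .read_cohort_vcf(vcf)
  info <- VariantAnnotation::info(v$vcf)
  ann <- if ("Pangolin" %in% names(info)) info$Pangolin else NULL
  preds <- .empty_predictions()
  if (!is.null(ann)) {
    rows <- vector("list", length(v$variant_id))
    for (i in seq_along(v$variant_id)) {
      entries <- ann[[i]]
      entries <- entries[!is.na(entries) & nzchar(entries)]
      if (length(entries) == 0L) next
      per <- lapply(entries, function(ent) {
        f <- strsplit(ent, "|", fixed = TRUE)[[1L]]
        if (length(f) < 3L) {
          stop("malformed Pangolin entry for variant ", v$variant_id[i], ": ", ent)
        }
        parse_ps <- function(tok) {
          ps <- strsplit(tok, ":", fixed = TRUE)[[1L]]
          if (length(ps) != 2L) {
            stop("malformed Pangolin position:score token for variant ",
                 v$variant_id[i], ": ", tok)
          }
          as.numeric(ps)
        }
        inc <- parse_ps(f[2L]); dec <- parse_ps(f[3L])
        data.table::data.table(
          variant_id = v$variant_id[i], source = "pangolin", gene = f[1L],
          event = c("usage_increase", "usage_decrease"),
          delta_score = abs(c(inc[2L], dec[2L])),
          score_sign = sign(c(inc[2L], dec[2L])),
          site_pos = v$pos[i] + as.integer(c(inc[1L], dec[1L]))
        )
      })
      rows[[i]] <- data.table::rbindlist(per)
    }
    got <- !vapply(rows, is.null, logical(1))
    if (any(got)) preds <- data.table::rbindlist(rows[got], fill = TRUE)
  }
  list(variants = .variant_table(v, preds), predictions = preds,
       genotypes = v$genotypes)
}

.empty_predictions <- function() {
  data.table::data.table(
    variant_id = character(), source = character(), gene = character(),
    event = character(), delta_score = numeric(), site_pos = integer()
  )
}

#' Format a SpliceAI INFO entry
#'
#' Inverse of the [parse_spliceai()] entry parser; used by the synthetic
#' generator so emitted annotations round-trip bit-exactly.
#'
#' @param alt ALT allele string.
#' @param gene Gene symbol.
#' @param ds Named or ordered numeric vector of the four delta scores
#'   (AG, AL, DG, DL).
#' @param dp Ordered integer vector of the four position offsets.
#' @return Single INFO entry string.
#' @export
format_spliceai_info <- function(alt, gene, ds, dp) {
  sprintf("%s|%s|%s|%s", alt, gene,
          paste(formatC(ds, format = "f", digits = 2), collapse = "|"),
          paste(as.integer(dp), collapse = "|"))
}

#' Read a population allele-frequency table
#'
#' @param path TSV with columns
#'   `chrom, pos, ref, alt, af_nonneuro, nhomalt_freq`.
#' @return `data.table` with a `variant_id` key column added.
#' @export
read_pop_freq <- function(path) {
  pf <- data.table::fread(path, colClasses = list(character = c("chrom", "ref", "alt")))
  req <- c("chrom", "pos", "ref", "alt", "af_nonneuro", "nhomalt_freq")
  if (!all(req %in% names(pf))) {
    stop("population frequency table must have columns ", paste(req, collapse = ", "))
  }
  pf[, "variant_id" := sprintf("%s:%d:%s:%s", pf$chrom, pf$pos, pf$ref, pf$alt)]
  pf[]
}

#' Rarity filter for qualifying variants
#'
#' Keeps variants strictly below the frequency thresholds in both the
#' population reference (gnomAD-style non-neurological controls) and the
#' study cohort. Under the allelic model the minor-allele/carrier
#' frequencies are compared; under the recessive model the homozygote
#' frequencies. Variants absent from the population table count as
#' frequency 0.
#'
#' @param variants Variant table from [parse_spliceai()]/[parse_pangolin()].
#' @param pop_freq Population table from [read_pop_freq()], or `NULL` to
#'   filter on cohort frequency only.
#' @param pop_af_max,cohort_carrier_max Strict upper thresholds,
#'   default 0.001 (0.1%).
#' @param model `"allelic"` or `"recessive"`.
#' @return Filtered variant table.
#' @export
rarity_filter <- function(variants, pop_freq = NULL, pop_af_max = 0.001,
                          cohort_carrier_max = 0.001,
                          model = c("allelic", "recessive")) {
  model <- match.arg(model)
  vt <- data.table::as.data.table(variants)
  cohort <- if (model == "allelic") vt$carrier_freq else vt$hom_freq
  cohort[is.na(cohort)] <- 0
  keep <- cohort < cohort_carrier_max
  if (!is.null(pop_freq)) {
    pf <- data.table::as.data.table(pop_freq)
    idx <- match(vt$variant_id, pf$variant_id)
    pop <- if (model == "allelic") pf$af_nonneuro[idx] else pf$nhomalt_freq[idx]
    pop[is.na(pop)] <- 0
    keep <- keep & pop < pop_af_max
  }
  vt[keep, ]
}
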