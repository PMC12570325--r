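# Reference junction database: outlier selection, QC filters, cross-tissue
# replication and Fisher meta-combination (cohort mode), plus the
# case/control detectability rule used for cryptic-exon reference panels.

#' Read the per-sample outlier p-value table
#'
#' Outlier p-values are an upstream input (LeafCutterMD-style); they are
#' consumed, never recomputed here.
#'
#' @param path TSV with columns `junction_id, sample, tissue, pvalue`.
#' @return `data.table` keyed by (junction_id, sample, tissue).
#' @export
read_outlier_table <- function(path) {
  ot <- data.table::fread(path)
  req <- c("junction_id", "sample", "tissue", "pvalue")
  if (!all(req %in% names(ot))) {
    stop("outlier table must have columns ", paste(req, collapse = ", "))
  }
  if (any(ot$pvalue <= 0 | ot$pvalue > 1)) {
    stop("outlier p-values must lie in (0, 1]")
  }
  if (anyDuplicated(ot[, req[1:3], with = FALSE])) {
    stop("duplicate (junction_id, sample, tissue) keys in outlier table")
  }
  ot
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample, donor, tissue, phenotype`
#'   (phenotype coded 0 = control, 1 = case).
#' @return `data.table`.
#' @export
read_sample_sheet <- function(path) {
  ss <- data.table::fread(path)
  req <- c("sample", "donor", "tissue", "phenotype")
  if (!all(req %in% names(ss))) {
    stop("sample sheet must have columns ", paste(req, collapse = ", "))
  }
  ss
}

#' Read a junction count matrix
#'
#' @param path TSV whose first column is `junction_id` and remaining columns
#'   are per-sample split-read counts.
#' @return `data.table` (junctions x samples).
#' @export
read_junction_counts <- function(path) {
  ct <- data.table::fread(path)
  if (names(ct)[1L] != "junction_id") {
    stop("first column of a junction count table must be 'junction_id'")
  }
  cnt <- as.matrix(ct[, -1L])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("junction counts must be non-negative integers")
  }
  ct
}

#' Convert RegTools junction BED lines to 1-based intron intervals
#'
#' RegTools emits BED12 where the block structure encodes anchor overhangs:
#' the intron starts at `chromStart + leftAnchor + 1` (1-based) and ends at
#' `chromEnd - rightAnchor`.
#'
#' @param path RegTools-style BED file.
#' @return `data.table` with `junction_id, chrom, start, end, strand, count`.
#' @export
read_regtools_junctions <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(bed) < 12L) stop("RegTools junction BED requires 12 columns")
  for (k in c(2L, 3L, 5L)) data.table::set(bed, j = k, value = as.integer(bed[[k]]))
  data.table::setnames(bed, 1:12, c("chrom", "chromStart", "chromEnd", "name",
                                    "score", "strand", "thickStart", "thickEnd",
                                    "rgb", "blockCount", "blockSizes", "blockStarts"))
  anchors <- data.table::tstrsplit(sub(",$", "", bed$blockSizes), ",", type.convert = TRUE)
  left <- anchors[[1L]]; right <- anchors[[2L]]
  out <- data.table::data.table(
    chrom = as.character(bed$chrom),
    start = bed$chromStart + left + 1L,
    end   = bed$chromEnd - right,
    strand = bed$strand,
    count = bed$score
  )
  out[, "junction_id" := junction_id(out$chrom, out$start, out$end, out$strand)]
  data.table::setcolorder(out, "junction_id")
  out[]
}

#' Select outlier junction observations
#'
#' @param ot Outlier table ([read_outlier_table()]).
#' @param alpha Significance cutoff; observations with `pvalue < alpha`
#'   (strict) are retained. Default 0.05.
#' @return Subset of `ot`.
#' @export
select_outlier_junctions <- function(ot, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ot[ot$pvalue < alpha, ]
}

#' Apply region-level QC filters to candidate junctions
#'
#' Removes junctions that (i) overlap an ENCODE-blacklist interval by at
#' least one base, (ii) lie in a gene whose median expression is below the
#' TPM floor (strict `<`), or (iii) sit on an excluded (sex) chromosome.
#' Junctions whose gene is missing from the TPM table are removed
#' conservatively, with a warning.
#'
#' @param junctions `data.table` with `junction_id, chrom, start, end,
#'   strand, gene_id`.
#' @param blacklist Path to a BED file, or a `GRanges`, of excluded regions;
#'   `NULL` to skip.
#' @param tpm_table `data.table` with `gene_id, median_tpm`; `NULL` to skip.
#' @param tpm_floor Median-TPM floor, default 2.
#' @param excluded_chroms Chromosomes dropped outright.
#' @return Filtered copy of `junctions`.
#' @export
apply_region_filters <- function(junctions, blacklist = NULL, tpm_table = NULL,
                                 tpm_floor = 2,
                                 excluded_chroms = c("chrX", "chrY", "X", "Y")) {
  jx <- data.table::as.data.table(junctions)
  keep <- !jx$chrom %in% excluded_chroms
  if (!is.null(blacklist)) {
    bl <- if (methods::is(blacklist, "GRanges")) blacklist else
      rtracklayer::import(blacklist, format = "bed")
    jgr <- GenomicRanges::GRanges(jx$chrom, IRanges::IRanges(jx$start, jx$end))
    hits <- GenomicRanges::countOverlaps(jgr, bl, ignore.strand = TRUE)
    keep <- keep & hits == 0L
  }
  if (!is.null(tpm_table)) {
    tpm <- data.table::as.data.table(tpm_table)
    med <- tpm$median_tpm[match(jx$gene_id, tpm$gene_id)]
    missing_gene <- is.na(med)
    if (any(missing_gene & keep)) {
      warning(sum(missing_gene & keep),
              " junction(s) removed: gene absent from TPM table")
    }
    keep <- keep & !missing_gene & med >= tpm_floor
  }
  jx[keep, ]
}

#' Require cross-tissue replication of outlier junctions within donors
#'
#' A junction is retained for a donor only when it is an outlier (already
#' selected by [select_outlier_junctions()]) in at least `min_tissues`
#' distinct tissue types of that same donor.
#'
#' @param outliers Outlier observations with columns
#'   `junction_id, sample, tissue` (and typically `pvalue`).
#' @param sample_sheet Sample sheet mapping `sample` to `donor`.
#' @param min_tissues Minimum distinct tissues per donor, default 2.
#' @return The outlier observations belonging to replicated
#'   (junction, donor) pairs, with a `donor` column added.
#' @export
require_cross_tissue_replication <- function(outliers, sample_sheet,
                                             min_tissues = 2L) {
  ot <- data.table::as.data.table(outliers)
  ss <- data.table::as.data.table(sample_sheet)
  ot <- merge(ot, ss[, c("sample", "donor")], by = "sample")
  reps <- ot[, list(n_tissues = length(unique(tissue))),
             by = c("junction_id", "donor")]
  ok <- reps[reps$n_tissues >= min_tissues, c("junction_id", "donor")]
  merge(ot, ok, by = c("junction_id", "donor"))
}

#' Combine p-values with Fisher's method
#'
#' The statistic is \eqn{X = -2 \sum_i \log p_i}, referred to a chi-square
#' distribution with \eqn{2k} degrees of freedom. For a single p-value the
#' combination is the identity.
#'
#' @param pvals Numeric vector of p-values in (0, 1], non-empty.
#' @return The combined (meta) p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) == 0L) stop("fisher_combine requires a non-empty p-value vector")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  x <- -2 * sum(log(pvals))
  stats::pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Build the cohort-mode reference junction database
#'
#' Pipeline: select outlier observations (`pvalue < alpha`), classify every
#' candidate junction and drop annotated and complex categories, apply
#' region filters, require cross-tissue replication within donors, and
#' Fisher-combine each replicated donor's tissue p-values. When several
#' donors carry a junction, the smallest per-donor meta p-value is stored
#' and all donors are recorded.
#'
#' @param outliers Outlier p-value table ([read_outlier_table()]).
#' @param sample_sheet Sample sheet ([read_sample_sheet()]).
#' @param gm `GeneModel`.
#' @param known_junctions Character vector of known junction ids.
#' @param blacklist,tpm_table,tpm_floor,excluded_chroms Passed to
#'   [apply_region_filters()].
#' @param alpha Outlier cutoff, default 0.05.
#' @param min_tissues Replication requirement, default 2.
#' @return `data.table` with one row per reference junction: `junction_id,
#'   chrom, start, end, strand, gene_id, category, meta_p, n_donors, donors,
#'   provenance = "cohort"`.
#' @export
build_reference_db <- function(outliers, sample_sheet, gm,
                               known_junctions = character(),
                               blacklist = NULL, tpm_table = NULL,
                               tpm_floor = 2,
                               excluded_chroms = c("chrX", "chrY", "X", "Y"),
                               alpha = 0.05, min_tissues = 2L) {
  sel <- select_outlier_junctions(outliers, alpha)
  if (nrow(sel) == 0L) return(.empty_reference_db("cohort"))

  jx <- parse_junction_id(unique(sel$junction_id))
  cat_ <- classify_junctions(jx, gm, known_junctions)
  jx$category <- as.character(cat_)
  jx$gene_id <- attr(cat_, "gene_id")
  jx <- jx[!jx$category %in% c("annotated", "complex"), ]
  if (nrow(jx) == 0L) return(.empty_reference_db("cohort"))

  jx <- apply_region_filters(jx, blacklist, tpm_table, tpm_floor, excluded_chroms)
  if (nrow(jx) == 0L) return(.empty_reference_db("cohort"))

  sel <- sel[sel$junction_id %in% jx$junction_id, ]
  rep_ot <- require_cross_tissue_replication(sel, sample_sheet, min_tissues)
  if (nrow(rep_ot) == 0L) return(.empty_reference_db("cohort"))

  donor_meta <- rep_ot[, list(meta_p = fisher_combine(pvalue)),
                       by = c("junction_id", "donor")]
  per_jx <- donor_meta[, list(
    meta_p = min(meta_p),
    n_donors = length(unique(donor)),
    donors = paste(sort(unique(donor)), collapse = ",")
  ), by = "junction_id"]

  db <- merge(jx, per_jx, by = "junction_id")
  db$provenance <- "cohort"
  data.table::setcolorder(db, c("junction_id", "chrom", "start", "end", "strand",
                                "gene_id", "category", "meta_p", "n_donors",
                                "donors", "provenance"))
  db[]
}

.empty_reference_db <- function(provenance) {
  data.table::data.table(
    junction_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), gene_id = character(),
    category = character(), meta_p = numeric(), n_donors = integer(),
    donors = character(), provenance = character()
  )
}

#' Build a cryptic-exon reference panel from case/control detectability
#'
#' A junction is retained when it is detectable (raw read count >= 1) in at
#' least one case sample and detectable in no more than 10% of control
#' samples (strictly more than the fraction removes it).
#'
#' @param counts Junction count table ([read_junction_counts()]).
#' @param sample_sheet Sample sheet; `phenotype` 1 marks cases.
#' @param gm Optional `GeneModel` used to annotate category and gene.
#' @param known_junctions Known junction ids for classification.
#' @param max_control_fraction Maximum tolerated control detectability,
#'   default 0.1.
#' @return Reference `data.table` with `provenance = "cryptic_exon"`.
#' @export
build_ce_reference <- function(counts, sample_sheet, gm = NULL,
                               known_junctions = character(),
                               max_control_fraction = 0.1) {
  ct <- data.table::as.data.table(counts)
  ss <- data.table::as.data.table(sample_sheet)
  samples <- setdiff(names(ct), "junction_id")
  pheno <- ss$phenotype[match(samples, ss$sample)]
  if (anyNA(pheno)) stop("count table contains samples absent from the sample sheet")
  if (!any(pheno == 1) || !any(pheno == 0)) {
    stop("cryptic-exon mode requires at least one case and one control sample")
  }
  mat <- as.matrix(ct[, samples, with = FALSE]) >= 1
  case_det <- rowSums(mat[, pheno == 1, drop = FALSE]) >= 1
  ctrl_frac <- rowMeans(mat[, pheno == 0, drop = FALSE])
  keep <- case_det & ctrl_frac <= max_control_fraction
  jx <- parse_junction_id(ct$junction_id[keep])
  if (nrow(jx) == 0L) return(.empty_reference_db("cryptic_exon"))
  if (!is.null(gm)) {
    cat_ <- classify_junctions(jx, gm, known_junctions)
    jx$category <- as.character(cat_)
    jx$gene_id <- attr(cat_, "gene_id")
  } else {
    jx$category <- NA_character_
    jx$gene_id <- NA_character_
  }
  jx$meta_p <- NA_real_
  jx$n_donors <- NA_integer_
  jx$donors <- NA_character_
  jx$provenance <- "cryptic_exon"
  data.table::setcolorder(jx, c("junction_id", "chrom", "start", "end", "strand",
                                "gene_id", "category", "meta_p", "n_donors",
                                "donors", "provenance"))
  jx[]
}

#' Write / read a reference junction database as TSV
#'
#' @param db Reference database table.
#' @param path Output path.
#' @export
write_reference_db <- function(db, path) {
  data.table::fwrite(db, path, sep = "\t")
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  data.table::fread(path, colClasses = list(character = c("chrom", "strand")))
}
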