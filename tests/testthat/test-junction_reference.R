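make_outliers <- function(...) {
  data.table::rbindlist(list(...), use.names = TRUE)
}
ot_row <- function(j, s, tis, p) {
  data.table::data.table(junction_id = j, sample = s, tissue = tis, pvalue = p)
}

test_that("outlier selection uses a strict p < alpha cutoff", {
  ot <- make_outliers(ot_row("j1", "a", "t1", 0.049), ot_row("j1", "b", "t1", 0.05),
                      ot_row("j2", "a", "t1", 0.010), ot_row("j2", "b", "t2", 0.9),
                      ot_row("j3", "a", "t1", 0.030), ot_row("j3", "b", "t2", 1.0))
  sel <- select_outlier_junctions(ot)
  expect_equal(nrow(sel), 3L)
  expect_false(any(sel$pvalue >= 0.05))
  all1 <- make_outliers(ot_row("j1", "a", "t1", 1), ot_row("j2", "b", "t2", 1))
  expect_equal(nrow(select_outlier_junctions(all1)), 0L)
})

test_that("region filters drop blacklist, low-TPM and sex-chromosome junctions", {
  jx <- data.table::data.table(
    junction_id = c("j_bl", "j_lowtpm", "j_ok", "j_x", "j_nogene"),
    chrom = c("1", "1", "1", "chrX", "1"),
    start = c(5500L, 9000L, 12000L, 100L, 15000L),
    end = c(5600L, 9100L, 12100L, 200L, 15100L),
    strand = "+",
    gene_id = c("GA", "GB", "GC", "GD", "GE"))
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t5000\t6000\tbad", bed)
  tpm <- data.table::data.table(gene_id = c("GA", "GB", "GC", "GD"),
                                median_tpm = c(50, 1.9, 2.0, 50))
  expect_warning(
    out <- apply_region_filters(jx, blacklist = bed, tpm_table = tpm),
    "absent from TPM")
  expect_identical(out$junction_id, "j_ok")  # TPM exactly 2.0 is kept
})

test_that("cross-tissue replication requires >= 2 tissues within one donor", {
  ss <- data.table::data.table(
    sample = c("A_mc", "A_lc", "B_mc", "C_mc"),
    donor = c("A", "A", "B", "C"),
    tissue = c("motor_cortex", "lumbar_cord", "motor_cortex", "motor_cortex"),
    phenotype = 1L)
  ot <- make_outliers(
    ot_row("j1", "A_mc", "motor_cortex", 0.01),  # replicates in donor A
    ot_row("j1", "A_lc", "lumbar_cord", 0.02),
    ot_row("j2", "A_mc", "motor_cortex", 0.01),  # one tissue in A, one in B
    ot_row("j2", "B_mc", "motor_cortex", 0.01),
    ot_row("j3", "C_mc", "motor_cortex", 1e-9))  # single-tissue donor
  kept <- require_cross_tissue_replication(ot, ss)
  expect_setequal(unique(kept$junction_id), "j1")
  expect_setequal(unique(kept$donor), "A")
})

test_that("Fisher combination matches its definition and invariants", {
  expect_equal(fisher_combine(0.03), 0.03)        # k = 1 identity
  expect_equal(fisher_combine(c(1, 1)), 1)
  # frozen oracle: Erlang(df=4) survival exp(-x/2)(1 + x/2) at x = -4 log(.05)
  x <- -4 * log(0.05)
  expect_equal(fisher_combine(c(0.05, 0.05)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
  expect_error(fisher_combine(numeric(0)), "non-empty")
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    expect_equal(fisher_combine(p), fisher_combine(sample(p)))  # permutation
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- p2[j] / 2
    expect_lte(fisher_combine(p2), fisher_combine(p))           # monotone
  }
})

test_that("cohort-mode reference building keeps only the planted junction", {
  cfg <- sim_config(seed = 7, n_cases = 50, n_controls = 50,
                    n_rna_cases = 30, n_rna_controls = 10,
                    planted = list(list(gene_index = 1L, skip_exon = 3L,
                                        n_pathogenic = 2L, odds_ratio = 20,
                                        carrier_freq = 0.02, n_rna_carriers = 3L)),
                    n_benign = 2)
  out <- file.path(tempdir(), "refdb_sim")
  bundle <- simulate_cohort(cfg, out)
  gm <- load_gene_model(bundle$paths[["genes.gtf"]])
  ot <- read_outlier_table(bundle$paths[["outlier_pvalues.tsv"]])
  ss <- read_sample_sheet(bundle$paths[["sample_sheet.tsv"]])
  known <- read_known_junctions(bundle$paths[["known_junctions.tsv"]])
  tpm <- data.table::fread(bundle$paths[["tpm.tsv"]])

  db <- build_reference_db(ot, ss, gm, known,
                           blacklist = bundle$paths[["blacklist.bed"]],
                           tpm_table = tpm)
  expect_identical(db$junction_id, bundle$truth$planted_junctions)
  expect_identical(db$category, "unannotated_exon_skipping")
  expect_true(db$meta_p < 0.05)
  expect_gte(db$n_donors, 1L)

  # same cohort, planted junction declared known -> empty DB
  db2 <- build_reference_db(ot, ss, gm,
                            c(known, bundle$truth$planted_junctions),
                            tpm_table = tpm)
  expect_equal(nrow(db2), 0L)
})

test_that("junctions failing cross-tissue replication are dropped", {
  ss <- data.table::data.table(sample = "A_mc", donor = "A",
                               tissue = "motor_cortex", phenotype = 1L)
  gm <- toy_gm()
  ot <- ot_row("1:200:499:+", "A_mc", "motor_cortex", 1e-8)
  db <- build_reference_db(ot, ss, gm)
  expect_equal(nrow(db), 0L)
})

test_that("cryptic-exon detectability rule follows the 10% control bound", {
  samples <- c("case1", paste0("ctrl", 1:76))
  cnt <- matrix(0L, nrow = 3, ncol = length(samples),
                dimnames = list(NULL, samples))
  cnt[1, "case1"] <- 5L                       # 1 case, 0 controls -> kept
  cnt[2, c("case1", paste0("ctrl", 1:9))] <- 1L   # 9/76 = 11.8% -> removed
  cnt[3, c("case1", paste0("ctrl", 1:7))] <- 2L   # 7/70 with 70 controls = 10%
  ct <- data.table::data.table(junction_id = c("1:200:299:+", "1:400:499:+",
                                               "1:200:499:+"))
  ct <- cbind(ct, data.table::as.data.table(cnt))
  # use 70 controls for the exact-10% row: drop 6 control columns
  ct10 <- ct[, c("junction_id", "case1", paste0("ctrl", 1:70)), with = FALSE]
  ss <- data.table::data.table(sample = samples, donor = samples,
                               tissue = "t", phenotype = c(1L, rep(0L, 76)))
  db <- build_ce_reference(ct, ss)
  expect_true("1:200:299:+" %in% db$junction_id)
  expect_false("1:400:499:+" %in% db$junction_id)
  db10 <- build_ce_reference(ct10, ss[ss$sample %in% names(ct10)[-1], ])
  expect_true("1:200:499:+" %in% db10$junction_id)  # exactly 10% -> kept
})

test_that("reference DB round-trips through TSV", {
  gm <- toy_gm()
  ss <- data.table::data.table(sample = c("A_a", "A_b"), donor = "A",
                               tissue = c("t1", "t2"), phenotype = 1L)
  ot <- make_outliers(ot_row("1:200:499:+", "A_a", "t1", 1e-4),
                      ot_row("1:200:499:+", "A_b", "t2", 1e-4))
  db <- build_reference_db(ot, ss, gm)
  f <- tempfile(fileext = ".tsv")
  write_reference_db(db, f)
  back <- read_reference_db(f)
  expect_equal(back$junction_id, db$junction_id)
  expect_equal(back$meta_p, db$meta_p, tolerance = 1e-12)
})

test_that("RegTools BED junctions convert to 1-based intron intervals", {
  f <- tempfile(fileext = ".bed")
  # intron [201, 299] 1-based: chromStart 150 + left anchor 50, chromEnd 349 - 50
  writeLines("1\t150\t349\tJUNC1\t12\t+\t150\t349\t0,0,0\t2\t50,50\t0,149", f)
  jx <- read_regtools_junctions(f)
  expect_identical(jx$junction_id, "1:201:299:+")
  expect_identical(jx$count, 12L)
})
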