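# Fixture builders and independent oracles, all generated in code.

# Write a GTF for a set of genes and load it.
# genes: list of list(gene_id, symbol, chrom, strand, exons = data.frame(start, end),
#                     basic = TRUE)
write_toy_gtf <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- unlist(lapply(genes, function(g) {
    basic <- if (isTRUE(g$basic) || is.null(g$basic)) ' tag "basic";' else ""
    tx <- paste0(g$gene_id, ".t1")
    attr_t <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";%s',
                      g$gene_id, g$symbol, tx, basic)
    span <- c(min(g$exons$start), max(g$exons$end))
    c(sprintf('%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
              g$chrom, span[1], span[2], g$strand, g$gene_id, g$symbol),
      sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, span[1], span[2], g$strand, attr_t),
      sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$exons$start, g$exons$end, g$strand, attr_t))
  }))
  writeLines(lines, path)
  path
}

toy_gene <- function(gene_id = "G1", symbol = "GENE1", chrom = "1",
                     strand = "+", starts = c(100, 300, 500), len = 100,
                     basic = TRUE) {
  list(gene_id = gene_id, symbol = symbol, chrom = chrom, strand = strand,
       exons = data.frame(start = starts, end = starts + len - 1), basic = basic)
}

toy_gm <- function(genes = list(toy_gene()), basic_only = TRUE) {
  load_gene_model(write_toy_gtf(genes), basic_only = basic_only)
}

# Independent penalized log-likelihood (used by the optim-based Firth oracle).
oracle_pll <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  W <- p * (1 - p)
  sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE)) +
    0.5 * as.numeric(determinant(crossprod(X * sqrt(W)), logarithm = TRUE)$modulus)
}

# Brute-force Firth maximizer: generic quasi-Newton on the penalized
# likelihood, optionally with one coefficient pinned at zero.
oracle_firth <- function(y, X, fix_idx = NULL) {
  k <- ncol(X)
  free <- setdiff(seq_len(k), fix_idx)
  fn <- function(b) {
    beta <- numeric(k)
    beta[free] <- b
    -oracle_pll(beta, y, X)
  }
  o <- optim(numeric(length(free)), fn, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))
  beta <- numeric(k)
  beta[free] <- o$par
  list(coef = beta, pll = -o$value)
}

# Random matching instance: one toy gene, a handful of candidate reference
# junctions (annotated-boundary and shifted-boundary mixes), and variants
# with random prediction sets.
random_match_instance <- function(seed) {
  set.seed(seed)
  n_ex <- sample(4:6, 1)
  starts <- 1000 + (seq_len(n_ex) - 1) * 500
  strand <- sample(c("+", "-"), 1)
  g <- toy_gene(starts = starts, len = 120, strand = strand)
  gm <- toy_gm(list(g))
  ex <- g$exons
  gene_span <- c(min(ex$start), max(ex$end))

  n_j <- sample(3:10, 1)
  jx <- list()
  tries <- 0
  while (length(jx) < n_j && tries < 200) {
    tries <- tries + 1
    a <- sample(seq_len(n_ex - 1), 1)
    b <- sample(seq(a + 1, n_ex), 1)
    d1 <- sample(c(0L, 0L, sample(c(-30:-3, 3:30), 1)), 1)
    d2 <- sample(c(0L, 0L, sample(c(-30:-3, 3:30), 1)), 1)
    s <- ex$end[a] + 1L + d1
    e <- ex$start[b] - 1L + d2
    if (s >= e || s <= gene_span[1] || e >= gene_span[2]) next
    id <- junction_id(g$chrom, s, e, strand)
    if (id %in% names(jx)) next
    jx[[id]] <- data.table::data.table(
      junction_id = id, chrom = g$chrom, start = s, end = e, strand = strand,
      gene_id = "G1", category = "candidate", meta_p = NA_real_,
      n_donors = NA_integer_, donors = NA_character_, provenance = "toy")
  }
  db <- data.table::rbindlist(jx)

  boundaries <- unique(c(db$start, db$end, gm$donor_sites$pos, gm$acceptor_sites$pos))
  n_v <- sample(5:50, 1)
  pos <- sample(seq(gene_span[1], gene_span[2]), n_v)
  vars <- data.table::data.table(
    variant_id = sprintf("%s:%d:A:C", g$chrom, pos),
    chrom = g$chrom, pos = pos, ref = "A", alt = "C")
  preds <- data.table::rbindlist(lapply(seq_len(n_v), function(i) {
    np <- sample(1:3, 1)
    site <- ifelse(runif(np) < 0.5,
                   sample(boundaries, np, replace = TRUE) + sample(-2:2, np, replace = TRUE),
                   pos[i] + sample(-40:40, np, replace = TRUE))
    data.table::data.table(
      variant_id = vars$variant_id[i], source = "spliceai", gene = g$symbol,
      event = sample(c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss"),
                     np, replace = TRUE),
      delta_score = round(runif(np), 2), site_pos = as.integer(site))
  }))
  mx <- preds[, list(max_delta = max(delta_score)), by = "variant_id"]
  vars$max_delta <- mx$max_delta[match(vars$variant_id, mx$variant_id)]
  list(gm = gm, db = db, variants = vars, predictions = preds)
}

# Exhaustive (variant x junction) evaluation of the match rules; the tier
# logic is re-derived here independently of classify_match_tier().
oracle_crsqtl_members <- function(inst, delta_min = 0.2, tol = 2L) {
  rows <- list()
  for (i in seq_len(nrow(inst$db))) {
    j <- inst$db[i, ]
    w <- tryCatch(flanking_exon_window(j, inst$gm),
                  WindowUndefined = function(cond) NULL)
    if (is.null(w)) next
    for (k in seq_len(nrow(inst$variants))) {
      v <- inst$variants[k, ]
      if (v$pos < w[["start"]] || v$pos > w[["end"]]) next
      pv <- inst$predictions[inst$predictions$variant_id == v$variant_id &
                               inst$predictions$delta_score >= delta_min, ]
      if (nrow(pv) == 0L) next
      hits <- vapply(seq_len(nrow(pv)), function(m) {
        isTRUE(prediction_matches_junction(pv[m, ], j, inst$gm, tol)[[1L]])
      }, logical(1))
      if (!any(hits)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        junction_id = j$junction_id, variant_id = v$variant_id,
        tier = if (all(hits)) "full" else "partial")
    }
  }
  out <- if (length(rows) == 0L)
    data.table::data.table(junction_id = character(), variant_id = character(),
                           tier = character())
  else data.table::rbindlist(rows)
  data.table::setkey(out, junction_id, variant_id)
  out
}

# canonical member representation for oracle comparisons
member_key <- function(x) {
  df <- data.frame(junction_id = x$junction_id, variant_id = x$variant_id,
                   tier = x$tier, stringsAsFactors = FALSE)
  df <- df[order(df$junction_id, df$variant_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
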