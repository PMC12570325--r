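# Gene models: exon/intron structure, splice-site catalogs, junction
# classification and flanking-exon search windows.

#' Format and parse splice-junction identifiers
#'
#' Junctions are intron intervals stored 1-based inclusive: `start` is the
#' first intronic base, `end` the last. The canonical identifier is
#' `"chrom:start:end:strand"`.
#'
#' @param chrom Chromosome name.
#' @param start First intronic base (1-based).
#' @param end Last intronic base (1-based), strictly greater than `start`.
#' @param strand `"+"` or `"-"`.
#' @return `junction_id()` returns a character vector of identifiers;
#'   `parse_junction_id()` returns a `data.table` with columns
#'   `junction_id, chrom, start, end, strand`.
#' @examples
#' junction_id("12", 57581952, 57583100, "+")
#' parse_junction_id("12:57581952:57583100:+")
#' @export
junction_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d:%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' @rdname junction_id
#' @param id Character vector of `"chrom:start:end:strand"` identifiers.
#' @export
parse_junction_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+):([0-9]+):([+-])$", id))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("malformed junction id(s): ", paste(utils::head(id[bad], 3), collapse = ", "))
  }
  dt <- data.table::data.table(
    junction_id = id,
    chrom  = vapply(m, `[`, "", 2L),
    start  = as.integer(vapply(m, `[`, "", 3L)),
    end    = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L)
  )
  if (any(dt$start >= dt$end)) {
    stop("junction start must be < end: ",
         paste(dt$junction_id[dt$start >= dt$end], collapse = ", "))
  }
  dt[]
}

#' Load a gene model from a GTF file
#'
#' Reads an Ensembl-dialect GTF and derives the structures needed downstream:
#' exon tables, annotated intron (junction) catalog, and strand-aware donor
#' and acceptor site sets. On the `+` strand the donor site is keyed by the
#' first intronic base of an intron and the acceptor by the last; the
#' convention is reversed on `-`.
#'
#' @param gtf_path Path to a GTF file with `exon` features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @param basic_only If `TRUE` (default), keep only transcripts carrying the
#'   Ensembl `tag "basic"` attribute. When the file has no tag attribute at
#'   all, a warning is emitted and all transcripts are retained.
#' @return An object of class `GeneModel`: a list with `data.table`
#'   components `genes`, `exons`, `junctions`, `donor_sites`,
#'   `acceptor_sites`.
#' @export
load_gene_model <- function(gtf_path, basic_only = TRUE) {
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", gtf_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  meta <- S4Vectors::mcols(gr)
  ex <- gr[meta$type == "exon"]
  if (length(ex) == 0L) stop("GTF '", gtf_path, "' contains no exon features")
  exdt <- data.table::data.table(
    chrom  = as.character(GenomicRanges::seqnames(ex)),
    start  = GenomicRanges::start(ex),
    end    = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = ex$gene_id,
    symbol = if (!is.null(ex$gene_name)) ex$gene_name else ex$gene_id,
    transcript_id = ex$transcript_id
  )
  if (anyNA(exdt$transcript_id) || any(!nzchar(exdt$transcript_id))) {
    stop("exon feature without transcript_id parent in '", gtf_path, "'")
  }
  if (any(!exdt$strand %in% c("+", "-"))) {
    stop("exon with undefined strand in '", gtf_path, "'")
  }
  if (basic_only) {
    tags <- ex$tag
    if (is.null(tags)) {
      warning("GTF has no 'tag' attribute; basic_only ignored, keeping all transcripts")
    } else {
      if (methods::is(tags, "List") || is.list(tags)) {
        is_basic <- vapply(tags, function(tg) "basic" %in% tg, logical(1))
      } else {
        is_basic <- !is.na(tags) & tags == "basic"
      }
      basic_tx <- unique(exdt$transcript_id[is_basic])
      exdt <- exdt[exdt$transcript_id %in% basic_tx]
      if (nrow(exdt) == 0L) stop("no transcripts tagged 'basic' in '", gtf_path, "'")
    }
  }
  data.table::setkey(exdt, transcript_id, start)

  # exons within a transcript must be disjoint and ordered
  chk <- exdt[, {
    ok <- if (.N < 2L) TRUE else all(start[-1L] > end[-.N])
    list(ok = ok)
  }, by = "transcript_id"]
  if (any(!chk$ok)) {
    stop("overlapping exons within transcript(s): ",
         paste(chk$transcript_id[!chk$ok], collapse = ", "))
  }

  jx <- exdt[, if (.N >= 2L) list(
    chrom  = chrom[-.N],
    start  = end[-.N] + 1L,
    end    = start[-1L] - 1L,
    strand = strand[-.N],
    gene_id = gene_id[-.N]
  ), by = "transcript_id"]
  jx <- unique(jx[, c("chrom", "start", "end", "strand", "gene_id")])
  jx[, "junction_id" := junction_id(jx$chrom, jx$start, jx$end, jx$strand)]

  donors <- unique(data.table::data.table(
    chrom = jx$chrom,
    pos = ifelse(jx$strand == "+", jx$start, jx$end),
    strand = jx$strand
  ))
  acceptors <- unique(data.table::data.table(
    chrom = jx$chrom,
    pos = ifelse(jx$strand == "+", jx$end, jx$start),
    strand = jx$strand
  ))

  genes <- exdt[, list(
    symbol = symbol[1L], chrom = chrom[1L], strand = strand[1L],
    start = min(start), end = max(end), n_transcripts = length(unique(transcript_id))
  ), by = "gene_id"]

  structure(
    list(genes = genes, exons = exdt, junctions = jx,
         donor_sites = donors, acceptor_sites = acceptors,
         source = gtf_path, basic_only = basic_only),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel:", nrow(x$genes), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$junctions), "annotated junctions\n")
  invisible(x)
}

#' Donor and acceptor boundary coordinates of a junction
#'
#' @param start,end Intronic interval bounds (1-based inclusive).
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of boundary positions (donor = 5' end of the
#'   intron in transcription order).
#' @keywords internal
donor_boundary <- function(start, end, strand) {
  ifelse(strand == "+", as.integer(start), as.integer(end))
}

#' @rdname donor_boundary
#' @keywords internal
acceptor_boundary <- function(start, end, strand) {
  ifelse(strand == "+", as.integer(end), as.integer(start))
}

.site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = "\r")

.genes_overlapping <- function(gm, chrom, start, end, strand) {
  g <- gm$genes
  keep <- g$chrom == chrom & g$strand == strand & g$start <= end & g$end >= start
  g[keep, ]
}

#' Classify splice junctions against a gene model and known-junction catalogs
#'
#' Categories follow the standard outlier-splicing taxonomy:
#' \describe{
#'   \item{annotated}{the junction equals an annotated intron or appears in
#'     the external known-junction catalog.}
#'   \item{unannotated_exon_skipping}{both boundary splice sites are
#'     annotated (donor on the donor side, acceptor on the acceptor side),
#'     at least one annotated exon lies strictly inside the intron interval,
#'     and the junction itself is unannotated.}
#'   \item{unannotated_donor / unannotated_acceptor}{exactly the donor-side
#'     (resp. acceptor-side) boundary is unannotated while the other
#'     boundary is an annotated site.}
#'   \item{complex}{everything else: junctions overlapping zero or more than
#'     one gene, both boundaries unannotated, or annotated-boundary pairs
#'     with no skipped exon. Complex junctions are excluded from reference
#'     databases as low-confidence events.}
#' }
#'
#' @param junctions A character vector of junction ids, or a data.frame with
#'   columns `chrom, start, end, strand`.
#' @param gm A [load_gene_model()] `GeneModel`.
#' @param known_junctions Optional character vector of additional known
#'   junction ids (e.g. a Snaptron-style catalog); treated as annotated.
#' @return Character vector of categories, one per junction, plus an
#'   attribute `"gene_id"` giving the assigned gene (`NA` for complex
#'   multi-/no-gene junctions).
#' @export
classify_junctions <- function(junctions, gm, known_junctions = character()) {
  jx <- if (is.character(junctions)) parse_junction_id(junctions) else
    data.table::as.data.table(junctions)
  if (!"junction_id" %in% names(jx)) {
    jx$junction_id <- junction_id(jx$chrom, jx$start, jx$end, jx$strand)
  }
  known <- unique(c(gm$junctions$junction_id, known_junctions))
  dkey <- .site_key(gm$donor_sites$chrom, gm$donor_sites$pos, gm$donor_sites$strand)
  akey <- .site_key(gm$acceptor_sites$chrom, gm$acceptor_sites$pos,
                    gm$acceptor_sites$strand)

  n <- nrow(jx)
  out <- character(n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ch <- jx$chrom[i]; s <- jx$start[i]; e <- jx$end[i]; st <- jx$strand[i]
    g <- .genes_overlapping(gm, ch, s, e, st)
    if (nrow(g) != 1L) { out[i] <- "complex"; next }
    gene[i] <- g$gene_id
    if (jx$junction_id[i] %in% known) { out[i] <- "annotated"; next }
    don_ok <- .site_key(ch, donor_boundary(s, e, st), st) %in% dkey
    acc_ok <- .site_key(ch, acceptor_boundary(s, e, st), st) %in% akey
    if (don_ok && acc_ok) {
      inside <- gm$exons[gm$exons$chrom == ch & gm$exons$strand == st &
                           gm$exons$start > s & gm$exons$end < e, ]
      out[i] <- if (nrow(inside) > 0L) "unannotated_exon_skipping" else "complex"
    } else if (acc_ok && !don_ok) {
      out[i] <- "unannotated_donor"
    } else if (don_ok && !acc_ok) {
      out[i] <- "unannotated_acceptor"
    } else {
      out[i] <- "complex"
    }
  }
  attr(out, "gene_id") <- gene
  out
}

#' @rdname classify_junctions
#' @param junction A single junction id or one-row data.frame.
#' @export
classify_junction <- function(junction, gm, known_junctions = character()) {
  res <- classify_junctions(junction, gm, known_junctions)
  structure(res[1L], gene_id = attr(res, "gene_id")[1L])
}

window_undefined <- function(msg) {
  structure(class = c("WindowUndefined", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Variant search window flanking a junction
#'
#' The search space for candidate splice-altering variants spans from the
#' leftmost base of the nearest annotated exon upstream of the junction to
#' the rightmost base of the nearest annotated exon downstream, including
#' the entire intervening sequence. "Nearest" is the annotated exon (from
#' any retained transcript of the junction's gene) whose inner boundary is
#' closest to the junction on that side; ties are broken in favour of the
#' longer exon.
#'
#' @param junction A junction id or one-row data.frame with
#'   `chrom, start, end, strand`.
#' @param gm A `GeneModel`.
#' @return Named integer vector `c(start =, end =)`; the interval always
#'   contains the junction. If no annotated flanking exon exists on one side
#'   within the gene (or no single gene can be assigned), a condition of
#'   class `"WindowUndefined"` is signalled.
#' @export
flanking_exon_window <- function(junction, gm) {
  j <- if (is.character(junction)) parse_junction_id(junction) else
    data.table::as.data.table(junction)
  ch <- j$chrom[1L]; s <- j$start[1L]; e <- j$end[1L]; st <- j$strand[1L]
  g <- .genes_overlapping(gm, ch, s, e, st)
  if (nrow(g) != 1L) {
    stop(window_undefined(sprintf(
      "junction %s overlaps %d genes; window undefined",
      junction_id(ch, s, e, st), nrow(g))))
  }
  ex <- gm$exons[gm$exons$gene_id == g$gene_id, ]
  left <- ex[ex$end < s, ]
  right <- ex[ex$start > e, ]
  if (nrow(left) == 0L || nrow(right) == 0L) {
    stop(window_undefined(sprintf(
      "junction %s lacks an annotated flanking exon on the %s side",
      junction_id(ch, s, e, st),
      if (nrow(left) == 0L) "left" else "right")))
  }
  left <- left[order(-left$end, -(left$end - left$start)), ][1L, ]
  right <- right[order(right$start, -(right$end - right$start)), ][1L, ]
  c(start = left$start, end = right$end)
}

#' Compute flanking windows for a table of junctions
#'
#' Junctions with an undefined window get `NA` bounds and a single summary
#' warning; callers are expected to drop them.
#'
#' @inheritParams classify_junctions
#' @return `data.table` with columns `junction_id, window_start, window_end`.
#' @export
flanking_exon_windows <- function(junctions, gm) {
  jx <- if (is.character(junctions)) parse_junction_id(junctions) else
    data.table::as.data.table(junctions)
  if (!"junction_id" %in% names(jx)) {
    jx$junction_id <- junction_id(jx$chrom, jx$start, jx$end, jx$strand)
  }
  ws <- we <- rep(NA_integer_, nrow(jx))
  for (i in seq_len(nrow(jx))) {
    w <- tryCatch(flanking_exon_window(jx[i, ], gm),
                  WindowUndefined = function(cond) NULL)
    if (!is.null(w)) { ws[i] <- w[["start"]]; we[i] <- w[["end"]] }
  }
  if (anyNA(ws)) {
    warning(sum(is.na(ws)), " junction(s) skipped: no defined flanking-exon window")
  }
  data.table::data.table(junction_id = jx$junction_id,
                         window_start = ws, window_end = we)
}

#' Read a known-junction catalog
#'
#' @param path TSV with columns `chrom, start, end, strand`.
#' @param zero_based If `TRUE`, `start` is 0-based (BED-style) and is
#'   shifted by +1 on read.
#' @return Character vector of junction ids.
#' @export
read_known_junctions <- function(path, zero_based = FALSE) {
  kj <- data.table::fread(path, colClasses = list(character = "chrom"))
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(kj))) {
    stop("known-junction file must have columns ", paste(req, collapse = ", "))
  }
  if (zero_based) kj$start <- kj$start + 1L
  junction_id(kj$chrom, kj$start, kj$end, kj$strand)
}
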