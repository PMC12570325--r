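# crsQTL core: matching splice predictions to reference junctions under the
# gain-use / loss-omit rules, full/partial tier assignment, and grouping of
# matched variants per junction.

.near_boundary <- function(site, boundary, exon_adjacent, tol) {
  abs(site - boundary) <= tol | abs(site - exon_adjacent) <= tol
}

.is_annotated_site <- function(gm, side, chrom, pos, strand) {
  tab <- if (side == "donor") gm$donor_sites else gm$acceptor_sites
  any(tab$chrom == chrom & tab$pos == pos & tab$strand == strand)
}

.annotated_sites_near <- function(gm, side, chrom, site_pos, strand, tol) {
  tab <- if (side == "donor") gm$donor_sites else gm$acceptor_sites
  tab$pos[tab$chrom == chrom & tab$strand == strand & abs(tab$pos - site_pos) <= tol]
}

#' Does one splice prediction match one reference junction?
#'
#' Matching rules:
#' \itemize{
#'   \item \strong{Gain} of an unannotated site (`donor_gain`,
#'     `acceptor_gain`, or Pangolin `usage_increase`): the predicted site
#'     must coincide (within `tol`, on either the intronic boundary base or
#'     the adjacent exonic base) with the corresponding junction boundary,
#'     and that boundary must \emph{not} be an annotated site. Increased
#'     usage of an already-annotated site never matches.
#'   \item \strong{Loss} of an annotated site (`donor_loss`,
#'     `acceptor_loss`, `usage_decrease`): the predicted position must
#'     identify an annotated site (within `tol`), and the junction must omit
#'     that site — either the site lies strictly inside the intron interval
#'     (spliced over, clause `"omit_interior"`), or the site is on the same
#'     side as one junction boundary while the junction uses a different
#'     site on that side within the junction's flanking-exon window (clause
#'     `"omit_alt_site"`).
#' }
#' Event/side inconsistencies (e.g. a donor event against the acceptor
#' boundary) simply fail to match; they are not errors.
#'
#' @param pred One prediction (list or one-row data.frame with `event`,
#'   `site_pos`).
#' @param junction One junction (list or one-row data.frame with
#'   `chrom, start, end, strand`).
#' @param gm `GeneModel`.
#' @param tol Site-position tolerance in bp, default 2; set 0 for exact
#'   boundary matching.
#' @return `TRUE`/`FALSE`, with attribute `"clause"` naming which rule fired
#'   (`"gain_site_use"`, `"omit_interior"`, `"omit_alt_site"`) on a match.
#' @export
prediction_matches_junction <- function(pred, junction, gm, tol = 2L) {
  p <- as.list(pred)
  j <- as.list(junction)
  ch <- j$chrom; s <- as.integer(j$start); e <- as.integer(j$end); st <- j$strand
  db <- donor_boundary(s, e, st); ab <- acceptor_boundary(s, e, st)
  # exonic base adjacent to each intron boundary
  adj_of <- function(b) if (b == s) s - 1L else e + 1L
  site <- as.integer(p$site_pos)
  ev <- p$event

  gain_match <- function(side, boundary) {
    if (!.near_boundary(site, boundary, adj_of(boundary), tol)) return(FALSE)
    !.is_annotated_site(gm, side, ch, boundary, st)
  }
  loss_match <- function(side) {
    sites <- .annotated_sites_near(gm, side, ch, site, st, tol)
    if (length(sites) == 0L) return(NA_character_)
    for (pos in sites) {
      if (pos > s && pos < e) return("omit_interior")
      jb <- if (side == "donor") db else ab
      if (!.near_boundary(pos, jb, adj_of(jb), tol)) {
        w <- tryCatch(flanking_exon_window(
          data.table::data.table(chrom = ch, start = s, end = e, strand = st), gm),
          WindowUndefined = function(cond) NULL)
        if (!is.null(w) && pos >= w[["start"]] && pos <= w[["end"]]) {
          return("omit_alt_site")
        }
      }
    }
    NA_character_
  }

  clause <- NA_character_
  if (ev == "donor_gain") {
    if (gain_match("donor", db)) clause <- "gain_site_use"
  } else if (ev == "acceptor_gain") {
    if (gain_match("acceptor", ab)) clause <- "gain_site_use"
  } else if (ev == "usage_increase") {
    if (gain_match("donor", db) || gain_match("acceptor", ab)) clause <- "gain_site_use"
  } else if (ev == "donor_loss") {
    clause <- loss_match("donor")
  } else if (ev == "acceptor_loss") {
    clause <- loss_match("acceptor")
  } else if (ev == "usage_decrease") {
    clause <- loss_match("donor")
    if (is.na(clause)) clause <- loss_match("acceptor")
  } else {
    stop("unknown prediction event: ", ev)
  }
  structure(!is.na(clause), clause = clause)
}

#' Tier of a variant's match to a junction
#'
#' A variant is a `"full"` match when all of its qualifying predictions
#' (delta score >= `delta_min`) match the junction, `"partial"` when at
#' least one but not all do, and `"none"` otherwise (including when no
#' prediction qualifies).
#'
#' @param preds Prediction table for one variant.
#' @param junction One junction row.
#' @param gm `GeneModel`.
#' @param delta_min Qualifying delta-score threshold (inclusive),
#'   default 0.2.
#' @param tol Site tolerance, see [prediction_matches_junction()].
#' @return List with `tier` and `matched` (qualifying predictions that
#'   matched, with a `clause` column).
#' @export
classify_match_tier <- function(preds, junction, gm, delta_min = 0.2, tol = 2L) {
  q <- data.table::as.data.table(preds)
  q <- q[q$delta_score >= delta_min, ]
  if (nrow(q) == 0L) {
    return(list(tier = "none", matched = q))
  }
  clauses <- character(nrow(q))
  hit <- logical(nrow(q))
  for (k in seq_len(nrow(q))) {
    m <- prediction_matches_junction(q[k, ], junction, gm, tol)
    hit[k] <- isTRUE(m[[1L]])
    clauses[k] <- if (hit[k]) attr(m, "clause") else NA_character_
  }
  matched <- q[hit, ]
  matched$clause <- clauses[hit]
  tier <- if (!any(hit)) "none" else if (all(hit)) "full" else "partial"
  list(tier = tier, matched = matched)
}

#' Group rarity-filtered variants into crsQTLs
#'
#' For every reference junction, candidate variants are those whose position
#' falls inside the junction's flanking-exon window; each candidate whose
#' qualifying predictions give a `full` or `partial` match becomes a member.
#' Junctions with at least one member yield a crsQTL. A variant may belong
#' to several crsQTLs (one per matched junction); no deduplication is
#' performed here.
#'
#' @param db Reference junction database ([build_reference_db()]).
#' @param variants Rarity-filtered variant table.
#' @param predictions Prediction table covering `variants`.
#' @param gm `GeneModel`.
#' @param delta_min Qualifying threshold, default 0.2.
#' @param tol Site tolerance, default 2.
#' @param full_only If `TRUE`, keep only full-match members (sensitivity
#'   analyses); default includes both tiers.
#' @return `data.table` of crsQTL memberships: `junction_id, gene_id,
#'   category, variant_id, tier, matched_events, clauses, delta_max`.
#'   Junctions with undefined windows are skipped with a warning.
#' @export
build_crsqtls <- function(db, variants, predictions, gm, delta_min = 0.2,
                          tol = 2L, full_only = FALSE) {
  vt <- data.table::as.data.table(variants)
  pr <- data.table::as.data.table(predictions)
  members <- list()
  skipped <- character()
  for (i in seq_len(nrow(db))) {
    j <- db[i, ]
    w <- tryCatch(flanking_exon_window(j, gm),
                  WindowUndefined = function(cond) NULL)
    if (is.null(w)) { skipped <- c(skipped, j$junction_id); next }
    cand <- vt[vt$chrom == j$chrom & vt$pos >= w[["start"]] & vt$pos <= w[["end"]], ]
    if (nrow(cand) == 0L) next
    for (v in cand$variant_id) {
      pv <- pr[pr$variant_id == v, ]
      res <- classify_match_tier(pv, j, gm, delta_min, tol)
      if (res$tier == "none") next
      if (full_only && res$tier != "full") next
      members[[length(members) + 1L]] <- data.table::data.table(
        junction_id = j$junction_id, gene_id = j$gene_id,
        category = j$category, variant_id = v, tier = res$tier,
        matched_events = paste(res$matched$event, collapse = ","),
        clauses = paste(res$matched$clause, collapse = ","),
        delta_max = max(res$matched$delta_score)
      )
    }
  }
  if (length(skipped) > 0L) {
    warning(length(skipped), " reference junction(s) skipped: undefined flanking window")
  }
  out <- if (length(members) == 0L) data.table::data.table(
    junction_id = character(), gene_id = character(), category = character(),
    variant_id = character(), tier = character(), matched_events = character(),
    clauses = character(), delta_max = numeric()
  ) else data.table::rbindlist(members)
  attr(out, "skipped_junctions") <- skipped
  out
}

#' Write a crsQTL membership table as TSV
#'
#' @param crsqtls Table from [build_crsqtls()].
#' @param path Output path.
#' @export
write_crsqtls <- function(crsqtls, path) {
  data.table::fwrite(crsqtls, path, sep = "\t")
  invisible(path)
}
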