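pred_row <- function(event, site, delta = 0.6, vid = "1:1:A:C") {
  data.table::data.table(variant_id = vid, source = "spliceai", gene = "GENE1",
                         event = event, delta_score = delta,
                         site_pos = as.integer(site))
}
jrow <- function(chrom, start, end, strand) {
  data.table::data.table(junction_id = junction_id(chrom, start, end, strand),
                         chrom = chrom, start = start, end = end, strand = strand)
}

test_that("gain predictions match junctions that use the unannotated site", {
  gm <- toy_gm()  # annotated donors {200,400}, acceptors {299,499}
  j <- jrow("1", 200, 490, "+")  # unannotated acceptor at 490
  m <- prediction_matches_junction(pred_row("acceptor_gain", 490), j, gm)
  expect_true(m[[1]])
  expect_equal(attr(m, "clause"), "gain_site_use")
  # within tolerance on the adjacent exonic base
  expect_true(prediction_matches_junction(pred_row("acceptor_gain", 491), j, gm)[[1]])
  # gain at an annotated boundary never matches
  j_ann <- jrow("1", 200, 499, "+")
  expect_false(prediction_matches_junction(pred_row("acceptor_gain", 499), j_ann, gm)[[1]])
  # far from either boundary
  expect_false(prediction_matches_junction(pred_row("donor_gain", 700), j, gm)[[1]])
  # tolerance 0 requires exact boundary hits
  expect_false(prediction_matches_junction(pred_row("acceptor_gain", 492), j, gm, tol = 0)[[1]])
})

test_that("loss of a spliced-over annotated site matches (exon-skipping case)", {
  gm <- toy_gm()
  skip <- jrow("1", 200, 499, "+")   # skips exon 2; its acceptor 299 is interior
  m <- prediction_matches_junction(pred_row("acceptor_loss", 299, delta = 0.64),
                                   skip, gm)
  expect_true(m[[1]])
  expect_equal(attr(m, "clause"), "omit_interior")
  # donor 400 also interior
  expect_true(prediction_matches_junction(pred_row("donor_loss", 400), skip, gm)[[1]])
})

test_that("loss matches same-side alternative-site usage within the window", {
  gm <- toy_gm()
  j <- jrow("1", 210, 499, "+")  # unannotated donor 210 replaces annotated 200
  m <- prediction_matches_junction(pred_row("donor_loss", 200), j, gm)
  expect_true(m[[1]])
  expect_equal(attr(m, "clause"), "omit_alt_site")
  # the junction that itself uses site 200 does not 'omit' it
  j_uses <- jrow("1", 200, 499, "+")
  expect_false(prediction_matches_junction(pred_row("donor_loss", 200), j_uses, gm)[[1]])
  # loss at a position identifying no annotated site
  expect_false(prediction_matches_junction(pred_row("donor_loss", 250), j, gm)[[1]])
})

test_that("event/side inconsistencies fail quietly, unknown events error", {
  gm <- toy_gm()
  j <- jrow("1", 200, 490, "+")
  # donor event pointed at the (unannotated) acceptor boundary: no match
  expect_false(prediction_matches_junction(pred_row("donor_gain", 490), j, gm)[[1]])
  expect_error(prediction_matches_junction(pred_row("nonsense", 490), j, gm),
               "unknown prediction event")
})

test_that("Pangolin usage events map onto the gain/loss rules", {
  gm <- toy_gm()
  j <- jrow("1", 200, 490, "+")
  expect_true(prediction_matches_junction(pred_row("usage_increase", 490), j, gm)[[1]])
  # increased usage of an annotated site is excluded by the gain rule
  j_ann <- jrow("1", 200, 499, "+")
  expect_false(prediction_matches_junction(pred_row("usage_increase", 499), j_ann, gm)[[1]])
  skip <- jrow("1", 200, 499, "+")
  expect_true(prediction_matches_junction(pred_row("usage_decrease", 299), skip, gm)[[1]])
})

test_that("match tiers follow the all/some/none rule", {
  gm <- toy_gm()
  skip <- jrow("1", 200, 499, "+")
  one_match <- pred_row("acceptor_loss", 299)
  expect_equal(classify_match_tier(one_match, skip, gm)$tier, "full")
  mixed <- rbind(pred_row("acceptor_loss", 299),
                 pred_row("donor_gain", 9999))
  expect_equal(classify_match_tier(mixed, skip, gm)$tier, "partial")
  none <- pred_row("acceptor_loss", 299, delta = 0.1)
  expect_equal(classify_match_tier(none, skip, gm)$tier, "none")
  # sub-threshold non-matching prediction does not demote a full match
  full_plus_noise <- rbind(pred_row("acceptor_loss", 299),
                           pred_row("donor_gain", 9999, delta = 0.1))
  expect_equal(classify_match_tier(full_plus_noise, skip, gm)$tier, "full")
})

test_that("crsQTL grouping equals the brute-force oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_match_instance(seed)
    got <- suppressWarnings(
      build_crsqtls(inst$db, inst$variants, inst$predictions, inst$gm))
    want <- oracle_crsqtl_members(inst)
    expect_equal(member_key(got), member_key(want), info = paste("seed", seed))
  }
})

test_that("memberships shrink monotonically in delta_min and tol", {
  for (seed in c(3, 14, 27)) {
    inst <- random_match_instance(seed)
    base <- suppressWarnings(build_crsqtls(inst$db, inst$variants,
                                           inst$predictions, inst$gm,
                                           delta_min = 0.2, tol = 2L))
    stricter <- suppressWarnings(build_crsqtls(inst$db, inst$variants,
                                               inst$predictions, inst$gm,
                                               delta_min = 0.5, tol = 2L))
    tighter <- suppressWarnings(build_crsqtls(inst$db, inst$variants,
                                              inst$predictions, inst$gm,
                                              delta_min = 0.2, tol = 0L))
    key <- function(x) paste(x$junction_id, x$variant_id)
    expect_true(all(key(stricter) %in% key(base)))
    expect_true(all(key(tighter) %in% key(base)))
  }
})

test_that("mirroring a locus preserves every match decision", {
  gm_f <- toy_gm(list(toy_gene(strand = "+")))
  C <- 1000L  # mirror coordinate: x -> C - x
  gm_r <- toy_gm(list(toy_gene(strand = "-", starts = C - c(599, 399, 199))))
  # forward junctions and predictions
  cases <- list(
    list(j = c(200L, 490L), ev = "acceptor_gain", site = 490L),
    list(j = c(200L, 499L), ev = "acceptor_loss", site = 299L),
    list(j = c(210L, 499L), ev = "donor_loss", site = 200L),
    list(j = c(200L, 490L), ev = "donor_gain", site = 700L))
  flip_ev <- identity  # donor stays donor in transcription sense
  for (cs in cases) {
    jf <- jrow("1", cs$j[1], cs$j[2], "+")
    jr <- jrow("1", C - cs$j[2], C - cs$j[1], "-")
    mf <- prediction_matches_junction(pred_row(cs$ev, cs$site), jf, gm_f)
    mr <- prediction_matches_junction(pred_row(flip_ev(cs$ev), C - cs$site), jr, gm_r)
    expect_equal(mf[[1]], mr[[1]], info = cs$ev)
  }
})

test_that("full-only filtering and multi-junction membership behave", {
  gm <- toy_gm()
  db <- data.table::rbindlist(list(
    cbind(jrow("1", 200, 499, "+"), gene_id = "G1", category = "unannotated_exon_skipping"),
    cbind(jrow("1", 210, 499, "+"), gene_id = "G1", category = "unannotated_donor")),
    fill = TRUE)
  vt <- data.table::data.table(variant_id = "1:250:A:C", chrom = "1", pos = 250L,
                               ref = "A", alt = "C", max_delta = 0.8)
  # donor_loss of annotated 200: interior to neither, alt-site for junction 2;
  # acceptor_loss of 299: interior to junction 1 only
  pr <- rbind(pred_row("acceptor_loss", 299, vid = "1:250:A:C"),
              pred_row("donor_loss", 200, vid = "1:250:A:C"))
  got <- build_crsqtls(db, vt, pr, gm)
  expect_equal(nrow(got), 2L)  # one membership per junction
  expect_setequal(got$tier, c("partial", "full"))
  full_only <- build_crsqtls(db, vt, pr, gm, full_only = TRUE)
  expect_true(all(full_only$tier == "full"))
})
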