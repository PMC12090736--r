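lineage_of <- function(s) parse_lineage(s)

pred_row <- function(ct, s, conf) {
  cbind(data.frame(contig_id = ct, stringsAsFactors = FALSE),
        lineage_of(s), confidence = conf)
}

link_row <- function(ct, s, rank) {
  cbind(data.frame(contig_id = ct, stringsAsFactors = FALSE),
        lineage_of(s), link_rank = rank)
}

test_that("contig intersection defines the denominator", {
  pred <- rbind(pred_row("c1", "d__B;f__F1", 90),
                pred_row("c2", "d__B;f__F1", 90),
                pred_row("c3", "d__B;f__F1", 90))
  link <- rbind(link_row("c2", "d__B;f__F1", 1),
                link_row("c3", "d__B;f__F1", 1),
                link_row("c4", "d__B;f__F1", 1))
  expect_setequal(intersect_contigs(pred, link), c("c2", "c3"))
  expect_warning(
    empty <- intersect_contigs(pred_row("x", "d__B", 1),
                               link_row("y", "d__B", 1)),
    "no contigs shared")
  expect_length(empty, 0)
})

test_that("the three stringencies accept nested sets of matches", {
  # pred top matches only the 2nd-ranked Hi-C host
  p <- pred_row("c", "d__B;p__P1;c__C1;o__O1;f__F1;g__G1", 95)
  h <- rbind(link_row("c", "d__B;p__P2;c__C2;o__O2;f__F9;g__G9", 1),
             link_row("c", "d__B;p__P1;c__C1;o__O1;f__F1;g__G1", 2))
  expect_false(is_concordant(p, h[order(h$link_rank), ], "family", "strict"))
  expect_true(is_concordant(p, h, "family", "top_vs_any"))
  expect_true(is_concordant(p, h, "family", "any_vs_any"))

  # only pred's 2nd prediction matches any Hi-C host
  p2 <- rbind(pred_row("c", "d__B;p__P3;c__C3;o__O3;f__F7;g__G7", 95),
              pred_row("c", "d__B;p__P2;c__C2;o__O2;f__F9;g__G9", 80))
  expect_false(is_concordant(p2, h, "family", "strict"))
  expect_false(is_concordant(p2, h, "family", "top_vs_any"))
  expect_true(is_concordant(p2, h, "family", "any_vs_any"))

  # identical top hosts: concordant under all three
  h2 <- link_row("c", "d__B;p__P3;c__C3;o__O3;f__F7;g__G7", 1)
  for (mode in concordance_modes()) {
    expect_true(is_concordant(p2, h2, "family", mode))
  }
  expect_error(is_concordant(p[0, ], h, "family", "strict"), "non-empty")
})

test_that("percent concordance is 100 * concordant / total contigs", {
  pred <- rbind(pred_row("c1", "d__B;p__P1;c__C1;o__O1;f__F1;g__G1", 90),
                pred_row("c2", "d__B;p__P1;c__C1;o__O1;f__F1;g__G2", 90),
                pred_row("c3", "d__B;p__P1;c__C1;o__O1;f__F2;g__G3", 90),
                pred_row("c4", "d__B;p__P1;c__C1;o__O1;f__F3;g__G4", 90))
  link <- rbind(link_row("c1", "d__B;p__P1;c__C1;o__O1;f__F1;g__G1", 1),
                link_row("c2", "d__B;p__P1;c__C1;o__O1;f__F1;g__G9", 1),
                link_row("c3", "d__B;p__P1;c__C1;o__O1;f__F9;g__G3", 1),
                link_row("c4", "d__B;p__P1;c__C1;o__O1;f__F9;g__G9", 1))
  rep <- concordance_report(pred, link)
  # 2 of 4 share a family with their top Hi-C hit
  expect_equal(concordance_percent(rep, "family", "strict"), 50.0)
  expect_true(all(rep$n_total == 4))
  expect_equal(attr(rep, "n_contigs_both"), 4)

  # identical single-host tables: 100% everywhere
  rep2 <- concordance_report(pred, within(pred, {
    link_rank <- 1L
    rm(confidence)
  }))
  expect_true(all(rep2$percent == 100))
})

test_that("most confident prediction uses the lexicographic tie-break", {
  pred <- rbind(pred_row("c1", "d__B;p__P1;c__C1;o__O1;f__Zeta;g__G1", 90),
                pred_row("c1", "d__B;p__P1;c__C1;o__O1;f__Alpha;g__G2", 90))
  link <- link_row("c1", "d__B;p__P1;c__C1;o__O1;f__Alpha;g__G2", 1)
  rep <- concordance_report(pred, link)
  # the tie resolves to the lexicographically smaller serialized lineage
  expect_equal(concordance_percent(rep, "family", "strict"), 100)
})

test_that("unranked Hi-C hosts count discordant unless dropped", {
  pred <- rbind(pred_row("c1", "d__B;p__P1;c__C1;o__O1;f__F1;g__G1", 90),
                pred_row("c2", "d__B;p__P1;c__C1;o__O1;f__F1;g__G1", 90))
  link <- rbind(link_row("c1", "d__B;p__P1;c__C1;o__O1;f__F1;g__G1", 1),
                link_row("c2", "d__B;p__P1;c__C1;o__O1;f__;g__", 1))
  rep <- concordance_report(pred, link)
  expect_equal(concordance_percent(rep, "family", "strict"), 50)
  expect_equal(rep$n_total[rep$rank == "family"][1], 2)
  dropped <- concordance_report(pred, link, drop_unranked = TRUE)
  expect_equal(concordance_percent(dropped, "family", "strict"), 100)
  expect_equal(dropped$n_total[dropped$rank == "family"][1], 1)
  # ...but the phylum denominator is untouched (both named there)
  expect_equal(dropped$n_total[dropped$rank == "phylum"][1], 2)
})

test_that("report matches the brute-force enumerator on random instances", {
  set.seed(11)
  checked <- 0
  while (checked < 150) {
    inst <- random_concordance_instance()
    if (is.null(inst$pred) || is.null(inst$link)) next
    shared <- intersect(inst$pred$contig_id, inst$link$contig_id)
    if (length(shared) == 0) next
    got <- as.data.frame(concordance_report(inst$pred, inst$link))
    want <- oracle_concordance(inst$pred, inst$link)
    key <- function(df) df[order(df$rank, df$mode),
                           c("rank", "mode", "n_concordant", "n_total",
                             "percent")]
    g <- key(got)
    w <- key(want)
    rownames(g) <- rownames(w) <- NULL
    expect_identical(g$n_concordant, w$n_concordant)
    expect_equal(g$percent, w$percent)
    checked <- checked + 1
  }
})

test_that("stringency relaxation never lowers concordance", {
  set.seed(23)
  for (i in 1:40) {
    inst <- random_concordance_instance()
    if (is.null(inst$pred) || is.null(inst$link)) next
    if (length(intersect(inst$pred$contig_id,
                         inst$link$contig_id)) == 0) next
    rep <- concordance_report(inst$pred, inst$link)
    for (r in lineage_ranks(comparison = TRUE)) {
      expect_lte(concordance_percent(rep, r, "strict"),
                 concordance_percent(rep, r, "top_vs_any"))
      expect_lte(concordance_percent(rep, r, "top_vs_any"),
                 concordance_percent(rep, r, "any_vs_any"))
    }
  }
})
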