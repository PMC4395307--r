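test_that("an exactly embedded motif literal is found with zero mismatches", {
  lib <- csb_motifs()
  literal <- gsub("-", "", lib$pattern[lib$name == "CSB-2"])
  seq <- paste0(strrep("AT", 40), literal, strrep("TA", 40))
  h <- scan_consensus_motif(seq, "CSB-2")
  expect_gte(nrow(h), 1L)
  best <- h[which.min(h$mismatches), ]
  expect_identical(best$mismatches, 0L)
  expect_identical(best$start, 81L)
  expect_identical(best$matched, literal)
})

test_that("zero-mismatch placements agree with a regex sliding-window oracle", {
  set.seed(77)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  lib <- csb_motifs()
  ## plant two instances so the oracle has something to find
  seq <- paste0(seq, gsub("-", "", lib$pattern[2]), seq,
                gsub("-", "", lib$pattern[7]))
  for (i in seq_len(nrow(lib))) {
    got <- scan_consensus_motif(seq, lib$name[i], max_mismatches = 0L,
                                collapse = FALSE)
    oracle <- regex_motif_starts(seq, lib$pattern[i])
    expect_setequal(unique(got$start), oracle)
  }
})

test_that("invalid motif patterns are rejected", {
  expect_error(scan_consensus_motif("ACGT", "AXG-T"), "only A, C, G, T")
  expect_error(scan_consensus_motif("ACGT", "----"), "no literal")
})

test_that("scan results are stable under appending unrelated downstream sequence", {
  sim <- simulate_dloop(sim_config(seed = 13))
  h1 <- scan_all_motifs(sim$sequence)
  set.seed(1)
  extended <- paste0(sim$sequence,
                     paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                           collapse = ""))
  h2 <- scan_all_motifs(extended)
  within <- h2[h2$end <= nchar(sim$sequence), ]
  for (nm in unique(h1$name)) {
    expect_true(all(h1$start[h1$name == nm] %in% within$start[within$name == nm]))
  }
})

test_that("TAS/cTAS detection: both variants, pairing, and absence", {
  t1 <- detect_tas("TACATATATGTA")
  expect_true(t1$found)
  expect_identical(c(t1$tas_start, t1$tas_end), c(1L, 5L))
  expect_identical(c(t1$ctas_start, t1$ctas_end), c(8L, 12L))
  expect_true(t1$hairpin_pairable)

  t2 <- detect_tas("GGGTAGCATATATGTAGGG")
  expect_true(t2$found)
  expect_identical(t2$tas_motif, "TAGCAT")
  expect_true(t2$hairpin_pairable)

  t3 <- detect_tas("GGGGCCCCGGGGCCCC")
  expect_false(t3$found)

  ## a core with no downstream counterpart is reported unpaired
  t4 <- detect_tas(paste0("TACAT", strrep("G", 50)))
  expect_true(t4$found)
  expect_false(t4$hairpin_pairable)
  expect_true(is.na(t4$ctas_start))
})

test_that("tandem repeats: exact triple, fractional copies and parameter errors", {
  h <- find_tandem_repeats("ACGTACGTACGT", min_period = 4)
  expect_identical(nrow(h), 1L)
  expect_identical(h$period, 4L)
  expect_equal(h$copy_number, 3.0)

  ## 30 bp unit, 5 full copies plus a half unit; boundary guard bases keep
  ## the flanks from continuing the period
  set.seed(9)
  unit <- paste(sample(c("A", "C", "G"), 30, replace = TRUE), collapse = "")
  array <- substr(strrep(unit, 6), 1, 165)
  flank1 <- paste0(paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                         collapse = ""), "T")
  flank2 <- paste0("T", paste(sample(c("A", "C", "G", "T"), 80,
                                     replace = TRUE), collapse = ""))
  h2 <- find_tandem_repeats(paste0(flank1, array, flank2), min_period = 10)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$period, 30L)
  expect_equal(h2$copy_number, 5.5)
  expect_identical(c(h2$start, h2$end), c(82L, 246L))
  expect_lt(abs(h2$copy_number * h2$period - (h2$end - h2$start + 1)),
            h2$period)

  expect_error(find_tandem_repeats("ACGT", min_period = 0), "min_period")
  expect_error(find_tandem_repeats("ACGTA", min_period = 10), "shorter")
})

test_that("no arrays are reported on most unstructured random sequences", {
  set.seed(555)
  empty <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
    h <- find_tandem_repeats(seq, min_period = 10, min_copies = 2.0)
    if (nrow(h) == 0L) empty <- empty + 1L
  }
  expect_gte(empty / reps, 0.95)
})

test_that("detector agrees with the exhaustive oracle on small planted instances", {
  set.seed(321)
  for (case in 1:25) {
    p <- sample(5:12, 1)
    copies <- sample(c(2, 2.5, 3, 3.5, 4), 1)
    unit <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
                  collapse = "")
    array <- substr(strrep(unit, ceiling(copies) + 1L), 1,
                    as.integer(round(p * copies)))
    flank1 <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1),
                           replace = TRUE), collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1),
                           replace = TRUE), collapse = "")
    seq <- substr(paste0(flank1, array, flank2), 1, 200)
    oracle <- tandem_repeat_oracle(seq, min_period = 5, max_period = 12,
                                   min_copies = 2.0)
    got <- find_tandem_repeats(seq, min_period = 5, max_period = 12,
                               min_copies = 2.0)
    for (i in seq_len(nrow(oracle))) {
      match_ <- got[got$period == oracle$period[i] &
                    floor(got$copy_number) == floor(oracle$copy_number[i]) &
                    got$start <= oracle$end[i] & got$end >= oracle$start[i], ]
      expect_gte(nrow(match_), 1L)
    }
  }
})

test_that("planted D-loop elements are recovered at their recorded coordinates", {
  for (seed in c(2, 8, 15, 23, 30)) {
    sim <- simulate_dloop(sim_config(seed = seed))
    ann <- annotate_dloop(sim$sequence)
    td <- sim$truth_df
    tas_row <- td[td$name == "TAS", ]
    expect_identical(ann$tas$tas_start, tas_row$start)
    expect_true(ann$tas$hairpin_pairable)
    for (nm in csb_motifs()$name) {
      tr <- td[td$name == nm, ]
      h <- ann$hits[ann$hits$name == nm, ]
      expect_true(any(h$start == tr$start & h$end == tr$end),
                  label = paste(nm, "recovered at planted coordinates, seed",
                                seed))
    }
    rep_row <- td[td$name == "tandem_repeat", ]
    expect_gte(nrow(ann$repeats), 1L)
    hit <- ann$repeats[ann$repeats$period == 30L, ]
    expect_gte(nrow(hit), 1L)
    expect_lte(abs(hit$copy_number[1] - 5.5), 0.5)
    expect_identical(hit$placement[1], "downstream-of-CSBs")
  }
})

test_that("the three-domain partition is ordered and flags absent blocks", {
  sim <- simulate_dloop(sim_config(seed = 4))
  ann <- annotate_dloop(sim$sequence)
  d <- ann$domains
  expect_identical(d$domain, c("TAS", "CCD", "CSB"))
  expect_true(all(!is.na(d$start)))
  expect_true(d$end[1] < d$start[2] && d$end[2] < d$start[3])
  expect_identical(length(ann$absent), 0L)

  ## Premnas-style D-loop: only CSB-3 downstream of the CCD
  spec <- dloop_spec(csb = c(ccd_names <- paste0("CSB-", c("F","E","D","C","B","A")),
                             "CSB-3"),
                     repeat_spec = list(period = 25L, copies = 5.5,
                                        placement = "downstream"))
  sim2 <- simulate_dloop(spec, seed = 6)
  ann2 <- annotate_dloop(sim2$sequence)
  expect_setequal(intersect(ann2$absent, c("CSB-1", "CSB-2")),
                  c("CSB-1", "CSB-2"))
  expect_true(all(ann2$repeats$placement == "downstream-of-CSBs"))

  ## no repeats requested -> no arrays reported
  sim3 <- simulate_dloop(dloop_spec(repeat_spec = NULL), seed = 10)
  ann3 <- annotate_dloop(sim3$sequence)
  expect_identical(nrow(ann3$repeats), 0L)
})
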