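test_that("start codons are classified with the canonical ATG/GTG/CTG set", {
  cases <- list(list("ATGGCCAAA", "ATG", TRUE),
                list("GTGACCTTT", "GTG", TRUE),
                list("CTGAAATTT", "CTG", TRUE),
                list("TTGAAACCC", "TTG", FALSE))
  for (cs in cases) {
    got <- classify_start_codon(cs[[1]])
    expect_identical(got$codon, cs[[2]])
    expect_identical(got$canonical, cs[[3]])
  }
  expect_error(classify_start_codon("AT"), "codon")
})

test_that("stop codons are classified including incomplete T-/TA- classes", {
  mk <- function(n, tail) paste0(strrep("C", n - nchar(tail)), tail)
  expect_identical(classify_stop_codon(mk(1866, "AGA")), "AGA")
  expect_identical(classify_stop_codon(mk(1045, "T")), "T-")
  expect_identical(classify_stop_codon(mk(683, "TA")), "TA-")
  expect_identical(classify_stop_codon(mk(975, "TAA")), "TAA")
  expect_identical(classify_stop_codon(mk(975, "TAG")), "TAG")
  ## wrong terminal base for the length class
  expect_identical(classify_stop_codon(mk(1045, "A")), "unclassified")
  expect_identical(classify_stop_codon(mk(975, "AAA")), "unclassified")
})

test_that("protein length follows the uniform subtract-stop rule", {
  expect_identical(protein_length(975, "TAA"), 324L)
  expect_identical(protein_length(1141, "T-"), 380L)
  expect_identical(protein_length(683, "TA-"), 227L)
  expect_identical(protein_length(6, "TAA"), 1L)
  expect_error(protein_length(975, "T-"), "inconsistent")
  expect_error(protein_length(100, "XYZ"), "unknown stop class")
})

test_that("published CDS rows consistent with the rule reproduce their residue counts", {
  rows <- published_cds_rows()
  for (i in seq_len(nrow(rows)))
    expect_identical(protein_length(rows$nt[i], rows$stop[i]), rows$aa[i])
  ## the two rows that do not follow the rule are one residue short of print
  expect_identical(protein_length(1566, "TAA"), 521L)
  expect_identical(protein_length(1866, "AGA"), 621L)
})

test_that("intergenic spacing handles gaps, overlaps and the circular wrap", {
  seq <- strrep("A", 200)
  f <- data.frame(label = c("g1", "g2"), start = c(1L, 104L),
                  end = c(100L, 200L), stringsAsFactors = FALSE)
  rec <- make_record(f, seq)
  sp <- intergenic_spacing(rec)
  expect_identical(sp$spacer[sp$label == "g1"], 3L)
  expect_identical(sp$spacer[sp$label == "g2"], 0L)  # wrap: 200 -> 1

  f2 <- data.frame(label = c("ATP8", "ATP6"), start = c(10L, 100L),
                   end = c(109L, 250L), stringsAsFactors = FALSE)
  sp2 <- intergenic_spacing(make_record(f2, strrep("A", 260)))
  expect_identical(sp2$spacer[sp2$label == "ATP8"], -10L)

  f3 <- data.frame(label = c("a", "b"), start = c(1L, 1L), end = c(50L, 50L))
  expect_error(intergenic_spacing(make_record(f3, strrep("A", 60))),
               "duplicate")
})

test_that("join locations wrapping the origin become two-interval features", {
  seq <- strrep("ACGT", 25)  # 100 bp circle
  gb <- c("LOCUS       WRAP 100 bp    DNA     circular VRT 01-JAN-2026",
          "FEATURES             Location/Qualifiers",
          "     CDS             join(90..100,1..10)",
          "                     /gene=\"ND1\"",
          "ORIGIN",
          paste0("        1 ", tolower(seq)),
          "//")
  rec <- parse_genbank(gb)
  f <- rec$features
  expect_identical(nrow(f), 1L)
  expect_identical(c(f$start, f$end, f$start2, f$end2), c(90L, 100L, 1L, 10L))
  expect_identical(feature_nt_size(f[1, ]), 21L)
  expect_identical(feature_seq(rec, 1),
                   paste0(substr(seq, 90, 100), substr(seq, 1, 10)))
})

test_that("malformed coordinates and length mismatches are rejected by name", {
  gb <- c("LOCUS       BAD 40 bp    DNA     circular",
          "FEATURES             Location/Qualifiers",
          "     CDS             12..xx",
          "                     /gene=\"ND2\"",
          "ORIGIN",
          paste0("        1 ", strrep("acgt", 10)), "//")
  expect_error(parse_genbank(gb), "ND2")
  gb2 <- gb
  gb2[3] <- "     CDS             12..20"
  gb2[6] <- paste0("        1 ", strrep("acgt", 9))
  expect_error(parse_genbank(gb2), "does not match")
})

test_that("synthetic genomes round-trip through the GenBank writer and parser", {
  sim <- simulate_mitogenome(sim_config(seed = 11))
  rec <- parse_genbank(sim$genbank)
  expect_identical(rec, parse_genbank(write_genbank(rec)))
  expect_identical(rec$features$label, canonical_gene_order()$gene)
  expect_identical(rec$length, sim$record$length)
})

test_that("raw annotation labels normalize through the synonym map", {
  expect_identical(normalize_gene_label("CYTB"), "Cytb")
  expect_identical(normalize_gene_label("COX1"), "COI")
  expect_identical(normalize_gene_label("control region"), "D-loop")
  expect_identical(normalize_gene_label("tRNA-Ser(UCN)"), "tRNA-Ser(UCN)")
  expect_identical(normalize_gene_label("unknown_thing"), "unknown_thing")
})

test_that("gene tables on synthetic genomes equal the generator ground truth", {
  for (seed in c(1, 42)) {
    sim <- simulate_mitogenome(sim_config(seed = seed))
    tbl <- gene_table(parse_genbank(sim$genbank))
    gt <- sim$ground_truth
    expect_identical(tbl$gene, gt$gene)
    expect_identical(tbl$nt_size, gt$nt_size)
    expect_identical(tbl$aa_size, gt$aa_size)
    expect_identical(tbl$start_codon, gt$start_codon)
    expect_identical(tbl$stop_codon, gt$stop_codon)
    expect_identical(tbl$intergenic_nt, gt$intergenic_nt)
    expect_identical(tbl$strand, gt$strand)
  }
})

test_that("stop classes, length mod 3 and size conservation hold over random configs", {
  for (seed in c(3, 7, 19)) {
    sim <- simulate_mitogenome(sim_config(seed = seed))
    tbl <- gene_table(sim$record)
    cds <- tbl[!is.na(tbl$stop_codon), ]
    mod <- cds$nt_size %% 3L
    expect_true(all(mod[cds$stop_codon %in% c("TAA", "TAG", "AGA")] == 0L))
    expect_true(all(mod[cds$stop_codon == "T-"] == 1L))
    expect_true(all(mod[cds$stop_codon == "TA-"] == 2L))
    ## feature sizes plus signed spacers tile the circle exactly
    expect_identical(sum(tbl$nt_size) + sum(tbl$intergenic_nt),
                     sim$record$length)
  }
})

test_that("a record without a D-loop yields a table without that row plus a warning", {
  sim <- simulate_mitogenome(sim_config(seed = 5))
  rec <- sim$record
  rec$features <- rec$features[rec$features$label != "D-loop", ]
  expect_warning(tbl <- gene_table(rec), "D-loop")
  expect_false("D-loop" %in% tbl$gene)
})

test_that("gene order comparison is rotation-invariant and localizes swaps", {
  sim <- simulate_mitogenome(sim_config(seed = 2))
  rec <- sim$record
  expect_identical(gene_order_signature(rec)$verdict, "identical")

  ## rotate the circle (cut in the 1 bp gap before COI) so tRNA-Phe no
  ## longer starts at position 1; no feature straddles the cut
  k <- rec$features$start[rec$features$label == "COI"] - 1L
  rot <- rec
  rot$sequence <- paste0(substr(rec$sequence, k + 1, rec$length),
                         substr(rec$sequence, 1, k))
  rot$features$start <- ((rec$features$start - 1L - k) %% rec$length) + 1L
  rot$features$end <- ((rec$features$end - 1L - k) %% rec$length) + 1L
  expect_true(all(rot$features$start <= rot$features$end))
  sig <- gene_order_signature(rot)
  expect_identical(sig$verdict, "identical")

  ## swap ND6 and Cytb labels -> rearranged, exactly that pair displaced
  sw <- rec
  i6 <- which(sw$features$label == "ND6")
  ib <- which(sw$features$label == "Cytb")
  sw$features$label[c(i6, ib)] <- c("Cytb", "ND6")
  sig2 <- gene_order_signature(sw)
  expect_identical(sig2$verdict, "rearranged")
  expect_setequal(sig2$displaced, c("ND6", "Cytb"))
  expect_gt(length(sig2$breakpoints), 0L)
})
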