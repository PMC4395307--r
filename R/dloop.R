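## Control-region dissection: TAS / central conserved domain (CCD) / CSB
## domain partition, element co-location and report writers.

ccd_motif_names <- function() paste0("CSB-", c("F", "E", "D", "C", "B", "A"))
csb_block_names <- function() paste0("CSB-", 1:3)

#' Partition a D-loop into TAS, CCD and CSB domains
#'
#' Builds the three-domain schematic of teleost control regions from element
#' hits: the TAS domain runs from the sequence start to just before the
#' first central-conserved-domain hit (it contains the TAS/cTAS hairpin),
#' the CCD spans the CSB-F..CSB-A hits, and the CSB domain spans CSB-1..3.
#' Domain boundaries between hits are a stated convention (midpoints are not
#' inferred; the domain edge is the flanking hit edge). Each tandem-repeat
#' array is labelled upstream- or downstream-of-CSBs relative to the last
#' detected CSB hit. Missing blocks are reported in `absent`. When the hits
#' violate the TAS < CCD < CSB order a warning is raised and a best-effort
#' partition returned.
#'
#' @param seq the D-loop sequence the inputs came from.
#' @param hits motif hits from [scan_all_motifs()].
#' @param tas result of [detect_tas()].
#' @param repeats result of [find_tandem_repeats()].
#' @return object of class `dloop_annotation`: list with `length`, `domains`
#'   (data.frame domain/start/end), `hits`, `tas`, `repeats` (with added
#'   `placement` column), `absent` (character vector of undetected motifs).
#' @export
partition_dloop <- function(seq, hits, tas, repeats) {
  n <- nchar(seq)
  ## domains are built from each motif's best hit (fewest mismatches, then
  ## leftmost): secondary hits within the mismatch budget are kept in the
  ## report but do not move domain boundaries
  best <- hits[order(hits$name, hits$mismatches, hits$start), ]
  best <- best[!duplicated(best$name), ]
  ccd_hits <- best[best$name %in% ccd_motif_names(), , drop = FALSE]
  csb_hits <- best[best$name %in% csb_block_names(), , drop = FALSE]
  absent <- setdiff(c(ccd_motif_names(), csb_block_names()), hits$name)

  ccd <- if (nrow(ccd_hits)) c(min(ccd_hits$start), max(ccd_hits$end)) else c(NA, NA)
  csb <- if (nrow(csb_hits)) c(min(csb_hits$start), max(csb_hits$end)) else c(NA, NA)
  tas_end <- if (isTRUE(tas$found) && !is.na(tas$ctas_end)) tas$ctas_end
             else if (isTRUE(tas$found)) tas$tas_end else NA_integer_
  tas_dom <- if (!is.na(tas_end))
    c(1L, min(tas_end, (ccd[1] %||% n) - 1L, na.rm = TRUE)) else c(NA, NA)
  ## enforce schematic order where possible
  ordered <- TRUE
  if (!any(is.na(c(tas_dom[2], ccd[1]))) && tas_dom[2] >= ccd[1]) ordered <- FALSE
  if (!any(is.na(c(ccd[2], csb[1]))) && ccd[2] >= csb[1]) ordered <- FALSE
  if (!ordered)
    warning("element hits violate the TAS < CCD < CSB domain order; ",
            "returning best-effort partition", call. = FALSE)
  domains <- data.frame(
    domain = c("TAS", "CCD", "CSB"),
    start = c(tas_dom[1], ccd[1], csb[1]),
    end = c(tas_dom[2], ccd[2], csb[2]))

  if (nrow(repeats)) {
    last_csb <- if (nrow(csb_hits)) max(csb_hits$end)
                else if (nrow(ccd_hits)) max(ccd_hits$end) else 0L
    repeats$placement <- ifelse(repeats$start > last_csb,
                                "downstream-of-CSBs", "upstream-of-CSBs")
  } else {
    repeats$placement <- character(0)
  }
  structure(list(length = n, domains = domains, hits = hits, tas = tas,
                 repeats = repeats, absent = absent),
            class = "dloop_annotation")
}

#' Annotate a D-loop end to end
#'
#' Runs the consensus-motif scan, TAS/cTAS detection and tandem-repeat
#' detection, then partitions the sequence into the TAS/CCD/CSB domains.
#'
#' @param seq D-loop sequence.
#' @param mismatch_frac optional mismatch budget as a fraction of each
#'   motif's literal length (default: the per-motif library budget, 15%).
#' @param gap_slack spacer slack passed to the scanner.
#' @param min_period,min_copies tandem-repeat settings.
#' @return a `dloop_annotation`.
#' @export
#' @examples
#' sim <- simulate_dloop(sim_config(seed = 3))
#' ann <- annotate_dloop(sim$sequence)
#' ann$domains
annotate_dloop <- function(seq, mismatch_frac = NULL, gap_slack = 2L,
                           min_period = 10L, min_copies = 2.0) {
  hits <- scan_all_motifs(seq, gap_slack = gap_slack,
                          mismatch_frac = mismatch_frac)
  tas <- detect_tas(seq)
  reps <- if (nchar(seq) >= 2L * min_period)
    find_tandem_repeats(seq, min_period = min_period, min_copies = min_copies)
  else find_tandem_repeats(strrep("A", 2L * min_period),
                           min_period = min_period)[0, ]
  partition_dloop(seq, hits, tas, reps)
}

#' @export
print.dloop_annotation <- function(x, ...) {
  cat("dloop_annotation:", x$length, "bp;",
      nrow(x$hits), "motif hits;",
      nrow(x$repeats), "tandem arrays\n")
  print(x$domains)
  invisible(x)
}

#' Table-6-style D-loop summary row
#'
#' @param seq D-loop sequence.
#' @param annotation optional pre-computed [annotate_dloop()] result.
#' @param id sequence identifier.
#' @return one-row data.frame: `id`, `size_bp`, `A`, `T`, `G`, `C`, `AT`,
#'   `tandem_repeats` (largest copy number, 0 when none).
#' @export
dloop_summary <- function(seq, annotation = NULL, id = "dloop") {
  if (is.null(annotation)) annotation <- annotate_dloop(seq)
  comp <- base_composition(seq)
  tr <- if (nrow(annotation$repeats)) max(annotation$repeats$copy_number) else 0
  data.frame(id = id, size_bp = nchar(seq),
             A = comp$pct2[["A"]], T = comp$pct2[["T"]],
             G = comp$pct2[["G"]], C = comp$pct2[["C"]],
             AT = round_half_up(comp$pct2[["A"]] + comp$pct2[["T"]], 2),
             tandem_repeats = tr, stringsAsFactors = FALSE)
}

#' Export D-loop annotations as GFF3
#'
#' Writes domains, motif hits, the TAS/cTAS element and tandem arrays of one
#' or more annotated D-loops through rtracklayer.
#'
#' @param annotations named list of `dloop_annotation` objects (names become
#'   seqids).
#' @param file output path.
#' @export
write_dloop_gff3 <- function(annotations, file) {
  rows <- list()
  add <- function(seqid, type, start, end, name, score = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, type = type, start = start, end = end, name = name,
      score = score, stringsAsFactors = FALSE)
  }
  for (id in names(annotations)) {
    a <- annotations[[id]]
    d <- a$domains[!is.na(a$domains$start), , drop = FALSE]
    for (i in seq_len(nrow(d)))
      add(id, "region", d$start[i], d$end[i], paste0(d$domain[i], "_domain"))
    h <- a$hits
    for (i in seq_len(nrow(h)))
      add(id, "sequence_conserved_region", h$start[i], h$end[i], h$name[i],
          h$mismatches[i])
    if (isTRUE(a$tas$found)) {
      add(id, "sequence_motif", a$tas$tas_start, a$tas$tas_end, "TAS")
      if (!is.na(a$tas$ctas_start))
        add(id, "sequence_motif", a$tas$ctas_start, a$tas$ctas_end, "cTAS")
    }
    r <- a$repeats
    for (i in seq_len(nrow(r)))
      add(id, "tandem_repeat", r$start[i], r$end[i],
          sprintf("period%d_x%.1f_%s", r$period[i], r$copy_number[i],
                  r$placement[i]), r$copy_number[i])
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) {
    writeLines("##gff-version 3", file)
    return(invisible(file))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = "+")
  S4Vectors::mcols(gr)$source <- "mitorg"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$score <- df$score
  S4Vectors::mcols(gr)$Name <- df$name
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}
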