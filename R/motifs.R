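## Consensus-motif library and gapped-motif scanning for the control region.
##
## Patterns are strings over {A,C,G,T,-}. Each maximal dash run of length k
## is a spacer that may expand to 0..(k + gap_slack) arbitrary bases (the
## printed consensus dashes are of heterogeneous typographic length; the
## default slack of 2 absorbs that).

#' Built-in consensus motif library for the anemonefish control region
#'
#' The TAS core motifs and the nine conserved-block consensus strings
#' (CSB-F..CSB-A of the central conserved domain, CSB-1..3 downstream), with
#' dash runs marking variable spacers. Typographic em dashes in the printed
#' consensus are stored as two ASCII hyphens each.
#'
#' @return data.frame with columns `name`, `pattern`, `max_mismatches`
#'   (default budget: ceiling of 15% of the literal length).
#' @export
csb_motifs <- function() {
  pat <- c(
    "CSB-F" = "GTA-TAAGAACCGACCAT",
    "CSB-E" = "GACAA--ATTGTG-GGGT",
    "CSB-D" = "TATTCCTGGCATTTGGTTCCTA-TTCAGG--CA",
    "CSB-C" = "CTT-CC-----------ATAAGTTAATG",
    "CSB-B" = "CAT---ACTC-TTACCCAC",
    "CSB-A" = "TC------GGTCAG---TT",
    "CSB-1" = "CATAA-TGATATCAAGAGCAT---A",
    "CSB-2" = "TAA-CCCCCCC---CCCCCC",
    "CSB-3" = "T--AAACCCCCC-G-AA-CA")
  lit <- nchar(gsub("-", "", pat))
  data.frame(name = names(pat), pattern = unname(pat),
             max_mismatches = as.integer(ceiling(0.15 * lit)),
             stringsAsFactors = FALSE)
}

## decompose a pattern into literal segments and spacer ranges
parse_motif_pattern <- function(pattern, gap_slack = 2L) {
  if (grepl("[^ACGT-]", pattern))
    stop("motif pattern may contain only A, C, G, T and '-'", call. = FALSE)
  if (!grepl("[ACGT]", pattern))
    stop("motif pattern has no literal bases", call. = FALSE)
  segs <- strsplit(pattern, "-+")[[1]]
  segs <- segs[nzchar(segs)]
  runs <- regmatches(pattern, gregexpr("-+", pattern))[[1]]
  ## leading/trailing dashes are meaningless for anchoring; drop them
  core <- sub("^-+", "", sub("-+$", "", pattern))
  runs <- regmatches(core, gregexpr("-+", core))[[1]]
  list(segments = segs,
       gap_max = if (length(runs)) nchar(runs) + gap_slack else integer(0),
       literal_len = sum(nchar(segs)))
}

#' Scan a sequence for a gapped consensus motif
#'
#' Finds placements of the motif where each spacer run expands to 0..k+slack
#' arbitrary bases, scoring placements by literal mismatches. All placements
#' within the mismatch budget are candidate hits; overlapping hits of the
#' same motif are collapsed to the best-scoring one (ties broken leftmost,
#' then shortest) unless `collapse = FALSE`.
#'
#' @param seq nucleotide string to scan.
#' @param motif a motif name from [csb_motifs()], or a pattern string over
#'   {A,C,G,T,-}.
#' @param max_mismatches mismatch budget; default ceiling(15% of literal
#'   length).
#' @param gap_slack extra bases each spacer run may absorb (default 2).
#' @param collapse collapse overlapping same-motif hits (default TRUE).
#' @return data.frame with columns `name`, `start`, `end`, `mismatches`,
#'   `matched`, `gaps` (comma-separated chosen spacer lengths), sorted by
#'   position; zero rows when nothing is found.
#' @export
#' @examples
#' scan_consensus_motif("AAGTATTAAGAACCGACCATAA", "CSB-F")
scan_consensus_motif <- function(seq, motif, max_mismatches = NULL,
                                 gap_slack = 2L, collapse = TRUE) {
  stopifnot_scalar_seq(seq)
  lib <- csb_motifs()
  if (motif %in% lib$name) {
    row <- lib[lib$name == motif, ]
    pattern <- row$pattern
    name <- motif
    if (is.null(max_mismatches)) max_mismatches <- row$max_mismatches
  } else {
    pattern <- motif
    name <- motif
  }
  pm <- parse_motif_pattern(pattern, gap_slack)
  if (is.null(max_mismatches))
    max_mismatches <- as.integer(ceiling(0.15 * pm$literal_len))

  s <- seq_ints(seq)
  n <- length(s)
  seg_int <- lapply(pm$segments, seq_ints)
  seg_len <- vapply(seg_int, length, integer(1))

  ## enumerate spacer-length combinations
  combos <- if (length(pm$gap_max))
    as.matrix(expand.grid(lapply(pm$gap_max, function(k) 0:k)))
  else matrix(integer(0), nrow = 1, ncol = 0)

  hits <- list()
  for (ci in seq_len(nrow(combos))) {
    gaps <- as.integer(combos[ci, ])
    ## offsets of each segment within the placement
    off <- integer(length(seg_len))
    pos <- 0L
    for (k in seq_along(seg_len)) {
      off[k] <- pos
      pos <- pos + seg_len[k] + if (k <= length(gaps)) gaps[k] else 0L
    }
    span <- sum(seg_len) + sum(gaps)
    if (span > n) next
    starts <- seq_len(n - span + 1L)
    mm <- integer(length(starts))
    for (k in seq_along(seg_int)) {
      sk <- seg_int[[k]]
      for (j in seq_along(sk)) {
        mm <- mm + (s[starts + off[k] + j - 1L] != sk[j])
      }
    }
    ok <- which(mm <= max_mismatches)
    if (length(ok))
      hits[[length(hits) + 1L]] <- data.frame(
        name = name, start = ok, end = ok + span - 1L,
        mismatches = mm[ok], gaps = paste(gaps, collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(name = character(), start = integer(), end = integer(),
                      mismatches = integer(), matched = character(),
                      gaps = character(), stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  ## order by score, then leftmost, then shortest (the tie-break rule)
  h <- h[order(h$mismatches, h$start, h$end - h$start), ]
  if (collapse) {
    kept <- h[0, ]
    for (i in seq_len(nrow(h))) {
      cand <- h[i, ]
      if (!nrow(kept) ||
          !any(cand$start <= kept$end & cand$end >= kept$start)) {
        kept <- rbind(kept, cand)
      }
    }
    h <- kept
  }
  h <- h[order(h$start, h$end), ]
  h$matched <- substring(seq, h$start, h$end)
  rownames(h) <- NULL
  h[, c("name", "start", "end", "mismatches", "matched", "gaps")]
}

#' Scan a D-loop for the whole consensus motif library
#'
#' @param seq D-loop sequence.
#' @param gap_slack,mismatch_frac scanner settings; `mismatch_frac`
#'   overrides the per-motif default budget when given.
#' @return data.frame of best hits (one collapsed hit set per motif).
#' @export
scan_all_motifs <- function(seq, gap_slack = 2L, mismatch_frac = NULL) {
  lib <- csb_motifs()
  out <- lapply(seq_len(nrow(lib)), function(i) {
    budget <- if (is.null(mismatch_frac)) NULL
      else as.integer(ceiling(mismatch_frac *
                              nchar(gsub("-", "", lib$pattern[i]))))
    scan_consensus_motif(seq, lib$name[i], max_mismatches = budget,
                         gap_slack = gap_slack)
  })
  do.call(rbind, out)
}

#' Locate the TAS / cTAS hairpin element
#'
#' Finds a TACAT (or the TAGCAT variant) termination-associated-sequence
#' core with a downstream reverse-complement counterpart ATGTA within
#' `max_loop` bases; their pairing supports the replication-termination
#' hairpin. The first such co-located pair is reported; a TAS core without a
#' nearby cTAS is reported unpaired, and absence of any core is an absent
#' element (not an error).
#'
#' @param seq D-loop sequence.
#' @param max_loop maximal distance between TAS core end and cTAS start
#'   (default 30).
#' @return list with `found`, `tas_start`, `tas_end`, `tas_motif`,
#'   `ctas_start`, `ctas_end`, `hairpin_pairable`.
#' @export
#' @examples
#' detect_tas("TACATATATGTA")  # TAS 1..5, cTAS 8..12, pairable
detect_tas <- function(seq, max_loop = 30L) {
  stopifnot_scalar_seq(seq)
  s <- toupper(seq)
  absent <- list(found = FALSE, tas_start = NA_integer_, tas_end = NA_integer_,
                 tas_motif = NA_character_, ctas_start = NA_integer_,
                 ctas_end = NA_integer_, hairpin_pairable = FALSE)
  cores <- list()
  for (m in c("TAGCAT", "TACAT")) {
    p <- gregexpr(m, s, fixed = TRUE)[[1]]
    if (p[1] != -1)
      cores[[length(cores) + 1L]] <- data.frame(start = as.integer(p),
                                                motif = m)
  }
  if (!length(cores)) return(absent)
  cores <- do.call(rbind, cores)
  cores <- cores[order(cores$start, -nchar(cores$motif)), ]
  ctas <- as.integer(gregexpr("ATGTA", s, fixed = TRUE)[[1]])
  ctas <- ctas[ctas > 0]
  for (i in seq_len(nrow(cores))) {
    tstart <- cores$start[i]
    tend <- tstart + nchar(cores$motif[i]) - 1L
    cand <- ctas[ctas > tend & ctas <= tend + max_loop]
    if (length(cand)) {
      cstart <- cand[1]
      ## hairpin pairable iff revcomp of the TAS core equals the cTAS;
      ## the optional G of the TA(G)CAT variant is a bulged base and is
      ## collapsed before the comparison
      core <- cores$motif[i]
      if (core == "TAGCAT") core <- "TACAT"
      pairable <- identical(revcomp(core), "ATGTA")
      return(list(found = TRUE, tas_start = tstart, tas_end = tend,
                  tas_motif = cores$motif[i], ctas_start = cstart,
                  ctas_end = cstart + 4L, hairpin_pairable = pairable))
    }
  }
  ## unpaired TAS core: report the first occurrence
  tstart <- cores$start[1]
  tend <- tstart + nchar(cores$motif[1]) - 1L
  list(found = TRUE, tas_start = tstart, tas_end = tend,
       tas_motif = cores$motif[1], ctas_start = NA_integer_,
       ctas_end = NA_integer_, hairpin_pairable = FALSE)
}
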