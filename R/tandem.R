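## Tandem-repeat detection by seed and extend. A deliberately small
## approximation in the spirit of Tandem Repeats Finder (not a clone):
## exact-unit k-mer seeds propose candidate periods, extension maximises the
## array span while keeping the per-base mismatch fraction (sequence vs its
## period-shifted self) within a budget, and copy number = span / period
## reported to one decimal so partial terminal units appear as fractional
## copies (5.5, 6.5, 3.5 ...).

#' Detect tandem-repeat arrays
#'
#' @param seq nucleotide string (length >= 2 * `min_period`).
#' @param min_period minimal repeat unit length in bp (default 10).
#' @param max_period maximal unit length (default: min(100, floor(n/2))).
#' @param min_copies minimal copy number to report (default 2.0).
#' @param max_mismatch_frac allowed fraction of mismatching positions
#'   between the array and its period-shifted self (default 0.2).
#' @return data.frame with columns `start`, `end`, `period`, `copy_number`
#'   (one decimal), `consensus` (first unit of the array), `mismatches`;
#'   arrays sorted by span, overlapping calls collapsed preferring longer
#'   spans then smaller periods. Zero rows when nothing is found.
#' @export
#' @examples
#' find_tandem_repeats(strrep("ACGTACGTACGT", 1), min_period = 4)
find_tandem_repeats <- function(seq, min_period = 10L, max_period = NULL,
                                min_copies = 2.0, max_mismatch_frac = 0.2) {
  stopifnot_scalar_seq(seq)
  if (min_period < 1L) stop("min_period must be >= 1", call. = FALSE)
  n <- nchar(seq)
  if (n < 2L * min_period)
    stop("sequence shorter than two minimal units", call. = FALSE)
  if (is.null(max_period)) max_period <- min(100L, n %/% 2L)
  s <- seq_ints(seq)

  cands <- list()
  for (p in min_period:max_period) {
    m <- s[seq_len(n - p)] == s[(p + 1L):n]   # match vector at lag p
    ## seeds: an exact full unit (p consecutive matches)
    run <- rle(m)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    seed_runs <- which(run$values & run$lengths >= p)
    if (!length(seed_runs)) next
    ## score-based extension: match +1, mismatch -penalty, with the penalty
    ## set so the break-even mismatch density equals the budget; an X-drop
    ## cutoff stops extension into unrelated flanks and the array is trimmed
    ## to the maximum-score endpoints
    penalty <- (1 - max_mismatch_frac) / max_mismatch_frac
    xdrop <- 2 * penalty
    extend <- function(a, b, m) {
      best <- 0; cur <- 0; arg <- b
      j <- b + 1L
      while (j <= length(m) && cur > best - xdrop) {
        cur <- cur + if (m[j]) 1 else -penalty
        if (cur > best) { best <- cur; arg <- j }
        j <- j + 1L
      }
      b <- arg
      best <- 0; cur <- 0; arg <- a
      j <- a - 1L
      while (j >= 1L && cur > best - xdrop) {
        cur <- cur + if (m[j]) 1 else -penalty
        if (cur > best) { best <- cur; arg <- j }
        j <- j - 1L
      }
      c(arg, b)
    }
    for (k in seed_runs) {
      ab <- extend(starts[k], ends[k], m)
      a <- ab[1]; b <- ab[2]
      mm <- sum(!m[a:b])
      span <- b - a + 1L + p
      copies <- span / p
      if (copies + 1e-9 >= min_copies)
        cands[[length(cands) + 1L]] <- data.frame(
          start = a, end = a + span - 1L, period = p,
          copy_number = round_half_up(copies, 1), mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), consensus = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (!length(cands)) return(empty)
  h <- unique(do.call(rbind, cands))
  ## drop arrays whose unit is itself a repeat of a kept smaller period,
  ## and collapse overlapping calls: longest span wins, then smaller period,
  ## then leftmost
  h <- h[order(-(h$end - h$start), h$period, h$start), ]
  kept <- h[0, ]
  for (i in seq_len(nrow(h))) {
    cand <- h[i, ]
    ov <- nrow(kept) &&
      any(pmin(kept$end, cand$end) - pmax(kept$start, cand$start) + 1L >
          0.5 * (cand$end - cand$start + 1L))
    if (!ov) kept <- rbind(kept, cand)
  }
  kept <- kept[order(kept$start), ]
  kept$consensus <- substring(seq, kept$start, kept$start + kept$period - 1L)
  rownames(kept) <- NULL
  kept[, c("start", "end", "period", "copy_number", "consensus", "mismatches")]
}

#' Exhaustive exact-match tandem-repeat oracle (small instances)
#'
#' Brute-force enumeration of maximal exact tandem arrays: for every period
#' p, every maximal run of positions i with seq[i] == seq[i+p] of length >=
#' p defines an array. Used as an independent check of
#' [find_tandem_repeats()] on small sequences; quadratic, do not use on
#' genomes.
#'
#' @param seq nucleotide string.
#' @param min_period,max_period period range to test.
#' @param min_copies minimal copy number.
#' @return data.frame with `start`, `end`, `period`, `copy_number`.
#' @export
tandem_repeat_oracle <- function(seq, min_period = 1L, max_period = 12L,
                                 min_copies = 2.0) {
  n <- nchar(seq)
  s <- seq_ints(seq)
  out <- list()
  for (p in seq.int(min_period, min(max_period, n %/% 2L))) {
    m <- s[seq_len(n - p)] == s[(p + 1L):n]
    run <- rle(m)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (k in which(run$values & run$lengths >= p)) {
      span <- run$lengths[k] + p
      if (span / p + 1e-9 >= min_copies)
        out[[length(out) + 1L]] <- data.frame(
          start = starts[k], end = starts[k] + span - 1L, period = p,
          copy_number = span / p)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric()))
  h <- do.call(rbind, out)
  ## same canonicalization as the detector (longest span, then smallest
  ## period; overlapping calls suppressed) so the two agree on which of
  ## several overlapping explanations of a region is reported
  h <- h[order(-(h$end - h$start), h$period, h$start), ]
  kept <- h[0, ]
  for (i in seq_len(nrow(h))) {
    cand <- h[i, ]
    ov <- nrow(kept) &&
      any(pmin(kept$end, cand$end) - pmax(kept$start, cand$start) + 1L >
          0.5 * (cand$end - cand$start + 1L))
    if (!ov) kept <- rbind(kept, cand)
  }
  kept <- kept[order(kept$start), ]
  rownames(kept) <- NULL
  kept
}
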