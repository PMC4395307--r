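## Independent oracles and small fixture builders used across the suite.

## minimal mito_record constructor for hand-built annotations
make_record <- function(features, sequence, id = "TEST", circular = TRUE) {
  features$start2 <- features$start2 %||% NA_integer_
  if (!"start2" %in% names(features)) features$start2 <- NA_integer_
  if (!"end2" %in% names(features)) features$end2 <- NA_integer_
  if (!"category" %in% names(features)) features$category <- "noncoding"
  if (!"strand" %in% names(features)) features$strand <- "H"
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  structure(list(id = id, length = nchar(sequence), is_circular = circular,
                 sequence = sequence, features = features),
            class = "mito_record")
}

`%||%` <- function(a, b) tryCatch(if (is.null(a)) b else a, error = function(e) b)

## brute-force gapped-motif oracle: all start positions admitting an exact
## (zero-mismatch) placement, via a perl regex with bounded gap quantifiers
## and a lookahead for overlapping matches. Independent of the scanner.
regex_motif_starts <- function(seq, pattern, gap_slack = 2L) {
  core <- sub("^-+", "", sub("-+$", "", pattern))
  segs <- strsplit(core, "-+")[[1]]
  runs <- regmatches(core, gregexpr("-+", core))[[1]]
  rx <- segs[1]
  for (i in seq_along(runs))
    rx <- paste0(rx, sprintf(".{0,%d}", nchar(runs[i]) + gap_slack),
                 segs[i + 1])
  starts <- gregexpr(sprintf("(?=%s)", rx), seq, perl = TRUE)[[1]]
  as.integer(starts[starts > 0])
}

## least-squares topology oracle: enumerate every unrooted topology over the
## taxa, fit branch lengths by unconstrained least squares on the path
## design matrix, and return the index of the minimal-residual topology.
ls_residual <- function(phy, d) {
  tips <- phy$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(phy$edge))
  for (r in seq_len(nrow(pairs))) {
    np <- ape::nodepath(phy, pairs[r, 1], pairs[r, 2])
    for (k in seq_len(length(np) - 1L)) {
      e <- which((phy$edge[, 1] == np[k] & phy$edge[, 2] == np[k + 1]) |
                 (phy$edge[, 1] == np[k + 1] & phy$edge[, 2] == np[k]))
      A[r, e] <- 1
    }
  }
  y <- d[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

best_topology_by_ls <- function(topologies, d) {
  res <- vapply(topologies, ls_residual, numeric(1), d = d)
  which.min(res)
}

## additive distance matrix from a phylo with branch lengths
additive_matrix <- function(phy) {
  m <- ape::cophenetic.phylo(phy)
  m[phy$tip.label, phy$tip.label]
}

## published per-gene CDS lengths and printed residue counts that follow the
## uniform subtract-stop rule (COI and ND5 are excluded: their printed
## counts are one residue larger than the rule gives)
published_cds_rows <- function() {
  data.frame(
    gene = c("ND1", "ND2", "COII", "ATP8", "ATP6", "COIII", "ND3", "ND4L",
             "ND4", "ND6", "Cytb"),
    nt = c(975L, 1045L, 691L, 168L, 683L, 785L, 349L, 297L, 1381L, 522L, 1141L),
    stop = c("TAA", "T-", "T-", "TAA", "TA-", "TA-", "T-", "TAA", "T-",
             "TAA", "T-"),
    aa = c(324L, 348L, 230L, 55L, 227L, 261L, 116L, 98L, 460L, 173L, 380L),
    stringsAsFactors = FALSE)
}
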