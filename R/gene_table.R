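## Gene-table construction: codon classes, protein lengths, signed intergenic
## spacers and gene-order signatures for annotated circular mitogenomes.

#' Classify the start codon of a coding sequence
#'
#' Mitochondrial CDSs initiate mostly at ATG, with GTG (typically COI) and
#' CTG as accepted alternatives; anything else is reported as atypical.
#'
#' @param cds_seq sense-strand CDS sequence (length >= 3).
#' @return list with `codon` (first 3-mer) and `canonical` flag
#'   (TRUE iff codon is ATG, GTG or CTG).
#' @export
#' @examples
#' classify_start_codon("ATGGCCAAA")$codon      # "ATG"
#' classify_start_codon("TTGAAA")$canonical     # FALSE
classify_start_codon <- function(cds_seq) {
  stopifnot_scalar_seq(cds_seq, "cds_seq")
  if (nchar(cds_seq) < 3L)
    stop("cds_seq shorter than one codon", call. = FALSE)
  codon <- toupper(substr(cds_seq, 1, 3))
  list(codon = codon, canonical = codon %in% c("ATG", "GTG", "CTG"))
}

#' Classify the stop codon (including incomplete T-/TA- classes)
#'
#' Vertebrate mitochondrial CDSs may end in a complete stop (TAA, TAG, or the
#' AGA seen in ND5) or in an incomplete stop of one (T-) or two (TA-) bases
#' completed to UAA by post-transcriptional polyadenylation. The class is
#' read from the CDS length modulo 3 and the terminal base(s):
#' length %% 3 == 0 with a terminal TAA/TAG/AGA gives that codon;
#' length %% 3 == 1 with terminal T gives "T-"; length %% 3 == 2 with
#' terminal TA gives "TA-"; anything else is "unclassified".
#'
#' @param cds_seq sense-strand CDS sequence.
#' @param downstream_base optional base following the CDS (unused by the
#'   classification, carried for reporting).
#' @return stop class string.
#' @export
#' @examples
#' classify_stop_codon(paste0(strrep("A", 1042), "T"))  # "T-"
classify_stop_codon <- function(cds_seq, downstream_base = NA_character_) {
  stopifnot_scalar_seq(cds_seq, "cds_seq")
  s <- toupper(cds_seq)
  n <- nchar(s)
  mod <- n %% 3L
  if (mod == 0L) {
    last3 <- substr(s, n - 2L, n)
    if (last3 %in% c("TAA", "TAG", "AGA")) return(last3)
  } else if (mod == 1L) {
    if (substr(s, n, n) == "T") return("T-")
  } else if (mod == 2L) {
    if (substr(s, n - 1L, n) == "TA") return("TA-")
  }
  "unclassified"
}

stop_codon_length <- function(stop_class) {
  switch(stop_class,
         "TAA" = 3L, "TAG" = 3L, "AGA" = 3L, "T-" = 1L, "TA-" = 2L,
         stop("unknown stop class '", stop_class, "'", call. = FALSE))
}

#' Encoded protein length from CDS length and stop class
#'
#' Applies the uniform subtract-stop rule: residues =
#' (nt_size - stop length) / 3, with stop length 3 for complete stops,
#' 1 for T- and 2 for TA-. The CDS length must be consistent with the stop
#' class (complete stops need nt_size %% 3 == 0, T- needs remainder 1,
#' TA- remainder 2).
#'
#' @param nt_size CDS length in bp.
#' @param stop_class one of "TAA", "TAG", "AGA", "T-", "TA-".
#' @return integer residue count.
#' @export
#' @examples
#' protein_length(975, "TAA")   # 324
#' protein_length(1141, "T-")   # 380
#' protein_length(683, "TA-")   # 227
protein_length <- function(nt_size, stop_class) {
  stop_len <- stop_codon_length(stop_class)
  if ((nt_size - stop_len) %% 3L != 0L)
    stop("nt_size ", nt_size, " inconsistent with stop class ", stop_class,
         call. = FALSE)
  as.integer((nt_size - stop_len) / 3L)
}

## order features clockwise on the H-strand (by start; a feature wrapping the
## origin sorts by its first interval)
ordered_features <- function(record) {
  f <- record$features
  f[order(f$start), , drop = FALSE]
}

#' Signed intergenic spacers between consecutive features
#'
#' For each feature, the signed gap to the *next* feature clockwise on the
#' H-strand circle: `next.start - current.end - 1` under circular arithmetic.
#' Negative values are overlapping nucleotides between adjacent genes. The
#' last feature's successor is the first (circular adjacency). Note that
#' comparative gene tables conventionally print each spacer on the
#' *downstream* gene's row; [gene_table()] follows that convention, this
#' function reports per upstream feature.
#'
#' @param record a `mito_record`.
#' @return data.frame with columns `label`, `next_label`, `spacer`.
#' @export
intergenic_spacing <- function(record) {
  f <- ordered_features(record)
  key <- paste(f$start, f$end)
  if (anyDuplicated(key))
    stop("duplicate identical feature spans in annotation", call. = FALSE)
  n <- nrow(f)
  if (n < 2L) stop("need at least two features", call. = FALSE)
  ends <- ifelse(is.na(f$end2), f$end, f$end2)
  nxt <- c(2:n, 1L)
  spacer <- integer(n)
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (j == 1L) {  # circular wrap: distance from last end to first start
      spacer[i] <- (record$length - ends[i]) + (f$start[j] - 1L)
    } else {
      spacer[i] <- f$start[j] - ends[i] - 1L
    }
  }
  data.frame(label = f$label, next_label = f$label[nxt], spacer = spacer,
             stringsAsFactors = FALSE)
}

#' Build the per-genome gene table
#'
#' One row per annotated feature in clockwise order: nucleotide size, encoded
#' protein length and codon classes for CDSs (L-strand CDSs are
#' reverse-complemented before codon analysis), anticodon for tRNAs, signed
#' intergenic nucleotides to the *previous* feature (the layout convention of
#' comparative mitogenome tables, negative = overlap) and strand.
#'
#' @param record a `mito_record`.
#' @return data.frame of class `mito_gene_table` with columns `gene`,
#'   `nt_size`, `aa_size`, `start_codon`, `stop_codon`, `anticodon`,
#'   `intergenic_nt`, `strand`.
#' @export
#' @examples
#' sim <- simulate_mitogenome(sim_config(seed = 1))
#' head(gene_table(parse_genbank(sim$genbank)))
gene_table <- function(record) {
  f <- ordered_features(record)
  n <- nrow(f)
  sp <- intergenic_spacing(record)        # spacer after feature i
  prev_spacer <- sp$spacer[c(n, seq_len(n - 1L))]  # spacer before feature i
  nt <- vapply(seq_len(n), function(i) feature_nt_size(f[i, ]), integer(1))
  aa <- rep(NA_integer_, n)
  start_codon <- rep(NA_character_, n)
  stop_codon <- rep(NA_character_, n)
  for (i in which(f$category == "CDS")) {
    s <- feature_seq(record, i)
    start_codon[i] <- classify_start_codon(s)$codon
    cls <- classify_stop_codon(s)
    stop_codon[i] <- cls
    if (cls != "unclassified") aa[i] <- protein_length(nt[i], cls)
  }
  if (!any(f$label == "D-loop"))
    warning("record ", record$id, " has no D-loop feature", call. = FALSE)
  structure(
    data.frame(gene = f$label, nt_size = nt, aa_size = aa,
               start_codon = start_codon, stop_codon = stop_codon,
               anticodon = f$anticodon, intergenic_nt = prev_spacer,
               strand = f$strand, stringsAsFactors = FALSE),
    class = c("mito_gene_table", "data.frame"))
}

#' Aggregate gene tables across genomes into a min~max range table
#'
#' Collapses per-genome gene tables to one row per gene in canonical order,
#' using the tilde notation `min~max` for ranges (single value when
#' invariant), slash-joined unions for codon columns (e.g. "GTG/ATG/CTG"),
#' and min~max for signed intergenic nucleotides.
#'
#' @param tables list of `mito_gene_table` data.frames.
#' @param reference_aa optional named integer vector of published amino-acid
#'   counts; genes whose computed count (by the uniform subtract-stop rule)
#'   disagrees are listed in the `discrepancies` attribute rather than
#'   special-cased.
#' @return data.frame with the same columns as [gene_table()], all character.
#' @export
aggregate_gene_tables <- function(tables, reference_aa = NULL) {
  all_genes <- unique(unlist(lapply(tables, `[[`, "gene")))
  canon <- canonical_gene_order()$gene
  genes <- c(intersect(canon, all_genes), setdiff(all_genes, canon))
  join_unique <- function(x) {
    x <- unique(x[!is.na(x)])
    if (!length(x)) NA_character_ else paste(x, collapse = "/")
  }
  rows <- lapply(genes, function(g) {
    sub <- do.call(rbind, lapply(tables, function(t) t[t$gene == g, ]))
    data.frame(
      gene = g,
      nt_size = range_tilde(sub$nt_size),
      aa_size = range_tilde(sub$aa_size),
      start_codon = join_unique(sub$start_codon),
      stop_codon = join_unique(sub$stop_codon),
      anticodon = join_unique(sub$anticodon),
      intergenic_nt = range_tilde(sub$intergenic_nt),
      strand = join_unique(sub$strand),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference_aa)) {
    comp <- vapply(names(reference_aa), function(g) {
      row <- out[out$gene == g, ]
      nrow(row) == 1L && !is.na(row$aa_size) &&
        row$aa_size == as.character(reference_aa[[g]])
    }, logical(1))
    attr(out, "discrepancies") <- names(reference_aa)[!comp]
  }
  out
}

#' Write a gene table as TSV
#'
#' Columns exactly: gene, nt_size, aa_size, start_codon, stop_codon,
#' anticodon, intergenic_nt, strand.
#'
#' @param table output of [gene_table()] or [aggregate_gene_tables()].
#' @param file output path.
#' @export
write_gene_table <- function(table, file) {
  cols <- c("gene", "nt_size", "aa_size", "start_codon", "stop_codon",
            "anticodon", "intergenic_nt", "strand")
  utils::write.table(table[, cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' Gene-order signature and comparison against the canonical vertebrate order
#'
#' Extracts the ordered (gene, strand) signature clockwise on the H-strand,
#' rotated so tRNA-Phe comes first (rotation-invariant comparison on the
#' circle), and compares it against the canonical vertebrate mitochondrial
#' order. When the anchor gene is absent the best rotation (fewest displaced
#' genes) is used with a warning.
#'
#' @param record a `mito_record`.
#' @return list with `signature` (data.frame gene/strand), `verdict`
#'   ("identical" or "rearranged"), `displaced` (genes out of canonical
#'   position) and `breakpoints` (adjacencies absent from the canonical
#'   order, as "a|b" strings).
#' @export
gene_order_signature <- function(record) {
  f <- ordered_features(record)
  if (nrow(f) < 2L) stop("need at least two features", call. = FALSE)
  sig <- data.frame(gene = f$label, strand = f$strand, stringsAsFactors = FALSE)
  canon <- canonical_gene_order()
  rotate <- function(df, k) if (k == 0L) df else df[c((k + 1L):nrow(df), 1:k), ]
  anchor <- which(sig$gene == "tRNA-Phe")
  if (length(anchor) == 1L) {
    sig <- rotate(sig, anchor - 1L)
  } else {
    warning("anchor gene tRNA-Phe absent; using best-rotation comparison",
            call. = FALSE)
    mism <- vapply(seq_len(nrow(sig)), function(k) {
      r <- rotate(sig, k - 1L)
      m <- min(nrow(r), nrow(canon))
      sum(r$gene[seq_len(m)] != canon$gene[seq_len(m)])
    }, integer(1))
    sig <- rotate(sig, which.min(mism) - 1L)
  }
  rownames(sig) <- NULL
  same_len <- nrow(sig) == nrow(canon)
  displaced <- if (same_len) sig$gene[sig$gene != canon$gene] else sig$gene
  adj <- paste(sig$gene, c(sig$gene[-1], sig$gene[1]), sep = "|")
  canon_adj <- paste(canon$gene, c(canon$gene[-1], canon$gene[1]), sep = "|")
  breakpoints <- setdiff(adj, canon_adj)
  verdict <- if (same_len && !length(displaced) &&
                 all(sig$strand == canon$strand)) "identical" else "rearranged"
  list(signature = sig, verdict = verdict, displaced = displaced,
       breakpoints = breakpoints)
}
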