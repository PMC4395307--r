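## GenBank flat-file I/O for annotated circular mitogenomes.
##
## Coordinates are 1-based inclusive in the GenBank dialect; a feature
## wrapping the origin of the circle carries two intervals (start/end and
## start2/end2) coming from a join() location. The strand written in ORIGIN
## is the H-strand; complement() locations are L-strand features.

## synonym table: raw label (upper-cased) -> canonical label
label_synonyms <- function() {
  c("CYTB" = "Cytb", "COB" = "Cytb", "CYB" = "Cytb",
    "COX1" = "COI", "CO1" = "COI", "COXI" = "COI", "COI" = "COI",
    "COX2" = "COII", "CO2" = "COII", "COXII" = "COII", "COII" = "COII",
    "COX3" = "COIII", "CO3" = "COIII", "COXIII" = "COIII", "COIII" = "COIII",
    "ATPASE6" = "ATP6", "ATPASE 6" = "ATP6", "ATP6" = "ATP6",
    "ATPASE8" = "ATP8", "ATPASE 8" = "ATP8", "ATP8" = "ATP8",
    "ND1" = "ND1", "ND2" = "ND2", "ND3" = "ND3", "ND4" = "ND4",
    "ND4L" = "ND4L", "ND5" = "ND5", "ND6" = "ND6",
    "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
    "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6",
    "12S RIBOSOMAL RNA" = "12S rRNA", "12S RRNA" = "12S rRNA",
    "S-RRNA" = "12S rRNA", "RRNS" = "12S rRNA",
    "16S RIBOSOMAL RNA" = "16S rRNA", "16S RRNA" = "16S rRNA",
    "L-RRNA" = "16S rRNA", "RRNL" = "16S rRNA",
    "CONTROL REGION" = "D-loop", "D-LOOP" = "D-loop", "D_LOOP" = "D-loop",
    "ORIGIN OF L-STRAND REPLICATION" = "O_L", "OL" = "O_L", "O_L" = "O_L")
}

#' Normalize a raw feature label to its canonical gene name
#'
#' Applies the package's versioned synonym map (CYTB -> Cytb, COX1 -> COI,
#' "control region" -> D-loop, ...). tRNA labels keep their isoacceptor
#' qualifier, e.g. `tRNA-Ser(UCN)`. Unknown labels pass through unchanged.
#'
#' @param label raw label from /gene, /product or the feature key.
#' @return canonical label string.
#' @export
normalize_gene_label <- function(label) {
  if (is.na(label)) return(NA_character_)
  key <- toupper(trimws(label))
  syn <- label_synonyms()
  if (key %in% names(syn)) return(unname(syn[key]))
  if (grepl("^TRNA-", key)) {
    aa <- sub("^tRNA-", "", label, ignore.case = TRUE)
    return(paste0("tRNA-", aa))
  }
  label
}

parse_location <- function(loc, featname = "feature") {
  strand <- "H"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  if (length(parts) > 2L)
    stop("feature '", featname, "': more than two intervals in location",
         call. = FALSE)
  iv <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)  # partial-end markers are tolerated
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
    if (length(m) != 3L) {
      m1 <- regmatches(p, regexec("^([0-9]+)$", p))[[1]]
      if (length(m1) == 2L) return(c(as.integer(m1[2]), as.integer(m1[2])))
      stop("feature '", featname, "': malformed coordinates '", p, "'",
           call. = FALSE)
    }
    c(as.integer(m[2]), as.integer(m[3]))
  })
  list(start = iv[[1]][1], end = iv[[1]][2],
       start2 = if (length(iv) == 2L) iv[[2]][1] else NA_integer_,
       end2 = if (length(iv) == 2L) iv[[2]][2] else NA_integer_,
       strand = strand)
}

feature_category <- function(key) {
  switch(key,
         "CDS" = "CDS", "tRNA" = "tRNA", "rRNA" = "rRNA",
         "D-loop" = "noncoding", "rep_origin" = "noncoding",
         "misc_feature" = "noncoding", "noncoding")
}

#' Parse a GenBank flat file into a mitogenome record
#'
#' Reads LOCUS, the feature table (CDS, tRNA, rRNA, D-loop, rep_origin;
#' standalone `gene` features that duplicate a typed feature are dropped) and
#' the ORIGIN sequence. Labels are normalized through the synonym map and
#' join() locations become two-interval spans for origin-wrapping features.
#'
#' @param x path to a GenBank file, or the file content as a character vector
#'   of lines (or a single string with embedded newlines).
#' @return an object of class `mito_record`: list with `id`, `length`,
#'   `is_circular`, `sequence` and a `features` data.frame (columns `label`,
#'   `category`, `start`, `end`, `start2`, `end2`, `strand`, `anticodon`).
#' @export
#' @examples
#' sim <- simulate_mitogenome(sim_config(seed = 1))
#' rec <- parse_genbank(sim$genbank)
#' rec$length
parse_genbank <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  if (length(x) == 1L) x <- strsplit(x, "\n", fixed = TRUE)[[1]]

  locus <- grep("^LOCUS", x, value = TRUE)
  if (!length(locus)) stop("no LOCUS line found", call. = FALSE)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L]))
  if (!length(len) || is.na(len)) stop("LOCUS line lacks a bp length",
                                       call. = FALSE)
  circular <- any(grepl("circular", locus[1]))

  acc <- grep("^ACCESSION", x, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1]), "\\s+")[[1]]
    if (length(a) >= 2L) id <- a[2]
  }

  fstart <- grep("^FEATURES", x)
  ostart <- grep("^ORIGIN", x)
  if (!length(fstart) || !length(ostart))
    stop("missing FEATURES or ORIGIN section", call. = FALSE)

  ## --- feature table ---
  flines <- x[(fstart[1] + 1L):(ostart[1] - 1L)]
  feats <- list()
  cur <- NULL
  for (ln in flines) {
    if (grepl("^ {5}\\S", ln)) {              # new feature: key at column 6
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- trimws(substr(ln, 1, 20))
      loc <- trimws(substr(ln, 21, nchar(ln)))
      cur <- list(key = key, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      q <- trimws(ln)
      if (startsWith(q, "/")) cur$quals <- c(cur$quals, q)
      else if (length(cur$quals)) {           # qualifier continuation
        cur$quals[length(cur$quals)] <- paste0(cur$quals[length(cur$quals)], q)
      } else cur$loc <- paste0(cur$loc, q)    # location continuation
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur

  qual_value <- function(quals, name) {
    hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
  }

  keep <- c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin", "misc_feature")
  rows <- list()
  for (f in feats) {
    if (!(f$key %in% keep)) next
    gene <- qual_value(f$quals, "gene")
    prod <- qual_value(f$quals, "product")
    note <- qual_value(f$quals, "note")
    label <- if (!is.na(gene)) gene else if (!is.na(prod)) prod
             else if (f$key == "D-loop") "D-loop"
             else if (f$key == "rep_origin") "O_L"
             else if (!is.na(note)) note else f$key
    label <- normalize_gene_label(label)
    lc <- parse_location(f$loc, label)
    rows[[length(rows) + 1L]] <- data.frame(
      label = label, category = feature_category(f$key),
      start = lc$start, end = lc$end, start2 = lc$start2, end2 = lc$end2,
      strand = if (f$key %in% c("D-loop", "rep_origin")) lc$strand else lc$strand,
      anticodon = qual_value(f$quals, "anticodon"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable features found", call. = FALSE)
  features <- do.call(rbind, rows)

  bad <- features$start < 1 | features$end > len |
    (!is.na(features$start2) & (features$start2 < 1 | features$end2 > len))
  if (any(bad))
    stop("feature '", features$label[which(bad)[1]],
         "': coordinates outside [1, ", len, "]", call. = FALSE)

  ## --- sequence ---
  olines <- x[(ostart[1] + 1L):length(x)]
  olines <- olines[!grepl("^//", olines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(olines, collapse = "")))
  if (nchar(seq) != len)
    stop("sequence length (", nchar(seq), ") does not match LOCUS length (",
         len, ")", call. = FALSE)

  structure(list(id = id, length = len, is_circular = circular,
                 sequence = seq, features = features),
            class = "mito_record")
}

#' @export
print.mito_record <- function(x, ...) {
  cat("mito_record", x$id, "-", x$length, "bp",
      if (x$is_circular) "circular" else "linear", "\n")
  cat(nrow(x$features), "features:",
      paste(utils::head(x$features$label, 6), collapse = ", "),
      if (nrow(x$features) > 6) "...", "\n")
  invisible(x)
}

#' Nucleotide size of a feature (sum of its one or two intervals)
#' @param feature one row of a `mito_record` features data.frame.
#' @return integer size in bp.
#' @export
feature_nt_size <- function(feature) {
  n <- feature$end - feature$start + 1L
  if (!is.na(feature$start2)) n <- n + feature$end2 - feature$start2 + 1L
  as.integer(n)
}

#' Extract the (strand-corrected) sequence of a feature
#'
#' Concatenates the feature's interval(s) on the H-strand and
#' reverse-complements L-strand features so codon analysis always sees the
#' sense strand.
#'
#' @param record a `mito_record`.
#' @param i feature row index.
#' @return character string.
#' @export
feature_seq <- function(record, i) {
  f <- record$features[i, ]
  s <- substr(record$sequence, f$start, f$end)
  if (!is.na(f$start2))
    s <- paste0(s, substr(record$sequence, f$start2, f$end2))
  if (identical(f$strand, "L")) s <- revcomp(s)
  s
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Inverse of [parse_genbank()] up to label normalization: emits LOCUS,
#' a feature table (CDS/tRNA/rRNA/D-loop/rep_origin) and the ORIGIN block.
#'
#' @param record a `mito_record`.
#' @param file optional path; when missing the text is returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_genbank <- function(record, file = NULL) {
  f <- record$features
  loc_of <- function(r) {
    core <- if (!is.na(r$start2))
      sprintf("join(%d..%d,%d..%d)", r$start, r$end, r$start2, r$end2)
    else sprintf("%d..%d", r$start, r$end)
    if (identical(r$strand, "L")) sprintf("complement(%s)", core) else core
  }
  key_of <- function(r) {
    if (r$label == "D-loop") "D-loop"
    else if (r$label == "O_L") "rep_origin"
    else if (r$category %in% c("CDS", "tRNA", "rRNA")) r$category
    else "misc_feature"
  }
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     circular VRT 01-JAN-2026",
                   record$id, record$length),
           "DEFINITION  synthetic anemonefish-style mitochondrial genome.",
           sprintf("ACCESSION   %s", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     %-16s1..%d", "source", record$length),
           "                     /organism=\"synthetic construct\"")
  for (i in seq_len(nrow(f))) {
    r <- f[i, ]
    key <- key_of(r)
    out <- c(out, sprintf("     %-16s%s", key, loc_of(r)))
    if (key == "CDS")
      out <- c(out, sprintf("                     /gene=\"%s\"", r$label))
    else if (key %in% c("tRNA", "rRNA"))
      out <- c(out, sprintf("                     /product=\"%s\"", r$label))
    else if (key == "rep_origin")
      out <- c(out, "                     /note=\"origin of L-strand replication\"")
    else if (key == "D-loop")
      out <- c(out, "                     /note=\"control region\"")
    if (!is.na(r$anticodon))
      out <- c(out, sprintf("                     /anticodon=\"%s\"", r$anticodon))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
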