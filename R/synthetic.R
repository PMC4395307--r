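## Seeded synthetic mitogenomes, D-loops, alignments and trees with
## ground-truth bookkeeping for every planted element. One global R RNG
## stream, seeded once per generator call from cfg$seed, makes identical
## configs byte-reproducible.

#' Simulation configuration
#'
#' Defaults encode the study conditions of the eight-anemonefish genome set:
#' gene lengths and signed spacers from the canonical layout table
#' ([mito_gene_layout()]), H-strand base frequencies at the published means
#' (A .293, T .257, G .158, C .292), and a D-loop carrying a TAS/cTAS
#' hairpin, all nine conserved blocks and an optional tandem-repeat array
#' placed downstream of the CSBs.
#'
#' @param seed integer seed.
#' @param n_genomes number of genomes for multi-genome simulation.
#' @param base_freqs named frequencies (A, C, G, T), must sum to 1.
#' @param dloop a [dloop_spec()].
#' @param divergence per-site substitution probability used when deriving
#'   multi-genome alignments from a common ancestor.
#' @param layout gene layout table (defaults to [mito_gene_layout()]).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genomes = 1L,
                       base_freqs = c(A = 0.293, T = 0.257, G = 0.158, C = 0.292),
                       dloop = dloop_spec(), divergence = 0.05,
                       layout = mito_gene_layout()) {
  if (abs(sum(base_freqs) - 1) > 1e-6)
    stop("base_freqs must sum to 1", call. = FALSE)
  if (divergence < 0 || divergence >= 0.75)
    stop("divergence must be in [0, 0.75)", call. = FALSE)
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 base_freqs = base_freqs[c("A", "C", "G", "T")],
                 dloop = dloop, divergence = divergence, layout = layout),
            class = "sim_config")
}

#' D-loop simulation spec
#'
#' @param tas plant a TAS/cTAS hairpin ("TACATATATGTA" or the TAG variant)?
#' @param tas_variant "TACAT", "TAGCAT" or "random".
#' @param csb character vector of motif names from [csb_motifs()] to plant
#'   (default all nine).
#' @param repeat_spec NULL for no array, or list(period =, copies =,
#'   placement = "downstream"/"upstream"); copies in steps of 0.5, >= 0.
#' @return list of class `dloop_spec`.
#' @export
dloop_spec <- function(tas = TRUE, tas_variant = "random",
                       csb = csb_motifs()$name,
                       repeat_spec = list(period = 30L, copies = 5.5,
                                          placement = "downstream")) {
  if (!is.null(repeat_spec)) {
    if (repeat_spec$copies < 0 ||
        abs(repeat_spec$copies * 2 - round(repeat_spec$copies * 2)) > 1e-9)
      stop("repeat copies must be >= 0 in steps of 0.5", call. = FALSE)
    if (repeat_spec$copies == 0) repeat_spec <- NULL
  }
  bad <- setdiff(csb, csb_motifs()$name)
  if (length(bad)) stop("unknown motif(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(tas = isTRUE(tas), tas_variant = tas_variant, csb = csb,
                 repeat_spec = repeat_spec), class = "dloop_spec")
}

## realize a consensus pattern: each dash run gets a gap length drawn
## uniformly from 0..k+slack. Gap fills avoid the first character of the
## following literal segment so that the realized instance has a unique
## minimal-mismatch placement (otherwise a fill base matching the next
## segment boundary lets the scanner report an equivalent, shifted span).
realize_motif <- function(pattern, freqs, gap_slack = 2L) {
  pm <- parse_motif_pattern(pattern, gap_slack)
  gaps <- if (length(pm$gap_max)) vapply(pm$gap_max, function(k)
    sample.int(k + 1L, 1L) - 1L, integer(1)) else integer(0)
  parts <- character(0)
  for (i in seq_along(pm$segments)) {
    parts <- c(parts, pm$segments[i])
    if (i <= length(gaps) && gaps[i] > 0L) {
      avoid <- substr(pm$segments[i + 1L], 1, 1)
      f <- freqs[setdiff(names(freqs), avoid)]
      parts <- c(parts, random_seq(gaps[i], f / sum(f)))
    }
  }
  ## chars that must not appear immediately before the instance: a match of
  ## the first segment's leading base there would allow a left-shifted
  ## equal-score placement absorbing the shift into the first gap
  headroom <- if (length(pm$gap_max)) pm$gap_max[1] - gaps[1] else 0L
  list(instance = paste(parts, collapse = ""), gaps = gaps,
       guard_len = headroom,
       guard_avoid = substr(pm$segments[1], 1, 1))
}

## internal D-loop builder; assumes the RNG is already seeded.
## AT-rich background mirrors the elevated A+T of real control regions.
build_dloop <- function(spec, freqs = c(A = 0.36, C = 0.20, G = 0.13, T = 0.31),
                        max_tries = 25L) {
  lib <- csb_motifs()
  for (attempt in seq_len(max_tries)) {
    parts <- character(0)
    truth <- list()
    pos <- 1L
    emit <- function(s) { parts <<- c(parts, s); pos <<- pos + nchar(s) }
    record <- function(name, start, len, extra = list())
      truth[[length(truth) + 1L]] <<- c(list(name = name, start = start,
                                             end = start + len - 1L), extra)
    emit(random_seq(sample(15:35, 1), freqs))
    if (spec$tas) {
      variant <- switch(spec$tas_variant,
                        "random" = sample(c("TACAT", "TAGCAT"), 1),
                        spec$tas_variant)
      literal <- paste0(variant, "ATATGTA")   # core + loop + cTAS
      record("TAS", pos, nchar(literal), list(variant = variant))
      emit(literal)
    }
    emit(random_seq(sample(25:45, 1), freqs))
    for (nm in intersect(lib$name, spec$csb)) {
      rm_ <- realize_motif(lib$pattern[lib$name == nm], freqs)
      if (rm_$guard_len > 0L) {   # block left-shifted equivalent placements
        f <- freqs[setdiff(names(freqs), rm_$guard_avoid)]
        emit(random_seq(rm_$guard_len, f / sum(f)))
      }
      record(nm, pos, nchar(rm_$instance),
             list(gaps = paste(rm_$gaps, collapse = ",")))
      emit(rm_$instance)
      emit(random_seq(sample(12:30, 1), freqs))
    }
    if (!is.null(spec$repeat_spec)) {
      rs <- spec$repeat_spec
      unit <- random_seq(rs$period, freqs)
      span <- as.integer(round(rs$period * rs$copies))
      array <- substr(strrep(unit, ceiling(rs$copies)), 1L, span)
      if (identical(rs$placement, "upstream")) {
        ## prepend before everything already laid out
        shift <- span + 20L
        lead <- paste0(array, random_seq(20L, freqs))
        for (i in seq_along(truth)) {
          truth[[i]]$start <- truth[[i]]$start + shift
          truth[[i]]$end <- truth[[i]]$end + shift
        }
        truth[[length(truth) + 1L]] <- list(
          name = "tandem_repeat", start = 1L, end = span,
          period = rs$period, copies = rs$copies, placement = "upstream")
        parts <- c(lead, parts)
        pos <- pos + shift
      } else {
        record("tandem_repeat", pos, span,
               list(period = rs$period, copies = rs$copies,
                    placement = "downstream"))
        emit(array)
      }
    }
    emit(random_seq(sample(20:45, 1), freqs))
    seq <- paste(parts, collapse = "")

    ## self-check: every planted element must be recoverable at its
    ## recorded coordinates by the annotator; otherwise redraw
    ok <- TRUE
    truth_df <- do.call(rbind, lapply(truth, function(t)
      data.frame(name = t$name, start = t$start, end = t$end,
                 stringsAsFactors = FALSE)))
    if (spec$tas) {
      tas <- detect_tas(seq)
      trow <- truth_df[truth_df$name == "TAS", ]
      if (!isTRUE(tas$found) || tas$tas_start != trow$start ||
          !tas$hairpin_pairable) ok <- FALSE
    }
    if (ok) {
      hits <- scan_all_motifs(seq)
      for (nm in intersect(lib$name, spec$csb)) {
        trow <- truth_df[truth_df$name == nm, ]
        h <- hits[hits$name == nm, ]
        if (!nrow(h) || !any(h$start == trow$start & h$end == trow$end)) {
          ok <- FALSE; break
        }
      }
    }
    if (ok && !is.null(spec$repeat_spec) && spec$repeat_spec$copies >= 2) {
      reps <- find_tandem_repeats(seq, min_period =
                                    min(10L, spec$repeat_spec$period))
      trow <- truth_df[truth_df$name == "tandem_repeat", ]
      match_ <- nrow(reps) && any(reps$period == spec$repeat_spec$period &
                                    abs(reps$copy_number -
                                          spec$repeat_spec$copies) <= 0.5)
      if (!match_) ok <- FALSE
    }
    if (ok)
      return(list(sequence = seq, truth = truth, truth_df = truth_df,
                  attempts = attempt))
  }
  stop("failed to build a self-consistent D-loop within ", max_tries,
       " attempts; the requested element set may be infeasible",
       call. = FALSE)
}

#' Simulate a D-loop with ground truth
#'
#' Generates a control-region sequence planting, in schematic order, a
#' TAS/cTAS hairpin, the requested conserved blocks (each consensus
#' realized with recorded spacer-gap choices) and an optional tandem-repeat
#' array, separated by random AT-rich filler. The generator re-draws filler
#' and gap choices until every planted element is recovered at its recorded
#' coordinates by the package's own annotator (self-consistency enforced at
#' generation).
#'
#' @param cfg a [sim_config()] (its `dloop` spec and `seed` are used), or a
#'   [dloop_spec()] together with `seed`.
#' @param seed used when `cfg` is a `dloop_spec`.
#' @return list with `sequence`, `truth` (list of planted elements),
#'   `truth_df` (name/start/end data.frame), `fasta` (two-line FASTA text).
#' @export
#' @examples
#' sim <- simulate_dloop(sim_config(seed = 7))
#' sim$truth_df
simulate_dloop <- function(cfg, seed = NULL) {
  if (inherits(cfg, "dloop_spec")) {
    spec <- cfg
    if (is.null(seed)) stop("seed required with a bare dloop_spec", call. = FALSE)
    set.seed(as.integer(seed))
  } else {
    spec <- cfg$dloop
    set.seed(cfg$seed)
  }
  out <- build_dloop(spec)
  out$fasta <- c(paste0(">dloop_sim seed-planted control region"),
                 out$sequence)
  out
}

## sample within an integer range
pick <- function(lo, hi) if (lo == hi) as.integer(lo) else
  sample(seq.int(lo, hi), 1L)

#' Simulate an annotated circular mitogenome with ground truth
#'
#' Lays out all 37 canonical genes plus the light-strand replication origin
#' and a D-loop in canonical vertebrate order with the published strand
#' assignments, lengths drawn within the published ranges and the published
#' signed intergenic spacers (negative spacers create real overlaps), draws
#' the background sequence at the configured base frequencies, plants
#' consistent start codons and stop classes (complete TAA/TAG/AGA and
#' incomplete T-/TA- with the matching length mod 3), and embeds a
#' simulated D-loop. Deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return for `n_genomes == 1`: list with `record` (`mito_record`),
#'   `genbank` (flat-file lines), `fasta`, `ground_truth` (per-feature
#'   data.frame), `dloop_truth`; for several genomes, a list of such lists.
#' @export
#' @examples
#' sim <- simulate_mitogenome(sim_config(seed = 1))
#' sim$record
simulate_mitogenome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sims <- lapply(seq_len(cfg$n_genomes), function(i)
    simulate_one_genome(cfg, sprintf("SIM%05d", i)))
  if (cfg$n_genomes == 1L) sims[[1]] else sims
}

simulate_one_genome <- function(cfg, id) {
  lay <- cfg$layout
  n <- nrow(lay)
  dl <- build_dloop(cfg$dloop)
  lens <- integer(n)
  spacers <- integer(n)
  starts_codon <- rep(NA_character_, n)
  stop_cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    lens[i] <- if (lay$gene[i] == "D-loop") nchar(dl$sequence)
               else pick(lay$len_min[i], lay$len_max[i])
    spacers[i] <- pick(lay$spacer_prev_min[i], lay$spacer_prev_max[i])
    if (lay$category[i] == "CDS") {
      starts_codon[i] <- sample(strsplit(lay$start_codons[i], "/")[[1]], 1L)
      stop_cls[i] <- sample(strsplit(lay$stop_classes[i], "/")[[1]], 1L)
    }
  }
  ## ND5 length must stay consistent with a complete stop (mod 3 == 0)
  i5 <- which(lay$gene == "ND5")
  if (length(i5)) lens[i5] <- sample(c(1866L, 1869L), 1L)

  start <- integer(n); end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    if (i > 1L) pos <- end[i - 1L] + spacers[i] + 1L
    start[i] <- pos
    end[i] <- pos + lens[i] - 1L
  }
  L <- end[n]

  seqv <- strsplit(random_seq(L, cfg$base_freqs), "")[[1]]
  constrained <- logical(L)
  put <- function(at, bases) {
    b <- strsplit(bases, "")[[1]]
    idx <- at + seq_along(b) - 1L
    clash <- constrained[idx] & seqv[idx] != b
    if (any(clash))
      stop("layout infeasible: conflicting codon constraints at position ",
           idx[which(clash)[1]], call. = FALSE)
    seqv[idx] <<- b
    constrained[idx] <<- TRUE
    invisible(NULL)
  }
  for (i in seq_len(n)) {
    if (lay$category[i] == "CDS") {
      stop_seq <- switch(stop_cls[i], "T-" = "T", "TA-" = "TA", stop_cls[i])
      if (lay$strand[i] == "H") {
        put(start[i], starts_codon[i])
        put(end[i] - nchar(stop_seq) + 1L, stop_seq)
      } else {
        ## L-strand: sense 5' end is the H-interval end
        put(end[i] - 2L, revcomp(starts_codon[i]))
        put(start[i], revcomp(stop_seq))
      }
    } else if (lay$gene[i] == "D-loop") {
      put(start[i], dl$sequence)
    }
  }
  sequence <- paste(seqv, collapse = "")

  features <- data.frame(
    label = lay$gene, category = lay$category,
    start = start, end = end,
    start2 = NA_integer_, end2 = NA_integer_,
    strand = lay$strand, anticodon = lay$anticodon,
    stringsAsFactors = FALSE)
  record <- structure(list(id = id, length = L, is_circular = TRUE,
                           sequence = sequence, features = features),
                      class = "mito_record")

  aa <- mapply(function(nt, cls) if (is.na(cls)) NA_integer_
               else protein_length(nt, cls), lens, stop_cls)
  ground_truth <- data.frame(
    gene = lay$gene, category = lay$category, start = start, end = end,
    strand = lay$strand, nt_size = lens, aa_size = as.integer(aa),
    start_codon = starts_codon, stop_codon = stop_cls,
    anticodon = lay$anticodon, intergenic_nt = spacers,
    stringsAsFactors = FALSE)

  dloop_truth <- dl$truth_df
  dloop_truth$genome_start <- dloop_truth$start + start[lay$gene == "D-loop"] - 1L

  list(record = record,
       genbank = write_genbank(record),
       fasta = c(paste0(">", id, " synthetic mitogenome"), sequence),
       ground_truth = ground_truth,
       dloop_truth = dloop_truth)
}

#' Evolve an alignment along a tree by per-branch substitution
#'
#' Applies independent per-site substitutions along every branch path from
#' the root (which carries the ancestor sequence) to each leaf: on each
#' branch a site mutates with probability `rate` and is replaced by one of
#' the three other bases uniformly. No indels, so the output is aligned.
#'
#' @param ancestor nucleotide string at the root.
#' @param tree a `tree_form` whose leaves name the output sequences, or an
#'   integer n for a star tree over n leaves ("t1".."tn").
#' @param rate per-site per-branch substitution probability in [0, 0.75).
#' @param seed integer seed.
#' @return named character vector of aligned sequences (leaf order).
#' @export
#' @examples
#' mutate_sequences(strrep("ACGT", 25), 3, rate = 0.1, seed = 1)
mutate_sequences <- function(ancestor, tree, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.75)
    stop("rate must be in [0, 0.75)", call. = FALSE)
  stopifnot_scalar_seq(ancestor, "ancestor")
  if (is.numeric(tree))
    tree <- tf_node(lapply(paste0("t", seq_len(tree)), tf_leaf))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  mutate_once <- function(v) {
    hit <- which(stats::runif(length(v)) < rate)
    if (length(hit)) {
      cur <- v[hit]
      v[hit] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    }
    v
  }
  out <- list()
  walk <- function(node, v) {
    if (is_tf_leaf(node)) { out[[node$label]] <<- paste(v, collapse = ""); return(invisible(NULL)) }
    for (ch in node$children) walk(ch, mutate_once(v))
    invisible(NULL)
  }
  walk(tree, strsplit(toupper(ancestor), "")[[1]])
  unlist(out)
}

#' Sample a random 10-taxon tree of a given topology type
#'
#' Draws a tree over taxa 1..10 whose [classify_tree_form()] verdict equals
#' the requested type, by construction plus a self-consistency check at
#' generation: the 1-5 subtree is randomly resolved, the Premnas/percula
#' arrangement follows the type definition (type IV picks one of its two
#' admissible shapes at random; NM nests taxon 9 inside the ingroup).
#'
#' @param type one of "I", "II", "III", "IV", "NM".
#' @param seed integer seed.
#' @return a `tree_form`.
#' @export
#' @examples
#' classify_tree_form(sample_tree_of_type("III", seed = 5))$type  # "III"
sample_tree_of_type <- function(type = c("I", "II", "III", "IV", "NM"),
                                seed = 1L) {
  type <- match.arg(type)
  set.seed(as.integer(seed))
  rand_subtree <- function(labels) {
    if (length(labels) == 1L) return(tf_leaf(labels))
    if (length(labels) == 2L)
      return(tf_node(lapply(sample(labels), tf_leaf)))
    k <- sample(2:min(3L, length(labels)), 1L)
    groups <- split(sample(labels), rep_len(seq_len(k), length(labels)))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups) == 1L) return(rand_subtree(groups[[1]]))
    tf_node(lapply(groups, rand_subtree))
  }
  t15 <- rand_subtree(as.character(1:5))
  t67 <- tf_node(list(tf_leaf("6"), tf_leaf("7")))
  a <- switch(type,
    "I" = tf_node(list(t15, tf_node(list(t67, tf_leaf("8"))))),
    "II" = tf_node(list(tf_leaf("8"), t15, t67)),
    "III" = if (sample(c(TRUE, FALSE), 1))
      tf_node(list(t15, tf_leaf("8"), t67))
    else tf_node(list(t67, t15, tf_leaf("8"))),
    "IV" = if (sample(c(TRUE, FALSE), 1))
      tf_node(list(tf_node(list(t15, tf_leaf("8"))), t67))
    else tf_node(list(tf_node(list(t15, t67)), tf_leaf("8"))),
    "NM" = tf_node(list(t15, tf_node(list(tf_node(list(t67, tf_leaf("8"))),
                                          tf_leaf("9"))))))
  tree <- if (type == "NM")
    tf_node(list(a, tf_leaf("10")))
  else tf_node(list(tf_node(list(a, tf_leaf("9"))), tf_leaf("10")))
  class(tree) <- c("tree_form", class(tree))
  got <- classify_tree_form(tree)$type
  if (!identical(got, type))
    stop("internal error: sampled tree classified as ", got, call. = FALSE)
  tree
}
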