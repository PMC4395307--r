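## Nucleotide-composition summaries, the anti-G-bias ANOVA and pairwise
## sequence identities.

#' Base composition of a nucleotide sequence
#'
#' Counts A/C/G/T over the sequence; ambiguity codes and gaps are excluded
#' from the denominator and reported separately. Percentages are kept at
#' full precision in `pct` and rounded half-up to 2 decimals in `pct2`.
#'
#' @param seq nucleotide string.
#' @return list with `counts` (named A/C/G/T), `pct`, `pct2`, `at_content`
#'   (A% + T%, full precision), `n_effective`, `n_excluded`.
#' @export
#' @examples
#' base_composition("ACGT")$pct2  # all 25.00
base_composition <- function(seq) {
  stopifnot_scalar_seq(seq)
  af <- Biostrings::alphabetFrequency(Biostrings::DNAString(gsub("[^A-Za-z-]", "", toupper(seq))))
  counts <- af[c("A", "C", "G", "T")]
  n_eff <- sum(counts)
  if (n_eff == 0L) stop("sequence contains no unambiguous A/C/G/T bases",
                        call. = FALSE)
  pct <- 100 * counts / n_eff
  list(counts = counts,
       pct = pct,
       pct2 = round_half_up(pct, 2),
       at_content = unname(pct["A"] + pct["T"]),
       n_effective = n_eff,
       n_excluded = sum(af) - n_eff)
}

#' Cross-genome Mean+/-SD composition summary
#'
#' Arithmetic mean and sample SD (n-1 denominator) per column of a
#' per-genome composition table, rounded half-up to the printed precision of
#' comparative mitogenome tables: integer bp for sizes, 2 decimals for
#' percentages. An `AT` column is derived as A + T per genome when absent,
#' so the A+T summary is the mean/SD of per-genome sums.
#'
#' @param df data.frame with a size column (`size_bp`) and percentage columns
#'   `A`, `T`, `G`, `C` (optionally `AT`); or a list of [base_composition()]
#'   results plus `sizes`.
#' @param sizes optional vector of genome sizes when `df` is a list of
#'   composition vectors.
#' @return data.frame with rows `mean`, `sd` (full precision) and character
#'   rows `mean_printed`, `sd_printed` at table precision, as attributes on
#'   a list: `summary` (numeric), `printed` (character).
#' @export
#' @examples
#' s <- summarize_compositions(anemonefish_composition())
#' s$printed["size_bp"]  # "16748" mean, "143" sd
summarize_compositions <- function(df, sizes = NULL) {
  if (!is.data.frame(df)) {
    vecs <- df
    if (is.null(sizes) || length(sizes) != length(vecs))
      stop("lengths of composition vectors and sizes differ", call. = FALSE)
    df <- do.call(rbind, lapply(vecs, function(v) as.data.frame(as.list(v$pct2))))
    df$size_bp <- sizes
  }
  if (nrow(df) < 2L) stop("need at least two genomes", call. = FALSE)
  if (!("AT" %in% names(df)) && all(c("A", "T") %in% names(df)))
    df$AT <- df$A + df$T
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  mean_v <- vapply(df[num], mean, numeric(1))
  sd_v <- vapply(df[num], stats::sd, numeric(1))   # n-1 denominator
  digits <- ifelse(num == "size_bp", 0L, 2L)
  fmt <- function(x) {
    vapply(seq_along(x), function(i) {
      v <- round_half_up(x[i], digits[i])
      if (digits[i] == 0L) format(v, big.mark = "", scientific = FALSE)
      else sprintf("%.2f", v)
    }, character(1))
  }
  printed <- rbind(mean = fmt(mean_v), sd = fmt(sd_v))
  colnames(printed) <- num
  list(n = nrow(df),
       mean = mean_v, sd = sd_v,
       printed = stats::setNames(
         paste0(printed["mean", ], "±", printed["sd", ]), num),
       mean_printed = printed["mean", ], sd_printed = printed["sd", ])
}

#' One-way ANOVA for compositional bias across bases
#'
#' Tests whether the four base percentages differ across a genome set:
#' groups are the bases (A, T, G, C), observations the genomes. The verdict
#' is "anti-G" when the group means differ significantly (p below `alpha`)
#' and G has the lowest mean. Grouping by base is the default because it is
#' the comparison that supports a base-bias verdict; `grouping = "genome"`
#' is exposed as the alternative reading (observations = bases per genome).
#'
#' @param df data.frame with numeric columns `A`, `T`, `G`, `C` (one row per
#'   genome).
#' @param alpha significance level (default 0.05).
#' @param grouping "base" (default) or "genome".
#' @return list with `F`, `df_between`, `df_within`, `p_value`,
#'   `lowest_group`, `verdict` ("anti-G" or "none").
#' @export
#' @examples
#' composition_anova(anemonefish_composition())$verdict  # "anti-G"
composition_anova <- function(df, alpha = 0.05, grouping = c("base", "genome")) {
  grouping <- match.arg(grouping)
  bases <- c("A", "T", "G", "C")
  if (!all(bases %in% names(df)))
    stop("df must contain columns A, T, G, C", call. = FALSE)
  if (nrow(df) < 2L)
    stop("need at least two observations per group", call. = FALSE)
  long <- data.frame(
    value = unlist(df[bases], use.names = FALSE),
    base = factor(rep(bases, each = nrow(df)), levels = bases),
    genome = factor(rep(seq_len(nrow(df)), times = length(bases))))
  group_var <- if (grouping == "base") "base" else "genome"
  fit <- stats::aov(stats::reformulate(group_var, "value"), data = long)
  tab <- anova(fit)
  means <- tapply(long$value, long[[group_var]], mean)
  lowest <- names(means)[which.min(means)]
  p <- tab[["Pr(>F)"]][1]
  list(F = unname(tab[["F value"]][1]),
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
       p_value = p, lowest_group = lowest,
       verdict = if (!is.na(p) && p < alpha && identical(lowest, "G"))
         "anti-G" else "none")
}

#' Pairwise identity matrix over an alignment
#'
#' Identity for a pair = matching columns / columns where neither sequence
#' has a gap ('-'), times 100 (pairwise, not listwise, gap deletion). The
#' summary mean+/-SD is over the off-diagonal pairs.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return list with `matrix` (percent, diagonal 100), `mean`, `sd`.
#' @export
#' @examples
#' pairwise_identity(c(a = "ACGT", b = "ACGA"))$matrix["a", "b"]  # 75
pairwise_identity <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  mat <- do.call(rbind, lapply(seqs, function(s) seq_ints(s)))
  gap <- utf8ToInt("-")
  id <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != gap & mat[j, ] != gap
    if (!any(ok)) stop("no comparable columns for pair ", i, ",", j,
                       call. = FALSE)
    v <- 100 * sum(mat[i, ok] == mat[j, ok]) / sum(ok)
    id[i, j] <- id[j, i] <- v
  }
  off <- id[upper.tri(id)]
  list(matrix = id, mean = mean(off), sd = stats::sd(off))
}
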