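## Rooted multifurcating tree structures ("tree forms"), clade algebra and
## topology-type classification.
##
## A tree_form node is either a leaf (list with $label) or an internal node
## (list with $children); written child order is preserved from the input
## because the type II vs III distinction is presentation-level (where the
## Premnas singleton is written within the anemonefish polytomy).

tf_leaf <- function(label) structure(list(label = label), class = "tree_form_node")
tf_node <- function(children) structure(list(children = children),
                                        class = "tree_form_node")
is_tf_leaf <- function(x) !is.null(x$label)

#' Parse a bracketed tree-form string or Newick into a tree
#'
#' Two dialects are accepted. Strings ending in ';' or containing ':' are
#' parsed as Newick via ape (branch lengths and internal node labels are
#' ignored for typing). Anything else is parsed as a tree-form string:
#' '(', '\[' and '\{' are interchangeable openers (decoration for nesting
#' depth), commas between siblings are optional (adjacent bracket groups are
#' siblings), a label written after a closing bracket is a sibling in the
#' enclosing group, numeric ranges like `1~5` expand to sibling leaves, and
#' singleton groups collapse to their only child.
#'
#' @param s tree string.
#' @return object of class `tree_form`.
#' @export
#' @examples
#' parse_tree_string("(({[(((1,2)3)4)5][(6,7)8]}9)10)")
#' parse_tree_string("((A:0.1,B:0.2):0.05,C:0.3);")
parse_tree_string <- function(s) {
  stopifnot_scalar_seq(s, "tree string")
  s <- gsub("\\s", "", s)
  if (grepl(";$", s) || grepl(":", s)) {
    if (!grepl(";$", s)) s <- paste0(s, ";")
    phy <- ape::read.tree(text = s)
    if (is.null(phy)) stop("Newick parse failed", call. = FALSE)
    return(phylo_to_treeform(phy))
  }
  s <- chartr("[]{}", "()()", s)
  ## bracket balance check with position reporting
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced brackets at position ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("unbalanced brackets: ", depth, " unclosed opener(s)", call. = FALSE)

  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() pos <<- pos + 1L

  read_items <- function() {   # returns a list of nodes (a label may expand)
    ch <- peek()
    if (ch == "(") {
      advance()
      children <- list()
      repeat {
        while (peek() == ",") advance()
        if (peek() == ")") { advance(); break }
        if (peek() == "") stop("unexpected end of string", call. = FALSE)
        children <- c(children, read_items())
      }
      if (!length(children)) stop("empty group at position ", pos, call. = FALSE)
      node <- if (length(children) == 1L) children[[1]] else tf_node(children)
      list(node)
    } else {
      lab <- ""
      while (!(peek() %in% c("(", ")", ",", ""))) { lab <- paste0(lab, peek()); advance() }
      if (!nzchar(lab)) stop("expected a label at position ", pos, call. = FALSE)
      m <- regexec("^([0-9]+)~([0-9]+)$", lab)[[1]]
      if (m[1] != -1) {
        g <- regmatches(lab, list(regexec("^([0-9]+)~([0-9]+)$", lab)[[1]]))[[1]]
        lapply(as.character(seq(as.integer(g[2]), as.integer(g[3]))), tf_leaf)
      } else list(tf_leaf(lab))
    }
  }
  items <- read_items()
  if (pos <= length(chars))
    stop("trailing characters after position ", pos - 1L, call. = FALSE)
  root <- if (length(items) == 1L) items[[1]] else tf_node(items)
  if (is_tf_leaf(root)) root <- tf_node(list(root))
  lv <- tree_leaves(root)
  if (anyDuplicated(lv))
    stop("duplicate leaf label: ", lv[duplicated(lv)][1], call. = FALSE)
  class(root) <- c("tree_form", class(root))
  root
}

## ape phylo -> tree_form (child order as stored in the edge matrix)
phylo_to_treeform <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(id) {
    if (id <= ntip) return(tf_leaf(phy$tip.label[id]))
    tf_node(lapply(kids[[as.character(id)]], build))
  }
  root <- build(ntip + 1L)
  class(root) <- c("tree_form", class(root))
  root
}

#' Leaf labels of a tree (left-to-right written order)
#' @param tree a `tree_form` (or node).
#' @return character vector.
#' @export
tree_leaves <- function(tree) {
  if (is_tf_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Serialize a tree to a parenthesised string / Newick
#' @param tree a `tree_form`.
#' @param newick append ';' (and quote nothing) for Newick consumers.
#' @return character string.
#' @export
treeform_to_string <- function(tree, newick = FALSE) {
  ser <- function(node) {
    if (is_tf_leaf(node)) return(node$label)
    paste0("(", paste(vapply(node$children, ser, character(1)),
                      collapse = ","), ")")
  }
  out <- ser(tree)
  if (is_tf_leaf(tree)) out <- paste0("(", out, ")")
  if (newick) paste0(out, ";") else out
}

#' @export
print.tree_form <- function(x, ...) {
  cat("tree_form:", treeform_to_string(x), "\n")
  invisible(x)
}

clade_key <- function(labels) paste(sort(labels), collapse = "\r")

#' All clades (leaf sets of internal nodes and leaves) of a tree
#' @param tree a `tree_form`.
#' @return list of character vectors (sorted labels), including the root set.
#' @export
tree_clades <- function(tree) {
  out <- list()
  walk <- function(node) {
    lv <- tree_leaves(node)
    out[[length(out) + 1L]] <<- sort(lv)
    if (!is_tf_leaf(node)) lapply(node$children, walk)
    invisible(NULL)
  }
  walk(tree)
  unique(out)
}

## smallest node whose leaf set contains all of `taxa`
mrca_node <- function(tree, taxa) {
  descend <- function(node) {
    if (is_tf_leaf(node)) return(node)
    for (ch in node$children) {
      if (all(taxa %in% tree_leaves(ch))) return(descend(ch))
    }
    node
  }
  if (!all(taxa %in% tree_leaves(tree)))
    stop("unknown leaf label(s): ",
         paste(setdiff(taxa, tree_leaves(tree)), collapse = ", "),
         call. = FALSE)
  descend(tree)
}

#' Test monophyly of a taxon set
#'
#' TRUE iff the smallest clade containing `taxa` equals `taxa`.
#'
#' @param tree a `tree_form`.
#' @param taxa character vector of leaf labels.
#' @return logical flag.
#' @export
#' @examples
#' tr <- parse_tree_string("(({[(((1,2)3)4)5][(6,7)8]}9)10)")
#' is_monophyletic(tr, as.character(1:8))  # TRUE
is_monophyletic <- function(tree, taxa) {
  node <- mrca_node(tree, taxa)
  setequal(tree_leaves(node), taxa)
}

## re-root on the outgroup edge via ape when the outgroup is not already a
## depth-1 child
root_at_outgroup <- function(tree, outgroup) {
  if (is_tf_leaf(tree)) return(tree)
  kids_sets <- lapply(tree$children, tree_leaves)
  if (any(vapply(kids_sets, function(k) identical(k, outgroup), logical(1))))
    return(tree)
  phy <- ape::read.tree(text = treeform_to_string(tree, newick = TRUE))
  phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  out <- phylo_to_treeform(phy)
  out
}

#' Classify a gene tree into topology types I-IV / NM / OTHER
#'
#' The four-way typing of anemonefish gene trees by the position of
#' Premnas biaculeatus (taxon 8) relative to the percula complex (6,7) and
#' the remaining Amphiprion species (1-5), with Abudefduf vaigiensis (9) and
#' the outgroup Chaetodon auripes (10) outside. With A the smallest clade
#' containing 1-8, the decision cascade is:
#' \itemize{
#'   \item NM (non-monophyletic) when A contains extra taxa;
#'   \item I when \{6,7,8\} and \{6,7\} are clades (percula complex +
#'     Premnas form the ancestral clade);
#'   \item IV when \{1,2,3,4,5,8\} is a clade, or A splits in two as \{8\}
#'     against \{1..7\} (Premnas roots the non-percula clade / all other
#'     anemonefishes);
#'   \item II / III when A is a polytomy with \{8\} as a singleton child:
#'     II when 8 is the first-written child, III otherwise (a
#'     presentation-level distinction; the polytomies are isomorphic);
#'   \item OTHER for anything else.
#' }
#' Trees whose root does not already separate the outgroup are re-rooted on
#' taxon 10 first.
#'
#' @param tree a `tree_form` whose leaves include "1".."8" (plus "10", and
#'   optionally "9", as outgroups).
#' @param ingroup leaf labels of the anemonefishes (default "1".."8").
#' @param premnas the Premnas leaf (default "8").
#' @param percula the percula-complex leaves (default c("6","7")).
#' @param outgroup the rooting taxon (default "10").
#' @return list with `type` (one of "I","II","III","IV","NM","OTHER") and
#'   `rationale` naming the matched rule.
#' @export
#' @examples
#' classify_tree_form(parse_tree_string("(({[8][1~5][6,7]}9)10)"))$type  # II
classify_tree_form <- function(tree, ingroup = as.character(1:8),
                               premnas = "8", percula = c("6", "7"),
                               outgroup = "10") {
  lv <- tree_leaves(tree)
  missing <- setdiff(ingroup, lv)
  if (length(missing))
    stop("tree lacks ingroup taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (outgroup %in% lv) tree <- root_at_outgroup(tree, outgroup)

  a_node <- mrca_node(tree, ingroup)
  a_set <- sort(tree_leaves(a_node))
  if (!setequal(a_set, ingroup))
    return(list(type = "NM",
                rationale = paste0("smallest clade containing the ingroup ",
                                   "also contains: ",
                                   paste(setdiff(a_set, ingroup),
                                         collapse = ", "))))
  keys <- vapply(tree_clades(tree), clade_key, character(1))
  has_clade <- function(x) clade_key(x) %in% keys

  if (has_clade(c(percula, premnas)) && has_clade(percula))
    return(list(type = "I",
                rationale = "percula complex + Premnas form one clade"))

  others <- setdiff(ingroup, c(percula, premnas))
  if (has_clade(c(others, premnas)))
    return(list(type = "IV",
                rationale = "Premnas sister to the non-percula Amphiprion clade"))
  kid_sets <- lapply(a_node$children, function(ch) sort(tree_leaves(ch)))
  if (length(kid_sets) == 2L) {
    singles <- vapply(kid_sets, function(k) identical(k, premnas), logical(1))
    if (any(singles))
      return(list(type = "IV",
                  rationale = "Premnas basal to all other anemonefishes"))
  }
  if (length(kid_sets) >= 3L) {
    singles <- vapply(kid_sets, function(k) identical(k, premnas), logical(1))
    if (any(singles)) {
      first <- identical(kid_sets[[1]], premnas)
      if (first)
        return(list(type = "II",
                    rationale = "ingroup polytomy with Premnas written first"))
      return(list(type = "III",
                  rationale = "ingroup polytomy with Premnas written medially"))
    }
  }
  list(type = "OTHER", rationale = "no typing rule matched")
}

#' p-distance matrix over an alignment
#'
#' Pairwise proportion of differing columns among columns where neither
#' sequence has a gap.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  pid <- pairwise_identity(seqs)
  d <- (100 - pid$matrix) / 100
  diag(d) <- 0
  d
}

#' Neighbor-joining tree rooted on an outgroup
#'
#' Standard NJ agglomeration (via ape) on a symmetric distance matrix; the
#' unrooted result is rooted on the outgroup edge and returned as a
#' `tree_form` for downstream typing.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @param outgroup taxon label to root on (optional).
#' @return a `tree_form`; the underlying `phylo` is attached as attribute
#'   `"phylo"`.
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (nrow(d) < 3L) stop("need at least three taxa", call. = FALSE)
  phy <- ape::nj(stats::as.dist(d))
  if (!is.null(outgroup)) {
    if (!(outgroup %in% phy$tip.label))
      stop("outgroup '", outgroup, "' not among taxa", call. = FALSE)
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  tf <- phylo_to_treeform(phy)
  attr(tf, "phylo") <- phy
  tf
}

#' Type a set of gene trees into a congruence report
#'
#' @param trees named character vector of tree strings (names = gene labels)
#'   or a data.frame with columns `gene`, `tree_form`.
#' @return data.frame with columns `gene`, `tree_form`, `type`, `rationale`.
#' @export
treeform_report <- function(trees) {
  if (is.data.frame(trees)) {
    genes <- trees$gene
    strings <- trees$tree_form
  } else {
    genes <- names(trees) %||% paste0("tree", seq_along(trees))
    strings <- unname(trees)
  }
  res <- lapply(strings, function(s) classify_tree_form(parse_tree_string(s)))
  data.frame(gene = genes, tree_form = strings,
             type = vapply(res, `[[`, character(1), "type"),
             rationale = vapply(res, `[[`, character(1), "rationale"),
             stringsAsFactors = FALSE)
}

#' Read a plain-text list of tree strings
#'
#' One tree per line, with an optional gene-label prefix separated by a tab;
#' blank lines and '#' comments are skipped. Files ending in .nwk/.tree/.nh
#' are read as Newick via ape instead, using tip-label order for names.
#'
#' @param path file path.
#' @return named character vector of tree strings.
#' @export
read_tree_list <- function(path) {
  if (grepl("\\.(nwk|tree|nh)$", path, ignore.case = TRUE)) {
    phys <- ape::read.tree(path)
    if (inherits(phys, "phylo")) phys <- list(phys)
    strings <- vapply(phys, function(p) ape::write.tree(p), character(1))
    names(strings) <- paste0("tree", seq_along(strings))
    return(strings)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  has_tab <- grepl("\t", lines)
  genes <- ifelse(has_tab, sub("\t.*$", "", lines),
                  paste0("tree", seq_along(lines)))
  strings <- ifelse(has_tab, sub("^[^\t]*\t", "", lines), lines)
  stats::setNames(strings, genes)
}
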