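## End-to-end pipeline: orchestrates gene-table, composition, D-loop and
## tree-form stages and writes the report bundle.

#' Pipeline run configuration
#'
#' @param genomes character vector of GenBank file paths (optional).
#' @param dloops FASTA path of D-loop sequences; when NULL and genomes are
#'   given, D-loops are extracted from the annotated records.
#' @param trees path to a tree-list file (see [read_tree_list()]) (optional).
#' @param out_dir output directory for the report bundle.
#' @param aggregate write the multi-genome min~max gene table (default TRUE
#'   when more than one genome).
#' @param mismatch_frac,gap_slack,min_period,min_copies stage parameters
#'   passed to the D-loop annotator.
#' @param outgroup rooting taxon for tree typing.
#' @return list of class `run_config`, serializable with
#'   [write_run_config()].
#' @export
run_config <- function(genomes = NULL, dloops = NULL, trees = NULL,
                       out_dir = "mitorg-out", aggregate = TRUE,
                       mismatch_frac = NULL, gap_slack = 2L,
                       min_period = 10L, min_copies = 2.0, outgroup = "10") {
  structure(list(genomes = genomes, dloops = dloops, trees = trees,
                 out_dir = out_dir, aggregate = aggregate,
                 mismatch_frac = mismatch_frac, gap_slack = gap_slack,
                 min_period = min_period, min_copies = min_copies,
                 outgroup = outgroup),
            class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(cfg)), path)
  invisible(path)
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  writeLines(msg, con)
}

#' Run the analysis pipeline and write the report bundle
#'
#' Runs the configured stages and writes, into `cfg$out_dir`:
#' `gene_table.tsv` (per-genome or aggregated min~max layout),
#' `composition.tsv` (per-genome sizes and base percentages plus a
#' Mean+/-SD row), `dloop.tsv` and `dloop.gff3` (control-region summaries
#' and element annotations), `treeform_report.tsv` (gene, tree form, type,
#' rationale) and `run_log.txt` (package version, parameters, inputs). Any
#' stage failure aborts with the stage name; outputs written before the
#' failure are flagged in the log.
#'
#' @param cfg a [run_config()].
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.null(cfg$genomes) && is.null(cfg$dloops) && is.null(cfg$trees))
    stop("usage error: no inputs configured (genomes, dloops or trees)",
         call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  pipeline_log(con, "mitorg ", as.character(utils::packageVersion("mitorg")))
  pipeline_log(con, "parameters: ",
               "mismatch_frac=", cfg$mismatch_frac %||% "default(0.15)",
               " gap_slack=", cfg$gap_slack, " min_period=", cfg$min_period,
               " min_copies=", cfg$min_copies, " outgroup=", cfg$outgroup)
  written <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      pipeline_log(con, "stage '", name, "' FAILED: ", conditionMessage(e),
                   "; partial outputs: ",
                   paste(unlist(written), collapse = ", "))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  records <- NULL
  if (!is.null(cfg$genomes)) {
    records <- stage("parse", function() lapply(cfg$genomes, parse_genbank))
    names(records) <- vapply(records, `[[`, character(1), "id")
    pipeline_log(con, "parsed ", length(records), " genome(s): ",
                 paste(names(records), collapse = ", "))

    stage("gene_table", function() {
      tabs <- lapply(records, gene_table)
      out <- file.path(cfg$out_dir, "gene_table.tsv")
      if (length(tabs) > 1L && isTRUE(cfg$aggregate))
        write_gene_table(aggregate_gene_tables(tabs), out)
      else write_gene_table(tabs[[1]], out)
      written$gene_table <<- out
    })

    stage("composition", function() {
      df <- do.call(rbind, lapply(names(records), function(id) {
        comp <- base_composition(records[[id]]$sequence)
        data.frame(id = id, size_bp = records[[id]]$length,
                   A = comp$pct2[["A"]], T = comp$pct2[["T"]],
                   G = comp$pct2[["G"]], C = comp$pct2[["C"]],
                   stringsAsFactors = FALSE)
      }))
      out <- file.path(cfg$out_dir, "composition.tsv")
      if (nrow(df) >= 2L) {
        s <- summarize_compositions(df[, -1])
        df <- rbind(df, data.frame(
          id = "Mean±SD",
          size_bp = s$printed[["size_bp"]],
          A = s$printed[["A"]], T = s$printed[["T"]],
          G = s$printed[["G"]], C = s$printed[["C"]],
          stringsAsFactors = FALSE))
      }
      utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
      written$composition <<- out
    })
  }

  dseqs <- NULL
  if (!is.null(cfg$dloops)) {
    dseqs <- stage("dloop_read", function() {
      x <- Biostrings::readDNAStringSet(cfg$dloops)
      stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
    })
  } else if (!is.null(records)) {
    dseqs <- unlist(lapply(names(records), function(id) {
      i <- which(records[[id]]$features$label == "D-loop")
      if (!length(i)) return(NULL)
      stats::setNames(feature_seq(records[[id]], i[1]), id)
    }))
  }
  if (!is.null(dseqs) && length(dseqs)) {
    stage("dloop", function() {
      anns <- lapply(dseqs, function(s)
        annotate_dloop(s, mismatch_frac = cfg$mismatch_frac,
                       gap_slack = cfg$gap_slack,
                       min_period = cfg$min_period,
                       min_copies = cfg$min_copies))
      summ <- do.call(rbind, lapply(names(anns), function(id)
        dloop_summary(dseqs[[id]], anns[[id]], id = id)))
      if (nrow(summ) >= 2L) {
        s <- summarize_compositions(summ[, c("size_bp", "A", "T", "G", "C", "AT")])
        summ$size_bp <- as.character(summ$size_bp)
        for (cc in c("A", "T", "G", "C", "AT"))
          summ[[cc]] <- sprintf("%.2f", summ[[cc]])
        summ <- rbind(summ, data.frame(
          id = "Mean±SD", size_bp = s$printed[["size_bp"]],
          A = s$printed[["A"]], T = s$printed[["T"]],
          G = s$printed[["G"]], C = s$printed[["C"]],
          AT = s$printed[["AT"]], tandem_repeats = "",
          stringsAsFactors = FALSE))
      }
      out_tsv <- file.path(cfg$out_dir, "dloop.tsv")
      utils::write.table(summ, out_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out_gff <- file.path(cfg$out_dir, "dloop.gff3")
      write_dloop_gff3(anns, out_gff)
      written$dloop_tsv <<- out_tsv
      written$dloop_gff3 <<- out_gff
      pipeline_log(con, "annotated ", length(anns), " D-loop(s)")
    })
  }

  if (!is.null(cfg$trees)) {
    stage("treeform", function() {
      trees <- read_tree_list(cfg$trees)
      rep_ <- treeform_report(trees)
      out <- file.path(cfg$out_dir, "treeform_report.tsv")
      utils::write.table(rep_, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written$treeform <<- out
      pipeline_log(con, "typed ", nrow(rep_), " tree(s): ",
                   paste(table(rep_$type), names(table(rep_$type)),
                         collapse = ", "))
    })
  }
  pipeline_log(con, "done; outputs: ", paste(unlist(written), collapse = ", "))
  written$log <- log_path
  invisible(written)
}
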