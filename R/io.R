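# Delimited-text formats (comma-separated, UTF-8, mandatory header, floats
# written with 17 significant digits for lossless round trips), FASTA probe
# export, GraphML export and JSON run reports.

.fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), "")
  out[is.na(x)] <- "NA"
  out
}

.write_csv <- function(df, path, numeric_cols) {
  for (nm in numeric_cols) df[[nm]] <- .fmt_num(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.read_csv_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  for (nm in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !(df[[nm]] %in% c("NA", "")))
    if (length(bad)) {
      stop(path, ": non-numeric '", nm, "' at line ", bad[1] + 1L, call. = FALSE)
    }
    df[[nm]] <- v
  }
  df
}

.validate_file_labels <- function(df, path) {
  pg <- enumerate_protein_genotypes()$label
  rg <- enumerate_re_genotypes()$label
  badp <- which(!df$protein %in% pg)
  badr <- which(!df$re %in% rg)
  if (length(badp)) {
    stop(path, ": unknown protein label '", df$protein[badp[1]],
         "' at line ", badp[1] + 1L, call. = FALSE)
  }
  if (length(badr)) {
    stop(path, ": unknown RE label '", df$re[badr[1]],
         "' at line ", badr[1] + 1L, call. = FALSE)
  }
  invisible(df)
}

#' Read / write a replicate-level measurement table
#'
#' CSV columns: `protein`, `re`, `replicate`, `dG_kcal_mol`.  Labels are
#' validated against the canonical genotype sets; malformed rows are
#' reported with their line numbers.
#'
#' @param path file path.
#' @return data.frame with columns `protein`, `re`, `replicate`, `dG`.
#' @export
read_measurements <- function(path) {
  df <- .read_csv_checked(path, c("protein", "re", "replicate", "dG_kcal_mol"),
                          "dG_kcal_mol")
  .validate_file_labels(df, path)
  data.frame(protein = df$protein, re = df$re, replicate = df$replicate,
             dG = df$dG_kcal_mol, stringsAsFactors = FALSE)
}

#' @rdname read_measurements
#' @param table data.frame with columns `protein`, `re`, `replicate` and a
#'   binding-energy column.
#' @export
write_measurements <- function(table, path) {
  ycol <- .response_column(table)
  out <- data.frame(protein = table$protein, re = table$re,
                    replicate = table$replicate,
                    dG_kcal_mol = table[[ycol]], stringsAsFactors = FALSE)
  .write_csv(out, path, "dG_kcal_mol")
}

#' Read / write a landscape of per-complex mean binding energies
#'
#' CSV columns: `protein`, `re`, `mean_dG`.
#'
#' @param path file path.
#' @return data.frame with columns `protein`, `re`, `mean_dG`.
#' @export
read_landscape <- function(path) {
  df <- .read_csv_checked(path, c("protein", "re", "mean_dG"), "mean_dG")
  .validate_file_labels(df, path)
  df[, c("protein", "re", "mean_dG")]
}

#' @rdname read_landscape
#' @param landscape data.frame (protein, re, mean_dG) or
#'   `synthetic_landscape`.
#' @export
write_landscape <- function(landscape, path) {
  ls <- .as_landscape(landscape)
  .write_csv(ls, path, "mean_dG")
}

#' Read a structural feature table
#'
#' CSV columns: `protein`, `re`, `feature`, `mean`, `sem`, `n`.
#'
#' @param path file path.
#' @export
read_features <- function(path) {
  df <- .read_csv_checked(path, c("protein", "re", "feature", "mean", "sem", "n"),
                          c("mean", "sem", "n"))
  .validate_file_labels(df, path)
  df
}

#' Export the sixteen labeled-probe sequences as FASTA
#'
#' One record per RE genotype; record IDs are the two-letter RE labels and
#' sequences the 8-base forward strands (see [probe_sequence()]).
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_probe_fasta <- function(path) {
  rg <- enumerate_re_genotypes()
  seqs <- probe_sequence(rg$label)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::DNAStringSet(stats::setNames(seqs, rg$label))
    Biostrings::writeXStringSet(ss, path)
  } else {
    writeLines(as.vector(rbind(paste0(">", rg$label), seqs)), path)
  }
  invisible(path)
}

#' Export a neutral graph
#'
#' Writes the graph either as GraphML or as a plain edge list
#' (`node1,node2,move_type`).
#'
#' @param graph a [build_joint_graph()] result.
#' @param path output file path.
#' @param format "graphml" or "edgelist".
#' @return the path, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("node1", "node2")
    utils::write.csv(el[, c("node1", "node2", "move_type")], path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Serialize a run configuration / report as JSON
#'
#' @param x a named list (configuration, seeds, constants, model specs...).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_run_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
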