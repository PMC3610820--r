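# Readers and writers for the standard formats: expression TSV, interaction
# edge lists (PSI-MI TAB 2.5, plain TSV, SIF), annotation TSV, reporter
# traces, GraphML export.

#' Read an expression matrix from TSV
#'
#' First column: gene identifier; remaining columns: timepoints, with
#' headers either "CT0".."CT47" style or plain numeric hours. Duplicate gene
#' rows are dropped (first occurrence wins) with a warning.
#'
#' @param path TSV file path.
#' @return Numeric matrix (genes x timepoints) with attribute `t` holding
#'   the parsed sampling times in hours.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty expression file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty expression file (no data rows): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  t <- parse_timepoints(header[-1], length(header) - 1)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    stop("ragged row at line ", which(nf != length(header))[1] + 1)
  }
  ids <- vapply(rows, `[[`, character(1), 1)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(length(t))))
  vals <- t(as.matrix(vals))
  if (anyNA(vals)) {
    # literal NA / empty cells are admitted as missing values (profiles with
    # missing timepoints are excluded downstream); anything else is an error
    txt <- t(vapply(rows, function(r) r[-1], character(length(t))))
    bad_cell <- is.na(vals) & !(txt %in% c("NA", ""))
    if (any(bad_cell)) {
      stop("non-numeric cell at line ", which(apply(bad_cell, 1, any))[1] + 1)
    }
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene row(s) dropped (first occurrence wins)")
    vals <- vals[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  dimnames(vals) <- list(ids, header[-1])
  attr(vals, "t") <- t
  message(nrow(vals), " gene profiles read from ", path)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param expr Matrix with rownames; columns written as "CT<h>" headers.
#' @param path Output path.
#' @param t Sampling times; defaults to attribute `t` or parsed colnames.
#' @export
write_expression_tsv <- function(expr, path, t = NULL) {
  t <- t %||% attr(expr, "t") %||% parse_timepoints(colnames(expr), ncol(expr))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  colnames(df) <- c("gene_id", paste0("CT", t))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction edge list
#'
#' Supports three dialects: PSI-MI TAB 2.5 (identifiers from columns 1-2,
#' column 7 retained as source annotation), plain 3+-column TSV
#' (idA, idB, source), and SIF ("A pp B ..."). Edges are undirected and
#' deduplicated; self-loops are dropped. Malformed PSI-MI TAB lines are
#' skipped with a count.
#'
#' @param path File path.
#' @param dialect One of "auto", "psimitab", "tsv", "sif".
#' @return data.frame: idA, idB, source.
#' @export
read_interactions <- function(path, dialect = c("auto", "psimitab", "tsv",
                                                "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty interaction file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
      else if (grepl("\\.mitab", path, ignore.case = TRUE) ||
               grepl("^#?ID\\(s\\)? interactor|uniprotkb:|intact:",
                     lines[1])) "psimitab"
      else if (grepl("\t", lines[1])) {
        nf <- length(strsplit(lines[1], "\t")[[1]])
        if (nf >= 11) "psimitab" else "tsv"
      } else "sif"
  }
  strip_ns <- function(x) sub("^[^:]+:", "", x)
  ed <- switch(dialect,
    psimitab = {
      body <- lines[!startsWith(lines, "#")]
      f <- strsplit(body, "\t", fixed = TRUE)
      ok <- lengths(f) >= 7
      if (any(!ok)) message(sum(!ok), " malformed MITAB line(s) skipped")
      f <- f[ok]
      data.frame(idA = strip_ns(vapply(f, `[[`, character(1), 1)),
                 idB = strip_ns(vapply(f, `[[`, character(1), 2)),
                 source = vapply(f, `[[`, character(1), 7),
                 stringsAsFactors = FALSE)
    },
    tsv = {
      body <- lines[!startsWith(lines, "#")]
      if (grepl("^idA\t", body[1])) body <- body[-1]
      f <- strsplit(body, "\t", fixed = TRUE)
      if (any(lengths(f) < 2)) stop("TSV edge rows need >= 2 columns")
      data.frame(idA = vapply(f, `[[`, character(1), 1),
                 idB = vapply(f, `[[`, character(1), 2),
                 source = vapply(f, function(r)
                   if (length(r) >= 3) r[[3]] else "UNKNOWN", character(1)),
                 stringsAsFactors = FALSE)
    },
    sif = {
      f <- strsplit(lines, "[ \t]+")
      if (any(lengths(f) < 3)) stop("SIF rows need 'source relation target'")
      do.call(rbind, lapply(f, function(r) {
        data.frame(idA = r[1], idB = r[-(1:2)], source = r[2],
                   stringsAsFactors = FALSE)
      }))
    },
    stop("unknown dialect; supported: psimitab, tsv, sif")
  )
  ed <- ed[ed$idA != ed$idB, , drop = FALSE]
  key <- paste(pmin(ed$idA, ed$idB), pmax(ed$idA, ed$idB))
  ed <- ed[!duplicated(key), , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

#' Write an edge table as TSV
#' @param edges data.frame with at least idA, idB.
#' @param path Output path.
#' @export
write_interactions_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an edge table as SIF
#' @param edges data.frame idA, idB; relation written as "pp".
#' @param path Output path.
#' @export
write_sif <- function(edges, path) {
  writeLines(paste(edges$idA, "pp", edges$idB), path)
  invisible(path)
}

#' Export a dynamic network as GraphML
#'
#' Writes the called edges as GraphML with score, q, phase and the dynamic
#' flag as edge attributes, for network viewers.
#'
#' @param dyn `dynamic_network` object.
#' @param path Output path.
#' @export
write_dynamic_graphml <- function(dyn, path) {
  e <- dyn$edges[dyn$edges$status == "tested", ]
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write per-gene rhythm results as TSV
#' @param scan `rhythm_scan` object.
#' @param path Output path.
#' @export
write_rhythm_tsv <- function(scan, path) {
  utils::write.table(scan$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reporter trace TSV (columns time_h, counts)
#' @param path File path.
#' @return data.frame time_h, counts.
#' @export
read_reporter_tsv <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("time_h", "counts") %in% names(d)))
  d
}

#' Read a gene-to-category annotation TSV
#'
#' Expects at least columns `gene` and `category` (extra columns such as a
#' category name are kept).
#' @param path File path.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(d))) {
    stop("annotation TSV needs columns 'gene' and 'category'")
  }
  d
}
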