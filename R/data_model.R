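#' Construct a time-course abundance matrix
#'
#' Bundles a feature-by-sample numeric matrix with its per-sample design
#' (condition label, Zeitgeber time in hours, replicate index) and validates
#' the invariants every downstream stage relies on: unique feature identifiers,
#' one sample-sheet row per matrix column (in matrix column order), ZT values
#' in `[0, 24)` and a unique (group, zt, replicate) triple per sample.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Rownames are feature ids, colnames are sample ids.
#' @param samples data.frame with columns `sample_id`, `group`, `zt`,
#'   `replicate`, one row per matrix column, in column order.
#' @return An object of class `time_course`: a list with elements `values`
#'   and `samples`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4), group = "SPF",
#'                     zt = c(0, 6, 12, 18), replicate = 1L)
#' tc <- time_course(x, sheet)
#' @export
time_course <- function(values, samples) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "zt", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  samples$zt <- as.numeric(samples$zt)
  samples$replicate <- as.integer(samples$replicate)

  fid <- rownames(values)
  if (is.null(fid) || anyNA(fid) || any(fid == ""))
    stop("'values' must have non-empty feature ids as rownames")
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet has ", nrow(samples), " rows but matrix has ",
         ncol(values), " columns")
  if (!is.null(colnames(values)) && !identical(colnames(values), samples$sample_id))
    stop("matrix column names do not match sample sheet order")
  colnames(values) <- samples$sample_id
  if (anyNA(values))
    stop("missing values are not supported; first NA at row ",
         which(is.na(values), arr.ind = TRUE)[1, 1])
  if (anyNA(samples$zt) || any(samples$zt < 0 | samples$zt >= 24))
    stop("zt values must lie in [0, 24)")
  if (anyNA(samples$replicate) || any(samples$replicate < 1L))
    stop("replicate must be an integer >= 1")
  key <- paste(samples$group, samples$zt, samples$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (group, zt, replicate) combination in sample sheet: ",
         paste(samples$sample_id[duplicated(key)][1]))
  structure(list(values = values, samples = samples), class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("time_course: ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  groups: ", paste(unique(x$samples$group), collapse = ", "), "\n", sep = "")
  cat("  ZT:     ", paste(sort(unique(x$samples$zt)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.time_course <- function(x) dim(x$values)

#' Feature identifiers of a time course
#' @param tcm a `time_course` object.
#' @return character vector of feature ids.
#' @export
features <- function(tcm) rownames(tcm$values)

#' Subset a time course to one condition
#'
#' @param tcm a `time_course` object.
#' @param group condition label to keep.
#' @return a `time_course` containing only the samples of `group`.
#' @export
subset_group <- function(tcm, group) {
  stopifnot(inherits(tcm, "time_course"))
  keep <- tcm$samples$group == group
  if (!any(keep)) stop("group '", group, "' not present in sample sheet")
  time_course(tcm$values[, keep, drop = FALSE], tcm$samples[keep, , drop = FALSE])
}

.detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a time-course matrix and sample sheet from delimited text
#'
#' The matrix file has feature ids in the first column and a header row of
#' sample ids; the sample sheet has columns `sample_id`, `group`, `zt`,
#' `replicate`. Matrix columns are reordered to sample-sheet order. Parsing is
#' strict: a non-numeric cell or an id mismatch between the two files is an
#' error naming the offending cell or ids, and features are never silently
#' dropped or reordered.
#'
#' The delimiter is inferred from the file extension (`.csv` means comma,
#' anything else tab) unless given explicitly.
#'
#' @param matrix_path path to the abundance matrix.
#' @param samplesheet_path path to the sample sheet.
#' @param delim optional explicit field delimiter applied to both files.
#' @return a `time_course` object.
#' @export
read_time_course <- function(matrix_path, samplesheet_path, delim = NULL) {
  for (p in c(matrix_path, samplesheet_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  mdelim <- .detect_delim(matrix_path, delim)
  sdelim <- .detect_delim(samplesheet_path, delim)
  raw <- utils::read.table(matrix_path, sep = mdelim, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file must have a feature-id column and >= 1 sample")
  fid <- raw[[1]]
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature id(s) in matrix: ", paste(utils::head(dup, 5), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", cells[bad[1], bad[2]], "' at feature '",
         fid[bad[1]], "', sample '", colnames(cells)[bad[2]], "'")
  }
  dimnames(vals) <- list(fid, colnames(cells))

  sheet <- utils::read.table(samplesheet_path, sep = sdelim, header = TRUE,
                             check.names = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "zt", "replicate")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  not_in_sheet <- setdiff(colnames(vals), sheet$sample_id)
  if (length(not_in_sheet))
    stop("matrix column(s) missing from sample sheet: ",
         paste(not_in_sheet, collapse = ", "))
  not_in_matrix <- setdiff(sheet$sample_id, colnames(vals))
  if (length(not_in_matrix))
    stop("sample sheet id(s) missing from matrix: ",
         paste(not_in_matrix, collapse = ", "))
  vals <- vals[, sheet$sample_id, drop = FALSE]
  time_course(vals, sheet)
}

#' Write a time course to delimited text
#'
#' Inverse of [read_time_course()]: writes the matrix (feature ids in a
#' `feature` column) and the sample sheet. Values are written at full
#' double precision so that a read round-trip reproduces them exactly.
#'
#' @param tcm a `time_course` object.
#' @param matrix_path,samplesheet_path output paths.
#' @param delim optional explicit delimiter; default inferred from extension.
#' @return invisibly, `tcm`.
#' @export
write_time_course <- function(tcm, matrix_path, samplesheet_path, delim = NULL) {
  stopifnot(inherits(tcm, "time_course"))
  mdelim <- .detect_delim(matrix_path, delim)
  sdelim <- .detect_delim(samplesheet_path, delim)
  df <- data.frame(feature = rownames(tcm$values),
                   format(tcm$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = mdelim, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tcm$samples, samplesheet_path, sep = sdelim, quote = FALSE,
                     row.names = FALSE)
  invisible(tcm)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of feature ids.
#' @param universe optional explicit universe; when given, every set member
#'   must belong to it.
#' @return object of class `gene_sets`.
#' @export
gene_sets <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    stray <- setdiff(unique(unlist(sets)), universe)
    if (length(stray))
      stop("set member(s) outside universe: ", paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(sets = sets, universe = universe), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("gene_sets: ", length(x$sets), " sets",
      if (!is.null(x$universe)) paste0(", universe of ", length(x$universe)), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_sets <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' One tab-separated line per set: name, description, then member ids.
#' Duplicate members within a line are counted once. A line with fewer than
#' three fields is an error naming the line number; an empty file yields an
#' empty collection.
#'
#' @param gmt_path path to a GMT file.
#' @return a `gene_sets` object (no universe attached).
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_sets(structure(list(), names = character(0))))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_sets(sets)
}

#' Export a seed correlation network
#'
#' Writes the significant edges of a [seed_network()] either as an edge-list
#' TSV (`node_a`, `node_b`, `r`, `p_adjusted`, `sign`) or as GraphML carrying
#' the same edge attributes plus per-node `degree` and `r_to_seed`.
#' A network with no significant edge yields a header-only edge list.
#'
#' @param net a `seed_network` object.
#' @param path output file path.
#' @param format `"edge_list"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("edge_list", "graphml")) {
  stopifnot(inherits(net, "seed_network"))
  format <- match.arg(format)
  ed <- net$edges[net$edges$significant, c("node_a", "node_b", "r", "p_adjusted"), drop = FALSE]
  ed$sign <- ifelse(ed$r >= 0, "+", "-")
  if (format == "edge_list") {
    utils::write.table(format(ed, digits = 17, trim = TRUE), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    nodes <- data.frame(name = c(net$seed, net$partners$feature),
                        stringsAsFactors = FALSE)
    nodes$degree <- net$degree[nodes$name]
    nodes$r_to_seed <- c(1, net$partners$r)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
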