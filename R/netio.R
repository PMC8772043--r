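# On-disk formats: TSV edge lists (RegNetwork-style exports), SIF, expression
# matrices with label files, GMT module files, JSON panels/metrics.

#' Read a background network edge list
#'
#' Parses a two/three-column edge list (regulator, target, optional type), the
#' dialect used by RegNetwork-style exports: tab-separated by default, lines
#' starting with `#` are comments. A comment of the form `# columns: a b c`
#' (written by [write_network()]) names the attribute columns so that tagged
#' differential networks round-trip.
#'
#' Duplicate directed edges are dropped (count reported via `message()`), as
#' are self-loops; self-loop endpoints still enter the node set, which is how
#' isolated nodes survive a TSV round-trip.
#'
#' @param path file to read.
#' @param delimiter field separator, default tab.
#' @return a directed `grn_network`; the third column, when present, is stored
#'   as edge attribute `type` (or the name given in a `# columns:` comment).
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  attr_name <- "type"
  hdr <- grep("^#\\s*columns:", lines, value = TRUE)
  if (length(hdr)) {
    cols <- strsplit(trimws(sub("^#\\s*columns:", "", hdr[1L])), "\\s+")[[1L]]
    if (length(cols) >= 3L) attr_name <- cols[3L]
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("empty edge list: ", path)
  fields <- strsplit(lines[idx], delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed edge-list line %d in %s (need >= 2 columns): '%s'",
                 idx[which(nf < 2L)[1L]], path, lines[idx[which(nf < 2L)[1L]]]))
  }
  from <- trimws(vapply(fields, `[`, character(1), 1L))
  to <- trimws(vapply(fields, `[`, character(1), 2L))
  third <- ifelse(nf >= 3L,
                  trimws(vapply(fields, function(f) f[3L] %||% "", character(1))),
                  NA_character_)
  loops <- from == to
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  dups <- !loops & duplicated(directed_key(from, to))
  if (any(dups)) message(sum(dups), " duplicate edge(s) dropped")
  ed <- data.frame(from = from[!loops & !dups], to = to[!loops & !dups],
                   stringsAsFactors = FALSE)
  if (any(!is.na(third))) ed[[attr_name]] <- third[!loops & !dups]
  grn_network(ed, nodes = unique(c(from, to)), directed = TRUE)
}

#' Write a network as a TSV edge list or SIF file
#'
#' The TSV dialect is the one [read_edge_list()] reads back: a `# columns:`
#' comment naming the emitted columns, then one `regulator<TAB>target[<TAB>attr]`
#' line per edge. Networks with a `condition` edge attribute (differential
#' networks) emit it as the third column. Isolated nodes are written as
#' self-referential lines, which the reader drops as self-loop edges while
#' keeping the node — so node and edge sets round-trip exactly.
#'
#' SIF (`u relation v`) is write-only and uses the `type` attribute (or `reg`)
#' as the relation.
#'
#' @param net a `grn_network` (or object coercible via [as_grn_network()]).
#' @param path output file.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  net <- as_grn_network(net)
  ed <- net$edges
  attr_col <- intersect(c("condition", "type"), names(ed))[1]
  if (format == "sif") {
    rel <- if (!is.na(attr_col)) ed[[attr_col]] else rep("reg", nrow(ed))
    lines <- sprintf("%s %s %s", ed$from, rel, ed$to)
  } else {
    cols <- c("regulator", "target", if (!is.na(attr_col)) attr_col)
    lines <- paste0("# columns: ", paste(cols, collapse = " "))
    if (nrow(ed)) {
      body <- paste(ed$from, ed$to, sep = "\t")
      if (!is.na(attr_col)) body <- paste(body, ed[[attr_col]], sep = "\t")
      lines <- c(lines, body)
    }
    isolated <- setdiff(net$nodes, c(ed$from, ed$to))
    if (length(isolated))
      lines <- c(lines, paste(isolated, isolated, sep = "\t"))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Read an expression matrix and its phenotype labels
#'
#' The expression file has sample ids in the header row and gene ids in the
#' first column; `.csv` files are comma-separated, anything else tab-separated.
#' The label file is a two-column table (sample id, 0/1 label, no header
#' required). Every sample in the matrix must be labeled; extra labels are
#' ignored.
#'
#' @param path expression matrix file (TSV or CSV).
#' @param label_path two-column label file.
#' @return an [expression_dataset()]; constant genes are flagged in its
#'   `zero_variance` element (also reported via `message()`).
#' @export
read_expression <- function(path, label_path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(raw) < 2L) stop("expression matrix needs gene ids plus >= 1 sample")
  genes <- trimws(raw[[1L]])
  samples <- trimws(colnames(raw)[-1L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 samples[bad[1L, 2L]]))
  }
  dimnames(num) <- list(genes, samples)
  lab <- utils::read.table(label_path, header = FALSE, sep = "",
                           colClasses = "character", comment.char = "#")
  # tolerate an optional header line
  if (nrow(lab) && suppressWarnings(is.na(as.numeric(lab[[2L]][1L]))))
    lab <- lab[-1L, , drop = FALSE]
  labels <- stats::setNames(suppressWarnings(as.numeric(trimws(lab[[2L]]))),
                            trimws(lab[[1L]]))
  missing <- setdiff(samples, names(labels))
  if (length(missing))
    stop("label file is missing sample(s): ", paste(missing, collapse = ", "))
  ds <- expression_dataset(num, labels[samples])
  if (length(ds$zero_variance))
    message("zero-variance gene(s) flagged: ",
            paste(ds$zero_variance, collapse = ", "))
  ds
}

#' Write a module partition as a GMT file
#'
#' One line per module: module id, a description, then the member genes,
#' tab-separated — the gene-set format used throughout enrichment tooling.
#'
#' @param partition a `module_partition` from [greedy_communities()], or a
#'   named list of character vectors (module id -> genes).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_modules <- function(partition, path) {
  mods <- if (inherits(partition, "module_partition")) {
    split(names(partition$membership), partition$membership)
  } else partition
  if (!length(mods)) stop("empty partition")
  genes <- unlist(mods, use.names = FALSE)
  if (anyDuplicated(genes))
    stop("overlapping modules: gene(s) assigned twice: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  ids <- names(mods) %||% paste0("M", seq_along(mods))
  lines <- vapply(seq_along(mods), function(i) {
    paste(c(ids[i], sprintf("module %s (n=%d)", ids[i], length(mods[[i]])),
            sort(mods[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT module file
#'
#' @param path GMT file written by [write_modules()].
#' @return named list of character vectors (module id -> member genes).
#' @export
read_modules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) sort(f[-(1:2)])),
                  vapply(fields, `[`, character(1), 1L))
}

#' Write an R object as JSON
#'
#' Thin wrapper fixing the serialization conventions used for panels, metrics
#' and manifests (unboxed scalars, full numeric precision, stable pretty
#' printing — identical objects give byte-identical files).
#'
#' @param x object to serialize.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
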