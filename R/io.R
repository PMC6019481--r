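#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, and tab-separated member
#' symbols. Duplicate symbols within a set are removed with a warning;
#' empty sets and malformed lines are rejected with the line number.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member symbols; descriptions
#'   in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member",
                   i), call. = FALSE)
    }
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("malformed GMT line %d: empty gene set '%s'", i, parts[1]),
           call. = FALSE)
    }
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate symbols removed",
                      i, parts[1]))
      members <- unique(members)
    }
    sets[[parts[1]]] <- members
    descs[parts[1]] <- parts[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of member-symbol vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the set
#'   names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Write a data frame as a TSV file
#'
#' Tab-separated, header row, UTF-8, "." decimal separator, no quoting and
#' no row names: the package's exchange format for all tables.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "NA")
}

#' Read a TSV file written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}

#' Write an expression matrix and its per-gene condition statistics
#'
#' @param em An `expr_matrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_expr_matrix <- function(em, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  paths <- c(
    matrix = file.path(dir, "expression_matrix.tsv"),
    samples = file.path(dir, "samples.tsv"),
    stats = file.path(dir, "condition_stats.tsv")
  )
  write_tsv(mat, paths["matrix"])
  write_tsv(em$samples, paths["samples"])
  st <- em$stats
  if (is.null(st)) st <- condition_stats(em)
  write_tsv(st, paths["stats"])
  invisible(paths)
}

#' Read an expression matrix written by [write_expr_matrix()]
#'
#' Rebuilds the collapsed matrix, mask, sample table and statistics. The
#' probe-level values are not round-tripped; tests needing them work from
#' the in-memory object.
#'
#' @param dir Directory written by [write_expr_matrix()].
#' @return An `expr_matrix` (without `probe_values`).
#' @export
read_expr_matrix <- function(dir) {
  mat <- read_tsv(file.path(dir, "expression_matrix.tsv"))
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  values <- as.matrix(mat[, -1, drop = FALSE])
  rownames(values) <- mat$gene
  st_path <- file.path(dir, "condition_stats.tsv")
  structure(list(values = values, mask = !is.na(values), samples = samples,
                 probe_values = NULL, probe_gene = NULL,
                 stats = if (file.exists(st_path)) read_tsv(st_path) else NULL),
            class = "expr_matrix")
}

#' Path to the packaged pathway gene-set fixture
#'
#' Twelve gene sets covering the pathway panel the protection analysis
#' targets: estrogen signaling (ESG), the five neurotransmission synapses
#' (GLU, GABA, ACH, DA, 5HT), apoptosis (APO), cell cycle (CC), synaptic
#' vesicle cycle (SVC), long-term potentiation (LTP) and depression (LTD),
#' and Alzheimer's disease (ALZ). Membership lists are representative rat
#' gene symbols curated at packaging time, not a KEGG export.
#'
#' @return Path to the GMT file.
#' @export
pathway_fixture <- function() {
  system.file("extdata", "pathways.gmt", package = "pathprotect",
              mustWork = TRUE)
}
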