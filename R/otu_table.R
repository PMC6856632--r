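#' Construct and validate an OTU count table
#'
#' The central community object: a samples x taxa matrix of non-negative
#' integer read counts with unique sample and taxon labels. All downstream
#' statistics (alpha diversity, beta diversity, betaMNTD/betaNTI, RC-Bray,
#' ANCOM, networks) consume this object.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns. Must carry
#'   row and column names; all cells must be non-negative integers.
#' @return the validated matrix with class `"otu_table"` prepended.
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty OTU table", call. = FALSE)
  if (!is.numeric(counts)) stop("OTU table has non-numeric cells", call. = FALSE)
  if (anyNA(counts)) stop("OTU table contains missing cells", call. = FALSE)
  if (any(counts < 0)) stop("OTU table contains negative counts", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("OTU table contains non-integer counts", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample labels", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon labels", call. = FALSE)
  storage.mode(counts) <- "double"
  counts <- round(counts)
  class(counts) <- c("otu_table", class(matrix()))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d taxa, %s reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read an OTU table from a tab-separated file
#'
#' The first row and first column carry labels; which axis holds samples is
#' declared explicitly because both conventions circulate.
#'
#' @param path path to a TSV file.
#' @param samples_as_rows logical; `TRUE` (default) if rows are samples.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, samples_as_rows = TRUE) {
  raw <- read.delim(path, row.names = 1, check.names = FALSE,
                    colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop("empty OTU table file", call. = FALSE)
  suppressWarnings(num <- vapply(raw, as.numeric, numeric(nrow(raw))))
  if (anyNA(num)) stop("non-numeric cell in OTU table file", call. = FALSE)
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(rownames(raw), colnames(raw)))
  if (!samples_as_rows) num <- t(num)
  otu_table(num)
}

#' Write an OTU table to a tab-separated file
#'
#' @param table an [otu_table].
#' @param path output path; samples are written as rows.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(sample = rownames(table), unclass(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from a tab-separated file
#'
#' Expects a header row and one row per sample with a `sample` column, a
#' `group` column and numeric environmental columns (latitude, longitude,
#' salinity, temperature, pH, depth, chlorophyll, cdom). Missing numeric
#' fields stay `NA`; they are never coerced to zero. Decimal points are
#' parsed locale-independently.
#'
#' @param path path to a TSV file.
#' @param groups allowed category set for `group`; set `NULL` to skip the
#'   check.
#' @return a data.frame with one row per sample.
#' @export
read_metadata <- function(path, groups = c("inshore", "offshore")) {
  md <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(md) == 0L) stop("empty metadata file", call. = FALSE)
  if (!all(c("sample", "group") %in% names(md))) {
    stop("metadata needs 'sample' and 'group' columns", call. = FALSE)
  }
  if (anyDuplicated(md$sample)) stop("duplicate sample labels in metadata", call. = FALSE)
  if (!is.null(groups) && !all(md$group %in% groups)) {
    bad <- setdiff(unique(md$group), groups)
    stop("group value(s) outside declared categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(names(md), c("sample", "group"))
  for (cc in num_cols) {
    v <- md[[cc]]
    if (is.character(v)) {
      v[v == ""] <- NA_character_
      suppressWarnings(vn <- as.numeric(v))
      if (any(!is.na(v) & is.na(vn))) {
        stop("non-numeric value in metadata column '", cc, "'", call. = FALSE)
      }
      md[[cc]] <- vn
    }
  }
  rownames(md) <- md$sample
  md
}

#' Write per-sample metadata to a tab-separated file
#' @param metadata data.frame as returned by [read_metadata] or
#'   [generate_environment].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Thin validated wrapper over [ape::read.tree]: tips must be uniquely
#' labelled, branch lengths present (unless `require_lengths = FALSE`) and
#' non-negative.
#'
#' @param path path to a file holding one Newick string.
#' @param require_lengths error if any branch length is missing (default).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path, require_lengths = TRUE) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: no tree in file", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (require_lengths) stop("tree has no branch lengths", call. = FALSE)
  } else {
    if (anyNA(tree$edge.length)) {
      if (require_lengths) stop("missing branch length", call. = FALSE)
    }
    if (any(tree$edge.length < 0, na.rm = TRUE)) {
      stop("negative branch length", call. = FALSE)
    }
  }
  tree
}

#' Load the bundled 13-sample pairwise turnover matrix
#'
#' A packaged copy of the pairwise community-turnover table from a 13-sample
#' Antarctic shelf-sediment 16S survey (8 inshore, 5 offshore samples): the
#' lower triangle holds betaNTI z-scores, the upper triangle RC-Bray values.
#' Both are returned as full symmetric matrices with an `NA` diagonal,
#' together with the sample-to-group map. Used as the worked reference
#' dataset for process classification.
#'
#' @return a list with elements `bnti` (13 x 13 symmetric z-score matrix),
#'   `rc` (13 x 13 symmetric matrix in `[-1, 1]`), and `groups` (named
#'   character vector, `"inshore"` / `"offshore"` per sample).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_paired_null.tsv",
                      package = "microassembly", mustWork = TRUE)
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  stopifnot(identical(rownames(m), colnames(m)), nrow(m) == 13L)
  n <- nrow(m)
  bnti <- rc <- matrix(NA_real_, n, n, dimnames = dimnames(m))
  lower <- lower.tri(m)
  bnti[lower] <- m[lower]
  bnti[upper.tri(bnti)] <- t(bnti)[upper.tri(bnti)]
  upper <- upper.tri(m)
  rc[upper] <- m[upper]
  rc[lower.tri(rc)] <- t(rc)[lower.tri(rc)]
  stopifnot(all(abs(rc[upper]) <= 1))
  groups <- setNames(
    ifelse(rownames(m) %in% c("JB01", "R02", "R04", "R08", "R09", "R14",
                              "R18", "R19"),
           "inshore", "offshore"),
    rownames(m))
  list(bnti = bnti, rc = rc, groups = groups)
}
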