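#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Values must be non-negative numbers; fractional values are
#' rounded with a warning.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count file must have a gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count at gene ", genes[bad[1, 1]],
         ", sample ", samples[bad[1, 2]])
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing count at gene ", genes[bad[1, 1]], ", sample ", samples[bad[1, 2]])
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop("negative count (", m[bad[1, 1], bad[1, 2]], ") at gene ",
         genes[bad[1, 1]], ", sample ", samples[bad[1, 2]])
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    warning("fractional counts rounded to integers")
    m <- round(m)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  message("read ", nrow(m), " genes x ", ncol(m), " samples from ", path)
  m
}

#' Write a count matrix as TSV
#'
#' First column `gene_id`, remaining columns the sample identifiers;
#' round-trips through [read_counts()].
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", nrow(counts), " genes x ", ncol(counts), " samples to ", path)
  invisible(path)
}

#' Read a sample sheet (CSV)
#'
#' Requires at least `sample_id`, `genotype`, `cell_type` and `condition`
#' columns; any further columns (e.g. `experiment_id`, QC metrics) are kept.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "genotype", "cell_type", "condition")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  message("read ", nrow(df), " samples from ", path)
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then the member genes, all
#' tab-separated. Duplicate genes within a line are removed with a warning;
#' duplicate set names or lines with fewer than three fields are errors.
#'
#' @param path file path.
#' @return named list of character vectors of gene identifiers, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("gene set '", f[1], "' has an empty gene list")
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) within set '", f[1], "' removed")
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  message("read ", length(sets), " gene sets from ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Generic long-format writer used for fit results, QC reports, labels and
#' enrichment tables.
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_result_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", nrow(table), " rows to ", path)
  invisible(path)
}
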