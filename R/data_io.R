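# Readers and writers for the pipeline's external artifacts: expression
# matrices, sample labels, gene lists, GMT gene-set collections, regulon
# tables, SIF network exports, and result tables.

#' Construct an expression dataset
#'
#' Bundles a gene-by-sample log-scale expression matrix with a two-class
#' sample annotation (`"case"` vs `"control"`). This is the substrate every
#' downstream stage of the pipeline consumes.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers). Log-scale units.
#' @param labels Character vector of length `ncol(values)` with entries
#'   `"case"` or `"control"`, in column order.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` and `labels`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(c("TP53", "GLI2", "MYC"), paste0("s", 1:4)))
#' expression_dataset(m, c("case", "case", "control", "control"))
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene rownames and sample colnames")
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  genes <- normalize_symbols(rownames(values))
  stop_if_duplicated(genes, "gene symbol")
  stop_if_duplicated(colnames(values), "sample id")
  rownames(values) <- genes
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("'labels' must have one entry per sample column")
  }
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% labels)) {
    stop("both classes ('case' and 'control') must be present")
  }
  structure(list(values = values, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%d case, %d control)\n",
    nrow(x$values), ncol(x$values),
    sum(x$labels == "case"), sum(x$labels == "control")
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# number of samples per class, with the >=2 guard used by statistical stages
class_counts <- function(dataset, min_per_class = 2L) {
  n_case <- sum(dataset$labels == "case")
  n_ctrl <- sum(dataset$labels == "control")
  if (n_case < min_per_class || n_ctrl < min_per_class) {
    stop(sprintf(
      "each class needs >= %d samples (have %d case, %d control)",
      min_per_class, n_case, n_ctrl
    ))
  }
  c(case = n_case, control = n_ctrl)
}

#' Read an expression matrix and its sample labels
#'
#' The matrix file is a TSV with a header row of sample identifiers and gene
#' symbols in the first column. The labels file is a two-column TSV
#' (sample, class) covering exactly the samples of the matrix; `case_class`
#' names the label token mapped to `"case"`, every other token (there must be
#' exactly one) becomes `"control"`.
#'
#' Gene symbols are uppercased and whitespace-stripped; row order is
#' preserved. Duplicate gene rows, non-numeric cells, and any
#' sample-vs-labels mismatch are errors.
#'
#' @param matrix_path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @param case_class Label token identifying case samples (default
#'   `"case"`).
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` on import (for raw
#'   count matrices; the pipeline works on log-scale values).
#' @return An [expression_dataset].
#' @export
read_expression <- function(matrix_path, labels_path, case_class = "case",
                            log2_transform = FALSE) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV needs a gene column and >= 1 sample")
  genes <- normalize_symbols(raw[[1L]])
  stop_if_duplicated(genes, "gene symbol")
  samples <- colnames(raw)[-1L]
  stop_if_duplicated(samples, "sample id")
  values <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    if (anyNA(col)) {
      i <- which(is.na(col))[1L]
      stop(sprintf("non-numeric expression value at row %d (gene %s), column %d (sample %s)",
                   i, genes[i], j + 1L, samples[j]))
    }
    values[, j] <- col
  }
  lab <- utils::read.delim(labels_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "class"))
  # tolerate a header line
  if (identical(tolower(lab$sample[1L]), "sample")) lab <- lab[-1L, , drop = FALSE]
  stop_if_duplicated(lab$sample, "sample id in labels")
  missing_in_labels <- setdiff(samples, lab$sample)
  if (length(missing_in_labels) > 0L) {
    stop("samples missing from labels file: ",
         paste(utils::head(missing_in_labels, 5L), collapse = ", "))
  }
  extra <- setdiff(lab$sample, samples)
  if (length(extra) > 0L) {
    stop("labels file has samples absent from the matrix: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  cls <- lab$class[match(samples, lab$sample)]
  other <- setdiff(unique(cls), case_class)
  if (!case_class %in% cls) stop(sprintf("no sample labelled '%s'", case_class))
  if (length(other) != 1L) {
    stop("labels must contain exactly one non-case class, found: ",
         paste(other, collapse = ", "))
  }
  if (log2_transform) values <- log2(values + 1)
  expression_dataset(values, ifelse(cls == case_class, "case", "control"))
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: writes the matrix TSV and the two-column
#' labels TSV (tokens `case`/`control`).
#'
#' @param dataset An [expression_dataset].
#' @param matrix_path,labels_path Output paths.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  df <- data.frame(gene = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(dataset$values), class = dataset$labels),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  invisible(NULL)
}

#' Read a gene list (one symbol per line)
#'
#' Symbols are uppercased and whitespace-stripped; blank lines are skipped;
#' duplicates (after normalisation) are collapsed, preserving first
#' occurrence order.
#'
#' @param path Path to the text file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- normalize_symbols(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("gene list is empty: ", path)
  unique(x)
}

#' @rdname read_gene_list
#' @param genes Character vector of symbols to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(NULL)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (members per set).
#' @param descriptions Optional named character vector of set descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L) stop("collection must contain at least one set")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every set must be named")
  }
  stop_if_duplicated(names(sets), "set name")
  sets <- lapply(sets, function(g) unique(normalize_symbols(g)))
  if (any(vapply(sets, length, 1L) == 0L)) stop("every set must be non-empty")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- vapply(x$sets, length, 1L)
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d (median %g)\n",
              length(sz), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

# union of all member genes across sets
collection_universe <- function(collection) {
  unique(unlist(collection$sets, use.names = FALSE))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: `name TAB description TAB gene TAB gene ...`, one set per
#' line. Member symbols are uppercased and deduplicated within each set.
#' Lines with fewer than three fields and duplicate set names are errors.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) {
    stop(sprintf("GMT line %d has %d fields (need >= 3: name, description, genes)",
                 which(nf < 3L)[1L], nf[which(nf < 3L)[1L]]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  stop_if_duplicated(nm, "set name")
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection] to write.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(NULL)
}

#' Construct a regulon set
#'
#' A regulon set is the directed network a master-regulator analysis
#' consumes: per transcription factor, a list of targets each carrying a
#' mode of regulation (signed, in `[-1, 1]`, from the Spearman correlation
#' of TF and target expression) and a confidence weight in `(0, 1]`
#' (within-regulon max-normalised mutual information).
#'
#' @param tf,target Character vectors (parallel) of regulator and target
#'   symbols.
#' @param mode Numeric vector in `[-1, 1]`.
#' @param weight Numeric vector in `(0, 1]`.
#' @return Object of class `regulon_set`: a data frame with columns
#'   `tf`, `target`, `mode`, `weight`, sorted by tf then target.
#' @export
regulon_set <- function(tf = character(), target = character(),
                        mode = numeric(), weight = numeric()) {
  df <- data.frame(tf = as.character(tf), target = as.character(target),
                   mode = as.numeric(mode), weight = as.numeric(weight),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    if (any(df$tf == df$target)) stop("a TF cannot be its own target")
    if (any(!is.finite(df$mode)) || any(df$mode < -1 | df$mode > 1)) {
      stop("mode must lie in [-1, 1]")
    }
    if (any(!is.finite(df$weight)) || any(df$weight <= 0 | df$weight > 1)) {
      stop("weight must lie in (0, 1]")
    }
    key <- paste(df$tf, df$target, sep = "\r")
    stop_if_duplicated(key, "tf-target pair")
    df <- df[order(df$tf, df$target), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("regulon_set", "data.frame")
  df
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("regulon_set: %d TFs, %d edges (%d repressive)\n",
              length(unique(x$tf)), nrow(x), sum(x$mode < 0)))
  invisible(x)
}

# split a regulon_set into a per-TF list of data frames
split_regulons <- function(regulons) {
  split(regulons[c("target", "mode", "weight")], regulons$tf)
}

#' Write / read a regulon table
#'
#' Four-column TSV (`tf`, `target`, `mode`, `weight`) with rows sorted by tf
#' then target for deterministic diffs. Numeric values round-trip to 10
#' significant digits. On read, a mode outside `[-1, 1]` or a weight outside
#' `(0, 1]` is an error.
#'
#' @param regulons A [regulon_set].
#' @param path File path.
#' @export
write_regulon_table <- function(regulons, path) {
  df <- as.data.frame(regulons)
  df$mode <- formatC(df$mode, digits = 12, format = "g")
  df$weight <- formatC(df$weight, digits = 12, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_regulon_table
#' @export
read_regulon_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("tf", "target", "mode", "weight")
  if (!all(need %in% colnames(df))) {
    stop("regulon table must have columns: ", paste(need, collapse = ", "))
  }
  regulon_set(df$tf, df$target, df$mode, df$weight)
}

#' Export a regulon set as a SIF network
#'
#' One line per edge, `tf <relation> target`, with relation `activates` for
#' mode >= 0 and `represses` for mode < 0 (an exactly-zero mode is treated
#' as activation; see [build_regulons()]).
#'
#' @param regulons A [regulon_set].
#' @param path Output path.
#' @export
export_sif <- function(regulons, path) {
  if (nrow(regulons) == 0L) {
    writeLines(character(), path)
    return(invisible(NULL))
  }
  rel <- ifelse(regulons$mode < 0, "represses", "activates")
  writeLines(paste(regulons$tf, rel, regulons$target, sep = "\t"), path)
  invisible(NULL)
}

#' Write / read a master-regulator result table
#'
#' TSV with columns `regulon`, `size`, `es`, `nes`, `p_value`, `fdr`,
#' `rank`, one row per tested regulon, sorted by rank.
#'
#' @param result An `mra` object (see [run_mra()]) or its result table.
#' @param path File path.
#' @export
write_mra_table <- function(result, path) {
  tab <- if (inherits(result, "mra")) result$table else result
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_mra_table
#' @export
read_mra_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a pathway deregulation score matrix
#'
#' Pathway-by-sample TSV, first column `pathway`.
#'
#' @param pds A `pds_matrix` (see [compute_pds()]).
#' @param path File path.
#' @export
write_pds_matrix <- function(pds, path) {
  df <- data.frame(pathway = rownames(pds), unclass(pds),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
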