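#' Read a tab-delimited expression matrix
#'
#' Reads a normalized expression matrix from a tab-delimited text file.
#' The first column holds probeset identifiers, the header row holds sample
#' identifiers, and every cell is a finite numeric intensity. Values are
#' expected to be log2-scale already; `linear = TRUE` applies
#' `log2(x + 1)` on read for matrices stored on the linear scale.
#'
#' @param path Path to a tab-delimited file.
#' @param linear Logical; if `TRUE`, values are log2-transformed with a
#'   pseudocount of 1 after reading.
#' @return A numeric matrix (probesets x samples) with unique row and
#'   column names.
#' @export
read_expression_matrix <- function(path, linear = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) {
    stop("expression matrix file must have an id column and >= 1 sample column")
  }
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicated probeset id(s): ", paste(unique(dup), collapse = ", "))
  }
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicated sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or non-finite value at row '%s', column '%s'",
                   ids[bad[1L]], samples[j]))
    }
    mat[, j] <- v
  }
  if (linear) mat <- log2(mat + 1)
  validate_expression_matrix(mat)
  mat
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with 6 significant digits, which exceeds microarray
#' measurement precision; a write-then-read round trip reproduces the text
#' representation exactly.
#'
#' @param mat Numeric matrix with probeset rownames and sample colnames.
#' @param path Output path.
#' @param digits Significant digits used for formatting.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path, digits = 6L) {
  validate_expression_matrix(mat)
  out <- data.frame(probeset_id = rownames(mat),
                    signif(mat, digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' @param mat Candidate matrix.
#' @return Invisibly, `mat`; errors on violation.
#' @keywords internal
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must have probeset rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicated probeset ids")
  if (anyDuplicated(colnames(mat))) stop("duplicated sample ids")
  if (!all(is.finite(mat))) stop("expression matrix contains non-finite values")
  invisible(mat)
}

#' Read a sample annotation table
#'
#' Tab-delimited with columns `sample_id`, `experiment_gene`, `clone_id`,
#' `condition` (one of induced/uninduced/parental/trisomic/control) and
#' `timepoint_h`.
#'
#' @param path Path to a tab-delimited file.
#' @return A data frame of sample annotations.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "experiment_gene", "clone_id", "condition",
                "timepoint_h")
  missing <- setdiff(required, colnames(ann))
  if (length(missing) > 0L) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ann$sample_id)) stop("duplicated sample_id in annotation")
  ann
}

#' Write a sample annotation table
#'
#' @param ann Data frame of sample annotations.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a matrix and annotation describe the same samples
#'
#' Every sample of the matrix must be annotated exactly once.
#'
#' @param mat Expression matrix.
#' @param ann Sample annotation data frame.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_annotation <- function(mat, ann) {
  missing <- setdiff(colnames(mat), ann$sample_id)
  if (length(missing) > 0L) {
    stop("unannotated sample(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ann$sample_id)) stop("duplicated sample_id in annotation")
  invisible(TRUE)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then one or more member
#' identifiers, all tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (unique members per set).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has no members (need name, description, >=1 member)", i))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) < 1L) {
      stop(sprintf("GMT line %d has no non-empty members", i))
    }
    sets[[fields[1L]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column probeset id-conversion table
#'
#' Maps source-platform identifiers to target-platform identifiers
#' (best-match style); many-to-one mappings are allowed. Repeated identical
#' pairs are collapsed with a warning.
#'
#' @param path Path to a two-column tab-delimited file (no header).
#' @return A data frame with columns `source_id`, `target_id`.
#' @export
read_id_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(source_id = character(), target_id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop(sprintf("malformed id-map line %d: expected 2 tab-separated fields, got %d",
                 which(nf != 2L)[1L], nf[nf != 2L][1L]))
  }
  src <- vapply(fields, `[[`, character(1L), 1L)
  tgt <- vapply(fields, `[[`, character(1L), 2L)
  if (any(!nzchar(src)) || any(!nzchar(tgt))) {
    stop("id map contains empty identifiers")
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsing ", sum(duplicated(key)), " repeated identical id pair(s)")
    keep <- !duplicated(key)
    src <- src[keep]
    tgt <- tgt[keep]
  }
  data.frame(source_id = src, target_id = tgt, stringsAsFactors = FALSE)
}

#' Read disorder intervals from a three-column table
#'
#' Tab-delimited with header columns `gene`, `start`, `end`; coordinates are
#' 1-based inclusive residue positions.
#'
#' @param path Path to the interval file.
#' @return A data frame with columns `gene`, `start`, `end`.
#' @export
read_disorder_intervals <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  required <- c("gene", "start", "end")
  if (!all(required %in% colnames(d))) {
    stop("disorder file needs columns: gene, start, end")
  }
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  if (any(is.na(d$start)) || any(is.na(d$end))) {
    stop("non-integer disorder interval coordinates")
  }
  if (any(d$start < 1L)) stop("disorder intervals must start at residue >= 1")
  if (any(d$start > d$end)) stop("disorder interval with start > end")
  d[required]
}

#' Log a pipeline stage message
#'
#' Lightweight stage logging: prints a timestamped message unless
#' `options(dosage21.quiet = TRUE)` is set.
#'
#' @param ... Message parts passed to [sprintf()]-free concatenation.
#' @return Invisibly `NULL`.
#' @export
stage_log <- function(...) {
  if (isTRUE(getOption("dosage21.quiet", FALSE))) return(invisible(NULL))
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
  invisible(NULL)
}
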