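#' @importFrom stats median mad cor p.adjust pbeta phyper rnbinom rlnorm rnorm
#'   runif rbinom pnorm qnorm sd setNames integrate quantile
#' @importFrom utils read.delim read.csv write.table combn head
NULL

#' Sentinel gene symbol for non-targeting control guides
#' @export
NON_TARGETING <- "NON_TARGETING"

# ---- GuideLibrary ------------------------------------------------------

#' Construct a guide library
#'
#' A guide library maps each sgRNA to its target gene. Non-targeting
#' control guides carry the sentinel gene symbol `NON_TARGETING` and are
#' flagged `is_control`. Gene symbols are opaque, case-sensitive strings;
#' no alias resolution is attempted.
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param sequence character vector of 20-nt protospacer sequences
#'   (alphabet A/C/G/T).
#' @param gene character vector of target gene symbols, with
#'   `NON_TARGETING` for control guides.
#' @return A `data.frame` of class `guide_library` with columns
#'   `guide_id`, `sequence`, `gene`, `is_control`.
#' @export
guide_library <- function(guide_id, sequence, gene) {
  lib <- data.frame(
    guide_id = as.character(guide_id),
    sequence = toupper(as.character(sequence)),
    gene = as.character(gene),
    stringsAsFactors = FALSE
  )
  lib$is_control <- lib$gene == NON_TARGETING
  class(lib) <- c("guide_library", "data.frame")
  validate_guide_library(lib)
}

validate_guide_library <- function(lib) {
  stopifnot(is.data.frame(lib))
  if (anyDuplicated(lib$guide_id)) {
    dup <- unique(lib$guide_id[duplicated(lib$guide_id)])
    stop("duplicated guide_id(s): ", paste(head(dup, 5), collapse = ", "))
  }
  bad <- grepl("[^ACGT]", lib$sequence)
  if (any(bad)) {
    stop("sequence outside {A,C,G,T} for guide(s): ",
         paste(head(lib$guide_id[bad], 5), collapse = ", "))
  }
  if (any(lib$is_control != (lib$gene == NON_TARGETING))) {
    stop("is_control flag inconsistent with the NON_TARGETING sentinel")
  }
  lib
}

#' Read a guide-library annotation ("chip") file
#'
#' Expects a CSV with a header and columns `guide_id`, `sequence`, `gene`
#' in that order; extra columns are ignored with a warning.
#'
#' @param path path to the chip CSV.
#' @return A [guide_library()].
#' @export
read_chip <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(x) == 0L) stop("empty chip file: ", path)
  need <- c("guide_id", "sequence", "gene")
  if (!all(need %in% names(x))) {
    stop("chip file must have columns guide_id, sequence, gene; found: ",
         paste(names(x), collapse = ", "))
  }
  extra <- setdiff(names(x), need)
  if (length(extra)) {
    warning("ignoring ", length(extra), " extra chip column(s): ",
            paste(extra, collapse = ", "))
  }
  guide_library(x$guide_id, x$sequence, x$gene)
}

#' Read a gene list (one symbol per line)
#'
#' Symbols are whitespace-trimmed and case-preserved; duplicates are
#' dropped with a warning stating how many were removed.
#'
#' @param path path to a plain-text file, one gene symbol per line.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("empty gene list: ", path)
  n_dup <- sum(duplicated(x))
  if (n_dup > 0L) warning("dropped ", n_dup, " duplicate gene symbol(s) in ", path)
  unique(x)
}

# ---- GeneSetRegistry ---------------------------------------------------

#' Construct a registry of named gene sets
#'
#' Holds the reference sets the pipeline consumes: `essential_ref` and
#' `nonessential_ref` (the normalization anchors), `qc_essential` (the
#' spliceosome/ribosome/proteasome set used for SSMD quality control) and
#' any further named sets. Anchor sets must be disjoint.
#'
#' @param ... named non-empty character vectors of gene symbols.
#' @return A named list of class `gene_set_registry`.
#' @export
gene_set_registry <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named")
  }
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  if (all(c("essential_ref", "nonessential_ref") %in% names(sets))) {
    ov <- intersect(sets$essential_ref, sets$nonessential_ref)
    if (length(ov)) {
      stop("essential_ref and nonessential_ref overlap: ",
           paste(head(ov, 5), collapse = ", "))
    }
  }
  structure(sets, class = "gene_set_registry")
}

# ---- SampleMeta / design ----------------------------------------------

valid_conditions <- c("plasmid", "ETP", "DMSO", "erlotinib", "other")

#' Construct a screen design table
#'
#' One row per sequenced sample: `sample_id`, `cell_line` (e.g. `control`,
#' `EGFR`, `KRAS`, `RIT1`), `condition` (`plasmid`, `ETP`, `DMSO`,
#' `erlotinib`, `other`) and `replicate`. Exactly one plasmid sample is
#' allowed per screen and `(cell_line, condition, replicate)` must be
#' unique.
#'
#' @param sample_id,cell_line,condition,replicate vectors of equal length.
#' @return A `data.frame` of class `screen_design`.
#' @export
screen_design <- function(sample_id, cell_line, condition, replicate) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    cell_line = as.character(cell_line),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$sample_id)) stop("sample_id must be unique")
  key <- paste(d$cell_line, d$condition, d$replicate)
  if (anyDuplicated(key)) {
    stop("(cell_line, condition, replicate) not unique: ",
         key[duplicated(key)][1])
  }
  if (any(d$replicate < 1L)) stop("replicate must be a positive integer")
  n_plasmid <- sum(d$condition == "plasmid")
  if (n_plasmid > 1L) stop("a screen design may contain at most one plasmid sample")
  class(d) <- c("screen_design", "data.frame")
  d
}

#' Read a screen design TSV
#' @param path tab-separated file with header
#'   `sample_id cell_line condition replicate`.
#' @return A [screen_design()].
#' @export
read_design <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "cell_line", "condition", "replicate")
  if (!all(need %in% names(x))) {
    stop("design file must have columns ", paste(need, collapse = ", "))
  }
  screen_design(x$sample_id, x$cell_line, x$condition, x$replicate)
}

# ---- CountMatrix -------------------------------------------------------

#' Construct a guide-by-sample count matrix
#'
#' @param counts non-negative integer matrix; rownames are guide ids,
#'   colnames are sample ids matching `design$sample_id`.
#' @param design a [screen_design()] covering every column.
#' @param library optional [guide_library()]; if given, row ids must be a
#'   subset of the library's guides.
#' @return A list of class `screen_counts` with elements `counts` and
#'   `design`.
#' @export
screen_counts <- function(counts, design, library = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have guide rownames and sample colnames")
  }
  storage.mode(counts) <- "integer"
  if (any(is.na(counts))) stop("counts contain NA after integer coercion")
  if (any(counts < 0L)) stop("negative counts are not allowed")
  missing_meta <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_meta)) {
    stop("no design entry for sample column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  if (!is.null(library)) {
    unknown <- setdiff(rownames(counts), library$guide_id)
    if (length(unknown)) {
      stop("guide id(s) absent from the library: ",
           paste(head(unknown, 10), collapse = ", "))
    }
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero counts for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts:", nrow(x$counts), "guides x", ncol(x$counts), "samples\n")
  cat("arms:", paste(unique(paste(x$design$cell_line, x$design$condition, sep = "/")),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Read a wide guide-count TSV (PoolQ-style)
#'
#' First column holds guide ids; remaining columns are samples named in
#' the design. Cells must be numeric and are coerced to integer counts.
#'
#' @param path path to the counts TSV.
#' @param library a [guide_library()]; unknown guide ids are a hard error.
#' @param design a [screen_design()] describing every sample column.
#' @return A [screen_counts()] object.
#' @export
read_count_matrix <- function(path, library, design) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (ncol(x) < 2L) stop("counts file needs a guide column plus >=1 sample column")
  guide_ids <- x[[1L]]
  sample_ids <- names(x)[-1L]
  missing_meta <- setdiff(sample_ids, design$sample_id)
  if (length(missing_meta)) {
    stop("no design entry for sample column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  m <- matrix(NA_real_, nrow = nrow(x), ncol = length(sample_ids),
              dimnames = list(guide_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(x[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric count at row ", i, " (guide ", guide_ids[i],
           "), column ", sample_ids[j])
    }
    m[, j] <- v
  }
  screen_counts(round(m), design, library = library)
}

#' Write a screen_counts object as a wide TSV
#' @param x a [screen_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "screen_counts"))
  out <- data.frame(guide_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- score tables ------------------------------------------------------

#' Write a score table as TSV (floats with 6 significant digits)
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
read_scores <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
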