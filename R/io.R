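# Readers and writers for the plain-text formats the pipeline touches.
# All files are UTF-8, tab-delimited where tabular; lines starting with '#'
# are comments (this also swallows QIIME2 "#q2:types" secondary headers,
# which are tolerated but never interpreted).

read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Read a feature table from TSV
#'
#' Two dialects are supported:
#' \describe{
#'   \item{dense}{features as rows; first column holds feature ids, header
#'     row holds sample ids.  Set `samples_as_rows = TRUE` if the file is
#'     transposed; the reader restores the canonical features x samples
#'     orientation.}
#'   \item{sparse}{three columns `feature`, `sample`, `count`, one row per
#'     nonzero cell.  A duplicated (feature, sample) pair is an error, not
#'     summed.}
#' }
#' Counts must be non-negative integers; violations raise an error naming
#' the offending cell.
#'
#' @param path file path
#' @param dialect `"dense"` or `"sparse"`
#' @param samples_as_rows dense dialect only: transpose on input
#' @param taxonomy optional named character vector of lineages to attach
#' @return a [feature_table]
#' @export
read_feature_table <- function(path, dialect = c("dense", "sparse"),
                               samples_as_rows = FALSE, taxonomy = NULL) {
  dialect <- match.arg(dialect)
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L) stop("feature table file '", path, "' is empty")
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (dialect == "dense") {
    ids <- df[[1L]]
    mat <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                   dimnames = dimnames(mat)))
    bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf(
        "invalid count '%s' for feature '%s', sample '%s' in '%s'",
        mat[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]],
        colnames(mat)[bad[1L, 2L]], path))
    rownames(num) <- ids
    if (samples_as_rows) num <- t(num)
    feature_table(num, taxonomy)
  } else {
    if (ncol(df) < 3L) stop("sparse dialect needs columns feature, sample, count")
    feat <- df[[1L]]; samp <- df[[2L]]; cnt <- df[[3L]]
    key <- paste(feat, samp, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("duplicate (feature, sample) triplet: ",
           gsub("\r", ", ", d, fixed = TRUE))
    }
    val <- suppressWarnings(as.numeric(cnt))
    bad <- which(is.na(val) | val < 0 | abs(val - round(val)) > 1e-8)
    if (length(bad))
      stop(sprintf("invalid count '%s' for feature '%s', sample '%s' in '%s'",
                   cnt[bad[1L]], feat[bad[1L]], samp[bad[1L]], path))
    fids <- unique(feat); sids <- unique(samp)
    m <- matrix(0L, length(fids), length(sids), dimnames = list(fids, sids))
    m[cbind(match(feat, fids), match(samp, sids))] <- as.integer(round(val))
    feature_table(m, taxonomy)
  }
}

#' Write a feature table to TSV
#'
#' @inheritParams read_feature_table
#' @param x a [feature_table]
#' @export
write_feature_table <- function(x, path, dialect = c("dense", "sparse")) {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    df <- data.frame(feature_id = rownames(x$counts), x$counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nz <- which(x$counts > 0L, arr.ind = TRUE)
    df <- data.frame(feature = rownames(x$counts)[nz[, 1L]],
                     sample = colnames(x$counts)[nz[, 2L]],
                     count = x$counts[nz])
    df <- df[order(df$feature, df$sample), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

sample_types <- c("floor", "field_control", "negative_control",
                  "extraction_control")

control_sample_types <- function() sample_types[-1L]

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `sample_type` (one of `floor`,
#' `field_control`, `negative_control`, `extraction_control`),
#' `pma_treated` (logical), `location_id`, `radius`, `session_index`,
#' `session_date`.  Location and radius may be empty for controls but are
#' mandatory for floor samples (the gradient statistics need them).
#' Unknown columns are carried through untouched.
#'
#' @param path file path
#' @return a `data.frame` of class `sample_metadata`
#' @export
read_metadata <- function(path) {
  lines <- read_tsv_lines(path)
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  validate_metadata(df)
}

#' Validate a sample metadata data frame
#'
#' @param df data frame with the columns documented in [read_metadata()]
#' @return the validated, type-coerced data frame (class `sample_metadata`)
#' @export
validate_metadata <- function(df) {
  req <- c("sample_id", "sample_type", "pma_treated", "location_id",
           "radius", "session_index", "session_date")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  bad_type <- setdiff(unique(df$sample_type), sample_types)
  if (length(bad_type))
    stop("unknown sample_type value(s): ", paste(bad_type, collapse = ", "),
         " (expected one of ", paste(sample_types, collapse = ", "), ")")
  df$pma_treated <- as.logical(toupper(as.character(df$pma_treated)))
  if (any(is.na(df$pma_treated)))
    stop("pma_treated must be TRUE/FALSE")
  df$location_id <- suppressWarnings(as.integer(df$location_id))
  df$radius <- suppressWarnings(as.numeric(df$radius))
  df$session_index <- suppressWarnings(as.integer(df$session_index))
  floor <- df$sample_type == "floor"
  if (any(floor & (is.na(df$radius) | is.na(df$location_id))))
    stop("floor sample(s) missing radius or location: ",
         paste(utils::head(df$sample_id[floor &
             (is.na(df$radius) | is.na(df$location_id))], 5L),
             collapse = ", "))
  if (any(df$radius < 0, na.rm = TRUE))
    stop("radius must be non-negative")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param df a metadata data frame
#' @param path file path
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the pipeline
#' relies on: unique tip labels and total branch lengths.  Edges with
#' missing lengths are set to 0 with a warning so path-length computations
#' stay defined.
#'
#' @param path file path (or a Newick string via `text`)
#' @param text optional Newick string, bypassing `path`
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("Newick input has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length in Newick input")
  tree
}

#' Write a phylogeny to Newick
#' @param tree an [ape::phylo] tree
#' @param path file path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read sequences from FASTA as uppercase character strings
#'
#' Gap characters are preserved (callers that need gap-free sequences strip
#' them); IUPAC ambiguity codes pass through.
#'
#' @param path FASTA file
#' @return named character vector, one string per record
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("no FASTA records in '", path, "'")
  seqs <- vapply(as.character(dna), function(s) toupper(paste(s, collapse = "")),
                 character(1L))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1L])
  names(seqs) <- ids
  seqs
}

#' Write named sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output file
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    idx <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, idx, pmin(idx + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
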