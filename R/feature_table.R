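#' Construct a feature table
#'
#' The central data structure of the pipeline: a matrix of non-negative
#' integer read counts with sOTUs (or genera) as rows and samples as columns,
#' optionally annotated with per-feature taxonomy lineage strings.
#'
#' The orientation is fixed: features are always rows, samples always
#' columns.  Readers that encounter the transposed layout transpose on the
#' way in, so downstream code never has to guess.
#'
#' @param counts numeric matrix of counts, features x samples.  Values must
#'   be non-negative and integral; row and column names must be present and
#'   unique.
#' @param taxonomy optional character vector of lineage strings (e.g.
#'   `"k__Bacteria; p__Firmicutes; ...; g__Bacillus"`), either named by
#'   feature id or in row order, covering every feature.
#' @return an object of class `feature_table`: a list with elements
#'   `counts` (integer matrix) and `taxonomy` (named character or `NULL`).
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 5L), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' ft <- feature_table(m)
#' sample_totals(ft)
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  # R drops a dimension's names when it is subset to length 0, so only
  # require names along dimensions that actually have entries
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("feature table requires row (feature) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(is.na(counts)))
    stop("feature table counts contain NA")
  if (any(counts < 0))
    stop("negative count for feature ",
         rownames(counts)[which(counts < 0, arr.ind = TRUE)[1L, 1L]])
  off <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(off) > 0L)
    stop(sprintf("non-integer count %s at feature '%s', sample '%s'",
                 format(counts[off[1L, , drop = FALSE]]),
                 rownames(counts)[off[1L, 1L]], colnames(counts)[off[1L, 2L]]))
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) {
      if (length(taxonomy) != nrow(counts))
        stop("unnamed taxonomy must have one entry per feature")
      names(taxonomy) <- rownames(counts)
    }
    missing <- setdiff(rownames(counts), names(taxonomy))
    if (length(missing))
      stop("taxonomy missing for feature(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    taxonomy <- taxonomy[rownames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  cat(sprintf("  taxonomy: %s\n",
              if (is.null(x$taxonomy)) "absent" else "present"))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Per-sample read totals (column sums)
#' @param x a `feature_table`
#' @return named numeric vector of per-sample totals
#' @export
sample_totals <- function(x) colSums(x$counts)

#' Subset a feature table by sample or feature ids
#'
#' Keeps taxonomy in sync with the retained features.
#'
#' @param x a `feature_table`
#' @param samples,features character vectors of ids to keep (NULL = keep all)
#' @param drop_features if TRUE, drop the named features instead of keeping
#'   them (applies to `features` only)
#' @export
ft_subset <- function(x, samples = NULL, features = NULL,
                      drop_features = FALSE) {
  counts <- x$counts
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(counts))
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    counts <- counts[, samples, drop = FALSE]
  }
  if (!is.null(features)) {
    if (drop_features) {
      counts <- counts[setdiff(rownames(counts), features), , drop = FALSE]
    } else {
      missing <- setdiff(features, rownames(counts))
      if (length(missing))
        stop("unknown feature id(s): ", paste(missing, collapse = ", "))
      counts <- counts[features, , drop = FALSE]
    }
  }
  tax <- if (is.null(x$taxonomy)) NULL else x$taxonomy[rownames(counts)]
  feature_table(counts, tax)
}
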