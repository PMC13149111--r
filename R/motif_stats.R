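#' 4x4 dinucleotide count/frequency matrix
#'
#' Tallies splice-site dinucleotides of non-canonical junctions into a
#' 4x4 matrix: rows are the first base of the dinucleotide, columns the
#' second (A/C/G/T in both). Optionally excludes one dinucleotide class
#' first — GT from donor tallies or AG from acceptor tallies — to expose
#' the distribution of the sites that are non-canonical on that side;
#' frequencies are renormalized over the remaining sites.
#'
#' @param dinucs Character vector of 2-mers (invalid-marker entries are
#'   dropped before tallying).
#' @param role `"donor"` or `"acceptor"`.
#' @param exclusion Optional 2-mer to remove before tallying (`NULL` for
#'   the full matrix).
#' @return Object of class `dinuc_matrix`: list with `counts` and
#'   `frequencies` (4x4 matrices), `n_valid`, `role`, `exclusion`,
#'   `degenerate` (`TRUE` when no sites remain, in which case the
#'   frequencies are undefined and set to `NA`).
#' @export
dinuc_counts <- function(dinucs, role = c("donor", "acceptor"),
                         exclusion = NULL) {
  role <- match.arg(role)
  dinucs <- dinucs[grepl("^[ACGT]{2}$", dinucs)]
  if (!is.null(exclusion)) {
    stopifnot(grepl("^[ACGT]{2}$", exclusion))
    dinucs <- dinucs[dinucs != exclusion]
  }
  counts <- matrix(0L, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  if (length(dinucs) > 0L) {
    first <- substr(dinucs, 1L, 1L)
    second <- substr(dinucs, 2L, 2L)
    tab <- table(factor(first, DNA_BASES), factor(second, DNA_BASES))
    counts <- matrix(as.integer(tab), 4L, 4L,
                     dimnames = list(DNA_BASES, DNA_BASES))
  }
  n_valid <- sum(counts)
  degenerate <- n_valid == 0L
  freqs <- if (degenerate) {
    matrix(NA_real_, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  } else {
    counts / n_valid
  }
  structure(list(counts = counts, frequencies = freqs, n_valid = n_valid,
                 role = role, exclusion = exclusion,
                 degenerate = degenerate),
            class = "dinuc_matrix")
}

#' Heatmap color specification for a dinucleotide matrix
#'
#' Power-law color normalization: each cell's color value is
#' `(frequency / max frequency) ^ gamma`, compressing the dynamic range
#' so minor classes stay visible next to a dominant one. Only the color
#' scale is transformed; the cell labels remain the raw frequencies.
#'
#' @param matrix A `dinuc_matrix` (see [dinuc_counts()]).
#' @param gamma Positive exponent (default 0.5; 1 reduces to linear
#'   scaling).
#' @return Object of class `heatmap_spec`: list with `color_values` (4x4
#'   in \[0, 1\], all 0 when the matrix is degenerate), `label_values`
#'   (the untransformed frequencies), `gamma`, `matrix`.
#' @export
heatmap_spec <- function(matrix, gamma = 0.5) {
  stopifnot(inherits(matrix, "dinuc_matrix"), gamma > 0)
  if (matrix$degenerate) {
    cv <- array(0, dim = c(4L, 4L), dimnames = dimnames(matrix$counts))
  } else {
    m <- max(matrix$frequencies)
    cv <- if (m == 0) {
      array(0, dim = c(4L, 4L), dimnames = dimnames(matrix$counts))
    } else {
      (matrix$frequencies / m)^gamma
    }
  }
  structure(list(color_values = cv, label_values = matrix$frequencies,
                 gamma = gamma, matrix = matrix),
            class = "heatmap_spec")
}

#' Flatten a dinucleotide matrix to a long table
#'
#' @param matrix A `dinuc_matrix`.
#' @param gamma Color-normalization exponent passed to [heatmap_spec()].
#' @return Data.frame with 16 rows: `first`, `second`, `count`,
#'   `frequency`, `color_value`.
#' @export
dinuc_table <- function(matrix, gamma = 0.5) {
  spec <- heatmap_spec(matrix, gamma)
  data.frame(first = rep(DNA_BASES, times = 4L),
             second = rep(DNA_BASES, each = 4L),
             count = as.vector(matrix$counts),
             frequency = as.vector(matrix$frequencies),
             color_value = as.vector(spec$color_values),
             stringsAsFactors = FALSE)
}
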