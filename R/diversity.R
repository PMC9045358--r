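# Alpha diversity: species richness, Shannon index, and quartile groups.

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the strictly positive entries of the
#' (internally renormalized) abundance vector. Natural logarithm by default.
#'
#' @param x Non-negative abundance or count vector, or a samples x features
#'   matrix (row-wise computation).
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Numeric value (or vector for a matrix input); `NA` with a warning
#'   for all-zero samples.
#' @examples
#' shannon(c(0.5, 0.5))          # log(2)
#' shannon(c(0.7, 0.2, 0.1))
#' @export
shannon <- function(x, base = exp(1)) {
  if (!is.null(dim(x))) return(apply(x, 1, shannon, base = base))
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot <= 0) {
    warning("all-zero abundance vector: Shannon index undefined")
    return(NA_real_)
  }
  p <- x[x > 0] / tot
  -sum(p * log(p, base = base))
}

#' Species richness
#'
#' Number of features with strictly positive abundance or count.
#'
#' @param x Non-negative vector, or a samples x features matrix.
#' @return Integer count (or vector for matrix input).
#' @export
richness <- function(x) {
  if (!is.null(dim(x))) return(apply(x, 1, richness))
  if (any(x < 0)) stop("abundances must be non-negative")
  sum(x > 0)
}

#' Per-sample alpha-diversity table
#'
#' @param profile Samples x MGS abundance (or count) matrix.
#' @return Data frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(profile) {
  ids <- rownames(profile)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(profile)))
  data.frame(sample_id = ids,
             richness = richness(profile),
             shannon = shannon(profile),
             row.names = NULL)
}

#' Quartile group assignment
#'
#' Partitions samples at the 25th/50th/75th sample quantiles (type-7 linear
#' interpolation). Q1 is the lowest quartile. When the quantile breaks are
#' degenerate (heavy ties), all samples falling into collapsed intervals
#' share the lowest applicable label; a fully degenerate vector is assigned
#' Q1 throughout with a warning.
#'
#' @param values Numeric vector, length >= 4.
#' @return Factor with levels `Q1`..`Q4` in sample order.
#' @export
quartile_groups <- function(values) {
  if (length(values) < 4) stop("need at least 4 values for quartiles")
  if (anyNA(values)) stop("missing values not allowed")
  br <- quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7)
  if (br[1] == br[5]) {
    warning("all values equal: degenerate quartiles, assigning Q1")
    return(factor(rep("Q1", length(values)), levels = paste0("Q", 1:4)))
  }
  # v <= q25 -> Q1; q25 < v <= q50 -> Q2; etc. Duplicate interior breaks
  # collapse intervals so tied values take the lowest applicable label.
  idx <- rowSums(outer(values, as.numeric(br[2:4]), ">")) + 1L
  factor(paste0("Q", idx), levels = paste0("Q", 1:4))
}
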