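# Compositional beta diversity: CLR transform, Aitchison distance, and a
# permutation PERMANOVA (McArdle-Anderson trace form) for continuous and
# binary covariates.

#' Centered log-ratio (CLR) transform
#'
#' `clr_i = log(x_i + pc) - mean_j log(x_j + pc)` per sample. Every output
#' row sums to zero, and the transform is invariant to per-sample scaling
#' of the input when `pseudocount = 0`.
#'
#' @param x Samples x features matrix of non-negative counts or abundances
#'   (a vector is treated as one sample).
#' @param pseudocount Value added to every entry before taking logs
#'   (default 1, intended for raw counts). Must be positive unless every
#'   entry of `x` already is.
#' @return Real matrix of the same shape.
#' @examples
#' clr_transform(c(2, 8), pseudocount = 0)
#' @export
clr_transform <- function(x, pseudocount = 1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(x < 0)) stop("entries must be non-negative")
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  if (pseudocount == 0 && any(x == 0)) {
    stop("`pseudocount` must be > 0 when zeros are present")
  }
  lx <- log(x + pseudocount)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Aitchison distance matrix
#'
#' Pairwise Euclidean distance between CLR-transformed samples.
#'
#' @param x Either an already CLR-transformed matrix (`clr = TRUE`, default)
#'   or a raw count/abundance matrix to transform first.
#' @param clr Set `FALSE` to apply [clr_transform()] with `pseudocount`
#'   before computing distances.
#' @param pseudocount Passed to [clr_transform()] when `clr = FALSE`.
#' @return Symmetric n x n numeric matrix with zero diagonal.
#' @export
aitchison_distance <- function(x, clr = TRUE, pseudocount = 1) {
  m <- if (clr) x else clr_transform(x, pseudocount)
  as.matrix(dist(m, method = "euclidean"))
}

#' Permutation PERMANOVA for a single covariate
#'
#' Tests the association between a distance matrix and one numeric covariate
#' (continuous or 0/1) using the Gower-centered inner-product matrix
#' `G = -1/2 J D^2 J` and the pseudo-F
#' `F = tr(HGH) / (tr((I-H)G(I-H)) / (n-2))` for the hat matrix `H` of the
#' intercept-plus-covariate design. Significance comes from permuting the
#' covariate; when `n! <= exhaustive_limit` all permutations are enumerated
#' and the p-value is exact, otherwise
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param d Distance matrix (square numeric matrix or a `dist`).
#' @param covariate Numeric vector, one value per sample, no missing values.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed.
#' @param exhaustive_limit Enumerate all permutations when `n!` is at or
#'   below this limit (default 10080, i.e. n <= 7).
#' @return Object of class `"permanova"`: a list with `f`, `r_squared`,
#'   `p_value`, `n_perm`, `exhaustive`, `n`.
#' @export
permanova <- function(d, covariate, n_perm = 999, seed = NULL,
                      exhaustive_limit = 10080) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 5) stop("need at least 5 samples")
  if (length(covariate) != n) stop("covariate length must match distance matrix")
  if (anyNA(covariate) || !is.numeric(covariate)) {
    stop("covariate must be numeric with no missing values")
  }
  if (sd(covariate) == 0) stop("constant covariate: PERMANOVA undefined")
  G <- gower_center(d)
  trG <- sum(diag(G))
  z <- covariate - mean(covariate)
  p_unit <- z / sqrt(sum(z^2))
  f_stat <- function(pv) {
    ssm <- as.numeric(crossprod(pv, G %*% pv))
    (ssm) / ((trG - ssm) / (n - 2))
  }
  f_obs <- f_stat(p_unit)
  ssm_obs <- as.numeric(crossprod(p_unit, G %*% p_unit))
  r2 <- ssm_obs / trG
  exhaustive <- factorial(n) <= exhaustive_limit
  if (exhaustive) {
    perms <- all_permutations(n)
    fs <- apply(perms, 1, function(ix) f_stat(p_unit[ix]))
    p_val <- mean(fs >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    p_val <- with_seed_(seed, {
      P <- replicate(n_perm, p_unit[sample.int(n)])
      ssm <- colSums(P * (G %*% P))
      fp <- ssm / ((trG - ssm) / (n - 2))
      (1 + sum(fp >= f_obs - 1e-12)) / (1 + n_perm)
    })
    n_used <- n_perm
  }
  structure(list(f = f_obs, r_squared = r2, p_value = p_val,
                 n_perm = n_used, exhaustive = exhaustive, n = n),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (single covariate, ", if (x$exhaustive) "exhaustive"
      else paste0(x$n_perm, " permutations"), ")\n", sep = "")
  cat(sprintf("  n = %d  pseudo-F = %.4f  R2 = %.4f  p = %.4g\n",
              x$n, x$f, x$r_squared, x$p_value))
  invisible(x)
}

# G = -1/2 J A J with A = D^2 and J the centering projector.
gower_center <- function(d) {
  A <- -0.5 * d^2
  A <- sweep(A, 1, rowMeans(A), "-")
  sweep(A, 2, colMeans(A), "-")
}

# All n! permutations of 1..n as an n! x n matrix (small n only).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {            # insert value n at each position
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Family-wise p-value adjustment
#'
#' Bonferroni (`min(1, k p)`) or Benjamini-Hochberg step-up adjustment for a
#' family of p-values; input order is preserved.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_family <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
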