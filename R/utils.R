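#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median sd cor dist hclust cutree as.dist
#'   kmeans coef glm binomial p.adjust lm confint pchisq rnorm runif rexp
#'   rbinom predict setNames aggregate var ecdf plogis qlogis dnorm
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shannon diversity of a count vector
#'
#' H = -sum p_i log p_i over the nonzero proportions, with the natural
#' logarithm. Used as the global diversity metric for cell phenotype
#' composition, both per sample and per community subgraph.
#'
#' @param counts Non-negative numeric vector of per-class counts.
#' @return Diversity H (>= 0), or `NA_real_` when the total count is zero.
#' @examples
#' shannon_diversity(c(10, 10, 10, 10))  # log(4)
#' shannon_diversity(42)                 # 0
#' @export
shannon_diversity <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

## cosine similarity between rows of two matrices (or vectors)
cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

## triangular-distribution sampler used for community sizes
rtri <- function(n, min, mode, max) {
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

## derive a per-task seed from a base seed, kept within 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stopifnot_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
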