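#' Derive a reproducible child seed for a pipeline stage
#'
#' A single user seed fans out to per-stage seeds by stable hashing of the
#' stage name, so a stage can be rerun in isolation and reproduce its
#' output exactly.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return A positive integer below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h * 7919) %% (2^31 - 1)) + 1L
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for random
#' agreement.  Used to score subtype-cluster recovery against simulator
#' truth.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

#' Mean silhouette width of a labeling
#'
#' Average silhouette over all points for a given labeling and distance
#' matrix; higher means the labeling matches the geometry.  Used to compare
#' batch versus subtype structure before and after batch-effect removal.
#'
#' @param d A `dist` object or square distance matrix.
#' @param labels Vector of group labels, one per point.
#' @return Numeric scalar (mean silhouette); `NA` if any class is a singleton
#'   relative to the definition (singletons get silhouette 0).
#' @export
mean_silhouette <- function(d, labels) {
  m <- as.matrix(d)
  labels <- as.character(labels)
  stopifnot(nrow(m) == length(labels))
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(m[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(m[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# internal: stop with a classed condition so callers/tests can be precise
abort <- function(msg, class) {
  stop(structure(class = c(class, "tallseq_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
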