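#' Friedman rank test for related samples
#'
#' The nonparametric test for differences among k treatments (e.g. raters)
#' over n blocks (e.g. neurons). Values are mid-ranked within each block;
#' with column rank sums \eqn{R_j},
#' \deqn{\chi^2_F = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1),}
#' divided by the tie-correction factor
#' \eqn{C = 1 - \sum (t^3 - t) / (n (k^3 - k))} when ties occur. The p-value
#' is the upper chi-square tail with k - 1 degrees of freedom. If every block
#' is completely tied the statistic is 0 and p = 1.
#'
#' @param x numeric matrix, n blocks (rows) x k treatments (columns),
#'   n >= 2, k >= 2, no missing cells.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @examples
#' m <- rbind(c(1.2, 2.5, 3.1), c(0.8, 1.9, 2.4))
#' friedmanRankTest(m)   # both blocks ordered the same way: chi^2 = 4
#' @export
friedmanRankTest <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    stop("need at least 2 blocks and 2 treatments", call. = FALSE)
  if (anyNA(x))
    stop("missing cells are not allowed", call. = FALSE)
  ranks <- t(apply(x, 1, rank))     # mid-ranks within each block
  Rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  tieSum <- 0
  for (i in seq_len(n)) {
    tl <- table(x[i, ])
    tieSum <- tieSum + sum(tl^3 - tl)
  }
  C <- 1 - tieSum / (n * (k^3 - k))
  if (C == 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- stat / C
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = stat, df = k - 1L, p.value = p)
}

#' Friedman tests over Sholl profiles
#'
#' For one neuron segmented by several users, blocks are the radii and
#' treatments are the users; radii missing (absent or NA) in any user's
#' profile are dropped listwise before testing.
#'
#' @param profiles list of \linkS4class{ShollProfile}, one per user, sharing
#'   a radius grid (profiles are aligned on the union of radii; radii absent
#'   from any profile are dropped).
#' @return list with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{n_radii} used.
#' @export
friedmanSholl <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  grids <- lapply(profiles, function(p) p@radii)
  common <- Reduce(intersect, grids)
  if (length(common) < 2L)
    stop("fewer than 2 radii shared by all profiles", call. = FALSE)
  m <- vapply(profiles, function(p) {
    p@counts[match(common, p@radii)]
  }, numeric(length(common)))
  res <- friedmanRankTest(m)
  res$n_radii <- length(common)
  res
}
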