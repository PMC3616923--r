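## Pooled two-proportion u statistic and category over-representation.

#' Pooled two-proportion u test
#'
#' Compares the proportion `y1/n1` in a focal set against `y2/n2` in a
#' comparison set with the pooled-variance normal statistic
#' \deqn{u = (\hat p_1 - \hat p_2)/\sigma,\quad
#'   \sigma = \sqrt{\bar p (1-\bar p)(1/n_1 + 1/n_2)},\quad
#'   \bar p = (y_1+y_2)/(n_1+n_2).}
#' When the pooled proportion is degenerate (0 or 1) the statistic is 0
#' and p is 1.
#'
#' @param y1,n1 successes and trials in the focal set.
#' @param y2,n2 successes and trials in the comparison set.
#' @param alternative "two.sided", "greater" (p1 > p2) or "less".
#' @return list of class `proportion_test` with fields y1, n1, y2, n2,
#'   p_hat1, p_hat2, p_bar, sigma, u, p_value, p_two_sided, p_one_sided,
#'   alternative.
#' @export
u_test <- function(y1, n1, y2, n2,
                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 >= 1, n2 >= 1)
  if (y1 > n1 || y2 > n2 || y1 < 0 || y2 < 0) stop("need 0 <= y <= n")
  p1 <- y1 / n1
  p2 <- y2 / n2
  pbar <- (y1 + y2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    sigma <- 0
    u <- 0
    p_two <- 1
    p_gt <- 1
  } else {
    sigma <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    u <- (p1 - p2) / sigma
    p_two <- 2 * pnorm(-abs(u))
    p_gt <- pnorm(u, lower.tail = FALSE)
  }
  p_value <- switch(alternative,
    two.sided = p_two, greater = p_gt, less = 1 - p_gt
  )
  structure(list(
    y1 = y1, n1 = n1, y2 = y2, n2 = n2,
    p_hat1 = p1, p_hat2 = p2, p_bar = pbar, sigma = sigma, u = u,
    p_value = p_value, p_two_sided = p_two,
    p_one_sided = if (u >= 0) p_gt else 1 - p_gt,
    alternative = alternative
  ), class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf(
    "u test: %d/%d (%.3f) vs %d/%d (%.3f): u = %.3f, p(%s) = %.4g\n",
    x$y1, x$n1, x$p_hat1, x$y2, x$n2, x$p_hat2, x$u, x$alternative,
    x$p_value
  ))
  invisible(x)
}

#' Category over-representation in a focal gene set
#'
#' One [u_test()] per category: y1 = focal genes in the category,
#' n1 = focal set size, y2 = background genes in the category,
#' n2 = background size. Benjamini-Hochberg FDR is computed across
#' categories on the two-sided p values; raw one- and two-sided p values
#' are both kept.
#'
#' @param focal character vector of gene ids (subset of background).
#' @param category_map data.frame(gene_id, category_id); a gene may carry
#'   several categories.
#' @param background character vector of gene ids (the universe).
#' @return data.frame(category_id, y1, n1, y2, n2, u, p_one_sided,
#'   p_two_sided, fdr) sorted by p_two_sided.
#' @export
overrepresentation <- function(focal, category_map, background) {
  if (length(focal) == 0) stop("empty focal set")
  if (!all(focal %in% background)) stop("focal set must be within background")
  cats <- unique(category_map$category_id)
  n1 <- length(unique(focal))
  n2 <- length(unique(background))
  rows <- lapply(cats, function(cc) {
    members <- unique(category_map$gene_id[category_map$category_id == cc])
    y1 <- sum(unique(focal) %in% members)
    y2 <- sum(unique(background) %in% members)
    t <- u_test(y1, n1, y2, n2)
    data.frame(
      category_id = cc, y1 = y1, n1 = n1, y2 = y2, n2 = n2,
      u = t$u, p_one_sided = t$p_one_sided, p_two_sided = t$p_two_sided
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_two_sided, method = "BH")
  out[order(out$p_two_sided), , drop = FALSE]
}
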