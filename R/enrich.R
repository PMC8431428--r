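# Hypergeometric over-representation analysis against a user-supplied
# gene-to-term annotation map.

#' Hypergeometric over-representation test
#'
#' For each term with at least `min_term` background genes, tests whether the
#' query set contains more of the term's genes than expected under sampling
#' without replacement: `p = P(X >= k)` for X hypergeometric with `K` term
#' genes among `N` background genes and `n` draws. P-values are BH-adjusted
#' across the tested terms and the table is sorted by p. The rich factor is
#' `k / K`, the fraction of the term captured by the query set.
#'
#' @param gene_set character vector of query gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids (non-empty;
#'   typically all genes in the count matrix, not only the DEG universe).
#' @param annotation named list mapping term ids to gene-id vectors (terms
#'   are intersected with the background).
#' @param alpha significance threshold recorded in the `significant` column.
#' @param min_term minimum term size within the background (default 2;
#'   smaller terms give degenerate tests and are skipped).
#' @return data frame sorted by `p_value` with columns `term_id`, `k`, `K`,
#'   `n`, `N`, `rich_factor`, `p_value`, `p_adj`, `significant`.
#' @examples
#' anno <- list(t1 = c("g1", "g2", "g3", "g4", "g5"))
#' hypergeom_enrich(c("g1", "g2", "g3", "g4"), paste0("g", 1:10), anno)
#' @export
hypergeom_enrich <- function(gene_set, background, annotation, alpha = 0.05,
                             min_term = 2) {
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (length(background) == 0) stop("background must be non-empty")
  offenders <- setdiff(gene_set, background)
  if (length(offenders)) {
    stop("gene_set is not a subset of the background; offenders: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) ", ...")
  }
  N <- length(background)
  n <- length(gene_set)
  terms <- lapply(annotation, function(g) intersect(unique(g), background))
  sizes <- lengths(terms)
  terms <- terms[sizes >= min_term]
  if (length(terms) == 0) {
    return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), rich_factor = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  K <- lengths(terms)
  k <- vapply(terms, function(g) length(intersect(g, gene_set)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = names(terms), k = unname(k), K = unname(K), n = n, N = N,
    rich_factor = unname(k / K), p_value = unname(p),
    p_adj = adjust_bh(unname(p)), stringsAsFactors = FALSE
  )
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
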