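#' Two-sided hypergeometric test
#'
#' Under `X ~ Hypergeometric(N, K, n)` (drawing `n` genes from a universe of
#' `N` of which `K` carry the annotation), the two-sided p-value is the
#' doubled smaller tail, capped at 1:
#' `min(1, 2 * min(P(X >= k), P(X <= k)))`.
#'
#' @param k observed overlap between query and term, `0 <= k <= min(K, n)`.
#' @param K term size.
#' @param n query size.
#' @param N universe size.
#' @return A p-value in (0, 1\].
#' @examples
#' hypergeom_two_sided(5, 5, 5, 10)  # 2/choose(10, 5)
#' @export
hypergeom_two_sided <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    stop("hypergeom_two_sided: require 0 <= k <= min(K, n), K <= N, n <= N")
  }
  p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  min(1, 2 * min(p_over, p_under))
}

#' Bonferroni correction
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @param m number of tests, `m >= length(pvals)`.
#' @return `min(1, m * p)` elementwise, order preserved.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (m < length(pvals)) stop("bonferroni: m must be >= length(pvals)")
  if (any(pvals <= 0 | pvals > 1)) stop("bonferroni: p-values must lie in (0, 1]")
  pmin(1, m * pvals)
}

#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the two membership indicator vectors over
#' the universe: with the 2x2 table (a = both, b = A only, c = B only,
#' d = neither), `p_o = (a + d)/N`, `p_e` the product-marginal expectation,
#' and `kappa = (p_o - p_e) / (1 - p_e)`. When `p_e = 1` (both marginals
#' degenerate) kappa is 1 for identical sets and 0 otherwise.
#'
#' @param genes_a,genes_b character vectors, subsets of `universe`.
#' @param universe non-empty character vector.
#' @return A number in \[-1, 1\].
#' @export
kappa_score <- function(genes_a, genes_b, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("kappa_score: empty universe")
  genes_a <- unique(as.character(genes_a))
  genes_b <- unique(as.character(genes_b))
  if (!all(genes_a %in% universe) || !all(genes_b %in% universe)) {
    stop("kappa_score: sets must be subsets of the universe")
  }
  N <- length(universe)
  a <- length(intersect(genes_a, genes_b))
  b <- length(setdiff(genes_a, genes_b))
  c <- length(setdiff(genes_b, genes_a))
  d <- N - a - b - c
  p_o <- (a + d) / N
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (p_e >= 1) return(if (b == 0 && c == 0) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Hypergeometric enrichment of a gene query
#'
#' One two-sided hypergeometric test per annotation term with non-zero
#' overlap, Bonferroni-corrected over the number of tested terms (or over
#' all annotation terms when `m_all_terms = TRUE`), filtered at
#' `p_bonferroni < alpha`.
#'
#' @param query character vector of gene identifiers. Genes outside the
#'   annotation universe are dropped with a warning.
#' @param annotation an [annotation_set].
#' @param alpha significance threshold on the Bonferroni-corrected p-value.
#' @param m_all_terms logical; if `TRUE` the Bonferroni factor is the total
#'   number of annotation terms rather than the number of tested
#'   (overlapping) terms.
#' @return A data frame of class `enrichment_result`, sorted by ascending
#'   `p_two_sided`, with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_two_sided`, `p_bonferroni`, `genes` (list column of query
#'   hits).
#' @export
enrich <- function(query, annotation, alpha = 0.05, m_all_terms = FALSE) {
  stopifnot(inherits(annotation, "annotation_set"))
  query <- unique(as.character(query))
  if (!length(query)) stop("enrich: empty query")
  outside <- setdiff(query, annotation$universe)
  if (length(outside)) {
    warning(sprintf("enrich: dropped %d query gene(s) outside the universe",
                    length(outside)))
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("enrich: no query gene in the universe")
  N <- length(annotation$universe)
  n <- length(query)
  hits <- lapply(annotation$terms, intersect, x = query)
  tested <- names(hits)[lengths(hits) >= 1]
  m <- if (m_all_terms) length(annotation$terms) else length(tested)
  rows <- lapply(tested, function(id) {
    k <- length(hits[[id]]); K <- length(annotation$terms[[id]])
    p <- hypergeom_two_sided(k, K, n, N)
    data.frame(term_id = id, term_name = unname(annotation$term_names[id]),
               k = k, K = K, n = n, N = N, p_two_sided = p,
               p_bonferroni = min(1, m * p))
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), term_name = character(), k = integer(),
               K = integer(), n = integer(), N = integer(),
               p_two_sided = numeric(), p_bonferroni = numeric())
  res$genes <- unname(hits[res$term_id])
  res <- res[res$p_bonferroni < alpha, , drop = FALSE]
  res <- res[order(res$p_two_sided, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Group enriched terms by kappa similarity
#'
#' Builds a term graph with an edge wherever the kappa score between two
#' terms' query-hit sets (over the annotation universe) reaches
#' `kappa_threshold`, and takes connected components as groups. Groups are
#' numbered from 0 in descending size, ties broken by the lexicographically
#' smallest member term.
#'
#' @param records an `enrichment_result` data frame from [enrich()] (or any
#'   data frame with a `term_id` column and a `genes` list column of query
#'   hits).
#' @param universe the gene universe over which kappa is computed.
#' @param kappa_threshold edge threshold, default 0.4.
#' @return A list of term groups; each is a list with `group_id` (integer,
#'   from 0), `member_terms` (sorted), `associated_genes` (sorted union of
#'   member hits).
#' @export
group_terms <- function(records, universe, kappa_threshold = 0.4) {
  stopifnot(is.data.frame(records), "term_id" %in% names(records),
            "genes" %in% names(records))
  ids <- records$term_id
  hits <- stats::setNames(records$genes, ids)
  nt <- length(ids)
  if (!nt) return(list())
  comp <- seq_len(nt)  # union-find over term indices
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nt > 1) {
    for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
      if (kappa_score(hits[[i]], hits[[j]], universe) >= kappa_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(nt), find, 0L)
  groups <- split(ids, root)
  leader <- vapply(groups, function(g) sort(g)[1], "")
  ord <- order(-lengths(groups), leader)
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) {
    members <- sort(groups[[i]])
    list(group_id = i - 1L,
         member_terms = members,
         associated_genes = sort(unique(unlist(hits[members]))))
  })
}

#' Write term groups to a TSV table
#'
#' One row per (group, term): `group_id`, `term_id`, `term_name`, `k`, `K`,
#' `n`, `N`, `p`, `p_bonf`, `associated_genes` (semicolon-joined union over
#' the group).
#'
#' @param groups from [group_terms()].
#' @param records the `enrichment_result` the groups were built from.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, records, path) {
  rows <- list()
  for (gr in groups) {
    for (tid in gr$member_terms) {
      r <- records[records$term_id == tid, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        group_id = gr$group_id, term_id = tid, term_name = r$term_name[1],
        k = r$k[1], K = r$K[1], n = r$n[1], N = r$N[1],
        p = r$p_two_sided[1], p_bonf = r$p_bonferroni[1],
        associated_genes = paste(gr$associated_genes, collapse = ";"))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = integer(), term_id = character(),
               term_name = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p = numeric(),
               p_bonf = numeric(), associated_genes = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
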