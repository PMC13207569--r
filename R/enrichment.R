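#' Signed hypergeometric enrichment/depletion of effect alleles
#'
#' For each (population, locus): the population's 2n chromosomes are modeled
#' as a draw without replacement from the pooled 2N chromosomes of which C
#' carry the effect allele, so the expected count is E = 2n*C/(2N). The raw
#' p-value is the single enrichment tail P(X >= c) when c >= E, else the
#' depletion tail P(X <= c). P-values are Benjamini-Hochberg adjusted across
#' all population x locus cells jointly, and transformed into signed scores
#' s = sign(c - E) * min(-log10(q), cap) (cells at exactly E score 0).
#'
#' @param freqs an \code{allele_freq_table} at one analysis level.
#' @param reference \code{"pooled"} (default): expectation from the pooled
#'   sample including the population itself; \code{"complement"}: expectation
#'   from the remaining populations only (the standard 2x2 layout). The
#'   hypergeometric tail itself is identical in both cases; the reference
#'   only determines E and hence the direction.
#' @param fdr significance threshold on the adjusted p (default 0.05).
#' @param cap cap on |score| (default 5).
#' @return data.frame of class \code{enrichment_result}, one row per cell:
#'   population, rsid, count, chroms, total_count, total_chroms, expected,
#'   p, q_adj, score, significant.
#' @export
hypergeom_enrichment <- function(freqs, reference = c("pooled", "complement"),
                                 fdr = 0.05, cap = 5) {
  reference <- match.arg(reference)
  cnt <- freq_matrix(freqs, "count")
  chr <- freq_matrix(freqs, "chroms")
  C <- colSums(cnt)          # pooled effect copies per locus
  N2 <- colSums(chr)         # pooled chromosomes per locus
  if (any(chr == rep(N2, each = nrow(chr))))
    stop("a population equals the full sample; enrichment is undefined")
  long <- data.frame(
    population = rep(rownames(cnt), times = ncol(cnt)),
    rsid = rep(colnames(cnt), each = nrow(cnt)),
    count = as.vector(cnt),
    chroms = as.vector(chr),
    total_count = rep(C, each = nrow(cnt)),
    total_chroms = rep(N2, each = nrow(cnt)),
    stringsAsFactors = FALSE)
  long$expected <- if (reference == "pooled") {
    long$chroms * long$total_count / long$total_chroms
  } else {
    long$chroms * (long$total_count - long$count) /
      (long$total_chroms - long$chroms)
  }
  delta <- long$count - long$expected
  up <- stats::phyper(long$count - 1, long$total_count,
                      long$total_chroms - long$total_count, long$chroms,
                      lower.tail = FALSE)
  down <- stats::phyper(long$count, long$total_count,
                        long$total_chroms - long$total_count, long$chroms)
  long$p <- ifelse(delta >= 0, up, down)
  long$q_adj <- stats::p.adjust(long$p, method = "BH")
  long$score <- sign(delta) * pmin(-log10(long$q_adj), cap)
  long$significant <- long$q_adj < fdr
  attr(long, "level") <- attr(freqs, "level")
  attr(long, "rsid_order") <- attr(freqs, "rsid_order")
  attr(long, "reference") <- reference
  class(long) <- c("enrichment_result", "data.frame")
  long
}

#' Score matrix of an enrichment result
#'
#' @param enr an [hypergeom_enrichment()] result.
#' @param what column to spread (default \code{"score"}).
#' @return populations x loci matrix.
#' @export
enrichment_matrix <- function(enr, what = "score") {
  pops <- unique(enr$population)
  rsids <- attr(enr, "rsid_order") %||% unique(enr$rsid)
  m <- matrix(NA_real_, length(pops), length(rsids),
              dimnames = list(pops, rsids))
  m[cbind(match(enr$population, pops), match(enr$rsid, rsids))] <- enr[[what]]
  m
}

#' Leaf orders from average-linkage correlation clustering
#'
#' Rows (populations) and columns (loci) are clustered independently by
#' hierarchical agglomerative clustering with average linkage on the distance
#' 1 - Pearson correlation. Zero-variance rows/columns (correlation
#' undefined) are placed last. Single-row or single-column matrices get the
#' identity order.
#'
#' @param mat numeric matrix (e.g. from [enrichment_matrix()]).
#' @return list with integer vectors \code{row_order} and \code{col_order}.
#' @export
cluster_orders <- function(mat) {
  list(row_order = cor_leaf_order(mat),
       col_order = cor_leaf_order(t(mat)))
}

cor_leaf_order <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(seq_len(n))
  s <- apply(m, 1, stats::sd)
  degenerate <- which(is.na(s) | s == 0)
  ok <- setdiff(seq_len(n), degenerate)
  if (length(ok) < 2L) return(unname(c(ok, degenerate)))
  d <- stats::as.dist(1 - stats::cor(t(m[ok, , drop = FALSE])))
  ord <- stats::hclust(d, method = "average")$order
  unname(c(ok[ord], degenerate))
}
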