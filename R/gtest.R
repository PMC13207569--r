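# --- exact G-based tests of genic / genotypic differentiation -------------
#
# Null: the two populations share the same allelic (genic) or genotypic
# composition. Conditioning on both margins of the counts table, the exact
# p-value is the probability of tables with G >= G_observed, where
# G = 2 * sum(O * ln(O/E)). Small supports are fully enumerated; larger
# genotypic tables fall back to a Metropolis Markov chain over tables with
# fixed margins (batch means give a standard error on p).

g_statistic <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  o <- tab[tab > 0]
  2 * sum(o * log(o / e[tab > 0]))
}

# log conditional probability of a table given fixed margins (independence)
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# enumerate all R x 2 tables with the margins of `tab`; returns exact
# P(G >= G_obs)
enumerate_exact_p <- function(tab, g_obs) {
  rs <- rowSums(tab); cs <- colSums(tab)
  R <- nrow(tab)
  acc <- 0; tot <- 0
  recurse <- function(i, remaining, col1) {
    if (i == R) {
      x <- remaining
      if (x > rs[R]) return()
      t2 <- cbind(c(col1, x), rs - c(col1, x))
      lp <- log_table_prob(t2)
      p <- exp(lp)
      tot <<- tot + p
      if (g_statistic(t2) >= g_obs - 1e-9) acc <<- acc + p
      return()
    }
    for (x in 0:min(rs[i], remaining)) recurse(i + 1L, remaining - x,
                                               c(col1, x))
  }
  recurse(1L, cs[1], numeric(0))
  acc / tot   # normalization guards rounding; tot == 1 analytically
}

# upper bound on the number of tables with these margins (R x 2)
table_support_bound <- function(tab) {
  rs <- rowSums(tab); c1 <- sum(tab[, 1])
  prod(pmin(rs, c1) + 1)
}

# Metropolis chain over R x 2 tables with fixed margins
mcmc_exact_p <- function(tab, g_obs, dememorization = 10000L,
                         batches = 100L, iter_per_batch = 5000L, seed = 1L) {
  set.seed(seed)
  R <- nrow(tab)
  cur <- tab
  step <- function(cur) {
    ij <- sample.int(R, 2L)
    i <- ij[1]; k <- ij[2]
    # move one unit between columns in rows i and k, margins preserved
    if (cur[i, 1] < 1L || cur[k, 2] < 1L) return(cur)
    ratio <- (cur[i, 1] * cur[k, 2]) /
      ((cur[i, 2] + 1) * (cur[k, 1] + 1))
    if (stats::runif(1) < ratio) {
      cur[i, 1] <- cur[i, 1] - 1L; cur[i, 2] <- cur[i, 2] + 1L
      cur[k, 1] <- cur[k, 1] + 1L; cur[k, 2] <- cur[k, 2] - 1L
    }
    cur
  }
  for (s in seq_len(dememorization)) cur <- step(cur)
  batch_means <- numeric(batches)
  for (b in seq_len(batches)) {
    hit <- 0L
    for (s in seq_len(iter_per_batch)) {
      cur <- step(cur)
      if (g_statistic(cur) >= g_obs - 1e-9) hit <- hit + 1L
    }
    batch_means[b] <- hit / iter_per_batch
  }
  list(p = mean(batch_means),
       se = stats::sd(batch_means) / sqrt(batches))
}

# counts table for one locus and two groups: genic = alleles x pops (2x2),
# genotypic = genotypes x pops (3x2)
locus_table <- function(d1, d2, flavor) {
  if (flavor == "genic") {
    rbind(effect = c(sum(d1), sum(d2)),
          other = c(2 * length(d1) - sum(d1), 2 * length(d2) - sum(d2)))
  } else {
    rbind(hom_other = c(sum(d1 == 0L), sum(d2 == 0L)),
          het = c(sum(d1 == 1L), sum(d2 == 1L)),
          hom_effect = c(sum(d1 == 2L), sum(d2 == 2L)))
  }
}

#' Exact G-test of genic or genotypic differentiation between two populations
#'
#' Per locus, tests homogeneity of allele counts (genic: 2 alleles x 2
#' populations) or genotype counts (genotypic: 3 genotypes x 2 populations)
#' with the log-likelihood-ratio statistic G over the exact conditional null
#' (fixed margins). Exact by full enumeration when the table support is below
#' \code{enumeration_bound}; otherwise by a Markov chain with the given
#' dememorization / batch schedule, whose batch spread yields a standard
#' error on p. Loci monomorphic in both populations are skipped. Per-locus
#' p-values are combined by Fisher's method: X2 = -2 sum(ln p) on 2L' df.
#'
#' @param dm a \code{dosage_matrix}.
#' @param level analysis level.
#' @param pair character vector of two population names.
#' @param flavor \code{"genic"} or \code{"genotypic"}.
#' @param enumeration_bound max table-support size enumerated exactly
#'   (default 1e6).
#' @param mc list of Markov-chain settings: \code{dememorization} (10000),
#'   \code{batches} (100), \code{iter_per_batch} (5000).
#' @param seed integer seed for the Markov chain.
#' @return list of class \code{g_test_result}: \code{per_locus} data.frame
#'   (rsid, G, p, se, method, skipped), \code{combined} list (X2, df, p),
#'   \code{pair}, \code{flavor}.
#' @export
exact_g_test <- function(dm, level = c("superpop", "subpop"), pair,
                         flavor = c("genic", "genotypic"),
                         enumeration_bound = 1e6,
                         mc = list(dememorization = 10000L, batches = 100L,
                                   iter_per_batch = 5000L),
                         seed = 1L) {
  level <- match.arg(level)
  flavor <- match.arg(flavor)
  stopifnot(length(pair) == 2L)
  g <- group_labels(dm, level)
  if (!all(pair %in% g)) stop("unknown population in pair")
  rows <- lapply(seq_len(ncol(dm$dosage)), function(j) {
    d1 <- dm$dosage[g == pair[1], j]
    d2 <- dm$dosage[g == pair[2], j]
    tab <- locus_table(d1, d2, flavor)
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
    rsid <- colnames(dm$dosage)[j]
    if (nrow(tab) < 2L)  # monomorphic in both populations: uninformative
      return(data.frame(rsid = rsid, G = NA_real_, p = NA_real_,
                        se = NA_real_, method = "skipped", skipped = TRUE,
                        stringsAsFactors = FALSE))
    g_obs <- g_statistic(tab)
    if (table_support_bound(tab) <= enumeration_bound) {
      data.frame(rsid = rsid, G = g_obs, p = enumerate_exact_p(tab, g_obs),
                 se = 0, method = "enumeration", skipped = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      est <- mcmc_exact_p(tab, g_obs, mc$dememorization, mc$batches,
                          mc$iter_per_batch, seed = seed + j)
      data.frame(rsid = rsid, G = g_obs, p = est$p, se = est$se,
                 method = "mcmc", skipped = FALSE, stringsAsFactors = FALSE)
    }
  })
  per_locus <- do.call(rbind, rows)
  inf <- per_locus[!per_locus$skipped, ]
  combined <- if (nrow(inf)) {
    x2 <- -2 * sum(log(pmax(inf$p, .Machine$double.xmin)))
    df <- 2L * nrow(inf)
    list(X2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
  } else list(X2 = NA_real_, df = 0L, p = NA_real_)
  structure(list(per_locus = per_locus, combined = combined, pair = pair,
                 flavor = flavor), class = "g_test_result")
}
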