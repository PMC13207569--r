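#' Per-population effect-allele frequencies
#'
#' Counts effect-allele copies per population at each locus: c = sum of
#' dosages in the group, over 2n chromosomes (2 x group size), p = c/(2n).
#'
#' @param dm a \code{dosage_matrix}.
#' @param level analysis level: \code{"superpop"} or \code{"subpop"}.
#' @return data.frame of class \code{allele_freq_table} with columns
#'   \code{population}, \code{rsid}, \code{count}, \code{chroms}, \code{p},
#'   \code{q}; the analysis level is kept as attribute \code{level}.
#' @export
allele_frequencies <- function(dm, level = c("superpop", "subpop")) {
  level <- match.arg(level)
  g <- group_labels(dm, level)
  if (any(table(g) == 0L)) stop("empty population group")
  counts <- rowsum(dm$dosage, g)            # pops x loci effect-allele copies
  sizes <- as.vector(table(g)[rownames(counts)])
  out <- data.frame(
    population = rep(rownames(counts), times = ncol(counts)),
    rsid = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts),
    chroms = rep(2L * sizes, times = ncol(counts)),
    stringsAsFactors = FALSE)
  out$p <- out$count / out$chroms
  out$q <- 1 - out$p
  attr(out, "level") <- level
  attr(out, "rsid_order") <- colnames(counts)
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

# pops x loci matrix of a column of an allele_freq_table
freq_matrix <- function(freqs, what = "p") {
  pops <- unique(freqs$population)
  rsids <- attr(freqs, "rsid_order") %||% unique(freqs$rsid)
  m <- matrix(NA_real_, length(pops), length(rsids),
              dimnames = list(pops, rsids))
  m[cbind(match(freqs$population, pops), match(freqs$rsid, rsids))] <-
    freqs[[what]]
  m
}

#' Monomorphism census
#'
#' A locus is fixed (monomorphic) in a population iff the effect-allele count
#' is 0 or equals the chromosome count. Reports per-population totals and the
#' full population x locus fixation mask; use [fixed_in()] to query loci fixed
#' in arbitrary population sets.
#'
#' @param freqs an \code{allele_freq_table}.
#' @return list of class \code{monomorph_census}: \code{per_population}
#'   (data.frame population, n_fixed) and \code{fixed} (logical matrix).
#' @export
monomorph_census <- function(freqs) {
  cnt <- freq_matrix(freqs, "count")
  chr <- freq_matrix(freqs, "chroms")
  fixed <- cnt == 0L | cnt == chr
  per_pop <- data.frame(population = rownames(fixed),
                        n_fixed = rowSums(fixed),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_population = per_pop, fixed = fixed),
            class = "monomorph_census")
}

#' Loci fixed in a configurable set of populations
#'
#' @param census a [monomorph_census()].
#' @param pops populations that must all show fixation; default all.
#' @param except populations that must NOT show fixation (e.g. "fixed in all
#'   populations except EUR").
#' @return character vector of locus identifiers.
#' @export
fixed_in <- function(census, pops = rownames(census$fixed), except = NULL) {
  f <- census$fixed
  pops <- setdiff(pops, except)
  sel <- colSums(f[pops, , drop = FALSE]) == length(pops)
  if (!is.null(except))
    sel <- sel & colSums(f[except, , drop = FALSE]) == 0L
  colnames(f)[sel]
}

# exact Hardy-Weinberg p-value: two-sided by probability mass over all
# heterozygote counts compatible with the observed allele counts
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  hets <- seq(nA %% 2L, min(nA, na), by = 2L)
  # P(n_Aa = h | n, nA) = n! 2^h nA! na! / (nAA! h! naa! (2n)!)
  logp <- lfactorial(n) + hets * log(2) + lfactorial(nA) + lfactorial(na) -
    lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# chi-square goodness-of-fit HWE test, 1 df, no continuity correction
hwe_chisq_pvalue <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg equilibrium tests per population and locus
#'
#' The default flavor is the exact conditional test: full enumeration of
#' heterozygote counts given the allele counts, two-sided by probability mass.
#' A 1-df chi-square flavor is available for comparison. Monomorphic loci get
#' p = 1 by convention.
#'
#' @param dm a \code{dosage_matrix}.
#' @param level analysis level.
#' @param flavor \code{"exact"} (default) or \code{"chisq"}.
#' @return data.frame of class \code{hwe_result}: population, rsid, genotype
#'   counts, p_value, flavor.
#' @export
hwe_test <- function(dm, level = c("superpop", "subpop"),
                     flavor = c("exact", "chisq")) {
  level <- match.arg(level)
  flavor <- match.arg(flavor)
  g <- group_labels(dm, level)
  pops <- sort(unique(g))
  pfun <- if (flavor == "exact") hwe_exact_pvalue else hwe_chisq_pvalue
  res <- lapply(pops, function(pop) {
    d <- dm$dosage[g == pop, , drop = FALSE]
    n_aa <- colSums(d == 0L)  # homozygous other allele
    n_Aa <- colSums(d == 1L)
    n_AA <- colSums(d == 2L)  # homozygous effect allele
    p <- vapply(seq_len(ncol(d)),
                function(j) pfun(n_AA[j], n_Aa[j], n_aa[j]), numeric(1))
    data.frame(population = pop, rsid = colnames(d),
               n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
               p_value = p, flavor = flavor,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "level") <- level
  class(out) <- c("hwe_result", "data.frame")
  out
}

#' Count loci departing from Hardy-Weinberg equilibrium per population
#'
#' @param hwe an [hwe_test()] result.
#' @param alpha per-test significance threshold (default 0.05, uncorrected).
#' @param adjust \code{"none"} (default) or \code{"BH"} for a
#'   Benjamini-Hochberg correction within each population before counting.
#' @return data.frame: population, n_tested, n_departing.
#' @export
hwe_departures <- function(hwe, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- lapply(split(hwe, hwe$population), function(h) {
    p <- h$p_value
    if (adjust == "BH") p <- stats::p.adjust(p, "BH")
    data.frame(population = h$population[1], n_tested = length(p),
               n_departing = sum(p < alpha), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-population diversity summary
#'
#' Per locus and population: observed heterozygosity Ho = n_het/n, expected
#' heterozygosity He = 2pq, Shannon's information index
#' I = -(p ln p + q ln q) (natural log, with 0 ln 0 = 0), and the fixation
#' index F = (He - Ho)/He where He > 0 (undefined at monomorphic loci).
#' Population summaries are the mean with its standard error (SD/sqrt(L'))
#' over loci, excluding undefined values for F only.
#'
#' @param dm a \code{dosage_matrix}.
#' @param level analysis level.
#' @return list of class \code{diversity_summary}: \code{per_locus}
#'   data.frame (population, rsid, Ho, He, I, F) and \code{summary}
#'   data.frame with mean, SE and SD of each index per population.
#' @export
diversity <- function(dm, level = c("superpop", "subpop")) {
  level <- match.arg(level)
  g <- group_labels(dm, level)
  pops <- sort(unique(g))
  per <- lapply(pops, function(pop) {
    d <- dm$dosage[g == pop, , drop = FALSE]
    n <- nrow(d)
    p <- colMeans(d) / 2
    q <- 1 - p
    Ho <- colMeans(d == 1L)
    He <- 2 * p * q
    xlx <- function(x) ifelse(x > 0, x * log(x), 0)
    I <- -(xlx(p) + xlx(q))
    F <- ifelse(He > 0, (He - Ho) / He, NA_real_)
    data.frame(population = pop, rsid = colnames(d), Ho = Ho, He = He,
               I = I, F = F, row.names = NULL, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
      sd = stats::sd(x), n = length(x))
  }
  summ <- do.call(rbind, lapply(split(per, per$population), function(h) {
    s <- cbind(Ho = msd(h$Ho), He = msd(h$He), I = msd(h$I), F = msd(h$F))
    data.frame(population = h$population[1],
               Ho_mean = s["mean", "Ho"], Ho_se = s["se", "Ho"],
               Ho_sd = s["sd", "Ho"],
               He_mean = s["mean", "He"], He_se = s["se", "He"],
               He_sd = s["sd", "He"],
               I_mean = s["mean", "I"], I_se = s["se", "I"],
               I_sd = s["sd", "I"],
               F_mean = s["mean", "F"], F_se = s["se", "F"],
               F_sd = s["sd", "F"], F_n = s["n", "F"],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_locus = per, summary = summ, level = level),
            class = "diversity_summary")
}
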