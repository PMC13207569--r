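# build a dosage_matrix from a plain dosage matrix and group labels
make_dm <- function(dosage, groups, superpops = groups, sex = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  panel <- data.frame(
    sample = sprintf("s%03d", seq_len(n)),
    subpop = as.character(groups),
    superpop = as.character(superpops),
    sex = if (is.null(sex)) rep(NA_character_, n) else sex,
    stringsAsFactors = FALSE)
  class(panel) <- c("sample_panel", "data.frame")
  loci <- data.frame(
    rsid = sprintf("snp%04d", seq_len(ncol(dosage))),
    chrom = "1", pos = 1000L * seq_len(ncol(dosage)),
    effect_allele = "A", other_allele = "G", beta = NA_real_,
    stringsAsFactors = FALSE)
  class(loci) <- c("locus_table", "data.frame")
  dimnames(dosage) <- list(panel$sample, loci$rsid)
  locusdiff:::new_dosage_matrix(dosage, loci, panel)
}

# allele_freq_table from explicit frequencies and chromosome counts
make_freqs <- function(p, chroms) {
  p <- as.matrix(p)  # pops x loci
  if (is.null(rownames(p))) rownames(p) <- paste0("P", seq_len(nrow(p)))
  if (is.null(colnames(p))) colnames(p) <- sprintf("snp%04d", seq_len(ncol(p)))
  chroms <- if (length(chroms) == 1) rep(chroms, nrow(p)) else chroms
  out <- data.frame(
    population = rep(rownames(p), times = ncol(p)),
    rsid = rep(colnames(p), each = nrow(p)),
    count = as.vector(round(p * chroms)),
    chroms = rep(chroms, times = ncol(p)),
    stringsAsFactors = FALSE)
  out$p <- out$count / out$chroms
  out$q <- 1 - out$p
  attr(out, "level") <- "subpop"
  attr(out, "rsid_order") <- colnames(p)
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

# the 26 subpopulation codes of the two-level panel, with superpopulation and
# cohort size (standard phase-3 metadata; sizes sum to 2504)
panel_1kg_layout <- function() {
  data.frame(
    subpop = c("ACB","ASW","ESN","GWD","LWK","MSL","YRI",
               "CLM","MXL","PEL","PUR",
               "CEU","FIN","GBR","IBS","TSI",
               "CDX","CHB","CHS","JPT","KHV",
               "BEB","GIH","ITU","PJL","STU"),
    superpop = rep(c("AFR","AMR","EUR","EAS","SAS"), c(7, 4, 5, 5, 5)),
    size = c(96,61,99,113,99,85,108, 94,64,85,104, 99,99,91,107,107,
             93,103,105,104,99, 86,103,102,96,102),
    stringsAsFactors = FALSE)
}

write_1kg_panel <- function(path) {
  lay <- panel_1kg_layout()
  rows <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i) {
    data.frame(sample = sprintf("%s%04d", lay$subpop[i], seq_len(lay$size[i])),
               pop = lay$subpop[i], super_pop = lay$superpop[i],
               gender = rep_len(c("male", "female"), lay$size[i]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent exact-HWE oracle: P(h hets) = C(n,a) C(n-a,h) 2^h / C(2n, nA),
# two-sided by probability mass (formulated via binomial coefficients, unlike
# the implementation's log-factorial route)
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    choose(n, a) * choose(n - a, h) * 2^h / choose(2 * n, nA)
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# independent exact G-test oracle for 2x2 tables via the hypergeometric pmf
oracle_g_exact_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  gstat <- function(t2) {
    e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    2 * sum(t2[t2 > 0] * log(t2[t2 > 0] / e[t2 > 0]))
  }
  g_obs <- gstat(tab)
  xs <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  pr <- stats::dhyper(xs, rs[1], rs[2], cs[1])
  gs <- vapply(xs, function(x)
    gstat(rbind(c(x, rs[1] - x), c(cs[1] - x, rs[2] - cs[1] + x))),
    numeric(1))
  sum(pr[gs >= g_obs - 1e-9])
}

# brute-force average-linkage merge heights on a distance matrix
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); besth <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < besth) { besth <- h; best <- c(i, j) }
    }
    heights <- c(heights, besth)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
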