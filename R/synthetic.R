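#' Simulation configuration for multi-population genotype data
#'
#' Describes a Balding-Nichols simulation: per locus an ancestral effect-allele
#' frequency p is drawn from \code{ancestral_freq}, each population's frequency
#' is drawn from a Beta distribution with mean p and variance p(1-p)*FST
#' (shape parameters p(1-FST)/FST and (1-p)(1-FST)/FST), and diploid genotypes
#' are two independent allele draws (Hardy-Weinberg proportions within
#' populations).
#'
#' @param n_pops number of populations.
#' @param pop_sizes integer vector of population sizes (all >= 1); recycled to
#'   \code{n_pops} if scalar.
#' @param n_loci number of biallelic loci.
#' @param ancestral_freq either a numeric vector of length \code{n_loci} of
#'   explicit ancestral frequencies, or a length-2 range \code{c(low, high)}
#'   to draw them uniformly from. Default \code{c(0.1, 0.9)}.
#' @param fst divergence parameter in [0,1) per population (recycled).
#'   \code{fst = 0} gives every population the ancestral frequency exactly.
#' @param fixed_loci optional data.frame with columns \code{locus} (1-based
#'   index), \code{pop} (1-based index), \code{allele} ("effect" or "other"):
#'   forces that population's frequency at that locus to 1 or 0.
#' @param beta_law optional function(n) drawing n per-locus effect sizes; when
#'   supplied the simulated locus table carries betas.
#' @param superpops optional character vector of length \code{n_pops} giving a
#'   two-level layout (subpopulations nested in superpopulations); by default
#'   each simulated population is its own subpopulation and superpopulation.
#' @param seed integer seed (mandatory; all randomness derives from it through
#'   per-locus, per-population substreams so that adding loci or populations
#'   does not perturb earlier draws).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_pops, pop_sizes, n_loci,
                       ancestral_freq = c(0.1, 0.9), fst = 0.1,
                       fixed_loci = NULL, beta_law = NULL,
                       superpops = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  pop_sizes <- rep_len(as.integer(pop_sizes), n_pops)
  fst <- rep_len(as.numeric(fst), n_pops)
  stopifnot(n_pops >= 1, all(pop_sizes >= 1L), n_loci >= 1,
            all(fst >= 0 & fst < 1))
  if (length(ancestral_freq) == n_loci && n_loci != 2) {
    stopifnot(all(ancestral_freq >= 0 & ancestral_freq <= 1))
  } else if (length(ancestral_freq) != 2) {
    stop("ancestral_freq must be a (low, high) range or one value per locus")
  }
  if (!is.null(fixed_loci)) {
    stopifnot(all(c("locus", "pop", "allele") %in% names(fixed_loci)))
    if (any(fixed_loci$locus < 1 | fixed_loci$locus > n_loci) ||
        any(fixed_loci$pop < 1 | fixed_loci$pop > n_pops))
      stop("fixed_loci index out of range")
    if (!all(fixed_loci$allele %in% c("effect", "other")))
      stop("fixed_loci allele must be 'effect' or 'other'")
  }
  if (!is.null(superpops)) stopifnot(length(superpops) == n_pops)
  structure(list(n_pops = n_pops, pop_sizes = pop_sizes, n_loci = n_loci,
                 ancestral_freq = ancestral_freq, fst = fst,
                 fixed_loci = fixed_loci, beta_law = beta_law,
                 superpops = superpops, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic substream seed for (locus, pop, purpose); stays below 2^31
substream_seed <- function(seed, locus, pop, purpose) {
  x <- (as.double(seed) %% 2147483647) * 48271 +
    locus * 104729 + pop * 1299709 + purpose * 15485863
  as.integer(x %% 2147483647)
}

#' Simulate a multi-population genotype dataset with known truth
#'
#' @param config a [sim_config()].
#' @return a list with elements \code{dosage} (a \code{dosage_matrix}),
#'   \code{panel}, \code{loci}, and \code{truth} (class \code{sim_truth}: the
#'   n_pops x n_loci matrix of true effect-allele frequencies plus the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_pops; L <- config$n_loci
  pop_names <- sprintf("POP%d", seq_len(K))
  superpops <- config$superpops %||% pop_names

  # ancestral frequencies, one substream per locus
  anc <- if (length(config$ancestral_freq) == L && L != 2) {
    config$ancestral_freq
  } else {
    lo <- config$ancestral_freq[1]; hi <- config$ancestral_freq[2]
    vapply(seq_len(L), function(l) {
      set.seed(substream_seed(config$seed, l, 0L, 1L))
      stats::runif(1, lo, hi)
    }, numeric(1))
  }

  freq <- matrix(NA_real_, K, L, dimnames = list(pop_names, NULL))
  for (l in seq_len(L)) {
    p <- anc[l]
    for (k in seq_len(K)) {
      f <- config$fst[k]
      freq[k, l] <- if (f == 0 || p == 0 || p == 1) p else {
        set.seed(substream_seed(config$seed, l, k, 2L))
        stats::rbeta(1, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      }
    }
  }
  if (!is.null(config$fixed_loci)) {
    for (r in seq_len(nrow(config$fixed_loci))) {
      fl <- config$fixed_loci[r, ]
      freq[fl$pop, fl$locus] <- if (fl$allele == "effect") 1 else 0
    }
  }

  n_tot <- sum(config$pop_sizes)
  sample_ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("%s_%04d", pop_names[k], seq_len(config$pop_sizes[k]))))
  panel <- data.frame(
    sample = sample_ids,
    subpop = rep(pop_names, config$pop_sizes),
    superpop = rep(superpops, config$pop_sizes),
    sex = rep(NA_character_, n_tot),
    stringsAsFactors = FALSE)
  class(panel) <- c("sample_panel", "data.frame")

  dosage <- matrix(0L, n_tot, L, dimnames = list(sample_ids, NULL))
  offs <- c(0L, cumsum(config$pop_sizes))
  for (l in seq_len(L)) {
    for (k in seq_len(K)) {
      n <- config$pop_sizes[k]
      set.seed(substream_seed(config$seed, l, k, 3L))
      # two independent allele draws per individual: HWE by construction
      dosage[(offs[k] + 1L):offs[k + 1L], l] <-
        stats::rbinom(n, 2L, freq[k, l])
    }
  }

  beta <- if (is.null(config$beta_law)) rep(NA_real_, L) else {
    set.seed(substream_seed(config$seed, 0L, 0L, 4L))
    config$beta_law(L)
  }
  loci <- data.frame(
    rsid = sprintf("snp%05d", seq_len(L)),
    chrom = "1",
    pos = 1000L * seq_len(L),
    effect_allele = "A",
    other_allele = "G",
    beta = beta,
    stringsAsFactors = FALSE)
  class(loci) <- c("locus_table", "data.frame")
  colnames(dosage) <- loci$rsid

  truth <- structure(list(freq = freq, config = config), class = "sim_truth")
  list(dosage = new_dosage_matrix(dosage, loci, panel),
       panel = panel, loci = loci, truth = truth)
}

#' Write a simulated dataset as VCF + panel + locus-table fixture files
#'
#' Emits exactly the three formats [build_dosage_matrix()] and friends read,
#' with an exact dosage round-trip: the VCF stores the other allele as REF and
#' the effect allele as ALT, genotypes unphased.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, named paths of the three files written.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             panel = file.path(dir, "panel.tsv"),
             loci = file.path(dir, "loci.tsv"))
  write_vcf(dataset$dosage, paths["vcf"])
  panel <- dataset$panel
  utils::write.table(
    data.frame(sample = panel$sample, pop = panel$subpop,
               super_pop = panel$superpop,
               gender = ifelse(is.na(panel$sex), "unknown", panel$sex)),
    paths["panel"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$loci, paths["loci"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# minimal VCF 4.1 writer for diploid GT-only fixtures
write_vcf <- function(dm, path) {
  stopifnot(inherits(dm, "dosage_matrix"))
  loci <- dm$loci
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##source=locusdiff_synthetic",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dm$dosage)), collapse = "\t")), con)
  for (i in seq_len(nrow(loci))) {
    writeLines(paste(c(loci$chrom[i], loci$pos[i], loci$rsid[i],
                       loci$other_allele[i], loci$effect_allele[i],
                       ".", "PASS", ".", "GT",
                       gt_code[dm$dosage[, i] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}
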