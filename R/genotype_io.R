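KG_SUPERPOPS <- c("AFR", "AMR", "EAS", "EUR", "SAS")

#' Read a candidate-locus table
#'
#' Reads a TSV describing the locus panel: one row per variant with its
#' identifier, genomic position, effect and other allele, and an optional
#' per-allele effect size (log-odds scale) used by the weighted risk score.
#'
#' @param path path to a tab-separated file with header columns
#'   \code{rsid}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele} and optionally \code{beta}.
#' @return a data.frame of class \code{locus_table}, rows in file order.
#' @export
read_locus_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("rsid", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("locus table is missing column(s): ", paste(miss, collapse = ", "))
  tab$pos <- suppressWarnings(as.integer(tab$pos))
  bad <- which(is.na(tab$pos) | tab$pos < 1L)
  if (length(bad))
    stop("malformed position at line ", bad[1] + 1L, " of ", path)
  bases <- c("A", "C", "G", "T")
  bad <- which(!(tab$effect_allele %in% bases) | !(tab$other_allele %in% bases))
  if (length(bad))
    stop("malformed allele at line ", bad[1] + 1L, " of ", path)
  same <- which(tab$effect_allele == tab$other_allele)
  if (length(same))
    stop("effect_allele equals other_allele for ", tab$rsid[same[1]])
  if (anyDuplicated(tab$rsid))
    stop("duplicate rsid: ", tab$rsid[duplicated(tab$rsid)][1])
  if ("beta" %in% names(tab)) {
    tab$beta <- suppressWarnings(as.numeric(tab$beta))
  } else {
    tab$beta <- NA_real_
  }
  tab <- tab[, c(req, "beta")]
  class(tab) <- c("locus_table", "data.frame")
  tab
}

#' Read a sample panel
#'
#' Reads a sample-to-population mapping in the 1000 Genomes \code{.panel}
#' dialect: columns \code{sample}, \code{pop} (subpopulation), \code{super_pop}
#' (superpopulation) and optionally \code{gender}.
#'
#' @param path path to a tab-separated panel file with header.
#' @param allowed_superpops optional character vector of valid superpopulation
#'   codes (e.g. \code{c("AFR","AMR","EAS","EUR","SAS")}); codes outside the
#'   set are rejected. \code{NULL} (default) accepts any code, which the
#'   synthetic fixtures rely on.
#' @return a data.frame of class \code{sample_panel} with columns
#'   \code{sample}, \code{subpop}, \code{superpop}, \code{sex}.
#' @export
read_panel <- function(path, allowed_superpops = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(tab)
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (!length(hit)) stop("panel file lacks a ", cands[1], " column")
    hit[1]
  }
  out <- data.frame(
    sample   = as.character(tab[[pick(c("sample", "sample_id"))]]),
    subpop   = as.character(tab[[pick(c("pop", "subpop"))]]),
    superpop = as.character(tab[[pick(c("super_pop", "superpop"))]]),
    stringsAsFactors = FALSE)
  sex_col <- intersect(c("gender", "sex"), nm)
  out$sex <- if (length(sex_col)) normalize_sex(tab[[sex_col[1]]])
             else rep(NA_character_, nrow(out))
  if (anyDuplicated(out$sample))
    stop("sample listed twice in panel: ",
         out$sample[duplicated(out$sample)][1])
  map <- unique(out[, c("subpop", "superpop")])
  dup <- map$subpop[duplicated(map$subpop)]
  if (length(dup))
    stop("subpopulation mapped to two superpopulations: ", dup[1])
  if (!is.null(allowed_superpops)) {
    bad <- setdiff(out$superpop, allowed_superpops)
    if (length(bad)) stop("unknown superpopulation code: ", bad[1])
  }
  class(out) <- c("sample_panel", "data.frame")
  out
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  out
}

#' Build a complete-case effect-allele dosage matrix from a VCF
#'
#' Matches each locus to the VCF by (chromosome, position), orients the dosage
#' to count copies of the effect allele whether it is REF or ALT, and applies
#' the complete-case rule: loci absent from the VCF, multi-allelic, not a
#' biallelic SNP, with non-matching alleles, or with any missing genotype call
#' are dropped and logged with a reason code.
#'
#' @param vcf path to a VCF file (v4.1+, plain or bgzipped) or a
#'   \code{vcfR::vcfR} object.
#' @param loci a \code{locus_table} (see [read_locus_table()]).
#' @param panel a \code{sample_panel}; every panel sample must be genotyped.
#' @return an object of class \code{dosage_matrix}: a list with the integer
#'   matrix \code{dosage} (samples x loci, values 0/1/2), the retained
#'   \code{loci}, the \code{panel}, and a \code{drops} data.frame with one row
#'   per excluded locus and its reason code.
#' @export
build_dosage_matrix <- function(vcf, loci, panel) {
  stopifnot(inherits(loci, "locus_table"), inherits(panel, "sample_panel"))
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF carries no GT genotypes")
  missing_smp <- setdiff(panel$sample, colnames(gt))
  if (length(missing_smp))
    stop("panel sample absent from VCF: ", missing_smp[1])
  gt <- gt[, panel$sample, drop = FALSE]

  key_vcf <- paste(fix[, "CHROM"], fix[, "POS"])
  key_loc <- paste(loci$chrom, loci$pos)
  dup_sites <- key_vcf[duplicated(key_vcf)]

  keep <- logical(nrow(loci))
  drops <- list()
  dosage <- matrix(NA_integer_, nrow = nrow(panel), ncol = nrow(loci),
                   dimnames = list(panel$sample, loci$rsid))
  drop <- function(i, reason) drops[[length(drops) + 1L]] <<-
    data.frame(rsid = loci$rsid[i], reason = reason, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(loci))) {
    if (key_loc[i] %in% dup_sites) { drop(i, "multiallelic_site"); next }
    j <- match(key_loc[i], key_vcf)
    if (is.na(j)) { drop(i, "absent_from_vcf"); next }
    ref <- fix[j, "REF"]; alt <- fix[j, "ALT"]
    if (grepl(",", alt, fixed = TRUE)) { drop(i, "multiallelic"); next }
    if (nchar(ref) != 1L || nchar(alt) != 1L) { drop(i, "not_snp"); next }
    ea <- loci$effect_allele[i]; oa <- loci$other_allele[i]
    if (!setequal(c(ea, oa), c(ref, alt))) {
      warning("alleles for ", loci$rsid[i], " do not match VCF REF/ALT; dropped")
      drop(i, "allele_mismatch"); next
    }
    g <- gt[j, ]
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    nalt <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".") || any(is.na(a))) NA_integer_
      else sum(a == "1")
    }, integer(1))
    nalt[is.na(g)] <- NA_integer_
    if (anyNA(nalt)) { drop(i, "missing_genotype"); next }
    if (any(nalt > 2L | nalt < 0L)) { drop(i, "bad_genotype"); next }
    d <- if (ea == alt) nalt else 2L - nalt
    if (paste0(sort(c(ea, oa)), collapse = "") %in% c("AT", "CG"))
      warning("strand-ambiguous alleles at ", loci$rsid[i],
              "; matched as-is without strand flipping")
    if (loci$chrom[i] %in% c("X", "chrX"))
      warning(loci$rsid[i], " is on X; genotypes treated as diploid")
    dosage[, i] <- d
    keep[i] <- TRUE
  }
  drops <- if (length(drops)) do.call(rbind, drops)
           else data.frame(rsid = character(), reason = character(),
                           stringsAsFactors = FALSE)
  new_dosage_matrix(dosage[, keep, drop = FALSE],
                    loci[keep, , drop = FALSE], panel, drops)
}

new_dosage_matrix <- function(dosage, loci, panel, drops = NULL) {
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(dosage) == nrow(panel), ncol(dosage) == nrow(loci),
            !anyNA(dosage), all(dosage >= 0L & dosage <= 2L))
  structure(list(dosage = dosage, loci = loci, panel = panel,
                 drops = drops %||% data.frame(rsid = character(),
                                               reason = character())),
            class = "dosage_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "loci\n")
  cat("  subpopulations:", length(unique(x$panel$subpop)),
      " superpopulations:", length(unique(x$panel$superpop)), "\n")
  if (nrow(x$drops))
    cat("  dropped loci:", nrow(x$drops), "(see $drops)\n")
  invisible(x)
}

#' @exportS3Method base::dim
dim.dosage_matrix <- function(x) dim(x$dosage)

# group labels at an analysis level, in panel order
group_labels <- function(dm, level = c("superpop", "subpop")) {
  level <- match.arg(level)
  dm$panel[[level]]
}
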