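#' Composite polygenic risk scores under the additive dosage model
#'
#' Unweighted mode: score = sum(dosage_i) / (2N) over the N scored loci, so an
#' individual homozygous for the risk allele everywhere scores 1 and one
#' carrying no risk alleles scores 0. Weighted mode: score =
#' sum(beta_i * dosage_i) / (2 * sum(beta_i)), the normalization that keeps
#' the weighted score on the same [0,1] scale (the raw unnormalized sum is
#' also returned). Loci with negative beta are flipped to the risk
#' orientation first (beta negated, dosage complemented). Population-specific
#' scores (psPRS) are the mean score of a population's members; box-plot
#' summaries use 1.5 x IQR whiskers.
#'
#' @param dm a \code{dosage_matrix}.
#' @param loci a \code{locus_table} of the loci to score (intersected with
#'   the matrix by rsid); betas required in weighted mode.
#' @param mode \code{"unweighted"} (default) or \code{"weighted"}.
#' @return list of class \code{prs_result}: \code{scores} data.frame (sample,
#'   subpop, superpop, sex, score, and raw_weighted in weighted mode),
#'   \code{summary} data.frame of per-population statistics at both levels,
#'   \code{n_loci}, \code{mode}.
#' @export
compute_prs <- function(dm, loci, mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  use <- intersect(loci$rsid, colnames(dm$dosage))
  if (!length(use)) stop("no scored loci present in the dosage matrix")
  sub <- loci[match(use, loci$rsid), ]
  d <- dm$dosage[, use, drop = FALSE]
  N <- length(use)
  raw <- NULL
  if (mode == "unweighted") {
    score <- rowSums(d) / (2 * N)
  } else {
    beta <- sub$beta
    if (anyNA(beta)) stop("weighted mode requires beta for every locus")
    flip <- beta < 0
    if (any(flip)) {   # orient to the risk-increasing allele
      d[, flip] <- 2L - d[, flip]
      beta[flip] <- -beta[flip]
    }
    raw <- as.vector(d %*% beta)
    score <- raw / (2 * sum(beta))
  }
  scores <- data.frame(sample = dm$panel$sample, subpop = dm$panel$subpop,
                       superpop = dm$panel$superpop, sex = dm$panel$sex,
                       score = score, stringsAsFactors = FALSE)
  if (!is.null(raw)) scores$raw_weighted <- raw
  summ <- rbind(prs_summary(scores, "superpop"),
                prs_summary(scores, "subpop"))
  structure(list(scores = scores, summary = summ, n_loci = N, mode = mode),
            class = "prs_result")
}

prs_summary <- function(scores, level) {
  out <- lapply(split(scores$score, scores[[level]]), function(x) {
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    lo <- qs[1] - 1.5 * iqr; hi <- qs[3] + 1.5 * iqr
    data.frame(n = length(x), psPRS = mean(x), sd = stats::sd(x),
               median = qs[2], q1 = qs[1], q3 = qs[3],
               whisker_low = min(x[x >= lo]), whisker_high = max(x[x <= hi]),
               n_outliers = sum(x < lo | x > hi))
  })
  res <- do.call(rbind, out)
  data.frame(level = level, population = names(out), res,
             row.names = NULL, stringsAsFactors = FALSE)
}

star_code <- function(p) ifelse(p < 0.001, "***",
                         ifelse(p < 0.01, "**",
                         ifelse(p < 0.05, "*", "ns")))

# Dunn's post hoc Z tests on pooled ranks with tie correction; BH-adjusted
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], Z = z,
             p_unadj = p, p_adj = p_adj, stars = star_code(p_adj),
             stringsAsFactors = FALSE)
}

#' Nonparametric comparison of risk scores across populations
#'
#' Kruskal-Wallis rank-sum test (tie-corrected) across the groups; when it is
#' significant at \code{gate_p}, Dunn's pairwise Z tests follow, using the
#' tie-corrected pooled-rank variance, with Benjamini-Hochberg adjustment
#' across all pairs and the usual star annotation (*** p<0.001, ** p<0.01,
#' * p<0.05 on the adjusted p). The Z sign convention is (mean rank of
#' group1) - (mean rank of group2).
#'
#' @param prs a [compute_prs()] result (or any data.frame with a
#'   \code{score} column and grouping columns).
#' @param level grouping column: \code{"superpop"}, \code{"subpop"} or
#'   \code{"sex"}.
#' @param gate_p Kruskal-Wallis threshold gating the post hoc tests
#'   (default 0.05).
#' @param force_posthoc compute Dunn's tests regardless of the gate.
#' @return list of class \code{group_comparison}: \code{kw} (H, df, p),
#'   \code{pairs} (data.frame or NULL), \code{note}.
#' @export
compare_groups <- function(prs, level = c("superpop", "subpop", "sex"),
                           gate_p = 0.05, force_posthoc = FALSE) {
  level <- match.arg(level)
  scores <- if (inherits(prs, "prs_result")) prs$scores else prs
  keep <- !is.na(scores[[level]])
  values <- scores$score[keep]
  groups <- scores[[level]][keep]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group with fewer than 2 members: ", names(tab)[tab < 2L][1])
  if (length(unique(values)) == 1L) {
    return(structure(list(kw = list(H = NA_real_, df = length(tab) - 1L,
                                    p = NA_real_),
                          pairs = NULL,
                          note = "all scores identical; no test performed"),
                     class = "group_comparison"))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  kw <- list(H = unname(kt$statistic), df = unname(kt$parameter),
             p = kt$p.value)
  pairs <- NULL
  if (force_posthoc || kw$p < gate_p) pairs <- dunn_test(values, groups)
  structure(list(kw = kw, pairs = pairs,
                 note = if (is.null(pairs)) "Kruskal-Wallis not significant; post hoc skipped"
                        else NA_character_),
            class = "group_comparison")
}

#' Sex-stratified comparison of risk scores
#'
#' Applies the same nonparametric machinery to male vs female strata (a
#' two-group Kruskal-Wallis test, equivalent to a rank-sum test).
#'
#' @param prs a [compute_prs()] result.
#' @param panel optional \code{sample_panel} supplying sex when the score
#'   table lacks it.
#' @return a \code{group_comparison}.
#' @export
sex_stratified_prs <- function(prs, panel = NULL) {
  scores <- prs$scores
  if (!is.null(panel))
    scores$sex <- panel$sex[match(scores$sample, panel$sample)]
  tab <- table(scores$sex)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 individuals of each sex")
  compare_groups(scores, level = "sex", force_posthoc = TRUE)
}
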