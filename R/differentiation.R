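#' Squared codominant-genotypic distance matrix between individuals
#'
#' Per-locus squared dosage difference, summed over loci: identical genotypes
#' contribute 0, homozygote vs heterozygote 1, opposite homozygotes 4. This is
#' the individual-by-individual distance the molecular variance analysis
#' partitions.
#'
#' @param dm a \code{dosage_matrix} (or a plain numeric matrix of dosages).
#' @return an N x N symmetric matrix of squared distances.
#' @export
genotype_distance_matrix <- function(dm) {
  d <- if (inherits(dm, "dosage_matrix")) dm$dosage else dm
  as.matrix(stats::dist(d))^2
}

# AMOVA variance components on a squared-distance matrix for given groups
amova_components <- function(d2, groups) {
  groups <- as.factor(groups)
  N <- nrow(d2)
  sizes <- table(groups)
  K <- length(sizes)
  ss_total <- sum(d2) / (2 * N)
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  df_among <- K - 1L
  df_within <- N - K
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / df_among
  va <- (ms_among - ms_within) / n0
  vw <- ms_within
  phi_raw <- if (va + vw > 0) va / (va + vw) else 0
  list(Va = va, Vw = vw, phi_raw = phi_raw, phi = max(0, phi_raw),
       df_among = df_among, df_within = df_within,
       SS_among = ss_among, SS_within = ss_within, SS_total = ss_total)
}

#' PhiPT from an analysis of molecular variance, with permutation test
#'
#' Partitions the squared genotypic distances into among-population (Va) and
#' within-population (Vw) variance components;
#' PhiPT = Va/(Va+Vw), truncated at 0 when the raw estimate is negative (the
#' untruncated value is also reported). Significance is assessed by permuting
#' individuals among populations (group sizes preserved):
#' p = (r+1)/(n_perm+1) where r counts permutations with PhiPT at least the
#' observed value.
#'
#' @param dm a \code{dosage_matrix}.
#' @param level analysis level.
#' @param n_perm number of permutations (default 999); 0 skips the test.
#' @param seed integer seed for the permutation stream (mandatory when
#'   \code{n_perm > 0}).
#' @return list of class \code{amova_phi}: Va, Vw, phi, phi_raw, df_among,
#'   df_within, p_perm, n_perm and the sums of squares.
#' @export
phi_pt <- function(dm, level = c("superpop", "subpop"), n_perm = 999,
                   seed = NULL) {
  level <- match.arg(level)
  g <- group_labels(dm, level)
  small <- names(which(table(g) < 2L))
  if (length(small))
    stop("population with fewer than 2 individuals: ", small[1])
  if (length(unique(g)) < 2L) stop("need at least 2 populations")
  d2 <- genotype_distance_matrix(dm)
  phi_pt_from_d2(d2, g, n_perm = n_perm, seed = seed)
}

phi_pt_from_d2 <- function(d2, g, n_perm = 999, seed = NULL) {
  obs <- amova_components(d2, g)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is mandatory when permuting")
    set.seed(seed)
    r <- 0L
    # compare untruncated estimates: truncation piles permutations onto an
    # atom at zero and would make null p-values non-uniform
    for (b in seq_len(n_perm)) {
      gp <- sample(g)
      if (amova_components(d2, gp)$phi_raw >= obs$phi_raw - 1e-12)
        r <- r + 1L
    }
    p_perm <- (r + 1) / (n_perm + 1)
  }
  structure(c(obs, list(p_perm = p_perm, n_perm = n_perm)),
            class = "amova_phi")
}

#' @exportS3Method base::print
print.amova_phi <- function(x, ...) {
  cat(sprintf("PhiPT = %.4f (raw %.4f), Va = %.4f, Vw = %.4f\n",
              x$phi, x$phi_raw, x$Va, x$Vw))
  if (!is.na(x$p_perm))
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}

#' Pairwise PhiPT and permutation p-values between populations
#'
#' @inheritParams phi_pt
#' @return list with symmetric matrices \code{phi}, \code{phi_raw} and
#'   \code{p} (zero diagonal; p diagonal NA).
#' @export
pairwise_phi_pt <- function(dm, level = c("superpop", "subpop"),
                            n_perm = 999, seed = NULL) {
  level <- match.arg(level)
  g <- group_labels(dm, level)
  pops <- sort(unique(g))
  d2 <- genotype_distance_matrix(dm)
  K <- length(pops)
  phi <- phi_raw <- matrix(0, K, K, dimnames = list(pops, pops))
  p <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    idx <- which(g %in% pops[c(a, b)])
    res <- phi_pt_from_d2(d2[idx, idx], g[idx], n_perm = n_perm,
                          seed = if (is.null(seed)) NULL
                                 else seed + 1000L * a + b)
    phi[a, b] <- phi[b, a] <- res$phi
    phi_raw[a, b] <- phi_raw[b, a] <- res$phi_raw
    p[a, b] <- p[b, a] <- res$p_perm
  }
  list(phi = phi, phi_raw = phi_raw, p = p)
}

#' Nei's standard genetic distance between populations
#'
#' For each pair, over shared loci: Jx = mean(p^2 + q^2), Jy likewise,
#' Jxy = mean(p p' + q q'); D = -ln(Jxy / sqrt(Jx Jy)). D is reported as +Inf
#' when Jxy = 0. The unbiased variant corrects the within-population
#' identities for sample size: Jx_hat = mean((2n(p^2+q^2) - 1)/(2n - 1)).
#'
#' @param freqs an \code{allele_freq_table} covering at least 2 populations.
#' @param unbiased use the sample-size-corrected identities (default FALSE,
#'   i.e. the standard distance).
#' @return symmetric matrix of distances, zero diagonal.
#' @export
nei_distance <- function(freqs, unbiased = FALSE) {
  p <- freq_matrix(freqs, "p")
  if (nrow(p) < 2L) stop("need at least 2 populations")
  if (ncol(p) == 0L) stop("zero shared loci")
  q <- 1 - p
  chr <- freq_matrix(freqs, "chroms")
  hom <- p^2 + q^2
  J_self <- if (unbiased) rowMeans((chr * hom - 1) / (chr - 1))
            else rowMeans(hom)
  K <- nrow(p)
  D <- matrix(0, K, K, dimnames = list(rownames(p), rownames(p)))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    jxy <- mean(p[a, ] * p[b, ] + q[a, ] * q[b, ])
    D[a, b] <- D[b, a] <- if (jxy == 0) Inf
      else -log(jxy / sqrt(J_self[a] * J_self[b]))
  }
  D
}

#' Combined pairwise differentiation matrix
#'
#' The conventional presentation: PhiPT below the diagonal, Nei's genetic
#' distance above, zero diagonal.
#'
#' @inheritParams phi_pt
#' @param unbiased passed to [nei_distance()].
#' @return list of class \code{diff_matrices}: \code{combined} (matrix),
#'   \code{phi}, \code{phi_p}, \code{nei}.
#' @export
differentiation_matrix <- function(dm, level = c("superpop", "subpop"),
                                   n_perm = 999, seed = NULL,
                                   unbiased = FALSE) {
  level <- match.arg(level)
  pw <- pairwise_phi_pt(dm, level, n_perm = n_perm, seed = seed)
  nei <- nei_distance(allele_frequencies(dm, level), unbiased = unbiased)
  pops <- rownames(pw$phi)
  nei <- nei[pops, pops]
  combined <- pw$phi
  combined[upper.tri(combined)] <- nei[upper.tri(nei)]
  structure(list(combined = combined, phi = pw$phi, phi_p = pw$p, nei = nei),
            class = "diff_matrices")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling (Gower): squared distances are double-centered and
#' eigendecomposed; coordinates are eigenvectors scaled by the square root of
#' their (positive) eigenvalues; percent variance is computed over the
#' positive eigenvalues. Backed by \code{stats::cmdscale}.
#'
#' @param d symmetric, zero-diagonal, nonnegative distance matrix (used
#'   directly as distances, e.g. a pairwise PhiPT matrix).
#' @return list of class \code{pcoa_result}: \code{points} (rows = objects,
#'   columns = axes in decreasing eigenvalue order), \code{eig} (all
#'   eigenvalues), \code{percent} (percent variance per retained axis).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be nonnegative")
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-9 & eig > 0)
  pts <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(pos))
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eig = eig,
                 percent = 100 * eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}
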