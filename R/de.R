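# Sex-biased differential expression between two assigned groups.
#
# The default test is an exact conditional negative-binomial test in the
# style classically used for two-group RNA-seq comparisons: counts are
# scaled to a common library size, a common NB dispersion is estimated by
# method of moments, and for each gene the two group sums are compared
# conditionally on their total, with the two-sided p-value defined as the
# summed probability of all outcomes no more likely than the observed one.
# `method = "binomial"` drops the dispersion (Poisson limit), reducing to
# the exact conditional binomial test on pooled counts.

# method-of-moments common dispersion on library-size-equalized counts
estimate_common_dispersion <- function(pseudo, grp) {
  phis <- c(); wts <- c()
  for (g in c("A", "B")) {
    x <- pseudo[, grp == g, drop = FALSE]
    n <- ncol(x)
    if (n < 2L) next
    m <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    keep <- m >= 5
    if (!any(keep)) next
    phis <- c(phis, (v[keep] - m[keep]) / m[keep]^2)
    wts <- c(wts, rep(n - 1L, sum(keep)))
  }
  if (!length(phis)) return(0)
  max(0, stats::median(rep(phis, wts)))
}

# two-sided exact conditional p-value for group-A sum yA of total n,
# group sizes nA/nB, per-sample null mean mhat, dispersion phi
exact_cond_pvalue <- function(yA, n, nA, nB, phi) {
  if (n == 0L) return(1)
  mhat <- n / (nA + nB)
  muA <- nA * mhat; muB <- nB * mhat
  if (phi <= 0) {
    logp <- function(y) stats::dbinom(y, n, nA / (nA + nB), log = TRUE)
    varc <- n * (nA / (nA + nB)) * (nB / (nA + nB))
  } else {
    sA <- nA / phi; sB <- nB / phi
    logp <- function(y) stats::dnbinom(y, size = sA, mu = muA, log = TRUE) +
      stats::dnbinom(n - y, size = sB, mu = muB, log = TRUE)
    vA <- muA + phi * muA^2 / nA
    vB <- muB + phi * muB^2 / nB
    varc <- 1 / (1 / vA + 1 / vB)
  }
  half <- ceiling(20 * sqrt(varc)) + 25L
  lo <- max(0L, floor(muA) - half); hi <- min(n, floor(muA) + half)
  lo <- min(lo, yA); hi <- max(hi, yA)
  ys <- lo:hi
  lp <- logp(ys)
  lse <- max(lp) + log(sum(exp(lp - max(lp))))
  p <- exp(lp - lse)
  obs <- p[ys == yA]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Test genes for sex-biased differential expression
#'
#' Compares the two assigned sex-groups gene by gene on library-size
#' normalized counts. Genes whose pooled count falls below `min_total` are
#' excluded from testing and reported as filtered. Significance follows
#' the raw p-value threshold `alpha` (Benjamini-Hochberg FDR is reported
#' alongside).
#'
#' @param counts a [count_matrix()].
#' @param assignment a [assign_sex_groups()] result (or data.frame with
#'   `id`, `group`); samples with `NA` group are dropped.
#' @param alpha raw p-value significance threshold (default 0.01).
#' @param min_total minimal pooled count for a gene to be tested.
#' @param method `"nb_exact"` (default) or `"binomial"` (no-dispersion
#'   limit).
#' @param dispersion optional fixed NB dispersion; estimated from the data
#'   when `NULL`.
#' @return A data.frame of class `de_result`: per gene the normalized group
#'   means (counts per million), `log2fc` (A over B), `direction` (group
#'   with the higher normalized mean), `p_value`, `fdr`, `significant`
#'   (p < alpha) and `filtered`.
#' @export
test_de <- function(counts, assignment, alpha = 0.01, min_total = 10L,
                    method = c("nb_exact", "binomial"), dispersion = NULL) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  asg <- as.data.frame(unclass(assignment), stringsAsFactors = FALSE)
  asg <- asg[!is.na(asg$group) & asg$id %in% colnames(counts), , drop = FALSE]
  grp <- stats::setNames(asg$group, asg$id)
  x <- unclass(counts)[, asg$id, drop = FALSE]
  nA <- sum(grp == "A"); nB <- sum(grp == "B")
  if (nA < 2L || nB < 2L)
    stop("each group needs at least 2 samples (A: ", nA, ", B: ", nB, ")")
  libs <- colSums(x)
  if (all(x == 0)) {
    # degenerate all-zero matrix: nothing testable, everything filtered
    res <- data.frame(gene_id = rownames(x), mean_A = 0, mean_B = 0,
                      log2fc = 0, direction = NA_character_,
                      p_value = NA_real_, fdr = NA_real_,
                      significant = FALSE, filtered = TRUE,
                      stringsAsFactors = FALSE)
    attr(res, "alpha") <- alpha; attr(res, "method") <- method
    attr(res, "dispersion") <- 0
    attr(res, "n_samples") <- c(A = nA, B = nB)
    class(res) <- c("de_result", "data.frame")
    return(res)
  }
  if (any(libs == 0)) stop("sample(s) with zero library size")
  cpm <- sweep(x, 2L, libs, "/") * 1e6
  mean_A <- rowMeans(cpm[, grp == "A", drop = FALSE])
  mean_B <- rowMeans(cpm[, grp == "B", drop = FALSE])
  total <- rowSums(x)
  filtered <- total < min_total
  L0 <- exp(mean(log(libs)))
  pseudo <- round(sweep(x, 2L, L0 / libs, "*"))
  phi <- if (method == "binomial") 0
         else if (!is.null(dispersion)) dispersion
         else estimate_common_dispersion(pseudo[!filtered, , drop = FALSE],
                                         grp)
  pvals <- rep(NA_real_, nrow(x))
  yA_all <- rowSums(pseudo[, grp == "A", drop = FALSE])
  n_all <- rowSums(pseudo)
  for (g in which(!filtered))
    pvals[g] <- exact_cond_pvalue(yA_all[g], n_all[g], nA, nB, phi)
  fdr <- rep(NA_real_, nrow(x))
  fdr[!filtered] <- stats::p.adjust(pvals[!filtered], method = "BH")
  res <- data.frame(
    gene_id = rownames(x),
    mean_A = mean_A, mean_B = mean_B,
    log2fc = log2((mean_A + 0.5) / (mean_B + 0.5)),
    direction = ifelse(mean_A > mean_B, "A",
                       ifelse(mean_B > mean_A, "B", NA_character_)),
    p_value = pvals, fdr = fdr,
    significant = !is.na(pvals) & pvals < alpha,
    filtered = filtered,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  attr(res, "dispersion") <- phi
  attr(res, "n_samples") <- c(A = nA, B = nB)
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x), "genes (", sum(x$filtered), "filtered ),",
      sum(x$significant), "significant at p <", attr(x, "alpha"), "\n")
  cat("  method:", attr(x, "method"), "| dispersion:",
      signif(attr(x, "dispersion"), 3), "| samples:",
      paste(names(attr(x, "n_samples")), attr(x, "n_samples"),
            sep = "=", collapse = " "), "\n")
  up <- table(factor(x$direction[x$significant], levels = c("A", "B")))
  cat("  up in A:", up["A"], "| up in B:", up["B"], "\n")
  invisible(x)
}
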