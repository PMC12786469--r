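# Listener-evaluation statistics: per-evaluator confusion metrics and
# binomial tests against a probability-matching chance level (Holm
# corrected), a group-level permutation test, Fleiss' kappa with a
# bootstrap CI, and Monte Carlo power estimation.

#' Probability-matching chance level
#'
#' Expected accuracy of a guesser who labels classes in proportion to
#' their base rates: with \code{p = nPos / (nPos + nNeg)}, the chance
#' level is \code{p^2 + (1 - p)^2}. For 36 vs 29 subjects this is
#' 0.5058, slightly above the uniform 0.5 baseline.
#'
#' @param nPos,nNeg non-negative class counts (at least one positive).
#' @return A probability.
#' @examples
#' chanceLevel(36, 29)  # 0.5058
#' @export
chanceLevel <- function(nPos, nNeg) {
  stopifnot(nPos >= 0, nNeg >= 0, nPos + nNeg >= 1)
  p <- nPos / (nPos + nNeg)
  p^2 + (1 - p)^2
}

#' Confusion-matrix metrics for one evaluator
#'
#' Missing ratings are excluded from that evaluator's denominator.
#' Ratios with a zero denominator are reported as \code{NA} (undefined),
#' never as 0.
#'
#' @param ratingsOne character vector of one evaluator's labels
#'   (NA = missing).
#' @param truth character vector of true groups.
#' @param positiveClass the label treated as positive (default "AD").
#' @return A one-row data.frame: accuracy, sensitivity, specificity,
#'   ppv, npv, nEvaluated.
#' @export
confusionMetrics <- function(ratingsOne, truth, positiveClass = "AD") {
  keep <- !is.na(ratingsOne)
  if (!any(keep)) stop("no non-missing ratings")
  r <- ratingsOne[keep]; tr <- truth[keep]
  tp <- sum(r == positiveClass & tr == positiveClass)
  tn <- sum(r != positiveClass & tr != positiveClass)
  fp <- sum(r == positiveClass & tr != positiveClass)
  fn <- sum(r != positiveClass & tr == positiveClass)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(accuracy = (tp + tn) / length(r),
             sensitivity = rat(tp, tp + fn),
             specificity = rat(tn, tn + fp),
             ppv = rat(tp, tp + fp),
             npv = rat(tn, tn + fn),
             nEvaluated = length(r))
}

#' Exact two-tailed binomial test against a chance level
#'
#' Two-tailed p by the minimum-likelihood method: the sum of the
#' probabilities of all outcomes no more likely than the observed count.
#'
#' @param kCorrect observed number of correct classifications.
#' @param n number of classifications.
#' @param p0 chance probability in (0, 1).
#' @return The p-value.
#' @export
binomialVsChance <- function(kCorrect, n, p0) {
  stopifnot(kCorrect >= 0, kCorrect <= n, p0 > 0, p0 < 1)
  binom.test(kCorrect, n, p = p0)$p.value
}

#' Holm step-down adjustment
#'
#' @param pValues numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
holmAdjust <- function(pValues) p.adjust(pValues, method = "holm")

#' Per-evaluator performance table
#'
#' Confusion metrics plus the exact binomial test of each evaluator's
#' correct-classification count against the probability-matching chance
#' level of the supplied truth, with Holm correction across evaluators.
#' The per-evaluator n is always taken from the non-missing cells of the
#' supplied matrix.
#'
#' @param rm a \code{RatingMatrix}.
#' @param positiveClass label treated as positive (default "AD").
#' @return A data.frame with one row per evaluator.
#' @export
evaluatePanel <- function(rm, positiveClass = "AD") {
  stopifnot(is(rm, "RatingMatrix"))
  tr <- groundTruth(rm)
  if (length(unique(tr)) < 2)
    stop("truth must contain both classes")
  p0 <- chanceLevel(sum(tr == positiveClass), sum(tr != positiveClass))
  rt <- ratings(rm)
  rows <- lapply(seq_len(ncol(rt)), function(j) {
    m <- confusionMetrics(rt[, j], tr, positiveClass)
    keep <- !is.na(rt[, j])
    k <- sum(rt[keep, j] == tr[keep])
    cbind(data.frame(evaluator = colnames(rt)[j]), m,
          data.frame(p_raw = binomialVsChance(k, sum(keep), p0)))
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holmAdjust(out$p_raw)
  out
}

#' Panel summary of evaluator metrics
#'
#' Mean, sample SD (n - 1 denominator), minimum and maximum of each
#' metric across evaluators. With a single evaluator the SD is undefined
#' and reported as NA with a warning.
#'
#' @param metrics numeric vector, matrix or data.frame of per-evaluator
#'   metric values (evaluators in rows; non-numeric columns dropped).
#' @return A data.frame with one row per metric: mean, sd, min, max.
#' @export
summarizePanel <- function(metrics) {
  if (is.vector(metrics) && is.numeric(metrics))
    metrics <- data.frame(value = metrics)
  metrics <- as.data.frame(metrics)
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  if (nrow(num) < 2) warning("single evaluator: SD undefined")
  out <- data.frame(
    metric = names(num),
    mean = vapply(num, mean, numeric(1), na.rm = TRUE),
    sd = if (nrow(num) < 2) NA_real_
         else vapply(num, sd, numeric(1), na.rm = TRUE),
    min = vapply(num, min, numeric(1), na.rm = TRUE),
    max = vapply(num, max, numeric(1), na.rm = TRUE))
  rownames(out) <- NULL
  out
}

# mean accuracy across evaluators for an arbitrary truth labelling;
# A = ratings=="AD" (NA-masked), W = !is.na(ratings)
.meanAccuracy <- function(WA, WnotA, nPerEval, truthPos) {
  counts <- drop(crossprod(truthPos, WA) + crossprod(1 - truthPos, WnotA))
  mean(counts / nPerEval)
}

#' Permutation test of the panel's mean accuracy
#'
#' Diagnostic labels are permuted across subjects while the ratings stay
#' fixed; the group statistic is the mean per-evaluator accuracy (each
#' evaluator scored over its non-missing cells). The primary p-value is
#' the add-one estimator (1 + B) / (1 + N) counting permutations whose
#' statistic is >= the observed one (ties counted); the naive proportion
#' is also returned.
#'
#' @param rm a \code{RatingMatrix}.
#' @param nPerm number of permutations (>= 100; default 10000).
#' @param seed integer seed.
#' @return A list: \code{p} (conservative), \code{pNaive},
#'   \code{observed} mean accuracy, \code{nPerm}.
#' @export
permutationTestMeanAccuracy <- function(rm, nPerm = 10000, seed = 1) {
  stopifnot(is(rm, "RatingMatrix"), nPerm >= 100)
  tr <- groundTruth(rm)
  if (length(unique(tr)) < 2) stop("degenerate truth: one class only")
  rt <- ratings(rm)
  W <- !is.na(rt)
  A <- rt == "AD"; A[!W] <- FALSE
  WA <- W & A; WnotA <- W & !A
  nPerEval <- colSums(W)
  tpos <- as.numeric(tr == "AD")
  obs <- .meanAccuracy(WA, WnotA, nPerEval, tpos)
  perm <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i)
      .meanAccuracy(WA, WnotA, nPerEval, sample(tpos)), numeric(1))
  })
  nGe <- sum(perm >= obs - 1e-12)
  list(p = (1 + nGe) / (1 + nPerm), pNaive = nGe / nPerm,
       observed = obs, nPerm = nPerm)
}

#' Fleiss' kappa for multiple raters
#'
#' Fleiss' (1971) chance-corrected agreement on the complete-item
#' submatrix: subjects with any missing rating are excluded (listwise),
#' matching the differing Ns between per-evaluator metrics and the
#' agreement analysis. If expected agreement is 1 (all raters unanimous
#' on a single category) kappa is undefined and returned as NA with a
#' warning.
#'
#' @param rm a \code{RatingMatrix}.
#' @return A list: \code{kappa}, \code{nItemsUsed}, \code{nRaters}.
#' @export
fleissKappa <- function(rm) {
  stopifnot(is(rm, "RatingMatrix"))
  rt <- ratings(rm)
  if (ncol(rt) < 2) stop("need at least 2 evaluators")
  complete <- rowSums(is.na(rt)) == 0
  if (!any(complete)) stop("no complete items")
  rt <- rt[complete, , drop = FALSE]
  nR <- ncol(rt)
  counts <- cbind(AD = rowSums(rt == "AD"),
                  control = rowSums(rt == "control"))
  Pi <- (rowSums(counts^2) - nR) / (nR * (nR - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (nrow(counts) * nR)
  Pe <- sum(pj^2)
  kappa <- if (abs(1 - Pe) < 1e-12) {
    warning("expected agreement is 1: kappa undefined")
    NA_real_
  } else (Pbar - Pe) / (1 - Pe)
  list(kappa = kappa, nItemsUsed = nrow(counts), nRaters = nR)
}

#' Bootstrap confidence interval for Fleiss' kappa
#'
#' Nonparametric bootstrap over items (subjects with complete ratings)
#' with replacement; percentile 2.5/97.5 bounds. Degenerate resamples in
#' which expected agreement is 1 are dropped.
#'
#' @param rm a \code{RatingMatrix}.
#' @param nBoot number of bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return Numeric c(low, high).
#' @export
bootstrapKappaCI <- function(rm, nBoot = 1000, seed = 1) {
  stopifnot(is(rm, "RatingMatrix"))
  rt <- ratings(rm)
  complete <- which(rowSums(is.na(rt)) == 0)
  ks <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- sample(complete, length(complete), replace = TRUE)
    sub <- ratingMatrix(groundTruth(rm)[idx], rt[idx, , drop = FALSE])
    suppressWarnings(fleissKappa(sub)$kappa)
  }, numeric(1)))
  ks <- ks[!is.na(ks)]
  if (!length(ks)) stop("all bootstrap resamples degenerate")
  unname(quantile(ks, c(0.025, 0.975)))
}

#' Monte Carlo power of the panel permutation test
#'
#' Simulates panels under the alternative: per-evaluator accuracies are
#' drawn from a normal distribution truncated (clipped) to [0, 1],
#' per-subject correctness is Bernoulli with that accuracy, and each
#' simulated panel is tested with the label-permutation test. Power is
#' the fraction of simulations rejecting at level alpha.
#'
#' @param nSubjects number of subjects (default 65).
#' @param nEvaluators panel size (default 8).
#' @param effectMeanAccuracy,effectSd alternative-hypothesis accuracy
#'   distribution parameters.
#' @param alpha significance level in (0, 1).
#' @param nSims number of simulated panels (>= 100).
#' @param seed integer seed.
#' @param nAd number of positive-class subjects (default proportional to
#'   36/65).
#' @param nPerm permutations per simulated test.
#' @return The estimated power (rejection fraction).
#' @export
powerSimulation <- function(nSubjects = 65, nEvaluators = 8,
                            effectMeanAccuracy, effectSd,
                            alpha = 0.05, nSims = 500, seed = 1,
                            nAd = round(nSubjects * 36 / 65),
                            nPerm = 499) {
  stopifnot(alpha > 0, alpha < 1, nSims >= 100)
  truth <- c(rep("AD", nAd), rep("control", nSubjects - nAd))
  rej <- withSeed(seed, vapply(seq_len(nSims), function(s) {
    acc <- pmin(pmax(rnorm(nEvaluators, effectMeanAccuracy, effectSd),
                     0), 1)
    ok <- vapply(acc, function(a) rbinom(nSubjects, 1, a) == 1,
                 logical(nSubjects))
    rt <- ifelse(ok, truth, ifelse(truth == "AD", "control", "AD"))
    rm <- ratingMatrix(truth, rt)
    pt <- permutationTestMeanAccuracy(rm, nPerm = nPerm,
                                      seed = substreamSeed(seed, s))
    pt$p <= alpha
  }, logical(1)))
  mean(rej)
}
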