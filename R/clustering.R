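#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of the two average-referenced maps.
#' Microstate topographies are polarity invariant, so callers use the
#' absolute value for class assignment and the sign for polarity alignment.
#'
#' @param u,w numeric vectors of equal length (one value per channel),
#'   neither constant.
#' @return Signed correlation in [-1, 1].
#' @export
#' @examples
#' spatialCorrelation(c(1, 0, -1, 0), c(0, 1, 0, -1))  # orthogonal: 0
spatialCorrelation <- function(u, w) {
  if (length(u) != length(w)) stop("maps must have equal channel counts")
  u <- u - mean(u); w <- w - mean(w)
  su <- sqrt(sum(u^2)); sw <- sqrt(sum(w^2))
  if (su == 0 || sw == 0) stop("spatial correlation undefined for a flat map")
  sum(u * w) / (su * sw)
}

# internal: normalized peak maps, GFP weights, and GEV bookkeeping
.peakPrep <- function(M) {
  Xc <- .centerRows(M)
  norms <- sqrt(rowSums(Xc^2))
  if (any(norms == 0)) stop("zero-GFP peak maps must be excluded upstream")
  list(Xc = Xc, Xn = Xc / norms, gfp = norms / sqrt(ncol(M)),
       w2 = norms^2 / ncol(M))
}

# GEV of an assignment under templates T (rows unit-norm, centered)
.gevAt <- function(p, lab, T) {
  rho <- rowSums(p$Xn * T[lab, , drop = FALSE])
  sum(p$w2 * rho^2) / sum(p$w2)
}

.eigTemplate <- function(p, sel) {
  M <- crossprod(p$Xn[sel, , drop = FALSE] * p$gfp[sel])
  e <- eigen(M, symmetric = TRUE)
  .unitMap(e$vectors[, 1])
}

#' Polarity-invariant modified K-means over peak topographies
#'
#' Iterates competitive assignment (each peak to the template with the
#' largest absolute spatial correlation) and template re-estimation until
#' the global explained variance (GEV) stabilizes; the best of
#' \code{nRestarts} random initializations (templates seeded from K random
#' peaks) by total GEV is returned.
#'
#' Two template-update rules are available. \code{"mean"} (default)
#' averages the assigned maps after polarity alignment (each map multiplied
#' by the sign of its correlation), then re-centers and re-normalizes.
#' \code{"eigen"} uses the dominant eigenvector of the GFP-weighted outer
#' product of the assigned normalized maps -- the template that exactly
#' maximizes the cluster's GEV, making the iteration monotone in GEV.
#'
#' GEV is GFP-weighted: \eqn{GEV_k = \sum_{p \in k} (GFP_p \rho_p)^2 /
#' \sum_p GFP_p^2}.
#'
#' @param tset a [TopographySet-class] (concatenated peaks).
#' @param K number of templates (<= number of peaks).
#' @param nRestarts random restarts (default 50).
#' @param seed RNG seed.
#' @param tol relative GEV change declaring convergence.
#' @param maxIter iteration cap per restart.
#' @param templateUpdate \code{"mean"} or \code{"eigen"} (see Details).
#' @return A [ClusteringResult-class].
#' @export
modifiedKMeans <- function(tset, K, nRestarts = 50, seed = 1, tol = 1e-6,
                           maxIter = 100, templateUpdate = c("mean", "eigen")) {
  templateUpdate <- match.arg(templateUpdate)
  M <- maps(tset)
  n <- nrow(M)
  if (K > n) stop("K exceeds the number of peak topographies")
  set.seed(seed)
  p <- .peakPrep(M)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    T <- .unitRows(p$Xc[sample.int(n, K), , drop = FALSE])
    gevOld <- -Inf; gev <- 0; lab <- integer(n); it <- 0L
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      R <- p$Xn %*% t(T)
      A <- abs(R)
      lab <- max.col(A, ties.method = "first")
      for (k in seq_len(K)) if (!any(lab == k)) {
        lab[which.min(A[cbind(seq_len(n), lab)])] <- k   # re-seed from worst fit
      }
      if (templateUpdate == "eigen") {
        for (k in seq_len(K)) T[k, ] <- .eigTemplate(p, lab == k)
      } else {
        sg <- sign(R[cbind(seq_len(n), lab)]); sg[sg == 0] <- 1
        for (k in seq_len(K)) {
          sel <- lab == k
          Tk <- .unitMap(colSums(p$Xc[sel, , drop = FALSE] * sg[sel]))
          # exactly cancelling members leave the template unchanged
          if (any(Tk != 0)) T[k, ] <- Tk
        }
      }
      gev <- .gevAt(p, lab, T)
      if (abs(gev - gevOld) < tol * max(abs(gevOld), .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      gevOld <- gev
    }
    if (is.null(best) || gev > best$gev)
      best <- list(gev = gev, T = T, lab = lab, it = it, conv = converged)
  }
  T <- best$T
  rownames(T) <- .stateNamesFor(K)
  colnames(T) <- colnames(M)
  R <- p$Xn %*% t(T)
  rho <- R[cbind(seq_len(n), best$lab)]
  pol <- sign(rho); pol[pol == 0] <- 1
  gevK <- vapply(seq_len(K), function(k)
    sum((p$w2 * rho^2)[best$lab == k]) / sum(p$w2), 0)
  tmpl <- new("TemplateSet", maps = T, labels = rownames(T))
  new("ClusteringResult", templates = tmpl,
      assignments = as.integer(best$lab), polarity = pol,
      gevTotal = sum(gevK), gevPerTemplate = gevK,
      cvCriterion = .cvCriterion(p, best$lab, T),
      nIterations = as.integer(best$it), converged = best$conv)
}

# predictive residual-variance criterion: sigma^2 * ((C-1)/(C-1-K))^2,
# sigma^2 = mean per-peak residual variance after projection on the
# assigned unit template
.cvCriterion <- function(p, lab, T) {
  C <- ncol(T)
  K <- nrow(T)
  if (K >= C - 1) return(NA_real_)
  proj <- rowSums(p$Xc * T[lab, , drop = FALSE])
  sigma2 <- mean(pmax(0, rowSums(p$Xc^2) - proj^2) / (C - 1))
  sigma2 * ((C - 1) / (C - 1 - K))^2
}

#' Choose the number of microstate classes by cross-validation
#'
#' Runs [modifiedKMeans()] for each K in \code{kRange} and picks the K
#' minimizing the predictive residual-variance criterion
#' \eqn{CV(K) = \hat\sigma^2 ((C-1)/(C-1-K))^2}, which penalizes the
#' per-peak residual variance by the degrees of freedom spent on templates.
#'
#' @param tset a [TopographySet-class].
#' @param kRange integer vector of candidate K (max must be < C - 1).
#' @param nRestarts,seed,tol,maxIter,templateUpdate passed to
#'   [modifiedKMeans()].
#' @return A list: \code{chosenK}, \code{table} (data.frame K, cv, gev),
#'   and \code{results} (the per-K [ClusteringResult-class] objects).
#' @export
selectK <- function(tset, kRange = 2:6, nRestarts = 50, seed = 1,
                    tol = 1e-6, maxIter = 100,
                    templateUpdate = c("mean", "eigen")) {
  if (!length(kRange)) stop("kRange must be non-empty")
  C <- ncol(maps(tset))
  if (max(kRange) >= C - 1)
    stop("max(kRange) must be smaller than the channel count minus 1")
  templateUpdate <- match.arg(templateUpdate)
  results <- lapply(kRange, function(K)
    modifiedKMeans(tset, K, nRestarts = nRestarts, seed = seed + K,
                   tol = tol, maxIter = maxIter,
                   templateUpdate = templateUpdate))
  tab <- data.frame(K = kRange,
                    cv = vapply(results, function(r) r@cvCriterion, 0),
                    gev = vapply(results, function(r) r@gevTotal, 0))
  list(chosenK = kRange[which.min(tab$cv)], table = tab,
       results = stats::setNames(results, paste0("K", kRange)))
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Relabel clustering templates against a canonical reference
#'
#' Finds the one-to-one template-to-reference matching that maximizes the
#' total absolute spatial correlation (exhaustive over all K! permutations,
#' deterministic first-in-lexicographic tie-break), reorders templates and
#' assignments accordingly, applies the reference labels, and flips each
#' template's polarity to agree with its reference map.
#'
#' @param result a [ClusteringResult-class].
#' @param reference a [TemplateSet-class] with the same K and channel count
#'   (e.g. [canonicalTemplates()]).
#' @return The relabeled [ClusteringResult-class]; GEV is unchanged.
#' @export
canonicalLabeling <- function(result, reference) {
  T <- maps(result@templates)
  Rf <- maps(reference)
  K <- nrow(T)
  if (nrow(Rf) != K) stop("reference K does not match result K")
  if (ncol(Rf) != ncol(T)) stop("channel counts differ")
  Rho <- .unitRows(T) %*% t(.unitRows(Rf))   # result x reference
  perms <- .permutations(seq_len(K))
  score <- vapply(perms, function(pm)
    sum(abs(Rho[cbind(pm, seq_len(K))])), 0)
  pm <- perms[[which.max(score)]]            # pm[j] = result row for ref j
  Tnew <- T[pm, , drop = FALSE]
  flip <- sign(Rho[cbind(pm, seq_len(K))])
  flip[flip == 0] <- 1
  Tnew <- Tnew * flip
  rownames(Tnew) <- reference@labels
  remap <- match(result@assignments, pm)
  pol <- result@polarity * flip[remap]
  tmpl <- new("TemplateSet", maps = Tnew, labels = reference@labels)
  new("ClusteringResult", templates = tmpl, assignments = as.integer(remap),
      polarity = pol, gevTotal = result@gevTotal,
      gevPerTemplate = result@gevPerTemplate[pm],
      cvCriterion = result@cvCriterion, nIterations = result@nIterations,
      converged = result@converged)
}

#' Topographic ANOVA (TANOVA) permutation test
#'
#' Tests whether two groups of maps share a common topography. The
#' statistic is the global map dissimilarity between the polarity-aligned,
#' GFP-normalized group-mean maps,
#' \eqn{DISS = \sqrt{mean_c (u_c/GFP_u - w_c/GFP_w)^2}}; the p-value is the
#' proportion of group-label permutations whose DISS is at least the
#' observed one (observed included). All distinct splits are enumerated
#' exactly when there are no more than \code{nPerm} of them.
#'
#' @param groupA,groupB [TopographySet-class] objects (e.g. one mean map
#'   per subject).
#' @param nPerm permutation budget (default 999).
#' @param seed RNG seed for the random-permutation branch.
#' @return A list: \code{diss}, \code{p}, \code{nPerm}, \code{exact}.
#' @export
tanova <- function(groupA, groupB, nPerm = 999, seed = 1) {
  A <- maps(groupA); B <- maps(groupB)
  if (!nrow(A) || !nrow(B)) stop("both groups must be non-empty")
  if (ncol(A) != ncol(B)) stop("channel counts differ")
  X <- rbind(A, B)
  nA <- nrow(A); n <- nrow(X)
  dissOf <- function(idxA) {
    u <- colMeans(X[idxA, , drop = FALSE])
    w <- colMeans(X[-idxA, , drop = FALSE])
    u <- u - mean(u); w <- w - mean(w)
    gu <- sqrt(mean(u^2)); gw <- sqrt(mean(w^2))
    if (gu == 0 || gw == 0) stop("zero-GFP mean map in TANOVA")
    u <- u / gu; w <- w / gw
    if (sum(u * w) < 0) w <- -w
    sqrt(mean((u - w)^2))
  }
  obs <- dissOf(seq_len(nA))
  # permuted splits whose polarity-opposed maps cancel to a zero-GFP mean
  # count as maximally dissimilar (conservative: a hit)
  dissPerm <- function(idx) tryCatch(dissOf(idx), error = function(e) Inf)
  nExact <- choose(n, nA)
  if (nExact <= nPerm) {
    splits <- utils::combn(n, nA)
    d <- apply(splits, 2, dissPerm)
    p <- mean(d >= obs - 1e-12)
    list(diss = obs, p = p, nPerm = ncol(splits), exact = TRUE)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPerm))
      if (dissPerm(sample.int(n, nA)) >= obs - 1e-12) hits <- hits + 1L
    list(diss = obs, p = (1 + hits) / (nPerm + 1), nPerm = nPerm,
         exact = FALSE)
  }
}
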