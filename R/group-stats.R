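#' Result of the repeated-measures multivariate group comparison
#'
#' @slot parameter which temporal parameter was compared.
#' @slot wilksLambda Wilks' Lambda for the group x state interaction.
#' @slot F approximate F (Rao's transformation).
#' @slot dfNum,dfDen degrees of freedom of the F approximation.
#' @slot pMultivariate multivariate p-value.
#' @slot posthoc per-state data.frame: t, p, group means (residual t-tests).
#' @slot alphaConfirmatory,alphaExploratory,alphaPosthoc the significance
#'   thresholds reported alongside (0.05, 0.1, and 0.05/K).
#' @slot degenerate empty string, or an explanation when the design was
#'   singular and no test could be computed.
#' @exportClass GroupStatsResult
setClass("GroupStatsResult",
  representation(parameter = "character", wilksLambda = "numeric",
                 F = "numeric", dfNum = "numeric", dfDen = "numeric",
                 pMultivariate = "numeric", posthoc = "data.frame",
                 alphaConfirmatory = "numeric", alphaExploratory = "numeric",
                 alphaPosthoc = "numeric", degenerate = "character"))

setMethod("show", "GroupStatsResult", function(object) {
  if (nzchar(object@degenerate)) {
    cat("GroupStatsResult (degenerate):", object@degenerate, "\n")
    return(invisible(NULL))
  }
  cat(sprintf("GroupStatsResult [%s]: Wilks' Lambda = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              object@parameter, object@wilksLambda, object@dfNum,
              object@dfDen, object@F, object@pMultivariate))
  print(object@posthoc, row.names = FALSE)
})

.paramColumns <- function(metrics, parameter) {
  col <- switch(parameter,
    mean_duration = "mean_duration_ms",
    gev = "gev",
    rtt = "ratio_total_time",
    occurrence = "occurrence_per_s",
    transition = NULL,
    stop("unknown parameter: ", parameter))
  states <- unique(metrics$state)
  ids <- unique(metrics$subject_id)
  if (!is.null(col)) {
    Y <- sapply(states, function(s)
      metrics[[col]][metrics$state == s][match(ids, metrics$subject_id[metrics$state == s])])
    colnames(Y) <- states
  } else {
    tcols <- grep("^trans_", names(metrics), value = TRUE)
    firstRows <- match(ids, metrics$subject_id)
    Y <- as.matrix(metrics[firstRows, tcols, drop = FALSE])
    colnames(Y) <- tcols
  }
  rownames(Y) <- ids
  Y
}

.subjectCovariates <- function(ids, subjects) {
  m <- match(ids, subjects$subject_id)
  if (anyNA(m)) stop("metrics contain subjects missing from the subject table")
  data.frame(group = factor(subjects$group[m]),
             age = as.numeric(subjects$age[m]),
             gender = factor(subjects$gender[m]))
}

#' Repeated-measures multivariate comparison of a microstate parameter
#'
#' Tests the group x microstate interaction on each subject's K-vector of
#' the chosen temporal parameter, with age and gender as covariates: the
#' K-1 within-subject difference contrasts are regressed on age, gender and
#' group, and the group effect (entered last) is evaluated with Wilks'
#' Lambda and Rao's F approximation. For \code{parameter = "transition"}
#' the off-diagonal row-normalized transition probabilities take the place
#' of the per-state vector.
#'
#' @param metrics long metrics table from [combineMetrics()].
#' @param subjects subject table (subject_id, group, age, gender).
#' @param parameter one of \code{"mean_duration"}, \code{"gev"},
#'   \code{"rtt"}, \code{"occurrence"}, \code{"transition"}.
#' @return A [GroupStatsResult-class]; singular designs yield a degenerate
#'   result carrying an explanation instead of an error.
#' @export
rmAnova <- function(metrics, subjects, parameter = "mean_duration") {
  Y <- .paramColumns(metrics, parameter)
  cov <- .subjectCovariates(rownames(Y), subjects)
  if (nlevels(cov$group) != 2 || any(table(cov$group) < 2))
    stop("need two groups with at least 2 subjects each")
  K <- ncol(Y)
  D <- Y[, -1, drop = FALSE] - Y[, 1]
  posthoc <- posthocResidualT(metrics, subjects, parameter)
  res <- tryCatch({
    fit <- stats::lm(D ~ age + gender + group, data = cov)
    at <- stats::anova(fit, test = "Wilks")
    i <- match("group", rownames(at))
    list(w = at[i, "Wilks"], f = at[i, "approx F"],
         d1 = at[i, "num Df"], d2 = at[i, "den Df"], p = at[i, "Pr(>F)"])
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(new("GroupStatsResult", parameter = parameter,
               wilksLambda = NA_real_, F = NA_real_, dfNum = NA_real_,
               dfDen = NA_real_, pMultivariate = NA_real_, posthoc = posthoc,
               alphaConfirmatory = 0.05, alphaExploratory = 0.1,
               alphaPosthoc = 0.05 / max(K, 1),
               degenerate = conditionMessage(res)))
  new("GroupStatsResult", parameter = parameter, wilksLambda = res$w,
      F = res$f, dfNum = res$d1, dfDen = res$d2, pMultivariate = res$p,
      posthoc = posthoc, alphaConfirmatory = 0.05, alphaExploratory = 0.1,
      alphaPosthoc = 0.05 / max(K, 1), degenerate = "")
}

#' Post hoc group t-tests on covariate-adjusted residuals
#'
#' Per state (or per transition pair), the parameter is regressed on age
#' and gender with both groups pooled; the unstandardized residuals are
#' compared between groups with a two-sample pooled-variance t-test. With a
#' two-level group factor, t is positive when the alphabetically first
#' group (e.g. "control") has the larger adjusted mean. The Bonferroni
#' threshold 0.05/K accompanies the p-values.
#'
#' @inheritParams rmAnova
#' @return data.frame with one row per state: t, p, and raw group means.
#' @export
posthocResidualT <- function(metrics, subjects, parameter = "mean_duration") {
  Y <- .paramColumns(metrics, parameter)
  cov <- .subjectCovariates(rownames(Y), subjects)
  g1 <- levels(cov$group)[1]
  g2 <- levels(cov$group)[2]
  out <- data.frame(state = colnames(Y), t = NA_real_, p = NA_real_,
                    mean1 = NA_real_, mean2 = NA_real_,
                    stringsAsFactors = FALSE)
  names(out)[4:5] <- paste0("mean_", c(g1, g2))
  # constant covariates carry no information; drop them so the pooled
  # residualization stays well-defined
  keep <- c(if (length(unique(cov$age)) > 1) "age",
            if (nlevels(droplevels(cov$gender)) > 1) "gender")
  form <- if (length(keep)) stats::reformulate(keep, "y") else y ~ 1
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    dat <- cbind(cov, y = y)
    res <- stats::residuals(stats::lm(form, data = dat))
    r1 <- res[cov$group == g1]
    r2 <- res[cov$group == g2]
    pooledVar <- (sum((r1 - mean(r1))^2) + sum((r2 - mean(r2))^2)) /
      (length(r1) + length(r2) - 2)
    out[[paste0("mean_", g1)]][j] <- mean(y[cov$group == g1])
    out[[paste0("mean_", g2)]][j] <- mean(y[cov$group == g2])
    if (pooledVar == 0) {
      if (mean(r1) == mean(r2)) {
        out$t[j] <- 0; out$p[j] <- 1
      } else {
        out$t[j] <- sign(mean(r1) - mean(r2)) * Inf
        out$p[j] <- 0
      }
    } else {
      se <- sqrt(pooledVar * (1 / length(r1) + 1 / length(r2)))
      tt <- (mean(r1) - mean(r2)) / se
      df <- length(r1) + length(r2) - 2
      out$t[j] <- tt
      out$p[j] <- 2 * stats::pt(-abs(tt), df)
    }
  }
  out
}
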