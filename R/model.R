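#' Case weights approximating a uniform age distribution
#'
#' Each recording is weighted by the inverse of the number of cases in its
#' completed-week bin, normalised to mean 1, so that over- and
#' under-represented gestational ages contribute equally to the fit.
#'
#' @param ages gestational ages in weeks, within `[21, 40]`.
#' @return positive numeric weights with mean 1.
#' @export
case_weights <- function(ages) {
  if (length(ages) == 0) stop("empty age vector")
  bin <- floor(ages)
  cnt <- table(bin)
  w <- 1 / as.numeric(cnt[as.character(bin)])
  w / mean(w)
}

#' Stepwise weighted regression of gestational age on HRV indices
#'
#' Weighted least squares with forward-backward stepwise selection on the
#' partial-F p-value: the forward step adds the candidate with the smallest
#' p-value if it is below `p_enter`; the backward step removes any included
#' predictor whose p-value exceeds `p_remove`; the steps alternate to a
#' fixed point. With `quadratic = TRUE` the candidate set is augmented with
#' squared terms of each (centered) index; centering constants are stored
#' with the model so prediction reproduces the training design. Weights are
#' treated as analytic (frequency-style) weights throughout, and the
#' adjusted R-squared is reported on the weighted fit.
#'
#' @param data data frame holding the target and candidate columns; rows
#'   with a missing candidate or target are dropped (count reported via
#'   `message()`).
#' @param candidates character vector of candidate predictor columns.
#' @param target name of the age column (default `"wga"`).
#' @param weights per-row case weights; default [case_weights()] of the
#'   target. Constant/collinear candidates are excluded with a warning.
#' @param p_enter,p_remove stepwise thresholds (defaults 0.05 / 0.10;
#'   `p_enter` must be below `p_remove`).
#' @param quadratic add centered squared terms of every candidate.
#' @param family label naming the model variant (e.g. `"full30"`,
#'   `"active10"`, `"quiet10"`, `"quiet10_patternseg"`).
#' @return object of class `fabas_model`: `coefficients`, `predictors`,
#'   `centers` (for squared terms), `adjusted_r2`, `n`, `family`, `config`,
#'   and the underlying `lm` fit as attribute `fit`.
#' @export
stepwise_fit <- function(data, candidates, target = "wga", weights = NULL,
                         p_enter = 0.05, p_remove = 0.10, quadratic = FALSE,
                         family = "full30") {
  stopifnot(p_enter < p_remove)
  miss <- !stats::complete.cases(data[, c(target, candidates), drop = FALSE])
  if (any(miss)) {
    message(sum(miss), " row(s) with missing values dropped")
    data <- data[!miss, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[!miss]
  }
  if (is.null(weights)) weights <- case_weights(data[[target]])
  centers <- numeric(0)
  if (quadratic) {
    for (cand in candidates) {
      ctr <- mean(data[[cand]])
      centers[cand] <- ctr
      data[[paste0(cand, "_sq")]] <- (data[[cand]] - ctr)^2
    }
    candidates <- c(candidates, paste0(candidates, "_sq"))
  }
  sds <- vapply(candidates, function(cand) stats::sd(data[[cand]]), numeric(1))
  if (any(sds == 0)) {
    warning("constant candidate(s) excluded: ",
            paste(candidates[sds == 0], collapse = ", "))
    candidates <- candidates[sds > 0]
  }
  df <- data
  df$.w <- weights
  fit_with <- function(preds) {
    f <- if (length(preds) == 0) stats::as.formula(paste(target, "~ 1")) else
      stats::as.formula(paste(target, "~", paste(preds, collapse = " + ")))
    stats::lm(f, data = df, weights = .w)
  }
  partial_p <- function(small, big) {
    a <- stats::anova(small, big)
    a[["Pr(>F)"]][2]
  }
  included <- character(0)
  fit <- fit_with(included)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      ps <- vapply(pool, function(cand) {
        partial_p(fit, fit_with(c(included, cand)))
      }, numeric(1))
      if (min(ps, na.rm = TRUE) < p_enter) {
        included <- c(included, pool[which.min(ps)])
        fit <- fit_with(included)
        changed <- TRUE
      }
    }
    repeat {
      if (length(included) == 0) break
      ps <- vapply(included, function(cand) {
        partial_p(fit_with(setdiff(included, cand)), fit)
      }, numeric(1))
      if (max(ps, na.rm = TRUE) > p_remove) {
        included <- setdiff(included, included[which.max(ps)])
        fit <- fit_with(included)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit), predictors = included,
                 centers = centers, adjusted_r2 = sm$adj.r.squared,
                 n = nrow(df), family = family,
                 intercept_only = length(included) == 0,
                 config = list(p_enter = p_enter, p_remove = p_remove,
                               quadratic = quadratic, candidates = candidates)),
            fit = fit, class = "fabas_model")
}

#' @export
print.fabas_model <- function(x, ...) {
  cat(sprintf("<fabas_model '%s'> n = %d, adjusted R^2 = %.3f\n",
              x$family, x$n, x$adjusted_r2))
  cat("  predictors:", if (length(x$predictors)) paste(x$predictors, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Predict gestational age (the fABAS score) from an index vector
#'
#' Applies the fitted linear combination; squared terms use the centering
#' constants stored with the model.
#'
#' @param object a `fabas_model`.
#' @param newdata an `index_vector`, a named list, or a data frame row with
#'   the model's predictor columns (base names for quadratic models).
#' @param ... unused.
#' @return predicted age in weeks; `NA` with a `reason` attribute when a
#'   required predictor is missing.
#' @export
predict.fabas_model <- function(object, newdata, ...) {
  if (length(object$predictors) == 0) {
    return(unname(object$coefficients[["(Intercept)"]]))
  }
  get1 <- function(nm) {
    base <- sub("_sq$", "", nm)
    v <- newdata[[base]]
    if (is.null(v) || all(is.na(v))) return(NULL)
    v <- as.numeric(v)
    if (endsWith(nm, "_sq")) (v - object$centers[[base]])^2 else v
  }
  first <- newdata[[sub("_sq$", "", object$predictors[1])]]
  score <- rep(object$coefficients[["(Intercept)"]], max(1L, length(first)))
  for (nm in object$predictors) {
    v <- get1(nm)
    if (is.null(v)) {
      return(structure(NA_real_, reason = paste("missing predictor:", sub("_sq$", "", nm))))
    }
    score <- score + object$coefficients[[nm]] * v
  }
  unname(score)
}

#' @rdname predict.fabas_model
#' @param model a `fabas_model`.
#' @param iv index values (see `newdata`).
#' @export
predict_age <- function(model, iv) predict.fabas_model(model, iv)

.nm_bins <- function() {
  # weekly bins with the sparse edges merged (21-24 and 37-40)
  b <- list(c(21, 24))
  for (w in 25:36) b[[length(b) + 1]] <- c(w, w)
  b[[length(b) + 1]] <- c(37, 40)
  b
}

.nm_bin_of <- function(wga) {
  w <- floor(wga)
  bins <- .nm_bins()
  for (i in seq_along(bins)) if (w >= bins[[i]][1] && w <= bins[[i]][2]) return(i)
  NA_integer_
}

#' Build a score normogram over gestational age
#'
#' Per-age-bin weighted mean and SD of the predicted scores. Bins are
#' weekly except for the merged edge bins 21-24 and 37-40 weeks, where
#' cohorts are typically sparse. Empty bins are omitted with a warning.
#'
#' @param scores predicted ages (weeks).
#' @param ages chronological gestational ages (weeks).
#' @param weights optional case weights (mean 1); equal weights by default.
#' @return data frame of class `fabas_normogram`: `bin_lo`, `bin_hi`,
#'   `mean`, `sd`, `n`.
#' @export
build_normogram <- function(scores, ages, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(scores))
  bins <- .nm_bins()
  rows <- lapply(seq_along(bins), function(i) {
    sel <- floor(ages) >= bins[[i]][1] & floor(ages) <= bins[[i]][2] &
      is.finite(scores)
    if (!any(sel)) return(NULL)
    s <- scores[sel]; w <- weights[sel]; w <- w / mean(w)
    m <- sum(w * s) / sum(w)
    sdv <- if (sum(sel) > 1) sqrt(sum(w * (s - m)^2) / (sum(w) - 1)) else NA_real_
    data.frame(bin_lo = bins[[i]][1], bin_hi = bins[[i]][2],
               mean = m, sd = sdv, n = sum(sel))
  })
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop)) warning(sum(drop), " empty normogram bin(s) omitted")
  structure(do.call(rbind, rows[!drop]),
            class = c("fabas_normogram", "data.frame"))
}

#' Deviation of a score from the normogram, in SD units
#'
#' @param score predicted age (weeks).
#' @param wga chronological age (weeks); its bin must be present.
#' @param nm a `fabas_normogram`.
#' @return z-score `(score - bin mean) / bin sd`; `NA` with a `reason`
#'   attribute when the bin SD is zero or missing.
#' @export
score_deviation <- function(score, wga, nm) {
  i <- which(nm$bin_lo <= floor(wga) & nm$bin_hi >= floor(wga))
  if (length(i) == 0) stop("no normogram bin for wga ", wga)
  if (!is.finite(nm$sd[i]) || nm$sd[i] <= 0) {
    return(structure(NA_real_, reason = "bin SD unavailable"))
  }
  (score - nm$mean[i]) / nm$sd[i]
}
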