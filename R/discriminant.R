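# Canonical discriminant functions, the 2-D fire-weather plane, quadratic
# discriminant classification and leave-one-out cross-validation.

#' Canonical discriminant analysis of a cluster model
#'
#' Eigen-decomposes `W^-1 B` (within- and between-cluster cross-product
#' matrices of the standardized variables) into `min(d, k-1)` canonical
#' axes, ordered by eigenvalue. Each axis reports its eigenvalue share of
#' the explained variation (`pct_variance`), its structural correlations
#' (Pearson correlation of each post-transform variable with the canonical
#' score) and a Wilks-based approximate F test. Axes are oriented so the
#' variable with the largest absolute structural correlation loads
#' positively. A quadratic discriminant classifier (class-specific
#' covariances) is fitted alongside and the resubstitution
#' misclassification rate reported.
#'
#' @param features An [fw_features()] object.
#' @param model An `fw_cluster` fitted on `features`, or a label vector
#'   (0 = unassigned, excluded).
#' @param priors `"equal"` (default) or `"proportional"` class priors for
#'   the classifier.
#' @return An object of class `fw_discriminant`: coefficients (d x q),
#'   eigenvalues, `pct_variance`, `struct_corr` (d x q), per-day `scores`
#'   (tibble: date, f1, f2, cluster; unassigned days NA), `f_stats`
#'   (tibble: function, eigenvalue, pct_variance, f_approx, p_value),
#'   the fitted classifier, `predicted`, and `misclassification`.
#' @export
fw_discriminant <- function(features, model, priors = c("equal",
                                                        "proportional")) {
  priors <- match.arg(priors)
  labels <- if (inherits(model, "fw_cluster")) model$labels else model
  values <- feature_matrix(features)
  raw <- raw_matrix(features)
  stopifnot(nrow(values) == length(labels))
  keep <- labels > 0
  v <- values[keep, , drop = FALSE]
  lab <- labels[keep]
  d <- ncol(v)
  k <- length(unique(lab))
  n <- nrow(v)
  if (k < 2) abort("discriminant analysis requires >= 2 clusters")
  if (n <= d + k) abort("discriminant analysis requires n > d + k")

  bw <- between_within(v, lab)
  winv_b <- tryCatch(solve(bw$W, bw$B), error = function(e) {
    warn("singular within-cluster matrix; ridge-regularized")
    solve(bw$W + diag(1e-8 * mean(diag(bw$W)), d), bw$B)
  })
  eig <- eigen(winv_b)
  lambda <- Re(eig$values)
  vecs <- Re(eig$vectors)
  ord <- order(lambda, decreasing = TRUE)
  q <- min(d, k - 1)
  lambda <- pmax(lambda[ord][seq_len(q)], 0)
  coef <- vecs[, ord[seq_len(q)], drop = FALSE]
  rownames(coef) <- colnames(v)

  grand <- colMeans(v)
  sc <- sweep(v, 2, grand) %*% coef
  # structural correlations against post-transform (pre-z) variables
  struct <- cor(raw[keep, , drop = FALSE], sc)
  for (j in seq_len(q)) {
    lead <- which.max(abs(struct[, j]))
    if (struct[lead, j] < 0) {
      coef[, j] <- -coef[, j]
      sc[, j] <- -sc[, j]
      struct[, j] <- -struct[, j]
    }
  }
  colnames(coef) <- colnames(sc) <- colnames(struct) <-
    paste0("f", seq_len(q))
  pct <- 100 * lambda / sum(lambda)
  fst <- wilks_f_tests(lambda, d, k, n)

  classifier <- fit_qda(v, lab, priors)
  pred <- predict_qda(classifier, v)
  misclass <- mean(pred != lab)

  scores <- tibble(date = if (!is.null(feature_dates(features)))
    feature_dates(features) else as.Date(NA)[seq_along(labels)],
    cluster = labels, f1 = NA_real_,
    f2 = NA_real_)
  scores$f1[keep] <- sc[, 1]
  scores$f2[keep] <- if (q >= 2) sc[, 2] else 0

  structure(list(
    coefficients = coef, eigenvalues = lambda, pct_variance = pct,
    struct_corr = struct, scores = scores,
    f_stats = tibble(fun = paste0("f", seq_len(q)),
                     eigenvalue = lambda, pct_variance = pct,
                     f_approx = fst$f, p_value = fst$p),
    grand_mean = grand, classifier = classifier, priors = priors,
    predicted = pred, labels_used = lab, misclassification = misclass,
    pipeline = list(variables = feature_vars(features),
                    log_vars = attr(features, "log_vars"),
                    center = attr(features, "center"),
                    scale = attr(features, "scale"))),
    class = "fw_discriminant")
}

# Sequential Wilks-lambda tests of canonical functions j..q with Rao's F
# approximation.
wilks_f_tests <- function(lambda, d, k, n) {
  q <- length(lambda)
  f <- p <- numeric(q)
  for (j in seq_len(q)) {
    wl <- prod(1 / (1 + lambda[j:q]))
    pj <- d - j + 1
    qj <- k - j
    m <- n - 1 - (d + k) / 2
    s2 <- (pj^2 * qj^2 - 4) / (pj^2 + qj^2 - 5)
    s <- if (is.finite(s2) && s2 > 0) sqrt(s2) else 1
    df1 <- pj * qj
    df2 <- m * s - pj * qj / 2 + 1
    wls <- wl^(1 / s)
    f[j] <- (1 - wls) / wls * df2 / df1
    p[j] <- pf(f[j], df1, df2, lower.tail = FALSE)
  }
  list(f = f, p = p)
}

#' @export
print.fw_discriminant <- function(x, ...) {
  q <- length(x$eigenvalues)
  cat("<fw_discriminant> ", q, " canonical function(s); variance split ",
      paste0(sprintf("%.0f%%", x$pct_variance), collapse = "/"),
      "; resubstitution misclassification ",
      sprintf("%.1f%%", 100 * x$misclassification), "\n", sep = "")
  cat("structural correlations:\n")
  print(round(x$struct_corr, 2))
  invisible(x)
}

#' @describeIn fw_discriminant Table-style tidy output: one row per
#'   (function, variable) with the structural correlation and the
#'   function's variance share.
#' @param x An `fw_discriminant`.
#' @param ... Unused.
#' @export
tidy.fw_discriminant <- function(x, ...) {
  q <- length(x$eigenvalues)
  list_rbind(lapply(seq_len(q), function(j) {
    tibble(fun = paste0("f", j),
           variable = rownames(x$struct_corr),
           structural_correlation = x$struct_corr[, j],
           pct_variance = x$pct_variance[j])
  }))
}

#' @describeIn fw_discriminant One-row model summary.
#' @export
glance.fw_discriminant <- function(x, ...) {
  tibble(n_functions = length(x$eigenvalues),
         pct_variance_f1 = x$pct_variance[1],
         pct_variance_f2 = if (length(x$pct_variance) >= 2)
           x$pct_variance[2] else NA_real_,
         misclassification = x$misclassification,
         priors = x$priors)
}

# Quadratic discriminant classifier via MASS; falls back to the pooled-
# covariance (linear) classifier when some class is too small for a
# class-specific covariance.
fit_qda <- function(v, lab, priors = "equal") {
  k <- length(unique(lab))
  prior <- if (priors == "equal") rep(1 / k, k) else
    as.numeric(table(lab)) / length(lab)
  sizes <- table(lab)
  if (min(sizes) <= ncol(v)) {
    warn("class too small for class-specific covariance; pooled fallback")
    fit <- MASS::lda(v, grouping = factor(lab), prior = prior)
  } else {
    fit <- MASS::qda(v, grouping = factor(lab), prior = prior)
  }
  fit
}

predict_qda <- function(fit, v) {
  as.integer(as.character(stats::predict(fit, v)$class))
}

#' Classify days with the fitted quadratic discriminant rule
#'
#' @param dmodel An [fw_discriminant()].
#' @param newdata An [fw_features()] object, a weather tibble (transformed
#'   through the training pipeline) or a bare standardized matrix.
#' @return A tibble: `cluster` (predicted) plus `date` when known.
#' @export
qda_classify <- function(dmodel, newdata) {
  stopifnot(inherits(dmodel, "fw_discriminant"))
  v <- newdata_to_matrix(dmodel, newdata)
  pred <- predict_qda(dmodel$classifier, v$x)
  out <- tibble(cluster = pred)
  if (!is.null(v$date)) out <- bind_cols(tibble(date = v$date), out)
  out
}

#' Project days onto the fire-weather plane
#'
#' Returns coordinates on canonical functions I and II for the supplied
#' days (training or new data run through the training transform/
#' standardization pipeline). When only one canonical function exists, the
#' second coordinate is zero.
#'
#' @param dmodel An [fw_discriminant()].
#' @param newdata [fw_features()], weather tibble, or standardized matrix
#'   with the training variables.
#' @return A tibble: `f1`, `f2` (plus `date` when known).
#' @export
fw_project <- function(dmodel, newdata) {
  stopifnot(inherits(dmodel, "fw_discriminant"))
  v <- newdata_to_matrix(dmodel, newdata)
  sc <- sweep(v$x, 2, dmodel$grand_mean) %*% dmodel$coefficients
  out <- tibble(f1 = sc[, 1],
                f2 = if (ncol(sc) >= 2) sc[, 2] else 0)
  if (!is.null(v$date)) out <- bind_cols(tibble(date = v$date), out)
  out
}

newdata_to_matrix <- function(dmodel, newdata) {
  vars <- dmodel$pipeline$variables
  if (inherits(newdata, "fw_features")) {
    if (!identical(feature_vars(newdata), vars)) {
      abort("variable mismatch between model and new features")
    }
    return(list(x = feature_matrix(newdata), date = feature_dates(newdata)))
  }
  if (is.data.frame(newdata)) {
    if (!all(vars %in% names(newdata))) {
      abort(paste0("new data lacks variable(s): ",
                   paste(setdiff(vars, names(newdata)), collapse = ", ")))
    }
    dat <- newdata[vars]
    for (v in dmodel$pipeline$log_vars) dat[[v]] <- log(dat[[v]])
    for (v in vars) {
      dat[[v]] <- (dat[[v]] - dmodel$pipeline$center[[v]]) /
        dmodel$pipeline$scale[[v]]
    }
    return(list(x = as.matrix(dat),
                date = if ("date" %in% names(newdata)) newdata$date))
  }
  stopifnot(is.matrix(newdata), ncol(newdata) == length(vars))
  list(x = newdata, date = NULL)
}

#' Leave-one-out cross-validation of the quadratic discriminant rule
#'
#' Refits the classifier with each day held out in turn and reports the
#' LOO misclassification rate, the per-cluster confusion matrix, and the
#' fraction of misclassified days falling within +/- `boundary_window` days
#' of a season predominance boundary (transitional days are expected to be
#' the hard ones).
#'
#' @param features An [fw_features()] object.
#' @param model `fw_cluster` or label vector.
#' @param priors As in [fw_discriminant()].
#' @param profile Optional [season_profile()] used for the boundary
#'   diagnostic (computed from the model when omitted and dates are known).
#' @param boundary_window Half-width in days (default 7).
#' @return A list: `rate`, `confusion` (table), `boundary_fraction`,
#'   `n_errors`, `resubstitution`.
#' @export
fw_loocv <- function(features, model, priors = c("equal", "proportional"),
                     profile = NULL, boundary_window = 7) {
  priors <- match.arg(priors)
  labels <- if (inherits(model, "fw_cluster")) model$labels else model
  values <- feature_matrix(features)
  keep <- labels > 0
  v <- values[keep, , drop = FALSE]
  lab <- labels[keep]
  k <- length(unique(lab))
  prior <- if (priors == "equal") rep(1 / k, k) else
    as.numeric(table(lab)) / length(lab)
  if (min(table(lab)) <= ncol(v)) {
    warn("class too small for class-specific covariance; pooled LOOCV")
    cv <- MASS::lda(v, grouping = factor(lab), prior = prior, CV = TRUE)
  } else {
    cv <- MASS::qda(v, grouping = factor(lab), prior = prior, CV = TRUE)
  }
  pred <- as.integer(as.character(cv$class))
  errors <- pred != lab
  confusion <- table(truth = lab, predicted = pred)

  boundary_fraction <- NA_real_
  dates <- feature_dates(features)
  if (!is.null(dates)) {
    if (is.null(profile) && inherits(model, "fw_cluster") &&
        !is.null(model$date)) {
      profile <- season_profile(model)
    }
    if (!is.null(profile) && any(errors)) {
      bdys <- unique(profile$predominance$start_doy)
      err_doy <- doy_folded(dates[keep][errors])
      near <- vapply(err_doy, function(d) {
        any(circular_doy_dist(d, bdys) <= boundary_window)
      }, logical(1))
      boundary_fraction <- mean(near)
    }
  }
  resub <- mean(predict_qda(fit_qda(v, lab, priors), v) != lab)
  list(rate = mean(errors), confusion = confusion,
       boundary_fraction = boundary_fraction, n_errors = sum(errors),
       resubstitution = resub)
}

circular_doy_dist <- function(d, b, period = 365) {
  raw <- abs(d - b)
  pmin(raw, period - raw)
}
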