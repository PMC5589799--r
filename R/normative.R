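# Normative model: per-feature polynomial age trends (BIC order selection)
# with optional sex/scanner covariates, robust artifact screening with
# validity odds, repeated-scan measurement error, and single-scan abnormality
# scoring with prediction-interval calibration (Student-t tails, leverage).

# polynomial multiply (coefficient convolution, lowest order first)
.poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# rebase coefficients from the t = (age - center)/scale basis to natural age
.poly_rebase <- function(b, center, scale) {
  out <- numeric(length(b))
  basis <- 1
  for (j in seq_along(b)) {
    out[seq_along(basis)] <- out[seq_along(basis)] + b[j] * basis
    basis <- .poly_mult(basis, c(-center / scale, 1 / scale))
  }
  out
}

# Consistency factor for the residual variance after screening |robust z| > c:
# expected variance retained when the Gaussian tail beyond the realized
# threshold is trimmed. The threshold uses a median/MAD z, whose sampling
# noise at sample size n widens the effectively trimmed mass, so the plain
# truncated-variance factor under-corrects; we integrate over the MAD's
# asymptotic relative error (CV ~ sqrt(1.361/n)).
.trim_factor <- function(c, n) {
  v <- function(cc) 1 - 2 * cc * stats::dnorm(cc) / (2 * stats::pnorm(cc) - 1)
  s <- sqrt(1.361 / n)
  d <- seq(-4, 4, length.out = 81)
  w <- stats::dnorm(d, sd = 1)
  w <- w / sum(w)
  sum(w * v(pmax(c * (1 + d * s), 0.5)))
}

#' Fit a low-order polynomial age trend to one feature
#'
#' Least-squares polynomial in age with the order (up to `max_order`) selected
#' by BIC; the population SD is the degrees-of-freedom-corrected residual SD.
#'
#' @param ages Ages in years.
#' @param values Feature values.
#' @param max_order Maximum polynomial order considered (default 3).
#' @return List of class `mn_age_trend` with `order`, `coefficients` (natural
#'   age basis, intercept first), `population_sd`, `df`, `residuals`, `fitted`
#'   and internals used for prediction.
#' @examples
#' tr <- fit_age_trend(20:60, 2 + 0.1 * (20:60))
#' tr$order          # 1
#' tr$coefficients   # ~ c(2, 0.1)
#' @export
fit_age_trend <- function(ages, values, max_order = 3) {
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  n <- length(ages)
  if (n < 2) stop("need at least two observations")
  nd <- length(unique(ages))
  center <- mean(ages)
  scale <- stats::sd(ages)
  if (!is.finite(scale) || scale == 0) scale <- 1
  t <- (ages - center) / scale
  orders <- 0:min(max_order, nd - 1, n - 2)
  Tm <- outer(t, 0:max(orders), "^")
  rss_floor <- 1e-20 * (sum(values^2) + 1)   # exact fits tie at the floor
  bic <- sapply(orders, function(o) {
    rss <- sum(qr.resid(qr(Tm[, 1:(o + 1), drop = FALSE]), values)^2)
    n * log(max(rss, rss_floor) / n) + (o + 2) * log(n)
  })
  o <- orders[which.min(bic)]
  X <- Tm[, 1:(o + 1), drop = FALSE]
  fit <- lm.fit(X, values)
  df <- n - (o + 1)
  sigma <- sqrt(sum(fit$residuals^2) / df)
  structure(list(
    order = o,
    coefficients = .poly_rebase(fit$coefficients, center, scale),
    coefficients_scaled = unname(fit$coefficients),
    population_sd = sigma, df = df,
    residuals = unname(fit$residuals), fitted = unname(fit$fitted.values),
    age_center = center, age_scale = scale,
    xtxinv = chol2inv(chol(crossprod(X)))
  ), class = "mn_age_trend")
}

#' @export
predict.mn_age_trend <- function(object, age, ...) {
  t <- (age - object$age_center) / object$age_scale
  drop(outer(t, seq_along(object$coefficients_scaled) - 1, "^") %*%
         object$coefficients_scaled)
}

#' @export
print.mn_age_trend <- function(x, ...) {
  cat("Polynomial age trend, order", x$order, "\n")
  cat("  coefficients (natural age basis):",
      signif(x$coefficients, 4), "\n")
  cat("  population SD:", signif(x$population_sd, 4),
      " (df =", x$df, ")\n")
  invisible(x)
}

#' Region- and parameter-specific measurement error from repeated scans
#'
#' Estimated from within-pair differences of repeated measurements of the same
#' subjects (after removing the fitted age-trend prediction at each scan's
#' age): `measurement_sd = sqrt(mean(d^2) / 2)`, the root-mean-square
#' difference over pairs divided by sqrt(2).
#'
#' @param x1,x2 Trend-corrected values (or residuals) of the first/second scan
#'   of each pair; equal length.
#' @return The measurement SD (0, with a warning, when no pairs are given).
#' @export
estimate_measurement_error <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  d <- (x1 - x2)[is.finite(x1) & is.finite(x2)]
  if (!length(d)) {
    warning("no repeat pairs available; measurement SD set to 0")
    return(0)
  }
  sqrt(mean(d^2) / 2)
}

#' Artifact probability and validity odds for one feature
#'
#' Flags statistical outliers by a robust rule (|z| > `z_threshold` with z
#' computed from the median and MAD) and converts the outlier fraction into an
#' artifact probability with Haldane +1/2 smoothing, so the odds for a valid
#' vs. artifactual measurement are always finite and positive.
#'
#' @param values Control residuals (or values) of one feature.
#' @param z_threshold Robust-z cutoff (default 3.5).
#' @return List with `outlier` (logical), `n_outliers`, `artifact_probability`
#'   `= (n_outliers + 1/2) / (n + 1)` and `odds_valid`.
#' @export
estimate_artifact_odds <- function(values, z_threshold = 3.5) {
  ok <- is.finite(values)
  med <- stats::median(values[ok])
  s <- stats::mad(values[ok])
  if (!is.finite(s) || s == 0) s <- stats::sd(values[ok])
  out <- rep(FALSE, length(values))
  if (is.finite(s) && s > 0) {
    out[ok] <- abs(values[ok] - med) / s > z_threshold
  }
  k <- sum(out)
  p <- (k + 0.5) / (sum(ok) + 1)
  list(outlier = out, n_outliers = k, artifact_probability = p,
       odds_valid = (1 - p) / p)
}

#' Two-sided abnormality probability of a single observation
#'
#' The probability that a residual of the observed magnitude occurs by chance
#' given the width of the control distribution and the measurement error:
#' `z = (value - trend(age)) / sqrt(population_sd^2 + measurement_sd^2)` and
#' `p` is the two-sided Gaussian (or Student-t, when `df` is finite) tail
#' probability. Within a fitted normative model the scoring additionally
#' accounts for the trend's prediction leverage; this standalone form is the
#' plain textbook statistic.
#'
#' @param value Observed value.
#' @param age Age at scan (years).
#' @param trend An `mn_age_trend` (or a numeric vector of natural-basis
#'   polynomial coefficients, intercept first).
#' @param population_sd Biological between-subject SD.
#' @param measurement_sd Measurement SD (default 0).
#' @param df Degrees of freedom of the tail (default `Inf`, Gaussian).
#' @return List with `sign` (of the residual), `z` and `p`.
#' @export
abnormality_p <- function(value, age, trend, population_sd,
                          measurement_sd = 0, df = Inf) {
  pred <- if (inherits(trend, "mn_age_trend")) {
    predict(trend, age)
  } else {
    drop(outer(age, seq_along(trend) - 1, "^") %*% trend)
  }
  r <- value - pred
  width <- sqrt(population_sd^2 + measurement_sd^2)
  z <- r / width
  p <- 2 * stats::pt(-abs(z), df = df)
  s <- sign(r)
  s[abs(z) < 1e-12] <- 0   # numerically zero residual
  list(sign = s, z = z, p = pmin(p, 1))
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up FDR decision at level `q` over one test family (conventionally the
#' 2,976 tests of one variant of one dataset).
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param q FDR level (default 0.01).
#' @return Logical vector: `TRUE` where the test survives FDR correction.
#' @export
fdr_flag <- function(p_values, q = 0.01) {
  if (!length(p_values)) return(logical(0))
  stats::p.adjust(p_values, method = "BH") <= q
}

# ---- covariate design ---------------------------------------------------------

# centred dummy design for the retained confounders; levels fixed at fit time
.cov_design <- function(meta, cov_info) {
  if (!length(cov_info$columns)) {
    return(matrix(0, nrow(meta), 0))
  }
  cols <- lapply(cov_info$columns, function(cn) {
    lv <- cov_info$levels[[cn]]
    x <- as.character(meta[[cn]])
    bad <- !x %in% lv
    if (any(bad)) {
      stop("unseen ", cn, " value(s) at scoring time: ",
           paste(unique(x[bad]), collapse = ", "),
           " (known: ", paste(lv, collapse = ", "),
           "); re-fit the model or map to the closest known group")
    }
    d <- outer(x, lv[-1], "==") * 1
    colnames(d) <- paste(cn, lv[-1], sep = "=")
    d
  })
  D <- do.call(cbind, cols)
  sweep(D, 2, cov_info$means)
}

.cov_info <- function(meta, covariates) {
  columns <- character(0)
  levels <- list()
  for (cn in covariates) {
    lv <- sort(unique(as.character(meta[[cn]])))
    lv <- lv[!is.na(lv)]
    if (length(lv) >= 2) {
      columns <- c(columns, cn)
      levels[[cn]] <- lv
    }
  }
  info <- list(columns = columns, levels = levels, means = numeric(0))
  if (length(columns)) {
    D <- .cov_design(meta, list(columns = columns, levels = levels,
                                means = 0))
    info$means <- colMeans(D)
  }
  info
}

# ---- block fitting ------------------------------------------------------------

# Fit all features of one matrix block (columns = features, rows = scans).
# D: centred covariate design shared by all features.
.fit_block <- function(Y, t, D, max_order, artifact_z, pair_idx) {
  n <- nrow(Y); m <- ncol(Y)
  nc <- ncol(D)
  max_order <- max(0, min(max_order, n - nc - 2))
  Tm <- outer(t, 0:max_order, "^")
  orders <- 0:max_order
  design <- function(o) cbind(Tm[, 1:(o + 1), drop = FALSE], D)

  qrs <- lapply(orders, function(o) qr(design(o)))
  rss <- sapply(orders, function(o) colSums(qr.resid(qrs[[o + 1]], Y)^2))
  if (m == 1) rss <- matrix(rss, nrow = 1)
  rss <- pmax(rss, 1e-20 * (colSums(Y^2) + 1))  # exact fits tie at the floor
  bic <- n * log(pmax(rss, 1e-300) / n) +
    matrix((orders + nc + 2) * log(n), m, length(orders), byrow = TRUE)
  ord <- orders[max.col(-bic, ties.method = "first")]

  # initial residuals at the selected order -> robust outlier screen
  R0 <- matrix(0, n, m)
  for (o in unique(ord)) {
    j <- ord == o
    R0[, j] <- qr.resid(qrs[[o + 1]], Y[, j, drop = FALSE])
  }
  med <- apply(R0, 2, stats::median)
  scl <- apply(R0, 2, stats::mad)
  sdfall <- apply(R0, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- sdfall[!is.finite(scl) | scl == 0]
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- abs(sweep(sweep(R0, 2, med), 2, scl, "/"))
  out <- Z > artifact_z
  n_out <- colSums(out)
  artifact_p <- (n_out + 0.5) / (n + 1)
  odds <- (1 - artifact_p) / artifact_p

  k_max <- max_order + 1 + nc
  coef <- matrix(0, k_max, m)
  sigma2 <- numeric(m)
  df <- numeric(m)
  trim <- .trim_factor(artifact_z, n)

  # clean features share the full design: vectorize per order
  for (o in unique(ord)) {
    j <- which(ord == o & n_out == 0)
    if (length(j)) {
      k <- o + 1 + nc
      fit <- lm.fit(design(o), Y[, j, drop = FALSE])
      cf <- matrix(fit$coefficients, k)
      coef[c(1:(o + 1), if (nc) (max_order + 2):k_max), j] <- cf
      df[j] <- n - k
      sigma2[j] <- colSums(matrix(fit$residuals, n)^2) / (n - k)
    }
  }
  # features with screened outliers: refit per feature without them
  for (j in which(n_out > 0)) {
    keep <- !out[, j]
    o <- max(0, min(ord[j], sum(keep) - nc - 2))
    k <- o + 1 + nc
    X <- design(o)[keep, , drop = FALSE]
    fit <- lm.fit(X, Y[keep, j])
    coef[c(1:(o + 1), if (nc) (max_order + 2):k_max), j] <- fit$coefficients
    ord[j] <- o
    df[j] <- sum(keep) - k
    sigma2[j] <- sum(fit$residuals^2) / df[j]
  }
  sigma2 <- sigma2 / trim   # de-bias for the screened tail mass

  # leverage of a new scan, shared per order (outlier-refit designs differ in
  # at most a few of n rows; the difference in h is O(1/n^2) and ignored)
  xtxinv <- lapply(orders, function(o) {
    chol2inv(chol(crossprod(design(o))))
  })

  # final residuals on all scans (outliers included, for the pair estimator)
  Rf <- Y - cbind(Tm, D) %*% coef

  meas_sd <- rep(0, m)
  if (nrow(pair_idx)) {
    Dif <- Rf[pair_idx[, 1], , drop = FALSE] -
      Rf[pair_idx[, 2], , drop = FALSE]
    # pairs containing a screened-out value would contaminate the estimate
    bad <- out[pair_idx[, 1], , drop = FALSE] |
      out[pair_idx[, 2], , drop = FALSE]
    Dif[bad] <- NA
    meas_sd <- sqrt(colMeans(Dif^2, na.rm = TRUE) / 2)
    meas_sd[!is.finite(meas_sd)] <- 0
  }
  sigma <- sqrt(sigma2)
  pop_sd <- sqrt(pmax(sigma2 - meas_sd^2, 0.01 * sigma2))

  list(order = ord, coef = coef, sigma = sigma, df = df,
       xtxinv = xtxinv, max_order = max_order, n_cov = nc,
       artifact_p = artifact_p, odds = odds, n_outliers = n_out,
       measurement_sd = meas_sd, population_sd = pop_sd,
       features = colnames(Y))
}

# score one block for new scans: X0 parts built from t_new and D_new
.score_block <- function(bl, Ynew, t_new, D_new) {
  n <- nrow(Ynew)
  Tm <- outer(t_new, 0:bl$max_order, "^")
  X0 <- cbind(Tm, D_new)
  pred <- X0 %*% bl$coef
  # per-order leverage h_i = x0' (X'X)^-1 x0, then pick per feature by order
  H <- sapply(seq_along(bl$xtxinv), function(oi) {
    o <- oi - 1
    x0 <- cbind(Tm[, 1:(o + 1), drop = FALSE], D_new)
    rowSums((x0 %*% bl$xtxinv[[oi]]) * x0)
  })
  if (n == 1) H <- matrix(H, nrow = 1)
  h <- H[, bl$order + 1, drop = FALSE]
  se <- sqrt(1 + h) * rep(bl$sigma, each = n)
  z <- (Ynew - pred) / se
  dfm <- rep(bl$df, each = n)
  if (!is.null(bl$delta_cv) && any(bl$delta_cv > 0)) {
    # asymmetry indices: z is a scale mixture z0/(1+delta), delta the relative
    # fluctuation of the (L+R) denominator; integrate the tail over delta with
    # the variance-matching factor g = E[(1+delta)^-2]
    s <- bl$delta_cv
    d <- seq(-4, 4, length.out = 21)
    w <- stats::dnorm(d)
    w <- w / sum(w)
    g <- colSums(w * outer(d, s, function(di, si) pmax(1 + si * di,
                                                       0.05)^-2))
    az <- abs(z)
    p <- 0
    for (i in seq_along(d)) {
      sc_i <- rep(pmax(1 + s * d[i], 0.05) * sqrt(g), each = n)
      p <- p + w[i] * 2 * stats::pt(-az * sc_i, df = dfm)
    }
  } else {
    p <- 2 * stats::pt(-abs(z), df = dfm)
  }
  p[p > 1] <- 1
  list(pred = pred, se = se, z = z, p = p)
}

# ---- the estimator ------------------------------------------------------------

#' Fit a normative model of regional brain morphometry
#'
#' For every feature of the 2,976-entry schema, in three blocks — raw measured
#' values, eTIV/contrast-normalized values, and hemispheric asymmetry indices —
#' fits a polynomial age trend (order selected by BIC up to `max_order`, with
#' sex and scanner-sequence retained as additive confounders by default),
#' screens region- and parameter-specific statistical outliers (robust z with
#' threshold `artifact_z`) and turns the outlier fraction into artifact
#' probabilities and validity odds, estimates the measurement error from
#' repeated scans of the same subjects within `repeat_window` years, and
#' stores the residual spread split into biological (`population_sd`) and
#' measurement components.
#'
#' @param cohort Normative cohort: one row per scan with metadata columns
#'   `subject_id`, `session_id`, `age`, `sex`, `scanner_sequence`, `etiv` (ml)
#'   and one column per measured schema feature (see [mn_schema()]).
#' @param schema Feature schema (default [mn_schema()]).
#' @param max_order Maximum polynomial order of the age trends.
#' @param covariates Metadata columns used as additive confounders (columns
#'   with fewer than two levels are dropped); `character(0)` disables them.
#' @param artifact_z Robust-z threshold of the artifact screen.
#' @param repeat_window Maximum age difference (years) for repeated scans of a
#'   subject to count as a measurement-error pair.
#' @param alpha Uncorrected significance level used when scoring (default
#'   0.01).
#' @param q FDR level of the corrected flags (default 0.01).
#' @return An object of class `normative_model`.
#' @seealso [score_scan()], [detect_regions()], [predict.normative_model()]
#' @export
fit_normative <- function(cohort, schema = mn_schema(), max_order = 3,
                          covariates = c("sex", "scanner_sequence"),
                          artifact_z = 3.5, repeat_window = 3,
                          alpha = 0.01, q = 0.01) {
  meta_needed <- c("subject_id", "session_id", "age", "sex",
                   "scanner_sequence", "etiv")
  missing_meta <- setdiff(meta_needed, names(cohort))
  if (length(missing_meta)) {
    stop("cohort lacks metadata column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  cm <- cohort_matrix(cohort, schema)
  X <- cm$X
  meta <- cm$meta
  if (any(meta$age <= 0) || any(meta$etiv <= 0)) {
    stop("age and etiv must be positive")
  }
  n <- nrow(X)
  reference_etiv <- exp(mean(log(meta$etiv)))
  nm <- normalize_matrix(X, meta$etiv, meta$scanner_sequence, schema,
                         reference_etiv)
  A <- asymmetry_matrix(X, schema)

  age_center <- mean(meta$age)
  age_scale <- stats::sd(meta$age)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  t <- (meta$age - age_center) / age_scale
  cov_info <- .cov_info(meta, covariates)
  D <- .cov_design(meta, cov_info)

  # repeat pairs: scans of the same subject within the window
  pair_idx <- do.call(rbind, lapply(split(seq_len(n), meta$subject_id),
                                    function(i) {
    if (length(i) < 2) return(NULL)
    cmb <- utils::combn(i, 2)
    keep <- abs(meta$age[cmb[1, ]] - meta$age[cmb[2, ]]) <= repeat_window
    t(cmb[, keep, drop = FALSE])
  }))
  if (is.null(pair_idx)) pair_idx <- matrix(integer(0), 0, 2)
  if (!nrow(pair_idx)) {
    warning("no repeated scans within the window; measurement SD set to 0")
  }

  blocks <- list(
    raw = .fit_block(X, t, D, max_order, artifact_z, pair_idx),
    normalized = .fit_block(nm$X, t, D, max_order, artifact_z, pair_idx),
    asymmetry = .fit_block(A, t, D, max_order, artifact_z, pair_idx)
  )
  # relative spread of each asymmetry index's (L+R) denominator, used to
  # integrate the scale mixture out of the AI tail probabilities
  am <- asymmetry_map(schema)
  den <- X[, am$left, drop = FALSE] + X[, am$right, drop = FALSE]
  dcv <- apply(den, 2, function(v) {
    md <- stats::median(v)
    if (!is.finite(md) || md <= 0) return(0)
    min(stats::mad(v) / md, 0.5)
  })
  blocks$asymmetry$delta_cv <- unname(dcv)

  structure(list(
    schema = schema, blocks = blocks,
    normalization = list(reference_etiv = reference_etiv,
                         contrast_refs = nm$contrast_refs,
                         exponents = etiv_exponents()),
    cov_info = cov_info,
    age_center = age_center, age_scale = age_scale,
    age_range = range(meta$age),
    alpha = alpha, q = q, artifact_z = artifact_z, max_order = max_order,
    n_scans = n, n_subjects = length(unique(meta$subject_id)),
    n_repeat_pairs = nrow(pair_idx),
    call = match.call(), version = "1"
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Normative morphometry model\n")
  cat("  cohort: ", x$n_scans, " scans of ", x$n_subjects, " subjects (",
      x$n_repeat_pairs, " repeat pairs), ages ",
      round(x$age_range[1], 1), "-", round(x$age_range[2], 1), " y\n",
      sep = "")
  cat("  features:", nrow(x$schema), "schema entries;",
      length(x$blocks$raw$features), "raw,",
      length(x$blocks$asymmetry$features), "asymmetry\n")
  cat("  reference eTIV:", round(x$normalization$reference_etiv), "ml;",
      "max trend order:", x$max_order, "\n")
  if (length(x$cov_info$columns)) {
    cat("  confounders:", paste(x$cov_info$columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.normative_model <- function(object, ...) {
  bl <- object$blocks
  tab <- do.call(rbind, lapply(names(bl), function(b) {
    data.frame(
      block = b, features = length(bl[[b]]$features),
      order_0 = sum(bl[[b]]$order == 0), order_1 = sum(bl[[b]]$order == 1),
      order_2 = sum(bl[[b]]$order == 2), order_3 = sum(bl[[b]]$order >= 3),
      median_artifact_p = stats::median(bl[[b]]$artifact_p),
      median_odds = stats::median(bl[[b]]$odds),
      median_meas_frac = stats::median(
        bl[[b]]$measurement_sd / pmax(bl[[b]]$sigma, 1e-300))
    )
  }))
  structure(list(model = object, blocks = tab),
            class = "summary.normative_model")
}

#' @export
print.summary.normative_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-block fit summary:\n")
  print(x$blocks, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Trend coefficients of a fitted normative model
#'
#' @param object A `normative_model`.
#' @param block `"raw"`, `"normalized"` or `"asymmetry"`.
#' @param natural Rebase the polynomial part to the natural age basis
#'   (intercept at age 0); covariate rows are left as fitted.
#' @param ... Unused.
#' @return Matrix `(max_order + 1 + n_covariates) x features`.
#' @export
coef.normative_model <- function(object, block = "normalized",
                                 natural = TRUE, ...) {
  bl <- object$blocks[[match.arg(block, names(object$blocks))]]
  cf <- bl$coef
  kp <- bl$max_order + 1
  if (natural) {
    cf[1:kp, ] <- apply(cf[1:kp, , drop = FALSE], 2, .poly_rebase,
                        center = object$age_center,
                        scale = object$age_scale)
  }
  colnames(cf) <- bl$features
  covn <- if (bl$n_cov) {
    unlist(lapply(object$cov_info$columns, function(cn) {
      paste(cn, object$cov_info$levels[[cn]][-1], sep = "=")
    }))
  } else {
    character(0)
  }
  rownames(cf) <- c(paste0("age^", 0:(kp - 1)), covn)
  cf
}

#' Expected feature values at given ages
#'
#' Predictions are at the cohort-average covariate mix unless `meta` supplies
#' `sex`/`scanner_sequence` values.
#'
#' @param object A `normative_model`.
#' @param age Ages (years).
#' @param features Feature identifiers (default: all of the block).
#' @param block Which block to predict from.
#' @param meta Optional data.frame with covariate columns, one row per age.
#' @param se Also return the single-scan prediction SE.
#' @param ... Unused.
#' @return Matrix `length(age) x length(features)` (list with `fit` and `se`
#'   when `se = TRUE`).
#' @export
predict.normative_model <- function(object, age, features = NULL,
                                    block = "normalized", meta = NULL,
                                    se = FALSE, ...) {
  bl <- object$blocks[[match.arg(block, names(object$blocks))]]
  t_new <- (age - object$age_center) / object$age_scale
  D_new <- if (is.null(meta)) {
    matrix(0, length(age), bl$n_cov)   # centred: cohort-average mix
  } else {
    .cov_design(meta, object$cov_info)
  }
  sc <- .score_block(bl, matrix(0, length(age), length(bl$features)),
                     t_new, D_new)
  fit <- sc$pred
  colnames(fit) <- bl$features
  if (!is.null(features)) fit <- fit[, features, drop = FALSE]
  if (!se) return(fit)
  s <- sc$se
  colnames(s) <- bl$features
  if (!is.null(features)) s <- s[, features, drop = FALSE]
  list(fit = fit, se = s)
}

#' Simulate feature values from a fitted normative model
#'
#' Draws feature-wise null observations (independent across features) from the
#' fitted trend and residual width at the requested ages, at the
#' cohort-average covariate mix; useful for calibration exercises.
#'
#' @param object A `normative_model`.
#' @param nsim Number of simulated scans.
#' @param seed Optional seed.
#' @param age Ages (years); recycled to `nsim`.
#' @param block Block to simulate from.
#' @param ... Unused.
#' @return Matrix `nsim x features`.
#' @export
simulate.normative_model <- function(object, nsim = 1, seed = NULL,
                                     age = mean(object$age_range),
                                     block = "normalized", ...) {
  if (!is.null(seed)) set.seed(seed)
  bl <- object$blocks[[match.arg(block, names(object$blocks))]]
  age <- rep_len(age, nsim)
  mu <- predict(object, age, block = block)
  Y <- mu + matrix(stats::rnorm(nsim * ncol(mu)), nsim) *
    rep(bl$sigma, each = nsim)
  colnames(Y) <- bl$features
  Y
}

#' Age-trend plot for one feature
#'
#' Trend curve with the +-2 SD single-scan band over the normative age range
#' (cohort-average covariate mix); optionally overlays cohort points and a
#' patient scan.
#'
#' @param x A `normative_model`.
#' @param feature Feature identifier.
#' @param block Block to plot.
#' @param cohort Optional cohort data.frame to overlay.
#' @param scan Optional list/row with `age` and `value` to highlight.
#' @param ... Passed to [plot()].
#' @export
plot.normative_model <- function(x, feature, block = "normalized",
                                 cohort = NULL, scan = NULL, ...) {
  bl <- x$blocks[[match.arg(block, names(x$blocks))]]
  j <- match(feature, bl$features)
  if (is.na(j)) stop("unknown feature: ", feature)
  ages <- seq(x$age_range[1], x$age_range[2], length.out = 100)
  pr <- predict(x, ages, features = feature, block = block, se = TRUE)
  ylim <- range(pr$fit - 2.5 * pr$se, pr$fit + 2.5 * pr$se)
  if (!is.null(scan)) ylim <- range(ylim, scan$value)
  plot(ages, pr$fit, type = "l", lwd = 2, ylim = ylim,
       xlab = "age [y]", ylab = feature, ...)
  graphics::polygon(c(ages, rev(ages)),
                    c(pr$fit - 2 * pr$se, rev(pr$fit + 2 * pr$se)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(ages, pr$fit, lwd = 2)
  if (!is.null(cohort)) {
    v <- cohort[[feature]]
    if (!is.null(v)) graphics::points(cohort$age, v, pch = 16, cex = 0.5,
                                      col = "grey40")
  }
  if (!is.null(scan)) {
    graphics::points(scan$age, scan$value, pch = 17, col = "firebrick",
                     cex = 1.3)
  }
  invisible(x)
}

# ---- scoring ------------------------------------------------------------------

# derive the three block matrices for new scans, using the model's stored
# normalization references
.derive_blocks <- function(model, cohort) {
  cm <- cohort_matrix(cohort, model$schema)
  X <- cm$X
  nm <- normalize_matrix(X, cm$meta$etiv, cm$meta$scanner_sequence,
                         model$schema, model$normalization$reference_etiv,
                         model$normalization$contrast_refs)
  list(meta = cm$meta, raw = X, normalized = nm$X,
       asymmetry = asymmetry_matrix(X, model$schema))
}

# vectorized scoring of many scans; returns per variant the value/p/z
# matrices over the full 2,976-feature family (measured block + asymmetry)
.score_all <- function(model, cohort) {
  db <- .derive_blocks(model, cohort)
  t_new <- (db$meta$age - model$age_center) / model$age_scale
  D_new <- .cov_design(db$meta, model$cov_info)
  sc_asym <- .score_block(model$blocks$asymmetry, db$asymmetry, t_new,
                          D_new)
  out <- list()
  for (v in c("raw", "normalized")) {
    sc <- .score_block(model$blocks[[v]], db[[v]], t_new, D_new)
    full <- function(el_m, el_a) {
      M <- cbind(el_m, el_a)
      colnames(M) <- c(model$blocks[[v]]$features,
                       model$blocks$asymmetry$features)
      M[, model$schema$feature, drop = FALSE]
    }
    out[[v]] <- list(value = full(db[[v]], db$asymmetry),
                     pred = full(sc$pred, sc_asym$pred),
                     se = full(sc$se, sc_asym$se),
                     z = full(sc$z, sc_asym$z),
                     p = full(sc$p, sc_asym$p))
  }
  out$meta <- db$meta
  out
}

#' Score a single scan against a normative model
#'
#' Computes, for every schema feature and both variants (raw and
#' eTIV/contrast-normalized; asymmetry indices enter both families), the
#' residual sign, the two-sided abnormality p-value, the signed decadic log-p
#' fingerprint value, and flag levels: `"uncorrected"` when `p < alpha` and
#' `"fdr"` when the test additionally survives Benjamini-Hochberg correction
#' at level `q` over the variant's 2,976-test family.
#'
#' @param model A [fit_normative()] model.
#' @param scan One-row data.frame in cohort format (metadata + measured
#'   feature columns).
#' @param alpha,q Override the model's flag levels.
#' @return A data.frame of class `abnormality_profile` with columns `feature`,
#'   `region`, `parameter`, `side`, `variant`, `value`, `predicted`, `se`,
#'   `z`, `sign`, `p`, `L`, `flag`; attributes `dataset_id`, `age`,
#'   `extrapolated`, `alpha`, `q`.
#' @export
score_scan <- function(model, scan, alpha = model$alpha, q = model$q) {
  stopifnot(nrow(scan) == 1)
  sc <- .score_all(model, scan)
  sch <- model$schema
  prof <- do.call(rbind, lapply(c("raw", "normalized"), function(v) {
    p <- drop(sc[[v]]$p)
    z <- drop(sc[[v]]$z)
    flag_u <- !is.na(p) & p < alpha
    flag_f <- flag_u & fdr_flag(p, q)
    data.frame(
      feature = sch$feature, region = sch$region, parameter = sch$parameter,
      side = sch$side, variant = v,
      value = drop(sc[[v]]$value), predicted = drop(sc[[v]]$pred),
      se = drop(sc[[v]]$se), z = z, sign = sign(z), p = p,
      L = signed_log_feature(p, sign(z)),
      flag = ifelse(flag_f, "fdr", ifelse(flag_u, "uncorrected", "none")),
      stringsAsFactors = FALSE
    )
  }))
  rownames(prof) <- NULL
  structure(prof,
            dataset_id = sc$meta$session_id, age = sc$meta$age,
            extrapolated = sc$meta$age < model$age_range[1] |
              sc$meta$age > model$age_range[2],
            alpha = alpha, q = q,
            class = c("abnormality_profile", "data.frame"))
}

#' @export
print.abnormality_profile <- function(x, ...) {
  cat("Abnormality profile for dataset", attr(x, "dataset_id"),
      "(age", round(attr(x, "age"), 1), "y)\n")
  if (isTRUE(attr(x, "extrapolated"))) {
    cat("  NOTE: age outside the normative range (extrapolated trends)\n")
  }
  for (v in unique(x$variant)) {
    xv <- x[x$variant == v, ]
    cat(sprintf("  %-10s %d tests, %d uncorrected (p < %.3g), %d FDR\n", v,
                nrow(xv), sum(xv$flag != "none", na.rm = TRUE),
                attr(x, "alpha"), sum(xv$flag == "fdr", na.rm = TRUE)))
  }
  invisible(x)
}

#' Score many scans at once
#'
#' @param model A `normative_model`.
#' @param cohort Data.frame of scans in cohort format.
#' @param profiles Return full [score_scan()] profiles (`TRUE`) or compact
#'   matrices of values, p-values and z per variant (`FALSE`, fast path).
#' @return A list of `abnormality_profile`s, or the compact list.
#' @export
score_cohort <- function(model, cohort, profiles = TRUE) {
  if (!profiles) return(.score_all(model, cohort))
  lapply(seq_len(nrow(cohort)), function(i) {
    score_scan(model, cohort[i, , drop = FALSE])
  })
}

#' Residuals of a normative model on a cohort
#'
#' @param object A `normative_model`.
#' @param cohort Cohort data.frame (e.g. the training cohort).
#' @param block Block of interest.
#' @param ... Unused.
#' @return Matrix of residuals `scans x features`.
#' @export
residuals.normative_model <- function(object, cohort,
                                      block = "normalized", ...) {
  block <- match.arg(block, names(object$blocks))
  db <- .derive_blocks(object, cohort)
  t_new <- (db$meta$age - object$age_center) / object$age_scale
  D_new <- .cov_design(db$meta, object$cov_info)
  sc <- .score_block(object$blocks[[block]], db[[block]], t_new, D_new)
  R <- db[[block]] - sc$pred
  colnames(R) <- object$blocks[[block]]$features
  R
}
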