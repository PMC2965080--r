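# Statistical suite: usage-vs-GC3 correlations, LOESS curves, Harvey-Collier
# nonlinearity tests, model variance explained, deviation screen.

# model-predicted usage of each modelled codon at each record's B (= gc3)
model_usage_matrix <- function(B, groups = build_synonym_groups()) {
  cols <- lapply(groups, function(gr) {
    vapply(gr$codons, function(cd) closed_form_usage(gr, cd, B),
           numeric(length(B)))
  })
  m <- do.call(cbind, cols)
  rownames(m) <- names(B)
  m
}

#' Correlation of per-codon usage with GC3 across records
#'
#' @param dataset A \code{usage_dataset}.
#' @param method Correlation type; the analyses default to Pearson.
#' @param min_aa_count Per-group codon-count filter (see
#'   \code{\link{per_group_frequencies}}).
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return data.frame with columns codon, group, gc_ending, correlation, n;
#'   codons observed in fewer than 3 records get \code{NA}.
#' @export
correlate_usage_gc3 <- function(dataset, method = c("pearson", "spearman"),
                                min_aa_count = 0L,
                                groups = build_synonym_groups()) {
  method <- match.arg(method)
  um <- usage_matrix(dataset, min_aa_count = min_aa_count, groups = groups)
  codons <- colnames(um$freq)
  res <- lapply(codons, function(cd) {
    ok <- !is.na(um$freq[, cd])
    n <- sum(ok)
    r <- if (n >= 3L) stats::cor(um$freq[ok, cd], um$gc3[ok],
                                 method = method) else NA_real_
    gr <- group_of(cd, groups)
    data.frame(codon = cd, group = gr$label,
               gc_ending = substr(cd, 3, 3) %in% c("G", "C"),
               correlation = r, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' LOESS fit of usage against GC3
#'
#' Local polynomial least-squares smoother with the conventional settings for
#' usage curves (span 1.0, degree 2), evaluated over the data's x-range.
#'
#' @param x,y Numeric vectors.
#' @param span,degree LOESS parameters.
#' @param grid Evaluation points (default: 101 points over range(x)).
#' @return data.frame with columns x, fitted.
#' @export
loess_curve <- function(x, y, span = 1.0, degree = 2L, grid = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(unique(x)) < degree + 2L) {
    stop("need at least degree + 2 distinct x values")
  }
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 101L)
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  data.frame(x = grid, fitted = stats::predict(fit, newdata =
                                                 data.frame(x = grid)))
}

# recursive residuals of y on X in the given row order (Brown-Durbin-Evans);
# used to carry the sign of the Harvey-Collier statistic and as the
# cross-check for the lmtest route.
recursive_residuals <- function(X, y) {
  n <- nrow(X); k <- ncol(X)
  stopifnot(n > k + 1L)
  w <- numeric(n - k)
  for (r in (k + 1L):n) {
    Xr <- X[1:(r - 1L), , drop = FALSE]
    XtXi <- chol2inv(chol(crossprod(Xr)))
    beta <- XtXi %*% crossprod(Xr, y[1:(r - 1L)])
    xr <- X[r, ]
    w[r - k] <- (y[r] - sum(xr * beta)) /
      sqrt(1 + drop(t(xr) %*% XtXi %*% xr))
  }
  w
}

#' Harvey-Collier linearity test of one codon's usage against GC3
#'
#' Regresses usage on GC3, orders records by GC3 (ties broken by record id for
#' determinism) and t-tests the mean of the recursive residuals against zero.
#' A large statistic magnitude indicates a nonlinear usage curve; the sign of
#' the mean recursive residual is retained (positive = convex departure).
#'
#' Note that on panels generated from the model, GC3 is itself a slightly
#' nonlinear function of the generating bias B (the isoleucine deficit), so
#' even a codon whose usage is exactly linear in B acquires a small curvature
#' against GC3; pass the known biases via \code{B} to test linearity against
#' the bias axis instead.
#'
#' @param dataset A \code{usage_dataset}.
#' @param codon Codon string.
#' @param min_aa_count Per-group filter.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @param B Optional per-record bias values to use as the regressor in place
#'   of each record's GC3.
#' @return List with \code{statistic} (signed), \code{p_value} and \code{n}.
#' @export
harvey_collier <- function(dataset, codon, min_aa_count = 0L,
                           groups = build_synonym_groups(), B = NULL) {
  um <- usage_matrix(dataset, min_aa_count = min_aa_count, groups = groups)
  if (!is.null(B)) um$gc3 <- setNames(B, um$record_ids)
  hc_core(um, normalize_codon(codon))
}

# Harvey-Collier core on a precomputed usage matrix
hc_core <- function(um, codon) {
  ok <- !is.na(um$freq[, codon])
  if (sum(ok) < 10L) stop("need >= 10 records with defined usage for ", codon)
  d <- data.frame(usage = um$freq[ok, codon], gc3 = um$gc3[ok],
                  id = um$record_ids[ok], stringsAsFactors = FALSE)
  d <- d[order(d$gc3, d$id), ]
  if (stats::var(d$gc3) == 0) stop("degenerate design: gc3 constant")
  ht <- lmtest::harvtest(usage ~ gc3, data = d)
  rr <- recursive_residuals(cbind(1, d$gc3), d$usage)
  list(statistic = unname(sign(mean(rr)) * ht$statistic),
       p_value = unname(ht$p.value), n = nrow(d))
}

#' Harvey-Collier tests for all modelled codons, ranked by magnitude
#'
#' @inheritParams harvey_collier
#' @return data.frame (one row per codon) with statistic, p_value, n,
#'   predicted_response, and rank (1 = most nonlinear).
#' @export
linearity_report <- function(dataset, min_aa_count = 0L,
                             groups = build_synonym_groups(), B = NULL) {
  codons <- unlist(lapply(groups, function(g) g$codons), use.names = FALSE)
  um <- usage_matrix(dataset, min_aa_count = min_aa_count, groups = groups)
  if (!is.null(B)) um$gc3 <- setNames(B, um$record_ids)
  rows <- lapply(codons, function(cd) {
    gr <- group_of(cd, groups)
    res <- tryCatch(hc_core(um, cd),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_, n = NA_integer_))
    data.frame(codon = cd, group = gr$label,
               statistic = res$statistic, p_value = res$p_value, n = res$n,
               predicted_response = predicted_response(gr, cd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$statistic)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# class membership table: one row per (group, class)
class_units <- function(groups = build_synonym_groups()) {
  do.call(rbind, lapply(groups, function(gr) {
    do.call(rbind, lapply(sort(unique(gr$gc_class)), function(g) {
      data.frame(group = gr$label, gc_class = g,
                 codons = I(list(names(gr$gc_class)[gr$gc_class == g])),
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Model variance explained, per codon or per GC class
#'
#' For each unit u (a codon, or a group's GC class with observed and predicted
#' usage summed within the class), computes
#' VE(u) = 1 - Var(model_u(gc3_r) - obs_u_r) / Var(obs_u_r) across records r,
#' taking each record's GC3 as its bias B. The weighted averages use the total
#' number of codons entering each unit's calculation as weights.
#'
#' Every record's GC3 stands in for its bias B by default. Because isoleucine
#' is the sole group whose predicted GC3 falls below B, a record's overall
#' GC3 carries a small isoleucine-induced deficit; when the generating biases
#' are known (synthetic panels), pass them via \code{B} to evaluate the model
#' at the exact bias instead.
#'
#' @param dataset A \code{usage_dataset}.
#' @param level \code{"codon"} or \code{"class"}.
#' @param min_aa_count Per-group filter.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @param B Optional per-record bias values overriding GC3.
#' @return List of class \code{fit_report}: \code{table} (per-unit VE, n,
#'   weight) and \code{weighted_average}.
#' @export
variance_explained <- function(dataset, level = c("codon", "class"),
                               min_aa_count = 0L,
                               groups = build_synonym_groups(), B = NULL) {
  level <- match.arg(level)
  um <- usage_matrix(dataset, min_aa_count = min_aa_count, groups = groups)
  pred <- model_usage_matrix(if (is.null(B)) um$gc3 else B, groups)
  if (level == "codon") {
    units <- lapply(colnames(um$freq), function(cd) {
      list(name = cd, obs = um$freq[, cd], mod = pred[, cd],
           wt = um$counts[, cd])
    })
  } else {
    cu <- class_units(groups)
    units <- lapply(seq_len(nrow(cu)), function(i) {
      cods <- cu$codons[[i]]
      list(name = sprintf("%s_%dxGC", cu$group[i], cu$gc_class[i]),
           obs = rowSums(um$freq[, cods, drop = FALSE]),
           mod = rowSums(pred[, cods, drop = FALSE]),
           wt = rowSums(um$counts[, cods, drop = FALSE]))
    })
  }
  rows <- lapply(units, function(u) {
    ok <- !is.na(u$obs)
    n <- sum(ok)
    if (n < 3L || stats::var(u$obs[ok]) == 0) {
      warning("unit ", u$name, " excluded from VE (zero variance or n < 3)")
      return(data.frame(unit = u$name, ve = NA_real_, n = n, weight = 0))
    }
    ve <- 1 - stats::var(u$mod[ok] - u$obs[ok]) / stats::var(u$obs[ok])
    data.frame(unit = u$name, ve = ve, n = n,
               weight = sum(u$wt[ok]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$ve)
  wavg <- sum(tab$ve[ok] * tab$weight[ok]) / sum(tab$weight[ok])
  structure(list(table = tab, weighted_average = wavg, level = level),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s level: weighted mean VE = %.4f over %d units\n",
              x$level, x$weighted_average, nrow(x$table)))
  invisible(x)
}

#' Maximum-likelihood estimate of the GC bias of each record
#'
#' Maximizes the multinomial log-likelihood of the observed codon counts over
#' all modelled synonym groups as a function of B. Used for parameter-recovery
#' checks; routine analyses take GC3 as the bias estimate.
#'
#' @param dataset A \code{usage_dataset}.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return Named numeric vector of B estimates.
#' @export
estimate_bias_mle <- function(dataset, groups = build_synonym_groups()) {
  um <- usage_matrix(dataset, groups = groups)
  gvec <- unlist(lapply(groups, function(gr) gr$gc_class), use.names = FALSE)
  mvec <- unlist(lapply(groups, function(gr)
    rep(gr$max_gc, length(gr$codons))), use.names = FALSE)
  # per-group log normalizer: log sum_c B^g (1-B)^(m-g)
  glab <- rep(vapply(groups, function(g) g$label, ""),
              vapply(groups, function(g) length(g$codons), 0L))
  loglik <- function(B, cnt) {
    lw <- gvec * log(B) + (mvec - gvec) * log1p(-B)
    lz <- tapply(exp(lw), glab, sum)
    sum(cnt * (lw - log(lz)[glab]))
  }
  est <- apply(um$counts, 1L, function(cnt) {
    stats::optimize(loglik, c(1e-9, 1 - 1e-9), cnt = cnt,
                    maximum = TRUE, tol = 1e-9)$maximum
  })
  setNames(est, um$record_ids)
}

#' Screen for codons deviating systematically from the model
#'
#' Mean observed-minus-predicted usage per codon, with a seeded bootstrap
#' percentile confidence interval over records; codons whose interval excludes
#' zero are flagged.
#'
#' @param dataset A \code{usage_dataset}.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed for the resampling.
#' @param min_aa_count Per-group filter.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @param B Optional per-record bias values overriding GC3 (see
#'   \code{\link{variance_explained}}).
#' @return data.frame with codon, mean_residual, ci_lo, ci_hi, n, flagged.
#' @export
deviation_screen <- function(dataset, n_boot = 1000L, conf = 0.95,
                             seed = 1L, min_aa_count = 0L,
                             groups = build_synonym_groups(), B = NULL) {
  um <- usage_matrix(dataset, min_aa_count = min_aa_count, groups = groups)
  pred <- model_usage_matrix(if (is.null(B)) um$gc3 else B, groups)
  resid <- um$freq - pred
  alpha <- (1 - conf) / 2
  set.seed(seed)
  n <- nrow(resid)
  boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  rows <- lapply(colnames(resid), function(cd) {
    r <- resid[, cd]
    ok <- !is.na(r)
    if (sum(ok) < 3L) {
      return(data.frame(codon = cd, mean_residual = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n = sum(ok), flagged = FALSE))
    }
    bm <- apply(boot_idx, 1L, function(ix) mean(r[ix], na.rm = TRUE))
    ci <- stats::quantile(bm, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    data.frame(codon = cd, mean_residual = mean(r[ok]),
               ci_lo = ci[1], ci_hi = ci[2], n = sum(ok),
               flagged = ci[1] > 0 || ci[2] < 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
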