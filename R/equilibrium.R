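# GC-biased CTMC over synonym groups: rate matrices, stationary distributions,
# closed-form equilibrium usage.

#' Convert GC bias B to the rate ratio lambda
#'
#' lambda is the ratio of GC-increasing to GC-decreasing mutation rates;
#' lambda = B / (1 - B), so lambda / (1 + lambda) = B.
#'
#' @param B GC bias in [0, 1).
#' @return lambda >= 0.
#' @export
bias_to_lambda <- function(B) {
  check_bias(B)
  if (any(B == 1)) {
    stop("lambda is infinite at B = 1; use the (B, 1-B) rate parameterization")
  }
  B / (1 - B)
}

check_bias <- function(B) {
  if (!is.numeric(B) || any(!is.finite(B)) || any(B < 0) || any(B > 1)) {
    stop("GC bias B must lie in [0, 1]")
  }
  invisible(B)
}

#' GC-biased mutation rate model
#'
#' Rates are scaled as (B, 1-B) rather than (lambda, 1): a GC-increasing
#' substitution on an edge runs at base_rate * B, the GC-decreasing reverse at
#' base_rate * (1 - B), and GC-preserving edges at base_rate in both
#' directions. Only the ratio B/(1-B) = lambda affects the equilibrium, so
#' this reproduces the lambda-scaled model while remaining finite at
#' B in {0, 1}.
#'
#' @param B GC bias in [0, 1].
#' @param base_rates Either a single positive number (all edges equal) or a
#'   numeric vector of per-edge symmetric base rates, recycled along the
#'   group's edge list. The equilibrium is invariant to these.
#' @return Object of class \code{rate_model}.
#' @export
rate_model <- function(B, base_rates = 1) {
  check_bias(B)
  if (any(!is.finite(base_rates)) || any(base_rates <= 0)) {
    stop("base rates must be positive and finite")
  }
  structure(list(B = B, base_rates = base_rates), class = "rate_model")
}

#' Build the CTMC rate matrix of a synonym group
#'
#' Off-diagonal entries follow the rate model; entries between codons not
#' joined by a single-site synonymous substitution are zero; rows sum to zero.
#'
#' @param group A \code{synonym_group}.
#' @param rm A \code{rate_model} (or a bare B value, taken with unit rates).
#' @return Square rate matrix with dimnames = group codons.
#' @export
build_rate_matrix <- function(group, rm) {
  if (is.numeric(rm)) rm <- rate_model(rm)
  stopifnot(inherits(rm, "rate_model"))
  codons <- group$codons
  Q <- matrix(0, length(codons), length(codons),
              dimnames = list(codons, codons))
  edges <- group$edges
  if (nrow(edges) > 0) {
    base <- rep_len(rm$base_rates, nrow(edges))
    B <- rm$B
    for (k in seq_len(nrow(edges))) {
      i <- edges$from[k]; j <- edges$to[k]; d <- edges$gc_delta[k]
      fwd <- if (d > 0) B else if (d < 0) 1 - B else 1
      rev <- if (d > 0) 1 - B else if (d < 0) B else 1
      Q[i, j] <- Q[i, j] + base[k] * fwd
      Q[j, i] <- Q[j, i] + base[k] * rev
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a CTMC generator
#'
#' Solves pi Q = 0, sum(pi) = 1 by replacing one balance equation with the
#' normalization constraint -- a deterministic, well-conditioned linear solve
#' for the small (<= 6 state) generators arising here.
#'
#' @param Q Square rate matrix (rows sum to 0).
#' @return Named probability vector.
#' @export
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  stopifnot(n == ncol(Q), max(abs(rowSums(Q))) < 1e-8)
  if (n == 1L) return(setNames(1, rownames(Q)))
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- tryCatch(solve(A, b),
                 error = function(e) stop("stationary solve failed (reducible ",
                                          "or ill-conditioned generator): ",
                                          conditionMessage(e)))
  if (any(pi < -1e-10)) {
    stop("stationary solve produced negative frequencies; generator may be reducible")
  }
  pi <- pmax(pi, 0)
  setNames(pi / sum(pi), rownames(Q))
}

#' Closed-form equilibrium codon usage
#'
#' At equilibrium the usage of codon c with GC class g in a group whose
#' variable positions number m (= max GC class) is
#' B^g (1-B)^(m-g) / sum over the group of the same expression. This single
#' expression specializes to: two-codon groups (1-B, B); four-codon groups
#' ((1-B)/2 and B/2); isoleucine ((1-B)/(2-B) for ATA and ATT, B/(2-B) for
#' ATC); arginine/leucine ((1-B)^2, B(1-B), B^2, each over (1+B), for the
#' 0xGC, 1xGC, 2xGC classes).
#'
#' @param group A \code{synonym_group}.
#' @param codon Codon in the group, or \code{NULL} for the whole group.
#' @param B GC bias in [0, 1] (vectorized when \code{codon} is given).
#' @return Equilibrium frequency (or named vector over the group's codons
#'   when \code{codon = NULL} and \code{B} is scalar).
#' @export
closed_form_usage <- function(group, codon = NULL, B) {
  check_bias(B)
  g_all <- group$gc_class
  m <- group$max_gc
  if (is.null(codon)) {
    stopifnot(length(B) == 1L)
    w <- B^g_all * (1 - B)^(m - g_all)
    return(w / sum(w))
  }
  codon <- normalize_codon(codon)
  if (!codon %in% group$codons) {
    stop("codon ", codon, " is not modelled in group ", group$label)
  }
  g <- g_all[[codon]]
  norm <- rowSums(outer(B, g_all, function(b, gc) b^gc * (1 - b)^(m - gc)))
  (B^g * (1 - B)^(m - g)) / norm
}

#' Total equilibrium usage of a GC class
#'
#' Sums \code{\link{closed_form_usage}} over the group's codons of class g;
#' e.g. the arginine/leucine 1xGC class totals 3B(1-B)/(1+B) and the 2xGC
#' class 2B^2/(1+B).
#'
#' @param group A \code{synonym_group}.
#' @param g GC class (<= group max).
#' @param B GC bias (vectorized).
#' @return Class usage total.
#' @export
class_usage <- function(group, g, B) {
  stopifnot(g >= 0, g <= group$max_gc)
  members <- names(group$gc_class)[group$gc_class == g]
  if (length(members) == 0L) return(rep(0, length(B)))
  rowSums(matrix(vapply(members, function(cd) closed_form_usage(group, cd, B),
                        numeric(length(B))), nrow = length(B)))
}

#' Model-predicted per-group GC3
#'
#' The equilibrium usage of a group's G/C-ending codons sums to B for every
#' group except isoleucine, whose odd codon number gives B/(2-B) <= B -- the
#' sole exception to the per-amino-acid GC3 identity.
#'
#' @param group A \code{synonym_group}.
#' @param B GC bias (vectorized).
#' @return Predicted fraction of third-position G/C in the group.
#' @export
predicted_gc3 <- function(group, B) {
  check_bias(B)
  gc_ending <- group$codons[substr(group$codons, 3, 3) %in% c("G", "C")]
  if (length(gc_ending) == 0L) return(rep(0, length(B)))
  rowSums(matrix(vapply(gc_ending, function(cd) closed_form_usage(group, cd, B),
                        numeric(length(B))), nrow = length(B)))
}

#' Location of the usage peak of a codon class
#'
#' For the non-monotone arginine/leucine 1xGC per-codon curve B(1-B)/(1+B)
#' the interior maximum is at B* = sqrt(2) - 1
#' (~0.414214), below neutral bias; monotone and linear classes have no
#' interior peak and return \code{NULL}. The analytic root (of 1 - 2B - B^2)
#' is cross-checked against a golden-section search at tolerance 1e-10.
#'
#' @param group A \code{synonym_group}.
#' @param g GC class.
#' @return List with \code{B} (argmax) and \code{usage} (per-codon usage at
#'   the peak), or \code{NULL} when the class curve is monotone on [0, 1].
#' @export
peak_bias <- function(group, g) {
  stopifnot(g >= 0, g <= group$max_gc)
  if (!(group$family == "six_codon" && g == 1L)) {
    return(NULL)  # linear or monotone nonlinear: no interior maximum
  }
  b_analytic <- sqrt(2) - 1
  f <- function(b) b * (1 - b) / (1 + b)
  b_numeric <- stats::optimize(f, c(0, 1), maximum = TRUE,
                               tol = 1e-10)$maximum
  if (abs(b_numeric - b_analytic) > 1e-6) {
    stop("numeric and analytic peak positions disagree")
  }
  list(B = b_analytic, usage = f(b_analytic))
}

#' Tidy table of model predictions over a grid of B
#'
#' @param B_grid Numeric vector of GC bias values.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return data.frame with columns group, codon, gc_class, B, predicted_usage,
#'   predicted_response.
#' @export
predict_usage_table <- function(B_grid = seq(0, 1, by = 0.01),
                                groups = build_synonym_groups()) {
  check_bias(B_grid)
  out <- lapply(groups, function(gr) {
    do.call(rbind, lapply(gr$codons, function(cd) {
      data.frame(group = gr$label, codon = cd,
                 gc_class = gc_class(gr, cd), B = B_grid,
                 predicted_usage = closed_form_usage(gr, cd, B_grid),
                 predicted_response = predicted_response(gr, cd),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
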