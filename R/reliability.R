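#' Item-level contribution matrices for the crowd subscales
#'
#' McDonald's omega needs item-level data for each crowd subscale. For the
#' mindset instrument, crowd `c`'s items are the seven per-question point
#' contributions to `c` (0, the rank-2 weight, or 2). For the photo-grid
#' instrument, crowd `c`'s items are signed selection indicators for each of
#' `c`'s photos: +1 if picked as best fit, -1 if picked as least fit, 0
#' otherwise. Neither instrument has a published item definition; both
#' choices are this package's documented convention.
#'
#' @param cohort Respondent table with raw response columns.
#' @param crowd One of [peer_crowds()].
#' @param rank2_weights Rank-2 weights for the mindset instrument.
#' @return Numeric matrix, one row per respondent, one column per item.
#' @export
vmls_item_matrix <- function(cohort, crowd,
                             rank2_weights = vmls_rank2_weights()) {
  stopifnot(crowd %in% peer_crowds())
  r1 <- vmls_choice_matrix(cohort, 1)
  r2 <- vmls_choice_matrix(cohort, 2)
  m <- 2 * (r1 == crowd) + rank2_weights[[crowd]] * (r2 == crowd)
  colnames(m) <- paste0("q", 1:7)
  m
}

#' @rdname vmls_item_matrix
#' @param grid_spec Photo map for the photo-grid instrument.
#' @export
ibase_item_matrix <- function(cohort, crowd, grid_spec = default_grid_spec()) {
  stopifnot(crowd %in% peer_crowds())
  best <- ibase_pick_matrix(cohort, grid_spec, "best")
  least <- ibase_pick_matrix(cohort, grid_spec, "least")
  photos <- grid_spec$photo_id[grid_spec$crowd == crowd]
  m <- vapply(photos, function(p) {
    rowSums(best == p) - rowSums(least == p)
  }, numeric(nrow(cohort)))
  matrix(m, nrow = nrow(cohort), dimnames = list(NULL, photos))
}

#' Fit a single-factor model to an item matrix
#'
#' Estimates loadings and uniquenesses of the one-factor model
#' `Sigma = lambda lambda' + diag(theta)` on the item correlation matrix.
#' The default estimator is unweighted least squares on the off-diagonal
#' correlations (robust for coarse categorical-ish items); maximum likelihood
#' (via [stats::factanal()]) is available as an option. Two-item scales are
#' fit under an equal-loading constraint (they are just-identified
#' otherwise). Negative uniquenesses (Heywood cases) are clamped to zero and
#' flagged. Loadings are sign-fixed so their sum is non-negative.
#'
#' @param items Numeric matrix, respondents x items (k >= 2, no missing
#'   cells, no constant columns).
#' @param method `"uls"` (default) or `"ml"`.
#' @param max_iter Iteration cap for the ULS optimizer.
#' @return List of class `one_factor_fit`: `loadings`, `uniquenesses`,
#'   `heywood` (logical), `method`, `converged`.
#' @export
fit_one_factor <- function(items, method = c("uls", "ml"), max_iter = 500) {
  method <- match.arg(method)
  x <- as.matrix(items)
  k <- ncol(x)
  if (k < 2) stop("at least 2 items are required", call. = FALSE)
  if (anyNA(x)) stop("item matrix has missing cells", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("item(s) with zero variance: ",
         paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", "),
         call. = FALSE)
  }
  R <- stats::cor(x)

  if (k == 2) {
    # equal-loading constraint: lambda^2 = r12 (floored at 0)
    lambda <- rep(sqrt(max(R[1, 2], 0)), 2)
    theta <- 1 - lambda^2
    return(new_one_factor_fit(lambda, theta, method = "uls(equal-loading)",
                              converged = TRUE, items = colnames(x)))
  }

  if (method == "ml") {
    fa <- stats::factanal(covmat = R, factors = 1, n.obs = nrow(x))
    lambda <- as.vector(fa$loadings)
    theta <- fa$uniquenesses
    return(new_one_factor_fit(lambda, theta, method = "ml", converged = TRUE,
                              items = colnames(x)))
  }

  # ULS: minimize sum over i<j of (r_ij - l_i l_j)^2
  off <- upper.tri(R)
  obj <- function(l) {
    fitted <- tcrossprod(l)
    sum((R[off] - fitted[off])^2)
  }
  ev <- eigen(R, symmetric = TRUE)
  start <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = max_iter))
  if (opt$convergence != 0) {
    stop(sprintf("one-factor ULS fit failed to converge within %d iterations (code %d)",
                 max_iter, opt$convergence), call. = FALSE)
  }
  lambda <- opt$par
  theta <- 1 - lambda^2
  new_one_factor_fit(lambda, theta, method = "uls", converged = TRUE,
                     items = colnames(x))
}

new_one_factor_fit <- function(lambda, theta, method, converged, items = NULL) {
  if (sum(lambda) < 0) lambda <- -lambda
  heywood <- any(theta < 0)
  theta <- pmax(theta, 0)
  if (!is.null(items)) {
    names(lambda) <- items
    names(theta) <- items
  }
  structure(list(loadings = lambda, uniquenesses = theta, heywood = heywood,
                 method = method, converged = converged),
            class = "one_factor_fit")
}

#' @export
print.one_factor_fit <- function(x, ...) {
  cat("<one_factor_fit>", x$method,
      if (x$heywood) "(Heywood case: uniqueness clamped to 0)", "\n")
  print(round(rbind(loading = x$loadings, uniqueness = x$uniquenesses), 3))
  invisible(x)
}

#' McDonald's omega
#'
#' Composite reliability from a one-factor model on standardized items:
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)`. Because the fit
#' is on the correlation matrix, omega is invariant to rescaling all items by
#' a common positive constant.
#'
#' @param items Item matrix (respondents x items), or an existing
#'   `one_factor_fit`.
#' @param method Passed to [fit_one_factor()] when `items` is a matrix.
#' @return Numeric omega in `[0, 1]`, with attribute `heywood` (logical).
#' @export
#' @examples
#' set.seed(1)
#' f <- rnorm(500)
#' items <- sapply(1:4, function(i) 0.7 * f + rnorm(500, 0, sqrt(0.51)))
#' mcdonalds_omega(items)
mcdonalds_omega <- function(items, method = c("uls", "ml")) {
  fit <- if (inherits(items, "one_factor_fit")) items else {
    fit_one_factor(items, method = match.arg(method))
  }
  s <- sum(fit$loadings)
  omega <- s^2 / (s^2 + sum(fit$uniquenesses))
  structure(min(max(omega, 0), 1), heywood = fit$heywood)
}

#' Reliability table for both instruments
#'
#' Computes McDonald's omega for each crowd subscale of each instrument —
#' the diagonal of the multi-trait multi-method matrix.
#'
#' @param cohort Respondent table with raw response columns.
#' @param grid_spec Photo map for the photo-grid instrument.
#' @param method Estimator passed to [fit_one_factor()].
#' @return Data frame: `instrument`, `crowd`, `k_items`, `omega`,
#'   `heywood_flag`.
#' @export
reliability_table <- function(cohort, grid_spec = default_grid_spec(),
                              method = c("uls", "ml")) {
  method <- match.arg(method)
  rows <- list()
  for (instrument in c("ibase", "vmls")) {
    for (crowd in peer_crowds()) {
      items <- if (instrument == "vmls") {
        vmls_item_matrix(cohort, crowd)
      } else {
        ibase_item_matrix(cohort, crowd, grid_spec)
      }
      om <- tryCatch(mcdonalds_omega(items, method = method),
                     error = function(e) structure(NA_real_, heywood = NA))
      rows[[length(rows) + 1]] <- data.frame(
        instrument = instrument, crowd = crowd, k_items = ncol(items),
        omega = as.numeric(om), heywood_flag = isTRUE(attr(om, "heywood")),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
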