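#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation computed from the definition, with the p-value
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' A perfect correlation (|r| = 1) gets p = 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, finite, each with
#'   nonzero variance.
#' @return List with elements `r`, `p`, `n`.
#' @export
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r = 0.6
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("at least 3 observations are required", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- min(max(r, -1), 1)
  p <- if (1 - r^2 <= .Machine$double.eps) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

mtmm_labels <- function() {
  data.frame(
    method = rep(c("ibase", "vmls"), each = 5),
    crowd = rep(peer_crowds(), 2),
    label = c(paste0("IBase.", peer_crowds()), paste0("VMLS.", peer_crowds())),
    stringsAsFactors = FALSE
  )
}

new_mtmm_matrix <- function(correlations, p_values, diagonal,
                            labels = mtmm_labels()) {
  dimnames(correlations) <- list(labels$label, labels$label)
  dimnames(p_values) <- list(labels$label, labels$label)
  diag(correlations) <- diagonal
  diag(p_values) <- NA_real_
  structure(list(labels = labels, correlations = correlations,
                 p_values = p_values, diagonal = diagonal),
            class = "mtmm_matrix")
}

#' Build the multi-trait multi-method matrix
#'
#' The 10x10 matrix of Pearson correlations among the five crowd scores of
#' each instrument (traits = crowds, methods = instruments), ordered
#' photo-grid crowds then mindset crowds, with the subscale reliabilities
#' (McDonald's omega) on the diagonal.
#'
#' @param scored Scored respondent table from [score_cohort()]; needs at
#'   least 3 complete respondents.
#' @param reliabilities Either a data frame from [reliability_table()] or a
#'   named 10-vector in matrix label order. `NA` diagonal entries are
#'   permitted (e.g. if a subscale fit failed).
#' @return An object of class `mtmm_matrix`.
#' @export
build_mtmm <- function(scored, reliabilities) {
  labels <- mtmm_labels()
  cols <- paste0(labels$method, "_", tolower(labels$crowd))
  missing <- setdiff(cols, names(scored))
  if (length(missing)) {
    stop("scored table lacks crowd score columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- scored[cols]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) {
    stop("insufficient data: fewer than 3 complete respondents", call. = FALSE)
  }
  if (is.data.frame(reliabilities)) {
    key <- paste0(reliabilities$instrument, "_", tolower(reliabilities$crowd))
    omega <- reliabilities$omega[match(cols, key)]
  } else {
    omega <- as.numeric(reliabilities)
    if (length(omega) != 10) {
      stop("reliabilities must supply 10 omega values", call. = FALSE)
    }
  }
  r <- matrix(NA_real_, 10, 10)
  p <- matrix(NA_real_, 10, 10)
  for (i in 1:10) {
    for (j in seq_len(i - 1)) {
      est <- pearson_with_p(x[[i]], x[[j]])
      r[i, j] <- r[j, i] <- est$r
      p[i, j] <- p[j, i] <- est$p
    }
  }
  new_mtmm_matrix(r, p, omega)
}

#' @export
print.mtmm_matrix <- function(x, digits = 2, ...) {
  m <- round(x$correlations, digits)
  cat("<mtmm_matrix> 10x10, diagonal = McDonald's omega\n")
  print(m)
  invisible(x)
}

#' Evaluate convergent and discriminant validity
#'
#' Applies the decision rules to a complete MTMM. Convergent validity passes
#' for a crowd iff the correlation between its two instruments' scores is
#' positive and significant at `alpha`. Every other off-diagonal cell
#' satisfies discriminant validity if it is non-significant, significantly
#' negative, or significantly positive but strictly weaker than *both*
#' convergent coefficients of the crowds it involves; otherwise it is
#' recorded as a violation (each violation lists which convergent
#' coefficient(s) it fails against).
#'
#' @param matrix An `mtmm_matrix` (from [build_mtmm()] or
#'   [mtmm_table3_fixture()]).
#' @param alpha Two-sided significance level (default 0.05, matching the
#'   weakest printed significance marker; no multiplicity correction).
#' @return Object of class `validity_report`: `convergent` (per-crowd data
#'   frame with `r`, `p`, `pass`), `violations` (data frame of offending
#'   cells), `n_convergent_pass`, `n_violations`, `alpha`.
#' @export
evaluate_validity <- function(matrix, alpha = 0.05) {
  stopifnot(inherits(matrix, "mtmm_matrix"), alpha > 0, alpha < 1)
  labels <- matrix$labels
  r <- matrix$correlations
  p <- matrix$p_values
  off <- upper.tri(r)
  if (anyNA(r[off]) || anyNA(p[off])) {
    stop("MTMM has missing off-diagonal cells", call. = FALSE)
  }
  crowds <- peer_crowds()
  conv_idx <- cbind(match(paste0("IBase.", crowds), labels$label),
                    match(paste0("VMLS.", crowds), labels$label))
  conv <- data.frame(
    crowd = crowds,
    r = r[conv_idx],
    p = p[conv_idx],
    stringsAsFactors = FALSE
  )
  conv$pass <- conv$r > 0 & conv$p < alpha
  conv_r <- stats::setNames(conv$r, crowds)

  viol <- list()
  for (i in 1:10) {
    for (j in seq_len(i - 1)) {
      ci <- labels$crowd[i]; cj <- labels$crowd[j]
      if (ci == cj && labels$method[i] != labels$method[j]) next  # convergent cell
      if (!(p[i, j] < alpha) || r[i, j] <= 0) next
      against <- unique(c(ci, cj))
      fails <- against[r[i, j] >= conv_r[against]]
      if (length(fails)) {
        viol[[length(viol) + 1]] <- data.frame(
          cell_row = labels$label[i], cell_col = labels$label[j],
          r = r[i, j],
          fails_against = paste(
            sprintf("%s (convergent r = %.2f)", fails, conv_r[fails]),
            collapse = "; "),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else {
    data.frame(cell_row = character(), cell_col = character(),
               r = numeric(), fails_against = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(convergent = conv, violations = violations,
                 n_convergent_pass = sum(conv$pass),
                 n_violations = nrow(violations), alpha = alpha),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> alpha = %g\n", x$alpha))
  cat(sprintf("Convergent validity: %d/5 crowds pass\n", x$n_convergent_pass))
  print(transform(x$convergent, r = round(r, 3),
                  p = signif(p, 3)), row.names = FALSE)
  if (x$n_violations == 0) {
    cat("No discriminant validity violations.\n")
  } else {
    cat(sprintf("Discriminant validity violations (%d):\n", x$n_violations))
    print(transform(x$violations, r = round(r, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Read/write an MTMM as CSV
#'
#' The CSV is a 10x10 layout with a label header row and column; the
#' diagonal holds omega (flagged by the `diagonal` column name convention in
#' the first cell). P-values are written as a second block beneath the
#' correlations.
#'
#' @param matrix An `mtmm_matrix`.
#' @param path File path.
#' @return `write_mtmm_csv`: `path` invisibly. `read_mtmm_csv`: an
#'   `mtmm_matrix`.
#' @export
write_mtmm_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "mtmm_matrix"))
  r <- as.data.frame(matrix$correlations)
  p <- as.data.frame(matrix$p_values)
  r <- cbind(data.frame(label.diag_is_omega = rownames(r)), r)
  p <- cbind(data.frame(label.diag_is_omega = rownames(p)), p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# correlations (diagonal = McDonald's omega)", con)
  utils::write.csv(r, con, row.names = FALSE)
  writeLines("# p-values", con)
  utils::write.csv(p, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mtmm_csv
#' @export
read_mtmm_csv <- function(path) {
  lines <- readLines(path)
  marks <- grep("^#", lines)
  stopifnot(length(marks) == 2)
  block <- function(from, to) {
    df <- utils::read.csv(text = paste(lines[from:to], collapse = "\n"),
                          check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    m
  }
  r <- block(marks[1] + 1, marks[2] - 1)
  p <- block(marks[2] + 1, length(lines))
  new_mtmm_matrix(r, p, diag(r))
}

#' The published validation study's printed MTMM
#'
#' Loads the packaged fixture transcribing the published 10x10 matrix:
#' correlations, significance markers, and the omega diagonal. Markers are
#' mapped to representative p-value bounds (`***` below 0.001, `**` below
#' 0.01, `*` below 0.05, none = non-significant) since exact p-values are
#' not printed.
#'
#' @return An `mtmm_matrix` carrying the printed values.
#' @export
#' @examples
#' evaluate_validity(mtmm_table3_fixture())
mtmm_table3_fixture <- function() {
  path <- system.file("extdata", "published_mtmm.csv", package = "peercrowds")
  stopifnot(nzchar(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- mtmm_labels()
  r <- matrix(NA_real_, 10, 10)
  p <- matrix(NA_real_, 10, 10)
  omega <- numeric(10)
  marker_p <- c("***" = 5e-4, "**" = 5e-3, "*" = 0.025, "ns" = 0.5)
  for (row in seq_len(nrow(df))) {
    i <- match(df$row_label[row], labels$label)
    j <- match(df$col_label[row], labels$label)
    if (is.na(i) || is.na(j)) {
      stop("unknown label in MTMM fixture: ",
           df$row_label[row], " / ", df$col_label[row], call. = FALSE)
    }
    if (i == j) {
      omega[i] <- df$value[row]
    } else {
      r[i, j] <- r[j, i] <- df$value[row]
      p[i, j] <- p[j, i] <- marker_p[[df$marker[row]]]
    }
  }
  new_mtmm_matrix(r, p, omega)
}
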