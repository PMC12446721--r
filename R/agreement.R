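#' Cross-tabulate two raters' binary diagnoses
#'
#' Builds the 2x2 agreement table between two raters over the same
#' participants (rows = rater A +/-, columns = rater B +/-). Pairs with a
#' missing rating on either side are dropped pairwise; the number dropped
#' is recorded.
#'
#' @param dx_a,dx_b Binary (0/1) vectors of equal length, one entry per
#'   participant; NA = missing rating.
#' @param raters Length-2 character vector naming the raters.
#' @return An object of class `agreement_table`: 2x2 integer matrix
#'   (counts for ++, +-, -+, --) with attributes `raters` and
#'   `n_dropped`.
#' @export
cross_tabulate <- function(dx_a, dx_b, raters = c("rater_a", "rater_b")) {
  if (length(dx_a) != length(dx_b)) {
    stop_scaleval("rating vectors must have equal length")
  }
  keep <- !is.na(dx_a) & !is.na(dx_b)
  a <- dx_a[keep]
  b <- dx_b[keep]
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop_scaleval("ratings must be binary 0/1")
  }
  m <- matrix(c(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
                sum(a == 0 & b == 1), sum(a == 0 & b == 0)),
              2, 2, byrow = TRUE,
              dimnames = list(paste0(raters[1], c(" +", " -")),
                              paste0(raters[2], c(" +", " -"))))
  structure(m, class = c("agreement_table", "matrix"),
            raters = raters, n_dropped = sum(!keep))
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("Agreement between", attr(x, "raters")[1], "and",
      attr(x, "raters")[2], "\n")
  print(unclass(x)[, , drop = FALSE])
  if (attr(x, "n_dropped") > 0) {
    cat("  (", attr(x, "n_dropped"), " pairs dropped for missing ratings)\n",
        sep = "")
  }
  invisible(x)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, where
#' `p_o` is observed agreement and `p_e` the agreement expected under
#' independent raters with the observed margins. Returns `NA` with a
#' warning when `p_e = 1` (both raters constant), where kappa is
#' undefined.
#'
#' @param table An [cross_tabulate()] result or plain 2x2 count matrix.
#' @return Kappa in \[-1, 1\], or `NA` if undefined.
#' @examples
#' cohen_kappa(cross_tabulate(c(1, 1, 0, 0), c(1, 0, 1, 0)))  # 0
#' @export
cohen_kappa <- function(table) {
  m <- unclass(as.matrix(table))
  if (!identical(dim(m), c(2L, 2L)) || any(m < 0)) {
    stop_scaleval("need a 2x2 matrix of non-negative counts")
  }
  n <- sum(m)
  if (n == 0) stop_scaleval("empty agreement table")
  p_o <- (m[1, 1] + m[2, 2]) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    warning("kappa undefined: expected agreement is 1 (constant raters)")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}
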