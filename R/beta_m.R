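#' Convert methylation beta-values to M-values
#'
#' The M-value is the variance-stabilized logit-like transform
#' \eqn{M = \log_2(\beta / (1 - \beta))} of a methylation fraction
#' \eqn{\beta \in (0, 1)}. Works elementwise on vectors and matrices,
#' preserving dimensions and dimnames.
#'
#' @param beta Numeric vector or matrix of beta-values, strictly in (0, 1).
#' @return M-values with the same shape as `beta`.
#' @seealso [m_to_beta()] for the inverse transform.
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' @export
beta_to_m <- function(beta) {
  if (!is.numeric(beta)) stop("beta must be numeric")
  bad <- which(!is.finite(beta) | beta <= 0 | beta >= 1)
  if (length(bad) > 0L) {
    stop("beta-values must lie strictly in (0, 1); offending entries: ",
         describe_entries(beta, bad))
  }
  log2(beta / (1 - beta))
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: \eqn{\beta = 2^M / (2^M + 1)}, computed in a
#' form stable for large |M|.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values in (0, 1) with the same shape as `m`.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("m must be numeric")
  if (anyNA(m)) stop("missing values in m")
  stats::plogis(m * log(2))
}

# human-readable coordinates of offending matrix/vector entries
describe_entries <- function(x, idx, max_show = 5L) {
  idx <- utils::head(idx, max_show)
  if (is.matrix(x)) {
    rc <- arrayInd(idx, dim(x))
    rn <- rownames(x) %||% as.character(seq_len(nrow(x)))
    cn <- colnames(x) %||% as.character(seq_len(ncol(x)))
    paste(sprintf("[sample %s, feature %s]", rn[rc[, 1L]], cn[rc[, 2L]]),
          collapse = ", ")
  } else {
    nm <- names(x) %||% as.character(seq_along(x))
    paste(nm[idx], collapse = ", ")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
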