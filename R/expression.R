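# Expression transforms and tissue-specificity classification.
#
# Expression is classified from FPKM with explicit thresholds: "low" when
# no tissue reaches the expressed cutoff, "specific" when the tau index
# (computed on log2(x + 1) values) reaches its cutoff in an expressed
# gene, "ubiquitous" when every tissue is expressed with low tau, and
# "intermediate" otherwise.

#' log2-transform an expression matrix
#'
#' Each value `x` becomes `log2(x + pseudo)`.
#'
#' @param mat Non-negative numeric matrix (genes x tissues).
#' @param pseudo Positive pseudo-count (default 1).
#' @return Transformed matrix of the same shape.
#' @export
log2_transform <- function(mat, pseudo = 1) {
  if (!is_number(pseudo) || pseudo <= 0)
    stop("pseudo must be > 0", call. = FALSE)
  if (any(mat < 0)) stop("expression values must be >= 0", call. = FALSE)
  log2(mat + pseudo)
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i(1 - x_i / x_max) / (n - 1)`: 0 for a uniform profile, 1
#' for single-tissue expression. Undefined (NA with a warning) for an
#' all-zero profile.
#'
#' @param profile Numeric vector of `n >= 2` non-negative values.
#' @return tau in \[0, 1\], or `NA` for an all-zero profile.
#' @export
tau_specificity <- function(profile) {
  if (length(profile) < 2L) stop("profile needs >= 2 tissues", call. = FALSE)
  if (any(profile < 0)) stop("profile values must be >= 0", call. = FALSE)
  mx <- max(profile)
  if (mx == 0) {
    warning("all-zero profile: tau undefined")
    return(NA_real_)
  }
  sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Classify expression as specific, ubiquitous, low or intermediate
#'
#' Calls, in order of precedence: `low` if every FPKM is below
#' `expressed_fpkm`; `specific` if tau (on the log2(x+1) profile) reaches
#' `tau_specific` and the maximal tissue is expressed; `ubiquitous` if
#' every tissue is expressed and tau is below the cutoff; otherwise
#' `intermediate`. Exactly one call per gene.
#'
#' @param mat FPKM matrix (genes x tissues).
#' @param expressed_fpkm Expressed threshold in FPKM units (default 1).
#' @param tau_specific Specificity cutoff on tau (default 0.85).
#' @return `data.frame`: `gene_id`, `tau`, `max_tissue`, `max_fpkm`,
#'   `call`, in input row order.
#' @export
classify_expression <- function(mat, expressed_fpkm = 1, tau_specific = 0.85) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 2L)
  lg <- log2_transform(mat, 1)
  out <- lapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    mx_i <- which.max(x)
    tau <- if (max(x) == 0) NA_real_ else tau_specificity(lg[i, ])
    call <- if (all(x < expressed_fpkm)) "low"
    else if (!is.na(tau) && tau >= tau_specific && x[mx_i] >= expressed_fpkm)
      "specific"
    else if (all(x >= expressed_fpkm) && !is.na(tau) && tau < tau_specific)
      "ubiquitous"
    else "intermediate"
    data.frame(gene_id = rownames(mat)[i], tau = tau,
               max_tissue = colnames(mat)[mx_i], max_fpkm = unname(x[mx_i]),
               call = call, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
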