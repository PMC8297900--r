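#' Four-way attachment codes and their binary collapses
#'
#' Attachment in middle childhood is coded four ways: B (secure),
#' A (insecure avoidant), C (insecure ambivalent) and D (insecure
#' disorganised). Two standard binary collapses exist: secure vs insecure
#' (B vs A/C/D) and organised vs disorganised (B/A/C vs D).
#'
#' @return `attachment_levels()` returns the canonical code order
#'   `c("B","A","C","D")`, the row/column order used throughout for
#'   confusion matrices.
#' @export
attachment_levels <- function() c("B", "A", "C", "D")

#' @rdname attachment_levels
#' @param label character vector of four-way codes.
#' @return `is_secure()` / `is_organised()` return logical vectors.
#' @export
is_secure <- function(label) {
  check_fourway(label)
  label == "B"
}

#' @rdname attachment_levels
#' @export
is_organised <- function(label) {
  check_fourway(label)
  label != "D"
}

#' @rdname attachment_levels
#' @return `binary_label()` projects four-way codes onto
#'   `"secure"`/`"insecure"`.
#' @export
binary_label <- function(label) {
  ifelse(is_secure(label), "secure", "insecure")
}

check_fourway <- function(label) {
  bad <- !(label %in% attachment_levels())
  if (any(bad)) {
    stop("invalid attachment code(s): ",
         paste(unique(label[bad]), collapse = ", "),
         " (expected one of B, A, C, D)", call. = FALSE)
  }
  invisible(label)
}

#' Build a confusion (cross-tabulation) matrix from paired codings
#'
#' Counts `counts[i, j]` = number of cases rated `levels[i]` by the first
#' rater/measure and `levels[j]` by the second.
#'
#' @param first,second equal-length vectors of categorical codes.
#' @param levels category order; defaults to the union of observed codes
#'   (or the canonical ABCD order when all codes are attachment codes).
#' @return an integer matrix with dimnames, class `"attachkin_confusion"`.
#' @export
pair_to_confusion <- function(first, second, levels = NULL) {
  if (length(first) == 0L) stop("no label pairs supplied", call. = FALSE)
  if (length(first) != length(second))
    stop("label vectors have different lengths", call. = FALSE)
  if (is.null(levels)) {
    obs <- unique(c(as.character(first), as.character(second)))
    levels <- if (all(obs %in% attachment_levels()))
      intersect(attachment_levels(), obs) else sort(obs)
  }
  f <- factor(first, levels = levels)
  s <- factor(second, levels = levels)
  if (anyNA(f) || anyNA(s))
    stop("labels outside the supplied category set", call. = FALSE)
  cm <- table(f, s)
  as_confusion(matrix(as.integer(cm), nrow = length(levels),
                      dimnames = list(levels, levels)))
}

as_confusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (any(m < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  if (sum(m) <= 0) stop("confusion matrix has zero total count", call. = FALSE)
  storage.mode(m) <- "integer"
  class(m) <- c("attachkin_confusion", class(m))
  m
}

#' Collapse a 4x4 ABCD confusion matrix onto a binary scheme
#'
#' Merges rows and columns of an ABCD cross-tabulation (order B, A, C, D)
#' into a 2x2 matrix: `"secure-insecure"` merges A, C and D;
#' `"organised-disorganised"` merges B, A and C. The total count is
#' preserved.
#'
#' @param cm 4x4 matrix in (B, A, C, D) order.
#' @param scheme collapse rule.
#' @return 2x2 `"attachkin_confusion"` matrix.
#' @export
collapse_confusion <- function(cm,
                               scheme = c("secure-insecure",
                                          "organised-disorganised")) {
  scheme <- match.arg(scheme)
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(4L, 4L)))
    stop("expected a 4x4 ABCD matrix in (B, A, C, D) order", call. = FALSE)
  groups <- if (scheme == "secure-insecure") {
    list(secure = 1L, insecure = 2:4)
  } else {
    list(organised = 1:3, disorganised = 4L)
  }
  out <- matrix(0L, 2L, 2L, dimnames = list(names(groups), names(groups)))
  for (i in 1:2) for (j in 1:2)
    out[i, j] <- sum(cm[groups[[i]], groups[[j]]])
  as_confusion(out)
}

#' Percent agreement and discordance of a confusion matrix
#'
#' Observed agreement is the diagonal mass: `100 * trace / N`. The value is
#' kept at full precision; rounding to the nearest integer percent happens
#' only in the print method.
#'
#' @param cm square confusion matrix of counts.
#' @return list of class `"agreement_result"` with `n`, `agreeing`,
#'   `discordant`, `percent_agreement` (full precision) and `kappa`.
#' @export
percent_agreement <- function(cm) {
  cm <- as_confusion(cm)
  n <- sum(cm)
  agreeing <- sum(diag(cm))
  structure(
    list(n = n, agreeing = agreeing, discordant = n - agreeing,
         percent_agreement = 100 * agreeing / n,
         kappa = cohen_kappa(cm)),
    class = "agreement_result")
}

#' Cohen's kappa for a square confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_o} the observed diagonal proportion and \eqn{p_e} the expected
#' agreement under independent marginals,
#' \eqn{p_e = \sum_i r_i c_i / N^2}.
#'
#' @param cm square matrix of counts with at least one nonzero marginal
#'   per side.
#' @return kappa in \[-1, 1\]; `NaN` with a warning when \eqn{p_e = 1}
#'   (all mass in a single cell on both margins).
#' @export
cohen_kappa <- function(cm) {
  cm <- as_confusion(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa undefined", call. = FALSE)
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("n = %d, agreement %d%%, discordant %d, kappa %.2f\n",
              x$n, round(x$percent_agreement), x$discordant, x$kappa))
  invisible(x)
}

#' Agreement report for an ABCD confusion matrix under every scheme
#'
#' Convenience wrapper: computes percent agreement, discordance and
#' Cohen's kappa for the full four-way matrix and for both binary
#' collapses.
#'
#' @param cm 4x4 ABCD matrix in (B, A, C, D) order.
#' @return named list of `agreement_result` objects:
#'   `four_way`, `secure_insecure`, `organised_disorganised`.
#' @export
agreement_report <- function(cm) {
  cm <- as_confusion(cm)
  list(
    four_way = percent_agreement(cm),
    secure_insecure = percent_agreement(
      collapse_confusion(cm, "secure-insecure")),
    organised_disorganised = percent_agreement(
      collapse_confusion(cm, "organised-disorganised")))
}

#' Expand a confusion matrix back into label pairs
#'
#' Inverse of [pair_to_confusion()] up to ordering; used by brute-force
#' recomputation oracles.
#'
#' @param cm square matrix of counts with dimnames.
#' @return data.frame with columns `first`, `second`.
#' @export
confusion_to_pairs <- function(cm) {
  cm <- as.matrix(cm)
  lv <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  idx <- which(cm > 0, arr.ind = TRUE)
  first <- rep(lv[idx[, 1]], cm[idx])
  second <- rep(lv[idx[, 2]], cm[idx])
  data.frame(first = first, second = second, stringsAsFactors = FALSE)
}

#' Read / write a labelled confusion matrix as CSV
#'
#' The CSV has category names in the first column and as the header row.
#'
#' @param path file path.
#' @return `read_confusion_csv()` returns an `"attachkin_confusion"` matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion(as.matrix(df))
}

#' @rdname read_confusion_csv
#' @param cm confusion matrix to write.
#' @export
write_confusion_csv <- function(cm, path) {
  write.csv(as.data.frame(as.matrix(cm)), path, row.names = TRUE)
  invisible(path)
}

#' Published SAM-vs-MCAST concordance counts
#'
#' The 4x4 cross-tabulation (rows: SAM manual codings; columns: MCAST
#' codings; order B, A, C, D) for the 61 children rated on both the
#' doll-play MCAST and its computerised delivery, shipped as a labelled CSV
#' under `extdata`. Used as the worked example for the agreement module.
#'
#' @return an `"attachkin_confusion"` 4x4 matrix, N = 61.
#' @export
sam_mcast_concordance <- function() {
  read_confusion_csv(system.file("extdata", "sam_mcast_concordance.csv",
                                 package = "attachkin", mustWork = TRUE))
}
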